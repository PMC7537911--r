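test_that("parameter constructor validates and records provenance", {
  p <- caru_params()
  expect_s3_class(p, "caru_params")
  expect_equal(p$v, p$v_i + p$v_sr + p$v_d)
  expect_equal(p$v / p$v_sr, 45.6, tolerance = 1e-12)
  expect_equal(p$g * p$tau_i / p$K_o^2, 1 / 1120, tolerance = 1e-12)
  expect_equal(p$k_m / p$k_p, p$K_o^2, tolerance = 1e-12)
  expect_error(caru_params(K_o = -1), "positive")
  expect_error(caru_params(B_b = -5), "negative")
  expect_error(caru_params(tau_i = 0), "positive")
  prov <- param_provenance()
  expect_setequal(prov[c("K_o", "B_b", "K_b", "K_SQ")], "PAPER")
  expect_true(all(prov[c("g", "g_up", "K_s", "v_sr")] == "DERIVED"))
})

test_that("parameter files round-trip and reject malformed input", {
  p <- caru_params(B_SQ = 2000)
  f <- withr::local_tempfile(fileext = ".txt")
  write_params(p, f)
  q <- read_params(f)
  for (n in names(p)) expect_equal(q[[n]], p[[n]], tolerance = 1e-14)
  ship <- system.file("extdata", "control_params.txt", package = "caosc")
  expect_true(nzchar(ship))
  pc <- read_params(ship)
  expect_equal(pc$K_o, 15)
  expect_equal(pc$B_b, 80)
  writeLines(c("g = 1", "oops"), f)
  expect_error(read_params(f), "malformed")
  writeLines("g = 1", f)
  expect_error(read_params(f), "missing")
})

test_that("free/total SR calcium invert each other and match a bisection oracle", {
  p0 <- caru_params(B_SQ = 0)
  x <- c(0, 10, 1e3, 1e4)
  expect_equal(free_sr_calcium(x, p0), x) # no buffer: identity
  expect_equal(total_sr_calcium(x, p0), x)

  p <- caru_params(B_SQ = 2000, K_SQ = 650)
  # frozen from the independent bisection oracle (tolerance 1e-10 relative)
  oracle <- bisect_free_sr(3000, 2000, 650)
  expect_equal(free_sr_calcium(3000, p), oracle, tolerance = 1e-10)
  expect_equal(free_sr_calcium(0, p), 0)
  # round trip at several magnitudes
  for (y in c(10, 1e3, 1e4)) {
    expect_equal(total_sr_calcium(free_sr_calcium(y, p), p), y,
                 tolerance = 1e-12)
  }
  expect_error(free_sr_calcium(-1, p), "nonnegative")
  expect_error(total_sr_calcium(-1, p), "nonnegative")
})

test_that("free SR calcium is monotone and within its mass bounds", {
  p <- caru_params(B_SQ = 5000)
  ct <- seq(0, 3e4, length.out = 300)
  fr <- free_sr_calcium(ct, p)
  expect_true(all(diff(fr) > 0))
  expect_true(all(fr <= ct + 1e-9))
  expect_true(all(fr >= pmax(0, ct - p$B_SQ) - 1e-9))
  cs <- seq(0, 1e4, length.out = 200)
  expect_true(all(diff(total_sr_calcium(cs, p)) > 0))
})

test_that("cytosolic closure solves the conservation quadratic exactly", {
  p <- caru_params()
  # all calcium in the SR: c_i = 0
  expect_equal(solve_cytosolic(54, 0, p$v * 54 / p$v_sr, p), 0,
               tolerance = 1e-12)
  # no cytosolic buffer: linear budget
  p_nb <- caru_params(B_b = 0)
  ci_lin <- (p_nb$v * 54 - p_nb$v_d * 3 - p_nb$v_sr * 2000) / p_nb$v_i
  expect_equal(solve_cytosolic(54, 3, 2000, p_nb), ci_lin, tolerance = 1e-12)
  # control parameters, arbitrary feasible states: residual check
  set.seed(42)
  for (k in 1:20) {
    cd <- runif(1, 0, 50)
    csrtot <- runif(1, 0, (p$v * 54 - p$v_d * cd) / p$v_sr)
    ci <- solve_cytosolic(54, cd, csrtot, p)
    expect_gte(ci, 0)
    expect_equal(total_cell_calcium(ci, cd, csrtot, p), 54,
                 tolerance = 1e-10)
  }
  expect_error(solve_cytosolic(10, 0, p$v * 54 / p$v_sr, p),
               class = "caosc_infeasible_state")
})

test_that("load_spec converts between average load and total content", {
  p <- caru_params()
  ls <- load_spec(54, p)
  expect_equal(ls$Q_T, 54 * (p$v_i + p$v_sr))
  expect_error(load_spec(-1, p), "nonnegative")
})
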