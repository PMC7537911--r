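test_that("right-hand sides honour their defining identities", {
  p <- ctrl
  # rest state: everything in the SR, all derivatives vanish
  for (v in c("three_var", "fast_ryr")) {
    st <- switch(v, three_var = c(0, ctrl$v * 54 / ctrl$v_sr, 0),
                 fast_ryr = c(0, ctrl$v * 54 / ctrl$v_sr))
    r <- caru_rhs(v, st, 54, p)
    expect_equal(r$deriv, rep(0, length(st)), tolerance = 1e-12)
    expect_equal(r$c_i, 0, tolerance = 1e-12)
  }
  # no release, no uptake: SR frozen, dyad relaxes to the cytosol
  p0 <- caru_params(g = 0, g_up = 0)
  r <- caru_rhs("three_var", c(10, 2000, 0.3), 54, p0)
  expect_equal(r$deriv[2], 0)
  expect_equal(r$deriv[1], -(10 - r$c_i) / p0$tau_i)
  # half-activation: release prefactor is g/2 at c_d = K_o
  r <- caru_rhs("fast_ryr", c(p$K_o, 2000), 54, p)
  expect_equal(r$P_o, 0.5)
  # mass conservation by construction: volume-weighted derivative sum is 0,
  # with the cytosolic rate from implicit differentiation of the closure
  set.seed(1)
  for (k in 1:5) {
    st <- c(runif(1, 0, 40), runif(1, 500, 2200))
    r <- caru_rhs("fast_ryr", st, 54, p)
    h <- 1e-3
    stp <- st + h * r$deriv
    cip <- solve_cytosolic(54, stp[1], stp[2], p)
    ci_dot <- (cip - r$c_i) / h
    buf <- 1 + p$B_b * p$K_b / (p$K_b + r$c_i)^2 # bound-buffer slope
    expect_equal(p$v_d * r$deriv[1] + p$v_sr * r$deriv[2] +
                   p$v_i * buf * ci_dot, 0, tolerance = 1e-4)
  }
})

test_that("fast-RyR reduction equals the three-variable model on the slaved manifold", {
  set.seed(7)
  for (k in 1:5) {
    cd <- runif(1, 0, 60)
    csrtot <- runif(1, 300, 2300)
    po <- cd^2 / (ctrl$K_o^2 + cd^2)
    r2 <- caru_rhs("fast_ryr", c(cd, csrtot), 54, ctrl)
    r3 <- caru_rhs("three_var", c(cd, csrtot, po), 54, ctrl)
    expect_equal(r2$deriv, r3$deriv[1:2], tolerance = 1e-12)
  }
})

test_that("fast-dyadic slaving algebra is consistent", {
  p <- ctrl
  # P_o = 0: no release path, c_d collapses onto c_i, gate opens as k_p c_d^2
  r <- caru_rhs("fast_dyadic", c(2000, 0), 54, p)
  expect_equal(r$c_d, r$c_i, tolerance = 1e-12)
  expect_equal(r$deriv[2], p$k_p * r$c_d^2, tolerance = 1e-12)
  # when c_i equals c_sr the slaved c_d equals both, for any P_o
  # (construct the load that puts the cytosol at the SR concentration)
  csr <- 30
  ct <- (p$v_i * (csr + p$B_b * csr / (p$K_b + csr)) + p$v_d * csr +
           p$v_sr * csr) / p$v
  for (po in c(0.2, 0.8)) {
    r <- caru_rhs("fast_dyadic", c(csr, po), ct, p)
    expect_equal(r$c_d, csr, tolerance = 1e-9)
  }
  expect_error(caru_rhs("fast_dyadic", c(100, 0.5), 54,
                        caru_params(B_SQ = 1000)), "B_SQ")
})

test_that("deterministic integration reproduces the three load regimes", {
  # low load: decays to the closed-RyR rest state
  lo <- integrate_caru("fast_ryr", 32, ctrl, t_end = 30000)
  expect_lt(max(tail(lo$c_i, 100)), 0.02)
  # intermediate load: sustained oscillation after the transient
  mid <- integrate_caru("fast_ryr", 54, ctrl, t_end = 45000)
  expect_true(as.logical(sustained_oscillation(mid)))
  # high load: settles on the high-cytosolic / depleted-SR state
  hi <- integrate_caru("fast_ryr", 75, ctrl, t_end = 30000)
  tail_ci <- tail(hi$c_i, 100)
  expect_lt(diff(range(tail_ci)), 1e-3)
  expect_gt(mean(tail_ci), 1)
  # trace invariants
  for (tr in list(lo, mid, hi)) {
    expect_true(all(diff(tr$t_ms) > 0))
    expect_lt(mass_drift(tr), 1e-8)
  }
})

test_that("mass is conserved along trajectories of every variant", {
  for (v in c("three_var", "fast_ryr", "fast_dyadic")) {
    tr <- integrate_caru(v, 54, ctrl, t_end = 10000)
    expect_lt(mass_drift(tr), 1e-8)
  }
  trq <- integrate_caru("fast_ryr", 80, caru_params(B_SQ = 2000),
                        t_end = 10000)
  expect_lt(mass_drift(trq), 1e-8)
  trs <- integrate_caru("fast_ryr", 45, ctrl, t_end = 10000, sigma = 2e-3,
                        seed = 5)
  expect_lt(mass_drift(trs), 1e-8)
})

test_that("adaptive integration is converged at its tolerances", {
  for (ct in c(32, 75, 54)) {
    t_end <- if (ct == 54) 2000 else 20000
    a <- integrate_caru("fast_ryr", ct, ctrl, t_end = t_end)
    b <- integrate_caru("fast_ryr", ct, ctrl, t_end = t_end,
                        rtol = 5e-9, atol = 5e-11)
    fin_a <- unlist(a[nrow(a), c("c_d", "c_sr_tot")])
    fin_b <- unlist(b[nrow(b), c("c_d", "c_sr_tot")])
    expect_lt(max(abs(fin_a - fin_b) / pmax(abs(fin_b), 1e-6)), 1e-6)
  }
})

test_that("RyR noise is unbiased uniform with the stated spread", {
  set.seed(11)
  cd <- rep(10, 2e5)
  det <- 100 / (ctrl$K_o^2 + 100)
  expect_equal(stochastic_po(cd[1], 0, ctrl), det)
  sig <- 2e-3
  draws <- stochastic_po(cd, sig, ctrl)
  expect_true(all(draws >= 0 & draws <= 1))
  expect_equal(mean(draws), det, tolerance = 1e-4)
  expect_equal(sd(draws), sig / sqrt(12), tolerance = 0.02)
  # clamping at the boundary
  expect_true(all(stochastic_po(rep(0, 1000), 2e-3, ctrl) >= 0))
})

test_that("sigma = 0 fixed-step runs equal an R-side Euler reference", {
  p <- ctrl
  dt <- 0.1
  tr <- integrate_caru("fast_ryr", 54, p, t_end = 10, sigma = 0,
                       method = "euler", dt = dt, sample_dt = dt)
  st <- c(unname(default_initial_state(54, p)[c("c_d", "c_sr_tot")]))
  ref <- matrix(NA_real_, nrow(tr), 2)
  ref[1, ] <- st
  for (i in 2:nrow(tr)) {
    d <- caru_rhs("fast_ryr", st, 54, p)$deriv
    st <- pmax(st + dt * d, 0)
    ref[i, ] <- st
  }
  expect_equal(tr$c_d, ref[, 1], tolerance = 1e-12)
  expect_equal(tr$c_sr_tot, ref[, 2], tolerance = 1e-12)
})

test_that("stochastic runs are reproducible and agree with deterministic periods above onset", {
  a <- integrate_caru("fast_ryr", 45, ctrl, t_end = 3000, sigma = 2e-3,
                      seed = 7)
  b <- integrate_caru("fast_ryr", 45, ctrl, t_end = 3000, sigma = 2e-3,
                      seed = 7)
  expect_identical(a$c_d, b$c_d)
  md <- trace_metadata(a)
  expect_equal(md$settings$dt, 0.1)
  expect_equal(md$sigma, 2e-3)
  # above the deterministic onset the noise barely perturbs the cycle
  det <- estimate_period(integrate_caru("fast_ryr", 54, ctrl,
                                        t_end = 45000))$period_ms
  sto <- estimate_period(integrate_caru("fast_ryr", 54, ctrl, t_end = 45000,
                                        sigma = 2e-3, seed = 3))$period_ms
  expect_lt(abs(sto - det) / det, 0.1)
})
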