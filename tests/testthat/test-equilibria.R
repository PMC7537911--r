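test_that("equilibrium residual has the documented root structure", {
  # the rest state is a root at every load
  expect_equal(equilibrium_residual(0, 32, ctrl), 0)
  expect_equal(equilibrium_residual(0, 100, ctrl), 0)
  # one/three/three fixed points at the reference loads
  expect_equal(nrow(find_fixed_points(32, ctrl)), 1L)
  expect_equal(nrow(find_fixed_points(54, ctrl)), 3L)
  expect_equal(nrow(find_fixed_points(75, ctrl)), 3L)
  expect_error(equilibrium_residual(1e5, 54, ctrl), "infeasible")
})

test_that("fixed points are accurate and labelled consistently", {
  for (ct in c(32, 54, 75)) {
    fp <- find_fixed_points(ct, ctrl)
    expect_true(all(fp$residual < 1e-9))
    expect_equal(fp$branch[1], "lower")
    expect_true(all(diff(fp$c_i) > 0))
    # every state satisfies conservation
    rec <- total_cell_calcium(fp$c_i, fp$c_d, fp$c_sr_tot, ctrl)
    expect_equal(rec, rep(ct, nrow(fp)), tolerance = 1e-9)
  }
  fp54 <- find_fixed_points(54, ctrl)
  expect_match(fp54$class[1], "stable")
  expect_true(all(fp54$class[2:3] %in%
                    c("saddle", "unstable_node", "unstable_spiral")))
  fp75 <- find_fixed_points(75, ctrl)
  expect_match(fp75$class[3], "^stable")
  expect_equal(fp75$branch, c("lower", "intermediate", "upper"))
})

test_that("the rest state is stable at every tested load", {
  for (ct in seq(20, 120, by = 20)) {
    fp <- find_fixed_points(ct, ctrl)
    expect_match(fp$class[1], "^stable", info = paste("load", ct))
  }
})

test_that("stability classes predict local simulation behaviour", {
  # stable upper point at 75: a small perturbation decays
  fp <- find_fixed_points(75, ctrl)
  up <- fp[3, ]
  tr <- integrate_caru("fast_ryr", 75, ctrl, t_end = 5000,
                       init = c(up$c_d * 1.02, up$c_sr_tot),
                       sample_dt = 1)
  d0 <- abs(tr$c_d[1] - up$c_d)
  expect_lt(abs(tail(tr$c_d, 1) - up$c_d), 0.1 * d0)
  # unstable upper point at 54: the same perturbation grows
  fp <- find_fixed_points(54, ctrl)
  up <- fp[3, ]
  tr <- integrate_caru("fast_ryr", 54, ctrl, t_end = 5000,
                       init = c(up$c_d * 1.02, up$c_sr_tot),
                       sample_dt = 1)
  expect_gt(max(abs(tr$c_d - up$c_d)), 10 * abs(tr$c_d[1] - up$c_d))
})

test_that("all variants share the same fixed points", {
  fp_ryr <- find_fixed_points(54, ctrl, variant = "fast_ryr")
  fp_3v <- find_fixed_points(54, ctrl, variant = "three_var")
  fp_fd <- find_fixed_points(54, ctrl, variant = "fast_dyadic")
  expect_equal(fp_3v$c_i, fp_ryr$c_i, tolerance = 1e-10)
  expect_equal(fp_fd$c_i, fp_ryr$c_i, tolerance = 1e-10)
  # and the slaved states are genuine equilibria of each variant's field
  for (v in c("three_var", "fast_dyadic")) {
    fp <- find_fixed_points(54, ctrl, variant = v)
    for (i in seq_len(nrow(fp))) {
      po <- fp$c_d[i]^2 / (ctrl$K_o^2 + fp$c_d[i]^2)
      st <- switch(v, three_var = c(fp$c_d[i], fp$c_sr_tot[i], po),
                   fast_dyadic = c(fp$c_sr_tot[i], po))
      expect_lt(max(abs(caru_rhs(v, st, 54, ctrl)$deriv)), 1e-7)
    }
  }
})

test_that("period estimator recovers known fixture ground truth", {
  sin1 <- generate_fixture("sinusoid", period_ms = 1000)
  expect_equal(estimate_period(sin1, transient = 0)$period_ms, 1000,
               tolerance = 1e-3)
  flat <- generate_fixture("constant")
  expect_true(is.na(estimate_period(flat, transient = 0)$period_ms))
  expect_false(as.logical(sustained_oscillation(flat, transient = 0)))
  rel <- generate_fixture("relaxation", period_ms = 700)
  expect_equal(estimate_period(rel, transient = 0)$period_ms, 700,
               tolerance = 5e-3)
  noisy <- generate_fixture("noisy_oscillation", period_ms = 800, cv = 0.1,
                            seed = 2)
  est <- estimate_period(noisy, transient = 0)
  expect_lt(abs(est$period_ms - 800) / 800, 0.05)
  expect_true(as.logical(sustained_oscillation(noisy, transient = 0,
                                               stochastic = TRUE)))
  expect_error(estimate_period(sin1, transient = 1e9), "too short")
})

test_that("locus finders order fold < homoclinic < Hopf and report period growth", {
  fold <- find_fold(ctrl)
  hopf <- find_hopf(ctrl, search = c(30, 90))
  hc <- find_homoclinic(ctrl, search = c(45, 56), step = 2)
  expect_lt(fold, hc$load)
  expect_lt(hc$load, hopf)
  # period decreases with load just above the homoclinic locus
  pd <- hc$periods[!is.na(hc$periods$period_ms), ]
  pd <- pd[order(pd$cT_bar), ]
  expect_gte(nrow(pd), 3)
  expect_true(all(diff(pd$period_ms) < 0))
  # no Hopf on a branch that never destabilises: high-CSQ regime
  expect_true(is.na(find_hopf(caru_params(B_SQ = 20000),
                              search = c(100, 160))))
})

test_that("a small sweep has continuous branches and bracketed loci", {
  dg <- sweep_diagram(c(36, 70), ctrl, step = 2, t_end = 45000)
  counts <- table(dg$branches$cT_bar)
  expect_true(all(counts %in% c(1, 3)))
  # fixed-point count changes exactly at the fold
  loads <- as.numeric(names(counts))
  below <- loads[loads < dg$loci$fold]
  above <- loads[loads > dg$loci$fold]
  expect_true(all(counts[as.character(below)] == 1))
  expect_true(all(counts[as.character(above)] == 3))
  # oscillating probes lie between the refined loci
  osc_loads <- dg$cycles$cT_bar[dg$cycles$oscillating]
  expect_true(all(osc_loads > dg$loci$homoclinic - 2))
  expect_true(all(osc_loads < dg$loci$hopf + 2))
  # limit-cycle extent encloses the unstable upper branch c_i
  mid <- dg$cycles[dg$cycles$cT_bar == 54, ]
  up <- dg$branches[dg$branches$cT_bar == 54 & dg$branches$branch == "upper", ]
  expect_lt(mid$cyc_min, up$c_i)
  expect_gt(mid$cyc_max, up$c_i)
})
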