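test_that("the dyadic nullcline splits above the onset and not below", {
  expect_false(nullcline_split(45, ctrl)$split)
  expect_true(nullcline_split(54, ctrl)$split)
  expect_equal(nullcline_split(45, ctrl)$n_windows, 1L)
  expect_equal(nullcline_split(54, ctrl)$n_windows, 2L)
})

test_that("nullcline intersections coincide with the fixed points", {
  nc <- compute_nullclines(54, ctrl, n_csr = 200, n_fast = 400)
  fp <- nc$fixed_points
  expect_equal(nrow(fp), 3L)
  # every nontrivial fixed point satisfies both curve equations
  for (i in 2:nrow(fp)) {
    a <- caosc:::.alpha_fast_ryr(fp$c_d[i], fp$c_sr[i], 54, ctrl)
    b <- caosc:::.beta_fast_ryr(fp$c_d[i], fp$c_sr[i], 54, ctrl)
    expect_lt(abs(a), 1e-8)
    expect_lt(abs(b), 1e-8)
  }
  # extracted curve points satisfy their defining equation
  smp <- nc$fast[seq(1, nrow(nc$fast), length.out = 25), ]
  resid <- mapply(function(cd, cs) caosc:::.alpha_fast_ryr(cd, cs, 54, ctrl),
                  smp$c_d, smp$c_sr)
  expect_lt(max(abs(resid)), 1e-6)
})

test_that("pinch-off load matches onset and ignores the SERCA rate", {
  po <- pinch_off_load(ctrl)
  on <- onset_analytic(ctrl)
  expect_lt(abs(po - on$cT_star) / on$cT_star, 0.1)
  # the dyadic nullcline does not involve g_up at all
  for (f in c(0.5, 1.5)) {
    po_f <- pinch_off_load(caru_params_mod(ctrl, g_up = ctrl$g_up * f))
    expect_lt(abs(po_f - po), 0.2)
  }
})

test_that("closed-form onset matches its algebra and monotonicities", {
  on <- onset_analytic(ctrl)
  gt <- ctrl$g * ctrl$tau_i / ctrl$K_o^2
  expect_equal(on$g_tilde, gt)
  expect_equal(on$cT_star,
               sqrt(ctrl$v_sr * ctrl$v_i * ctrl$B_b /
                      (ctrl$v^2 * gt * ctrl$K_b)) -
                 ctrl$v_sr / (4 * gt * ctrl$K_b * ctrl$v),
               tolerance = 1e-12)
  expect_equal(on$csr_lower_at_onset, ctrl$v / ctrl$v_sr * on$cT_star)
  expect_equal(on$csr_star,
               on$csr_lower_at_onset / 2 - 1 / (8 * gt * ctrl$K_b))
  # sudden SR drop at onset: below half the pre-onset level (control values)
  expect_lt(on$csr_star, on$csr_lower_at_onset / 2)
  # onset rises with buffer amount; around the control point it also rises
  # as K_b is lowered (both closed-form terms scale inversely with K_b, and
  # the numeric pinch-off confirms the direction, see the buffer-scan test)
  expect_gt(onset_analytic(caru_params_mod(ctrl, B_b = 160))$cT_star,
            on$cT_star)
  expect_gt(onset_analytic(caru_params_mod(ctrl, K_b = 0.25))$cT_star,
            on$cT_star)
  expect_error(onset_analytic(caru_params(B_SQ = 100)), "B_SQ")
  expect_error(onset_analytic(caru_params(B_b = 0)), "B_b")
})

test_that("buffer scans pass through the control point and match the numeric onset", {
  cur <- onset_vs_buffers(ctrl, Bb_range = c(40, 80, 160),
                          Kb_range = c(0.25, 0.5, 1))
  on <- onset_analytic(ctrl)
  expect_equal(cur$vs_Bb$cT_star[cur$vs_Bb$B_b == 80], on$cT_star)
  expect_equal(cur$vs_Kb$cT_star[cur$vs_Kb$K_b == 0.5], on$cT_star)
  expect_true(all(diff(cur$vs_Bb$cT_star) > 0)) # doubling B_b delays onset
  # whatever direction the closed form takes in K_b, the independent numeric
  # pinch-off must move the same way (here: onset falls as K_b grows)
  pinch <- vapply(c(0.25, 1), function(kb) {
    pinch_off_load(caru_params_mod(ctrl, K_b = kb), search = c(30, 90),
                   tol = 0.2)
  }, numeric(1))
  expect_equal(sign(diff(pinch)), sign(diff(cur$vs_Kb$cT_star[c(1, 3)])))
  expect_lt(abs(pinch[1] - cur$vs_Kb$cT_star[1]) / cur$vs_Kb$cT_star[1], 0.1)
  expect_lt(abs(pinch[2] - cur$vs_Kb$cT_star[3]) / cur$vs_Kb$cT_star[3], 0.1)
})

test_that("sign-based stability reports match the nullcline-slope argument", {
  fp75 <- find_fixed_points(75, ctrl)
  rep75 <- jacobian_sign_report(fp75$c_i[3], 75, ctrl)
  expect_lt(rep75$f1, 0)
  expect_lt(rep75$g2, 0)
  expect_equal(rep75$sign_verdict, "stable")
  expect_match(rep75$eigen_class, "^stable")

  fp54 <- find_fixed_points(54, ctrl)
  rep54 <- jacobian_sign_report(fp54$c_i[3], 54, ctrl)
  expect_gt(rep54$f1, 0)
  expect_lt(rep54$g2, 0)
  expect_equal(rep54$sign_verdict, "indeterminate")
  expect_match(rep54$eigen_class, "unstable")
  # whenever the signs do decide, they agree with the eigenvalues
  for (ct in c(70, 75, 80)) {
    fp <- find_fixed_points(ct, ctrl)
    rp <- jacobian_sign_report(fp$c_i[nrow(fp)], ct, ctrl)
    if (rp$sign_verdict != "indeterminate") {
      expect_equal(rp$sign_verdict,
                   sub("_(node|spiral)$", "", rp$eigen_class))
    }
  }
})

test_that("fast-dyadic gating nullcline splits at its oscillation onset", {
  expect_false(nullcline_split(45, ctrl, variant = "fast_dyadic")$split)
  expect_true(nullcline_split(54, ctrl, variant = "fast_dyadic")$split)
  po_fd <- pinch_off_load(ctrl, variant = "fast_dyadic")
  onset_fd <- find_homoclinic(ctrl, variant = "fast_dyadic",
                              search = c(44, 56), step = 2)$load
  expect_lt(abs(po_fd - onset_fd), 2)
})
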