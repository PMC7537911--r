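# Nullcline geometry of the two-variable reductions.
# fast_ryr:     plane (c_d, c_sr); alpha = dc_d/dt, beta = dc_sr/dt.
# fast_dyadic:  plane (c_sr, P_o); the gating nullcline dP_o/dt = 0 plays the
#               role of the fast nullcline.

# alpha residual on a (c_d, c_sr) grid line, vectorised over c_d.
# c_sr is the free SR concentration; the state's total follows from the
# rapid-buffer relation so the same expressions cover B_SQ > 0.
.alpha_fast_ryr <- function(c_d, c_sr, cT_bar, p) {
  csrtot <- total_sr_calcium(c_sr, p)
  R <- (p$v * cT_bar - p$v_d * c_d - p$v_sr * csrtot) / p$v_i
  ci <- ifelse(R < 0, NA_real_,
               0.5 * ((R - p$K_b - p$B_b) +
                        sqrt((R - p$K_b - p$B_b)^2 + 4 * p$K_b * R)))
  P_o <- c_d^2 / (p$K_o^2 + c_d^2)
  p$g * P_o * (c_sr - c_d) - (c_d - ci) / p$tau_i
}

.beta_fast_ryr <- function(c_d, c_sr, cT_bar, p) {
  csrtot <- total_sr_calcium(c_sr, p)
  R <- (p$v * cT_bar - p$v_d * c_d - p$v_sr * csrtot) / p$v_i
  ci <- ifelse(R < 0, NA_real_,
               0.5 * ((R - p$K_b - p$B_b) +
                        sqrt((R - p$K_b - p$B_b)^2 + 4 * p$K_b * R)))
  P_o <- c_d^2 / (p$K_o^2 + c_d^2)
  (p$v_i / p$v_sr) * p$g_up * ci^2 / (p$K_s^2 + ci^2) -
    (p$v_d / p$v_sr) * p$g * P_o * (c_sr - c_d)
}

# gating residual dP_o/dt on a (c_sr, P_o) grid line (fast_dyadic, B_SQ = 0)
.gate_fast_dyadic <- function(P_o, c_sr, cT_bar, p) {
  a <- p$tau_i * p$g * P_o
  M <- p$v * cT_bar - p$v_sr * c_sr - p$v_d * a * c_sr / (1 + a)
  A <- p$v_i + p$v_d / (1 + a)
  b <- (A * p$K_b + p$v_i * p$B_b - M) / A
  ci <- ifelse(M < 0, NA_real_,
               0.5 * (-b + sqrt(b^2 + 4 * p$K_b * M / A)))
  cd <- (a * c_sr + ci) / (1 + a)
  p$k_p * cd^2 * (1 - P_o) - p$k_m * P_o
}

# sign-change count of a residual along one grid line (NA-tolerant)
.count_roots <- function(vals) {
  s <- sign(vals[is.finite(vals)])
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}

#' Detect the nullcline pinch-off at a given load
#'
#' The fast nullcline of each two-variable reduction (the \eqn{\dot c_d = 0}
#' curve for `fast_ryr`, the \eqn{\dot P_o = 0} curve for `fast_dyadic`) is
#' scanned line-by-line in \eqn{c_{sr}}: on each line the residual's roots
#' along the fast coordinate are counted. A connected S-shaped nullcline
#' produces one contiguous window of \eqn{c_{sr}} values carrying three
#' roots; at the pinch-off two of the three solutions are lost over an
#' interior range of \eqn{c_{sr}}, so the 3-root window splits into two
#' disjoint windows. The nullcline is declared split when two (or more)
#' disjoint 3-root windows of at least `min_run` grid lines each are found.
#'
#' @param cT_bar Average total calcium load (\eqn{\mu}M).
#' @param p A [caru_params()] object.
#' @param variant `"fast_ryr"` or `"fast_dyadic"`.
#' @param n_csr,n_fast Grid resolution (lines in \eqn{c_{sr}}; points along
#'   the fast coordinate per line).
#' @param min_run Minimum window width in grid lines.
#' @return List: `split` (logical), `n_windows`, and `counts` (per-line root
#'   counts, for inspection).
#' @export
nullcline_split <- function(cT_bar, p = caru_params(), variant = "fast_ryr",
                            n_csr = 400, n_fast = 600, min_run = 2) {
  variant <- match.arg(variant, c("fast_ryr", "fast_dyadic"))
  csr_max <- free_sr_calcium(p$v * cT_bar / p$v_sr, p) * (1 - 1e-9)
  csr <- seq(csr_max * 0.01, csr_max, length.out = n_csr)
  counts <- vapply(csr, function(s) {
    if (variant == "fast_ryr") {
      cd_max <- min((p$v * cT_bar - p$v_sr * total_sr_calcium(s, p)) /
                      p$v_d * (1 - 1e-9), 5000)
      if (cd_max <= 1e-4) return(0L)
      cd <- exp(seq(log(1e-4), log(cd_max), length.out = n_fast))
      .count_roots(.alpha_fast_ryr(cd, s, cT_bar, p))
    } else {
      # log-spaced: the lower gating branch lives at very small P_o
      po <- exp(seq(log(1e-8), log(1 - 1e-6), length.out = n_fast))
      .count_roots(.gate_fast_dyadic(po, s, cT_bar, p))
    }
  }, integer(1))
  r <- rle(counts >= 3)
  wins <- sum(r$values & r$lengths >= min_run)
  list(split = wins >= 2, n_windows = wins, counts = counts)
}

#' Nullclines of a two-variable reduction at a given load
#'
#' Extracts both nullclines by per-line root enumeration (with `uniroot`
#' polishing): for `fast_ryr`, the \eqn{\dot c_d = 0} curve (roots in
#' \eqn{c_d} per \eqn{c_{sr}} line) and the \eqn{\dot c_{sr} = 0} curve
#' (roots in \eqn{c_{sr}} per \eqn{c_d} line and vice versa, stitched); for
#' `fast_dyadic`, the gating curve \eqn{\dot P_o = 0} and the matching
#' \eqn{\dot c_{sr} = 0} curve in the \eqn{(c_{sr}, P_o)} plane.
#'
#' @param cT_bar Average total calcium load (\eqn{\mu}M).
#' @param p A [caru_params()] object.
#' @param variant `"fast_ryr"` or `"fast_dyadic"`.
#' @param n_csr,n_fast Grid resolution.
#' @return A `caru_nullclines` list: `fast` and `slow` (data frames of curve
#'   points; columns `c_sr` plus `c_d` or `P_o`), `split` / `n_windows` from
#'   [nullcline_split()], and `fixed_points` (the [find_fixed_points()]
#'   table, whose states lie on both curves).
#' @export
compute_nullclines <- function(cT_bar, p = caru_params(),
                               variant = "fast_ryr", n_csr = 300,
                               n_fast = 500) {
  variant <- match.arg(variant, c("fast_ryr", "fast_dyadic"))
  csr_max <- free_sr_calcium(p$v * cT_bar / p$v_sr, p) * (1 - 1e-9)
  csr_grid <- seq(csr_max * 0.005, csr_max, length.out = n_csr)
  polish <- function(f, xg, vals) {
    s <- sign(vals)
    idx <- which(is.finite(s[-1]) & is.finite(s[-length(s)]) &
                   diff(s) != 0)
    vapply(idx, function(i) {
      stats::uniroot(f, c(xg[i], xg[i + 1]), tol = 1e-10)$root
    }, numeric(1))
  }
  fast_pts <- do.call(rbind, lapply(csr_grid, function(s) {
    if (variant == "fast_ryr") {
      cd_max <- min((p$v * cT_bar - p$v_sr * total_sr_calcium(s, p)) /
                      p$v_d * (1 - 1e-9), 5000)
      if (cd_max <= 1e-4) return(NULL)
      xg <- exp(seq(log(1e-4), log(cd_max), length.out = n_fast))
      r <- polish(function(x) .alpha_fast_ryr(x, s, cT_bar, p), xg,
                  .alpha_fast_ryr(xg, s, cT_bar, p))
      if (!length(r)) NULL else data.frame(c_sr = s, c_d = r)
    } else {
      xg <- exp(seq(log(1e-8), log(1 - 1e-6), length.out = n_fast))
      r <- polish(function(x) .gate_fast_dyadic(x, s, cT_bar, p), xg,
                  .gate_fast_dyadic(xg, s, cT_bar, p))
      if (!length(r)) NULL else data.frame(c_sr = s, P_o = r)
    }
  }))
  slow_pts <- do.call(rbind, lapply(csr_grid, function(s) {
    if (variant == "fast_ryr") {
      cd_max <- min((p$v * cT_bar - p$v_sr * total_sr_calcium(s, p)) /
                      p$v_d * (1 - 1e-9), 5000)
      if (cd_max <= 1e-4) return(NULL)
      xg <- exp(seq(log(1e-4), log(cd_max), length.out = n_fast))
      r <- polish(function(x) .beta_fast_ryr(x, s, cT_bar, p), xg,
                  .beta_fast_ryr(xg, s, cT_bar, p))
      if (!length(r)) NULL else data.frame(c_sr = s, c_d = r)
    } else {
      beta_fd <- function(po) {
        vapply(po, function(q) {
          st <- caru_rhs("fast_dyadic", c(s, q), cT_bar, p)
          st$deriv[1]
        }, numeric(1))
      }
      xg <- seq(1e-6, 1 - 1e-6, length.out = max(100, n_fast %/% 4))
      r <- tryCatch(polish(function(x) beta_fd(x), xg, beta_fd(xg)),
                    error = function(e) numeric(0))
      if (!length(r)) NULL else data.frame(c_sr = s, P_o = r)
    }
  }))
  spl <- nullcline_split(cT_bar, p, variant = variant)
  structure(list(fast = fast_pts, slow = slow_pts, split = spl$split,
                 n_windows = spl$n_windows, variant = variant,
                 cT_bar = cT_bar,
                 fixed_points = find_fixed_points(cT_bar, p,
                                                  variant = variant)),
            class = "caru_nullclines")
}

#' @export
print.caru_nullclines <- function(x, ...) {
  cat(sprintf(
    "Nullclines (%s) at cT_bar = %g uM: %s (%d three-root window%s), %d fixed point%s\n",
    x$variant, x$cT_bar, if (x$split) "PINCHED" else "connected",
    x$n_windows, if (x$n_windows == 1) "" else "s", nrow(x$fixed_points),
    if (nrow(x$fixed_points) == 1) "" else "s"))
  invisible(x)
}

#' Critical load of the nullcline pinch-off
#'
#' Bisects the load at which the fast nullcline first splits
#' ([nullcline_split()]). The split is the geometric criterion for
#' oscillation onset, so this load matches the first sustained oscillation
#' and, at control parameters, the closed-form [onset_analytic()] estimate
#' to within its stated approximations. It does not involve the SERCA rate,
#' so it is invariant to changes of `g_up` by construction.
#'
#' @param p A [caru_params()] object (`B_SQ = 0` for the analytic-comparison
#'   regime; the detector itself works for any `B_SQ`).
#' @param variant `"fast_ryr"` or `"fast_dyadic"`.
#' @param search Load interval (\eqn{\mu}M).
#' @param tol Bisection tolerance (\eqn{\mu}M).
#' @return Pinch-off load (\eqn{\mu}M), or `NA` when no transition occurs in
#'   `search`.
#' @export
pinch_off_load <- function(p = caru_params(), variant = "fast_ryr",
                           search = c(40, 60), tol = 0.05) {
  is_split <- function(cT) nullcline_split(cT, p, variant = variant)$split
  # locate a split load by coarse upward scan (the split also closes again
  # at high loads, so the upper search end need not itself be split)
  grid <- seq(search[1], search[2], length.out = 41)
  first <- NA_integer_
  for (i in seq_along(grid)) {
    if (is_split(grid[i])) { first <- i; break }
  }
  if (is.na(first) || first == 1) return(NA_real_)
  lo <- grid[first - 1]; hi <- grid[first]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (is_split(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Closed-form onset of oscillations (no calsequestrin)
#'
#' Under the approximations \eqn{c_d \ll K_o}, \eqn{c_d \ll c_{sr}} and
#' bound-buffer dominance in the cytosol, the pinch-off condition reduces to
#' a quadratic in the SR concentration whose discriminant vanishes at the
#' critical load
#' \deqn{\bar c_T^* = \sqrt{\frac{v_{sr} v_i B_b}{v^2 \tilde g K_b}}
#'   - \frac{v_{sr}}{4 \tilde g K_b v}, \qquad
#'   \tilde g = g\,\tau_i / K_o^2,}
#' with diastolic SR calcium at onset
#' \deqn{c_{sr}^* = \frac{v \bar c_T^*}{2 v_{sr}} - \frac{1}{8 \tilde g K_b}.}
#' Just below onset the rest state holds \eqn{(v/v_{sr})\,\bar c_T^*} in the
#' SR, so the onset is accompanied by a sudden drop in basal SR calcium (to
#' less than half the pre-onset value at control parameters).
#'
#' @param p A [caru_params()] object with `B_SQ = 0` and `B_b > 0`.
#' @return An `onset_result` list: `cT_star` (\eqn{\mu}M), `csr_star`
#'   (\eqn{\mu}M), `csr_lower_at_onset` \eqn{= (v/v_{sr}) \bar c_T^*}
#'   (\eqn{\mu}M) and `g_tilde` (\eqn{\mu}M\eqn{^{-2}}). If the formula has
#'   no positive solution, `cT_star` is `NA` ("no onset").
#' @export
onset_analytic <- function(p = caru_params()) {
  if (p$B_SQ != 0) stop("closed-form onset assumes B_SQ = 0")
  if (p$B_b <= 0) stop("closed-form onset assumes a cytosolic buffer, B_b > 0")
  g_tilde <- p$g * p$tau_i / p$K_o^2
  cT_star <- sqrt(p$v_sr * p$v_i * p$B_b / (p$v^2 * g_tilde * p$K_b)) -
    p$v_sr / (4 * g_tilde * p$K_b * p$v)
  if (!is.finite(cT_star) || cT_star <= 0) {
    return(structure(list(cT_star = NA_real_, csr_star = NA_real_,
                          csr_lower_at_onset = NA_real_, g_tilde = g_tilde),
                     class = "onset_result"))
  }
  csr_star <- p$v * cT_star / (2 * p$v_sr) - 1 / (8 * g_tilde * p$K_b)
  structure(list(cT_star = cT_star, csr_star = csr_star,
                 csr_lower_at_onset = (p$v / p$v_sr) * cT_star,
                 g_tilde = g_tilde),
            class = "onset_result")
}

#' @export
print.onset_result <- function(x, ...) {
  cat("Closed-form oscillation onset (B_SQ = 0):\n")
  cat(sprintf("  critical load      cT* = %.4g uM\n", x$cT_star))
  cat(sprintf("  SR free Ca at onset csr* = %.4g uM\n", x$csr_star))
  cat(sprintf("  pre-onset rest SR       = %.4g uM\n", x$csr_lower_at_onset))
  cat(sprintf("  g_tilde = g tau_i / Ko^2 = %.4g uM^-2\n", x$g_tilde))
  invisible(x)
}

#' Onset load as a function of cytosolic buffer parameters
#'
#' Tabulates the closed-form onset [onset_analytic()] over ranges of the
#' cytosolic buffer concentration `B_b` (at control `K_b`) and dissociation
#' constant `K_b` (at control `B_b`). More buffer delays the onset to higher
#' loads; higher buffer affinity (lower `K_b`) brings oscillations to lower
#' loads.
#'
#' @param p A [caru_params()] object (`B_SQ = 0`).
#' @param Bb_range,Kb_range Numeric vectors of buffer values (\eqn{\mu}M).
#' @return List of two data frames, `vs_Bb` (`B_b`, `cT_star`) and `vs_Kb`
#'   (`K_b`, `cT_star`).
#' @export
onset_vs_buffers <- function(p = caru_params(),
                             Bb_range = seq(10, 300, by = 5),
                             Kb_range = seq(0.1, 2, by = 0.05)) {
  if (any(Bb_range <= 0) || any(Kb_range <= 0)) {
    stop("buffer ranges must be positive")
  }
  vs_Bb <- data.frame(
    B_b = Bb_range,
    cT_star = vapply(Bb_range, function(b) {
      onset_analytic(caru_params_mod(p, B_b = b))$cT_star
    }, numeric(1)))
  vs_Kb <- data.frame(
    K_b = Kb_range,
    cT_star = vapply(Kb_range, function(k) {
      onset_analytic(caru_params_mod(p, K_b = k))$cT_star
    }, numeric(1)))
  list(vs_Bb = vs_Bb, vs_Kb = vs_Kb)
}

#' Modify a parameter set
#'
#' Returns a copy of `p` with the named fields replaced and the result
#' re-validated (the unit volume is recomputed).
#'
#' @param p A [caru_params()] object.
#' @param ... Named replacements, e.g. `caru_params_mod(p, B_SQ = 2000)`.
#' @return A new `caru_params` object.
#' @export
caru_params_mod <- function(p, ...) {
  repl <- list(...)
  bad <- setdiff(names(repl), setdiff(names(p), "v"))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  q <- unclass(p)
  q[names(repl)] <- repl
  q$v <- q$v_i + q$v_sr + q$v_d
  class(q) <- "caru_params"
  validate_params(q)
  q
}

#' Sign-based stability report from the nullcline slopes
#'
#' At a fixed point of the fast-RyR reduction the diagonal Jacobian entries
#' \eqn{f_1 = \partial \dot c_d / \partial c_d} and \eqn{g_2 = \partial
#' \dot c_{sr} / \partial c_{sr}} are readable from the nullcline slopes.
#' When both are negative the trace criterion gives stability outright; when
#' \eqn{f_1 > 0} the signs alone cannot decide (the outcome depends on the
#' relative speed of \eqn{c_d} and \eqn{c_{sr}}) and the verdict defers to
#' the eigenvalues.
#'
#' @param c_i Cytosolic calcium of the fixed point (a row of
#'   [find_fixed_points()]).
#' @param cT_bar Load at which the fixed point was computed (\eqn{\mu}M).
#' @param p A [caru_params()] object.
#' @return List: `f1`, `g2` (per ms), `sign_verdict` (`"stable"`,
#'   `"unstable"` or `"indeterminate"`), and `eigen_class` (the eigenvalue
#'   classification, which always resolves the case).
#' @export
jacobian_sign_report <- function(c_i, cT_bar, p = caru_params()) {
  cd <- .cd_of_ci(c_i, p)
  csrtot <- max(.csrtot_of_ci(c_i, cT_bar, p), 0)
  J <- .jacobian_at("fast_ryr", c(cd, csrtot), cT_bar, p)
  f1 <- J[1, 1]; g2 <- J[2, 2]
  det <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  # verdict from signs alone: mixed diagonal signs leave the trace criterion
  # undecided (the outcome depends on the relative rates, i.e. magnitudes)
  verdict <- if (f1 < 0 && g2 < 0 && det > 0) {
    "stable"
  } else if (f1 > 0 && g2 > 0) {
    "unstable"
  } else {
    "indeterminate"
  }
  ev <- eigen(J, only.values = TRUE)$values
  list(f1 = f1, g2 = g2, sign_verdict = verdict,
       eigen_class = .classify_eigs(ev))
}
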