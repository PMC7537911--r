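# Fixed points are found on the cytosolic-calcium axis: at equilibrium the
# dyad balance and the uptake/release balance reduce (for any B_SQ, via the
# rapid-buffer relation) to a one-dimensional root problem f(c_i; cT_bar) = 0.

# dyadic calcium at equilibrium as a function of c_i (uptake through the dyad)
.cd_of_ci <- function(c_i, p) {
  c_i + (p$v_i / p$v_d) * p$tau_i * p$g_up * c_i^2 / (p$K_s^2 + c_i^2)
}

# total SR calcium at equilibrium from conservation
.csrtot_of_ci <- function(c_i, cT_bar, p) {
  c_d <- .cd_of_ci(c_i, p)
  (p$v * cT_bar - p$v_d * c_d -
     p$v_i * (c_i + p$B_b * c_i / (p$K_b + c_i))) / p$v_sr
}

# largest c_i compatible with a nonnegative SR content at this load
.ci_max <- function(cT_bar, p) {
  if (cT_bar <= 0) return(0)
  f <- function(ci) .csrtot_of_ci(ci, cT_bar, p)
  stats::uniroot(f, c(1e-12, 1e7), tol = 1e-12)$root
}

#' Scalar equilibrium residual \eqn{f(c_i; \bar c_T)}
#'
#' Substitutes the equilibrium expressions for \eqn{c_d(c_i)} and
#' \eqn{c_{sr}^{tot}(c_i)} (conservation) into the dyad balance; its roots
#' are the fixed points of every model variant (the variants share fixed
#' points because they share the equilibrium equations). Calsequestrin
#' enters through [free_sr_calcium()], so the same residual covers
#' \eqn{B_{SQ} > 0}.
#'
#' @param c_i Cytosolic free calcium (\eqn{\mu}M); vectorised.
#' @param cT_bar Average total calcium load (\eqn{\mu}M).
#' @param p A [caru_params()] object.
#' @return Residual (\eqn{\mu}M/ms); zero at equilibria. `c_i = 0` is always
#'   a root (the closed-RyR rest state exists at every load). Infeasible
#'   `c_i` (negative implied SR content) raises an error.
#' @export
equilibrium_residual <- function(c_i, cT_bar, p = caru_params()) {
  csrtot <- .csrtot_of_ci(c_i, cT_bar, p)
  if (any(csrtot < 0)) {
    stop("infeasible c_i: implied SR calcium is negative at this load")
  }
  c_d <- .cd_of_ci(c_i, p)
  c_sr <- free_sr_calcium(csrtot, p)
  P_o <- c_d^2 / (p$K_o^2 + c_d^2)
  p$g * P_o * (c_sr - c_d) - (c_d - c_i) / p$tau_i
}

# numeric Jacobian of a variant's vector field at a state, with one-sided
# differences at the nonnegativity / feasibility boundaries
.jacobian_at <- function(variant, state, cT_bar, p) {
  n <- length(state)
  J <- matrix(0, n, n)
  f0 <- caru_rhs(variant, state, cT_bar, p)$deriv
  eval_or_null <- function(s) {
    tryCatch(caru_rhs(variant, s, cT_bar, p)$deriv,
             caosc_infeasible_state = function(e) NULL)
  }
  for (j in seq_len(n)) {
    h <- 1e-6 * max(1, abs(state[j]))
    sp <- state; sp[j] <- sp[j] + h
    sm <- state; sm[j] <- sm[j] - h
    fp <- eval_or_null(sp)
    fm <- if (sm[j] >= 0) eval_or_null(sm) else NULL
    J[, j] <- if (!is.null(fp) && !is.null(fm)) {
      (fp - fm) / (2 * h)
    } else if (!is.null(fp)) {
      (fp - f0) / h
    } else if (!is.null(fm)) {
      (f0 - fm) / h
    } else {
      stop("cannot differentiate: both finite-difference probes infeasible")
    }
  }
  J
}

# eigenvalue-based stability class; |Re| below tol counts as neutral and is
# resolved conservatively towards stability (the rest state carries an exact
# structural zero along the uptake direction)
.classify_eigs <- function(ev, tol = 1e-9) {
  re <- Re(ev); im <- Im(ev)
  spiral <- any(abs(im) > tol)
  if (!spiral && any(re > tol) && any(re < -tol)) return("saddle")
  if (any(re > tol)) return(if (spiral) "unstable_spiral" else "unstable_node")
  if (spiral) "stable_spiral" else "stable_node"
}

#' Fixed points of the minimal CaRU model at a given load
#'
#' All equilibria are located by dense log-spaced bracketing of
#' [equilibrium_residual()] on the feasible \eqn{c_i} interval followed by
#' root polishing; the closed-RyR rest state \eqn{c_i = c_d = 0} is always
#' included. Linear stability is classified from the eigenvalues of the
#' requested variant's Jacobian (the fixed-point locations themselves are
#' variant-independent; stability is not).
#'
#' @param cT_bar Average total calcium load (\eqn{\mu}M).
#' @param p A [caru_params()] object.
#' @param variant Variant whose Jacobian classifies stability.
#' @param n_grid Number of bracketing points (log-spaced on
#'   \eqn{[10^{-4}, c_i^{max}]}); the default resolves the five-fixed-point
#'   calsequestrin window.
#' @return A data frame of class `caru_fixed_points`: one row per fixed
#'   point, ordered by `c_i`, with the state (`c_i`, `c_d`, `c_sr_tot`,
#'   `c_sr`), `branch` (`lower`/`intermediate`/`upper`), `class` (stability),
#'   leading eigenvalue parts `re1`, `re2`, `im1`, and the absolute
#'   `residual` of the equilibrium equations.
#' @examples
#' find_fixed_points(54)   # rest state + two coexisting branches
#' @export
find_fixed_points <- function(cT_bar, p = caru_params(),
                              variant = "fast_ryr", n_grid = 2000) {
  variant <- match.arg(variant, .variants)
  roots <- 0
  if (cT_bar > 0) {
    hi <- .ci_max(cT_bar, p)
    if (hi > 1e-4) {
      grid <- exp(seq(log(1e-4), log(hi * (1 - 1e-9)), length.out = n_grid))
      r <- equilibrium_residual(grid, cT_bar, p)
      idx <- which(diff(sign(r)) != 0)
      found <- vapply(idx, function(i) {
        stats::uniroot(equilibrium_residual, c(grid[i], grid[i + 1]),
                       cT_bar = cT_bar, p = p, tol = 1e-13)$root
      }, numeric(1))
      found <- sort(found)
      if (length(found) > 1) { # merge near-duplicates
        keep <- c(TRUE, diff(found) > 1e-6)
        found <- found[keep]
      }
      roots <- c(0, found)
    }
  }
  rows <- lapply(seq_along(roots), function(k) {
    ci <- roots[k]
    cd <- .cd_of_ci(ci, p)
    csrtot <- max(.csrtot_of_ci(ci, cT_bar, p), 0)
    csr <- free_sr_calcium(csrtot, p)
    state <- switch(variant,
                    fast_ryr = c(cd, csrtot),
                    three_var = c(cd, csrtot, cd^2 / (p$K_o^2 + cd^2)),
                    fast_dyadic = c(csrtot, cd^2 / (p$K_o^2 + cd^2)))
    J <- .jacobian_at(variant, state, cT_bar, p)
    ev <- eigen(J, only.values = TRUE)$values
    ev <- ev[order(-Re(ev))]
    resid <- if (ci > 0) abs(equilibrium_residual(ci, cT_bar, p)) else 0
    data.frame(c_i = ci, c_d = cd, c_sr_tot = csrtot, c_sr = csr,
               class = .classify_eigs(ev),
               re1 = Re(ev[1]), re2 = Re(ev[min(2, length(ev))]),
               im1 = abs(Im(ev[1])), residual = resid)
  })
  fp <- do.call(rbind, rows)
  fp$branch <- "intermediate"
  fp$branch[1] <- "lower"
  if (nrow(fp) > 1) fp$branch[nrow(fp)] <- "upper"
  fp <- fp[, c("c_i", "c_d", "c_sr_tot", "c_sr", "branch", "class",
               "re1", "re2", "im1", "residual")]
  attr(fp, "cT_bar") <- cT_bar
  attr(fp, "variant") <- variant
  class(fp) <- c("caru_fixed_points", "data.frame")
  fp
}

#' Estimate the oscillation period of a trace
#'
#' Detects cycles of `c_i` after a transient using mid-level crossings with a
#' hysteresis band (robust to noise), locates the peak inside each cycle and
#' returns the mean inter-peak interval.
#'
#' @param trace A `caru_trace`.
#' @param transient Initial time (ms) discarded before analysis.
#' @param min_amplitude Peak-to-peak amplitude (\eqn{\mu}M) below which the
#'   trace is declared non-oscillatory; default 5\% of the post-transient
#'   maximum of `c_i`.
#' @param min_peaks Minimum number of detected peaks required to report a
#'   period.
#' @return List: `period_ms` (`NA` if non-oscillatory), `n_peaks`,
#'   `peak_times`, `amplitude` (peak-to-peak of `c_i`), `cv` (coefficient of
#'   variation of inter-peak intervals).
#' @export
estimate_period <- function(trace, transient = 20000, min_amplitude = NULL,
                            min_peaks = 3) {
  stopifnot(inherits(trace, "caru_trace"))
  keep <- trace$t_ms >= transient
  if (sum(keep) < 10) {
    stop("trace too short: fewer than 10 samples after the transient")
  }
  x <- trace$c_i[keep]
  t <- trace$t_ms[keep]
  amp <- max(x) - min(x)
  if (is.null(min_amplitude)) min_amplitude <- 0.05 * max(abs(x))
  none <- list(period_ms = NA_real_, n_peaks = 0L,
               peak_times = numeric(0), amplitude = amp, cv = NA_real_)
  if (!is.finite(amp) || amp <= 0 || amp < min_amplitude) return(none)
  hi <- min(x) + 0.55 * amp
  lo <- min(x) + 0.45 * amp
  # hysteresis upcrossings
  state <- x[1] > hi
  ups <- integer(0)
  for (i in seq_along(x)) {
    if (!state && x[i] > hi) { state <- TRUE; ups <- c(ups, i) }
    else if (state && x[i] < lo) state <- FALSE
  }
  if (length(ups) < min_peaks) return(none)
  peak_t <- vapply(seq_len(length(ups) - 1), function(k) {
    seg <- ups[k]:(ups[k + 1] - 1)
    t[seg[which.max(x[seg])]]
  }, numeric(1))
  if (length(peak_t) < min_peaks) return(none)
  iv <- diff(peak_t)
  if (!length(iv)) return(none)
  list(period_ms = mean(iv), n_peaks = length(peak_t) + 1L,
       peak_times = peak_t, amplitude = amp,
       cv = if (length(iv) > 1) stats::sd(iv) / mean(iv) else 0)
}

#' Classify a trace as a sustained oscillation
#'
#' A trace counts as a sustained oscillation when, after the transient, the
#' peak-to-peak amplitude of `c_i` exceeds 5\% of a reference amplitude
#' (`amp_ref`, by default the trace's own post-transient maximum) plus an
#' absolute floor, at least `min_cycles` inter-peak intervals are present,
#' their coefficient of variation is below `cv_max` (20\% deterministic,
#' 60\% stochastic — near-onset cycles are slow and irregular under noise),
#' and the amplitude does not decay between the first and second half of the
#' analysis window (which discards slowly damped spirals).
#'
#' @param trace A `caru_trace`.
#' @param transient Discarded initial time (ms).
#' @param amp_ref Reference amplitude (\eqn{\mu}M) for the 5\% rule, e.g. the
#'   maximum `c_i` over a sweep.
#' @param stochastic Use the stochastic CV bound.
#' @param min_cycles Minimum number of inter-peak intervals.
#' @param floor Absolute amplitude floor (\eqn{\mu}M).
#' @return Logical, with the [estimate_period()] analysis as attribute
#'   `"analysis"`.
#' @export
sustained_oscillation <- function(trace, transient = 20000, amp_ref = NULL,
                                  stochastic = FALSE, min_cycles = 5,
                                  floor = 0.02) {
  cv_max <- if (stochastic) 0.6 else 0.2
  keep <- trace$t_ms >= transient
  x <- trace$c_i[keep]; t <- trace$t_ms[keep]
  if (is.null(amp_ref)) amp_ref <- max(abs(x))
  thr <- max(0.05 * amp_ref, floor)
  pe <- estimate_period(trace, transient = transient, min_amplitude = thr,
                        min_peaks = min_cycles + 1)
  ok <- !is.na(pe$period_ms) && is.finite(pe$cv) && pe$cv < cv_max
  if (ok) { # non-decay check on the analysis window
    half <- t[1] + (t[length(t)] - t[1]) / 2
    a1 <- diff(range(x[t < half])); a2 <- diff(range(x[t >= half]))
    ok <- a2 > 0.5 * a1 && a2 > thr
  }
  structure(ok, analysis = pe)
}

# probe integration used by locus searches and sweeps
.probe <- function(cT_bar, p, variant = "fast_ryr", t_end = 45000,
                   transient = 20000, sigma = 0, dt = 0.1, seed = NULL,
                   amp_ref = NULL) {
  tr <- integrate_caru(variant, cT_bar, p, t_end = t_end, sigma = sigma,
                       dt = dt, seed = seed,
                       sample_dt = if (sigma > 0) 2 else 2)
  osc <- sustained_oscillation(tr, transient = transient, amp_ref = amp_ref,
                               stochastic = sigma > 0)
  list(trace = tr, osc = isTRUE(osc), analysis = attr(osc, "analysis"))
}

#' Fold locus: smallest load with coexisting nontrivial fixed points
#'
#' Bisects the load at which the pair of nontrivial equilibrium branches is
#' born (below it the closed-RyR rest state is the only fixed point).
#'
#' @param p A [caru_params()] object.
#' @param search Load interval (\eqn{\mu}M) to search.
#' @param tol Bisection tolerance (\eqn{\mu}M).
#' @return Fold load (\eqn{\mu}M), or `NA` if no fold lies in `search`.
#' @export
find_fold <- function(p = caru_params(), search = c(20, 200), tol = 0.05) {
  has3 <- function(cT) nrow(find_fixed_points(cT, p)) >= 3
  lo <- search[1]; hi <- search[2]
  if (has3(lo) || !has3(hi)) return(NA_real_)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (has3(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Hopf locus on the upper fixed-point branch
#'
#' Tracks the upper branch over a load grid and bisects the zero crossing of
#' the leading eigenvalue real part of the chosen variant's Jacobian.
#'
#' @param p A [caru_params()] object.
#' @param search Load interval (\eqn{\mu}M); scanning starts just above the
#'   fold.
#' @param variant Variant whose Jacobian is used.
#' @param tol Bisection tolerance (\eqn{\mu}M).
#' @param step Coarse scan step (\eqn{\mu}M).
#' @return Hopf load (\eqn{\mu}M), or `NA` when the branch never changes
#'   stability in `search` (e.g. high calsequestrin, where the upper state is
#'   born stable at a saddle-node instead).
#' @export
find_hopf <- function(p = caru_params(), search = c(20, 200),
                      variant = "fast_ryr", tol = 0.05, step = 2) {
  fold <- find_fold(p, search = search)
  if (is.na(fold)) return(NA_real_)
  re_upper <- function(cT) {
    fp <- find_fixed_points(cT, p, variant = variant)
    if (nrow(fp) < 3) return(NA_real_)
    fp$re1[nrow(fp)]
  }
  grid <- seq(fold + 0.1, search[2], by = step)
  vals <- vapply(grid, re_upper, numeric(1))
  ok <- !is.na(vals)
  ch <- which(diff(sign(vals[ok])) != 0)
  if (!length(ch)) return(NA_real_)
  gi <- grid[ok]
  lo <- gi[ch[1]]; hi <- gi[ch[1] + 1]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (sign(re_upper(mid)) == sign(re_upper(lo))) lo <- mid else hi <- mid
  }
  locus <- (lo + hi) / 2
  # a genuine Hopf needs a complex pair crossing on a continuous branch;
  # a stability change through a fold/branch reorganisation (e.g. the
  # saddle-node stabilisation at high calsequestrin) is not one
  probe <- function(cT) {
    fp <- find_fixed_points(cT, p, variant = variant)
    fp[nrow(fp), c("c_i", "im1")]
  }
  below <- probe(max(locus - 4 * tol, fold + 0.05))
  above <- probe(locus + 4 * tol)
  spiral <- below$im1 > 1e-9 || above$im1 > 1e-9
  continuous <- abs(above$c_i - below$c_i) < 0.2 * max(below$c_i, 1e-9)
  if (!spiral || !continuous) return(NA_real_)
  locus
}

#' Homoclinic locus: smallest load with a sustained limit cycle
#'
#' Sweeps the load downward over sustained-oscillation probes (long
#' integrations from the kicked initial state, classified by
#' [sustained_oscillation()]) and bisects the boundary. Approaching the locus
#' from above the period grows without bound, the signature of a homoclinic
#' (infinite-period) bifurcation.
#'
#' @param p A [caru_params()] object.
#' @param variant Simulated variant.
#' @param search Load interval (\eqn{\mu}M); the upper end should oscillate.
#' @param tol Bisection tolerance (\eqn{\mu}M).
#' @param step Coarse upward scan step (\eqn{\mu}M).
#' @param t_end,transient Probe integration length and discarded transient
#'   (ms).
#' @return List: `load` (\eqn{\mu}M, `NA` if no oscillation was found
#'   anywhere in `search`) and `periods`, a data frame of probe loads and
#'   periods recording the period growth on approach.
#' @export
find_homoclinic <- function(p = caru_params(), variant = "fast_ryr",
                            search = c(35, 80), tol = 0.1, step = 2,
                            t_end = 60000, transient = 20000) {
  periods <- data.frame(cT_bar = numeric(0), period_ms = numeric(0))
  note <- function(cT, pr) {
    periods <<- rbind(periods,
                      data.frame(cT_bar = cT,
                                 period_ms = pr$analysis$period_ms))
    pr$osc
  }
  osc_at <- function(cT) note(cT, .probe(cT, p, variant, t_end = t_end,
                                         transient = transient))
  grid <- seq(search[1], search[2], by = step)
  first <- NA_integer_
  for (i in seq_along(grid)) {
    if (osc_at(grid[i])) { first <- i; break }
  }
  if (is.na(first)) return(list(load = NA_real_, periods = periods))
  if (first == 1) return(list(load = grid[1], periods = periods))
  lo <- grid[first - 1]; hi <- grid[first]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (osc_at(mid)) hi <- mid else lo <- mid
  }
  list(load = (lo + hi) / 2, periods = periods[order(periods$cT_bar), ])
}

#' Bifurcation sweep over the total-calcium load
#'
#' For each load on a grid, records all fixed points with stability and (for
#' the simulated variant) the limit-cycle extent and period measured by
#' direct long integration after the transient; then refines the fold,
#' homoclinic and Hopf loci by bisection.
#'
#' @param cT_range Load interval (\eqn{\mu}M) `c(min, max)`.
#' @param p A [caru_params()] object.
#' @param variant Simulated/classified variant.
#' @param step Grid step (\eqn{\mu}M).
#' @param do_cycles Integrate for limit cycles (set `FALSE` for a
#'   fixed-points-only sweep).
#' @param t_end,transient Probe settings (ms) for cycle measurement.
#' @param locus_tol Bisection tolerance for the loci (\eqn{\mu}M).
#' @return A `caru_bifurcation` list: `branches` (long data frame of fixed
#'   points per load), `cycles` (per load: `oscillating`, `cyc_min`,
#'   `cyc_max` of \eqn{c_i}, `period_ms`), and `loci`
#'   (`fold`, `homoclinic`, `hopf`).
#' @export
sweep_diagram <- function(cT_range, p = caru_params(), variant = "fast_ryr",
                          step = 0.25, do_cycles = TRUE, t_end = 60000,
                          transient = 20000, locus_tol = 0.1) {
  stopifnot(length(cT_range) == 2, diff(cT_range) > 0)
  loads <- seq(cT_range[1], cT_range[2], by = step)
  branches <- do.call(rbind, lapply(loads, function(cT) {
    fp <- find_fixed_points(cT, p, variant = variant)
    cbind(cT_bar = cT, as.data.frame(fp))
  }))
  cycles <- NULL
  if (do_cycles) {
    probes <- lapply(loads, function(cT) {
      pr <- .probe(cT, p, variant, t_end = t_end, transient = transient)
      tail_ci <- pr$trace$c_i[pr$trace$t_ms >= transient]
      data.frame(cT_bar = cT, oscillating = pr$osc,
                 cyc_min = if (pr$osc) min(tail_ci) else NA_real_,
                 cyc_max = if (pr$osc) max(tail_ci) else NA_real_,
                 period_ms = if (pr$osc) pr$analysis$period_ms else NA_real_)
    })
    cycles <- do.call(rbind, probes)
  }
  loci <- list(
    fold = find_fold(p, search = c(max(cT_range[1] - 10, 1e-3),
                                   cT_range[2]), tol = locus_tol),
    homoclinic = if (do_cycles) {
      find_homoclinic(p, variant, search = cT_range, tol = locus_tol,
                      t_end = t_end, transient = transient)$load
    } else NA_real_,
    hopf = find_hopf(p, search = c(max(cT_range[1] - 10, 1e-3), cT_range[2]),
                     variant = variant, tol = locus_tol))
  structure(list(branches = branches, cycles = cycles, loci = loci,
                 variant = variant, params = unclass(p)),
            class = "caru_bifurcation")
}

#' @export
print.caru_bifurcation <- function(x, ...) {
  cat(sprintf("Bifurcation sweep (%s variant), %d loads\n", x$variant,
              length(unique(x$branches$cT_bar))))
  cat(sprintf("  fold       : %s uM\n", format(x$loci$fold)))
  cat(sprintf("  homoclinic : %s uM\n", format(x$loci$homoclinic)))
  cat(sprintf("  Hopf       : %s uM\n", format(x$loci$hopf)))
  invisible(x)
}

#' Deterministic oscillatory load window
#'
#' The sustained-oscillation window of a variant is bounded below by the
#' homoclinic locus and above by the Hopf locus.
#'
#' @param p A [caru_params()] object.
#' @param variant Simulated variant.
#' @param search Load interval (\eqn{\mu}M).
#' @param tol Locus tolerance (\eqn{\mu}M).
#' @return `c(lo, hi)` in \eqn{\mu}M, or `NULL` when no sustained
#'   oscillation exists in `search` (empty window).
#' @export
oscillatory_window <- function(p = caru_params(), variant = "fast_ryr",
                               search = c(35, 90), tol = 0.1) {
  lo <- find_homoclinic(p, variant, search = search, tol = tol)$load
  if (is.na(lo)) return(NULL)
  hi <- find_hopf(p, search = c(max(search[1] - 20, 1e-3), search[2] + 40),
                  variant = variant, tol = tol)
  if (is.na(hi)) hi <- search[2]
  c(lo, hi)
}
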