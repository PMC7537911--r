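#' Simulate a chain of diffusively coupled stochastic release units
#'
#' A qualitative, desk-scale surrogate for wave phenomenology: `n_units`
#' fast-RyR units with per-step RyR noise ([stochastic_po()]), coupled by
#' pairwise diffusive exchange of cytosolic free calcium (rate `D_i`, per
#' ms) and optionally of free SR calcium (`D_sr`). Each unit keeps its own
#' total-calcium load, which evolves only through the exchange terms;
#' because exchange is pairwise antisymmetric the lattice-average load is
#' conserved exactly while the single-unit closure (cytosolic calcium slaved
#' to the local load) is untouched. No-flux boundaries; fixed-step Euler
#' with the step part of the model specification.
#'
#' @param n_units Number of units in the chain.
#' @param cT_bar Initial (uniform) load per unit (\eqn{\mu}M).
#' @param p A [caru_params()] object.
#' @param D_i,D_sr Exchange rates between neighbours (ms\eqn{^{-1}}).
#' @param sigma RyR noise strength.
#' @param t_end Simulated time (ms).
#' @param dt Euler step (ms); must satisfy the exchange stability bound
#'   `dt * 2 * max(D_i, D_sr) < 1` (violations are refused with a suggested
#'   step).
#' @param sample_dt Output sampling interval (ms).
#' @param seed Optional integer seed.
#' @param init Optional list with vectors `c_d`, `c_sr_tot`, `cT` (length
#'   `n_units`) overriding the uniform rest initial state.
#' @param kick_unit,kick Units (integer vector) given an initial
#'   dyadic-calcium kick (\eqn{\mu}M) to seed a release event; `NULL` for
#'   none. A single kicked unit is usually a sub-critical nucleus against
#'   the strong cytosolic buffering; a block of about three units ignites.
#' @return A `caru_lattice` list: `t` (ms), matrices `ci`, `cd`, `csrtot`,
#'   `cT` (samples \eqn{\times} units), and metadata.
#' @examples
#' \donttest{
#' lt <- lattice_simulate(20, cT_bar = 45, t_end = 5000, seed = 1)
#' dim(lt$ci)
#' }
#' @export
lattice_simulate <- function(n_units = 50, cT_bar = 54, p = caru_params(),
                             D_i = 0.5, D_sr = 0, sigma = 2e-3,
                             t_end = 30000, dt = 0.1, sample_dt = 5,
                             seed = NULL, init = NULL, kick_unit = NULL,
                             kick = 25) {
  stopifnot(n_units >= 1, t_end > 0, dt > 0)
  if (dt * 2 * max(D_i, D_sr) >= 1) {
    stop(sprintf("exchange step unstable; use dt < %g ms",
                 1 / (2 * max(D_i, D_sr))))
  }
  if (is.null(init)) {
    cd0 <- rep(0, n_units)
    cT0 <- rep(cT_bar, n_units)
    csr0 <- rep(p$v * cT_bar / p$v_sr, n_units)
  } else {
    cd0 <- init$c_d; csr0 <- init$c_sr_tot; cT0 <- init$cT
    stopifnot(length(cd0) == n_units, length(csr0) == n_units,
              length(cT0) == n_units)
  }
  if (!is.null(kick_unit)) {
    stopifnot(all(kick_unit >= 1), all(kick_unit <= n_units))
    cd0[kick_unit] <- kick
    csr0[kick_unit] <- (p$v * cT0[kick_unit] - p$v_d * kick) / p$v_sr
  }
  if (!is.null(seed)) set.seed(seed)
  thin <- max(1L, as.integer(round(sample_dt / dt)))
  n_steps <- as.integer(ceiling(t_end / dt))
  out <- .Call("caosc_lattice", as.numeric(cd0), as.numeric(csr0),
               as.numeric(cT0), .parms_vector(p, cT_bar), as.numeric(D_i),
               as.numeric(D_sr), as.numeric(sigma), as.numeric(dt), n_steps,
               thin, PACKAGE = "caosc")
  structure(list(t = out$t, ci = out$ci, cd = out$cd, csrtot = out$csrtot,
                 cT = out$cT,
                 metadata = list(n_units = n_units, cT_bar = cT_bar,
                                 D_i = D_i, D_sr = D_sr, sigma = sigma,
                                 dt = dt, sample_dt = thin * dt, seed = seed,
                                 params = unclass(p))),
            class = "caru_lattice")
}

#' @export
print.caru_lattice <- function(x, ...) {
  md <- x$metadata
  cat(sprintf(
    "CaRU lattice: %d units, cT_bar = %g uM, sigma = %g, D_i = %g, %d samples over %g ms\n",
    md$n_units, md$cT_bar, md$sigma, md$D_i, length(x$t), max(x$t)))
  invisible(x)
}

#' Mean lattice load (conservation diagnostic)
#'
#' @param lattice A `caru_lattice`.
#' @return Numeric vector: lattice-average total calcium load per sample; in
#'   exact arithmetic constant over time.
#' @export
lattice_mean_load <- function(lattice) {
  stopifnot(inherits(lattice, "caru_lattice"))
  rowMeans(lattice$cT)
}

#' Detect propagating release events in a lattice trace
#'
#' Thresholds the space-time cytosolic-calcium array at `threshold`
#' (default: midpoint between the resting level and the maximum observed
#' level), labels 4-connected supra-threshold components, and reports one
#' event per component with its origin, spatial extent and front speed (from
#' a linear fit of first-activation time per unit).
#'
#' @param lattice A `caru_lattice`.
#' @param threshold Activation threshold on `ci` (\eqn{\mu}M), or `NULL` for
#'   the default.
#' @param min_samples Discard components smaller than this many space-time
#'   cells.
#' @return Data frame with one row per event: `event`, `start_unit`,
#'   `start_ms`, `extent_units`, `duration_ms`, `speed_units_per_ms` (`NA`
#'   for single-unit events).
#' @export
wave_events <- function(lattice, threshold = NULL, min_samples = 3) {
  stopifnot(inherits(lattice, "caru_lattice"))
  ci <- lattice$ci
  if (is.null(threshold)) {
    rest <- stats::median(ci[1, ])
    threshold <- rest + 0.5 * (max(ci) - rest)
    if (!is.finite(threshold) || threshold <= rest) return(.empty_events())
  }
  mask <- ci > threshold
  if (!any(mask)) return(.empty_events())
  lab <- .Call("caosc_label_components", mask, PACKAGE = "caosc")
  t <- lattice$t
  evs <- lapply(seq_len(max(lab)), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx) < min_samples) return(NULL)
    units <- sort(unique(idx[, 2]))
    first_t <- vapply(units, function(u) min(t[idx[idx[, 2] == u, 1]]),
                      numeric(1))
    origin <- units[which.min(first_t)]
    speed <- NA_real_
    if (length(units) >= 3 && stats::sd(first_t) > 0) {
      fit <- stats::lm(units ~ first_t)
      speed <- abs(unname(stats::coef(fit)[2]))
    }
    data.frame(start_unit = origin, start_ms = min(first_t),
               extent_units = length(units),
               duration_ms = max(t[idx[, 1]]) - min(t[idx[, 1]]),
               speed_units_per_ms = speed)
  })
  evs <- do.call(rbind, evs)
  if (is.null(evs)) return(.empty_events())
  evs <- evs[order(evs$start_ms), , drop = FALSE]
  evs$event <- seq_len(nrow(evs))
  rownames(evs) <- NULL
  evs[, c("event", "start_unit", "start_ms", "extent_units", "duration_ms",
          "speed_units_per_ms")]
}

.empty_events <- function() {
  data.frame(event = integer(0), start_unit = integer(0),
             start_ms = numeric(0), extent_units = integer(0),
             duration_ms = numeric(0), speed_units_per_ms = numeric(0))
}
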