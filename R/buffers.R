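#' Free SR calcium from total SR calcium (rapid calsequestrin buffer)
#'
#' Calsequestrin (CSQ) binding is fast compared with release, so bound SR
#' calcium tracks its equilibrium \eqn{c_{bSQ} = B_{SQ} c_{sr}/(K_{SQ} +
#' c_{sr})}. Inverting the resulting relation between total and free SR
#' calcium gives the nonnegative root
#' \deqn{c_{sr} = \tfrac12\left[b + \sqrt{b^2 + 4 c_{sr}^{tot} K_{SQ}}\right],
#'   \quad b = c_{sr}^{tot} - K_{SQ} - B_{SQ}.}
#' Working with the total concentration and recovering the free one
#' algebraically conserves calcium mass exactly, which is why the dynamic
#' state of every model variant carries `c_sr_tot` rather than `c_sr`.
#'
#' @param c_sr_tot Total SR calcium (free + CSQ-bound), \eqn{\mu}M. Vectorised.
#' @param p A [caru_params()] object (uses `B_SQ`, `K_SQ`).
#' @return Free SR calcium (\eqn{\mu}M), same length as `c_sr_tot`.
#' @seealso [total_sr_calcium()] for the exact inverse.
#' @export
free_sr_calcium <- function(c_sr_tot, p = caru_params()) {
  if (any(!is.finite(c_sr_tot)) || any(c_sr_tot < 0)) {
    stop("c_sr_tot must be finite and nonnegative")
  }
  b <- c_sr_tot - p$K_SQ - p$B_SQ
  0.5 * (b + sqrt(b * b + 4 * c_sr_tot * p$K_SQ))
}

#' Total SR calcium from free SR calcium
#'
#' Forward form of the rapid-buffer relation:
#' \eqn{c_{sr}^{tot} = c_{sr} + B_{SQ} c_{sr} / (K_{SQ} + c_{sr})}.
#' Exact algebraic inverse of [free_sr_calcium()].
#'
#' @param c_sr Free SR calcium, \eqn{\mu}M. Vectorised.
#' @param p A [caru_params()] object.
#' @return Total SR calcium (\eqn{\mu}M).
#' @export
total_sr_calcium <- function(c_sr, p = caru_params()) {
  if (any(!is.finite(c_sr)) || any(c_sr < 0)) {
    stop("c_sr must be finite and nonnegative")
  }
  c_sr + p$B_SQ * c_sr / (p$K_SQ + c_sr)
}

#' Cytosolic free calcium from the total-calcium conservation law
#'
#' With no transmembrane fluxes the average total calcium load
#' \deqn{\bar c_T = \frac{v_i}{v}\left(c_i + \frac{B_b c_i}{K_b + c_i}\right)
#'   + \frac{v_d}{v} c_d + \frac{v_{sr}}{v} c_{sr}^{tot}}
#' is conserved, so \eqn{c_i} is never integrated: it is recovered at every
#' state from this quadratic. Writing the cytosolic budget (total cytosolic
#' calcium per cytosolic volume) as
#' \eqn{R = (v\,\bar c_T - v_d c_d - v_{sr} c_{sr}^{tot})/v_i}, the unique
#' nonnegative root is
#' \deqn{c_i = \tfrac12\left[(R - K_b - B_b) +
#'   \sqrt{(R - K_b - B_b)^2 + 4 K_b R}\right].}
#'
#' @param cT_bar Average total calcium load (\eqn{\mu}M).
#' @param c_d Dyadic free calcium (\eqn{\mu}M). Vectorised with `c_sr_tot`.
#' @param c_sr_tot Total SR calcium (\eqn{\mu}M).
#' @param p A [caru_params()] object.
#' @return Cytosolic free calcium \eqn{c_i} (\eqn{\mu}M).
#'   Substituting the result back into the conservation law reproduces
#'   `cT_bar` to round-off.
#' @section Errors: a negative cytosolic budget (more calcium placed in the
#'   dyad and SR than the load allows) signals integrator or caller misuse
#'   and raises an error of class `caosc_infeasible_state`.
#' @export
solve_cytosolic <- function(cT_bar, c_d, c_sr_tot, p = caru_params()) {
  R <- (p$v * cT_bar - p$v_d * c_d - p$v_sr * c_sr_tot) / p$v_i
  # tolerate round-off-scale violations of the budget (e.g. finite-difference
  # probes at the all-calcium-in-SR boundary)
  tiny <- R < 0 & R > -1e-8 * (abs(cT_bar) + 1)
  R[tiny] <- 0
  if (any(R < 0)) {
    stop(structure(
      class = c("caosc_infeasible_state", "error", "condition"),
      list(message = sprintf(
             "infeasible state: cytosolic calcium budget is negative (min R = %.6g uM)",
             min(R)),
           call = sys.call(-1))))
  }
  b <- R - p$K_b - p$B_b
  0.5 * (b + sqrt(b * b + 4 * p$K_b * R))
}

#' Reconstruct the total-calcium load from a state
#'
#' Evaluates the conservation law at a state `(c_i, c_d, c_sr_tot)`. Used by
#' the mass-conservation invariant checks: for any state produced by the
#' package, the reconstruction equals the configured load to root-solver
#' tolerance.
#'
#' @param c_i,c_d,c_sr_tot Cytosolic free, dyadic free and total SR calcium
#'   (\eqn{\mu}M). Vectorised.
#' @param p A [caru_params()] object.
#' @return The implied average total calcium load (\eqn{\mu}M).
#' @export
total_cell_calcium <- function(c_i, c_d, c_sr_tot, p = caru_params()) {
  (p$v_i * (c_i + p$B_b * c_i / (p$K_b + c_i)) +
     p$v_d * c_d + p$v_sr * c_sr_tot) / p$v
}
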