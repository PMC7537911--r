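#' Model parameters for the minimal calcium-release-unit model
#'
#' Constructs and validates the parameter set of the minimal CaRU model.
#' Units are fixed project-wide: concentrations in \eqn{\mu}M, time in ms,
#' and compartment volumes as dimensionless fractions of the unit volume
#' \eqn{v = v_i + v_{sr} + v_d}.
#'
#' @param g RyR release conductance (ms\eqn{^{-1}}).
#' @param tau_i Dyad-to-cytosol diffusion time (ms).
#' @param g_up SERCA maximal uptake rate (\eqn{\mu}M/ms).
#' @param K_s SERCA half-saturation constant (\eqn{\mu}M).
#' @param K_o RyR half-activation of the open probability (\eqn{\mu}M);
#'   \eqn{K_o^2 = k_m/k_p}.
#' @param k_p RyR opening rate coefficient (\eqn{\mu}M\eqn{^{-2}}
#'   ms\eqn{^{-1}}).
#' @param k_m RyR closing rate (ms\eqn{^{-1}}).
#' @param v_i,v_sr,v_d Cytosolic, SR and dyadic volume fractions
#'   (dimensionless; their sum is the unit volume \eqn{v}).
#' @param B_b Generic cytosolic buffer concentration (\eqn{\mu}M).
#' @param K_b Cytosolic buffer dissociation constant (\eqn{\mu}M).
#' @param B_SQ Calsequestrin concentration in the SR (\eqn{\mu}M).
#' @param K_SQ Calsequestrin dissociation constant (\eqn{\mu}M).
#'
#' @return An object of class `caru_params`: a named list of the values
#'   above plus the derived unit volume `v`.
#'
#' @details The defaults are the package's control set. Values printed in the
#'   source literature (`K_o`, `B_b`, `K_b`, `K_SQ`) are tagged `PAPER` in
#'   [param_provenance()]; the remaining rates and volumes are tagged
#'   `DERIVED`: they were calibrated once against the printed onset algebra
#'   (which pins \eqn{v/v_{sr}} = 45.6 and
#'   \eqn{\tilde g = g\,\tau_i/K_o^2 = 1/1120\;\mu}M\eqn{^{-2}}) and the
#'   printed bifurcation loci of the control bifurcation diagram. See the
#'   methods vignette for the calibration argument.
#'
#' @examples
#' p <- caru_params()
#' p$v_i + p$v_sr + p$v_d  # unit volume, 1 by construction
#' caru_params(B_SQ = 2000) # 2 mM calsequestrin
#' @export
caru_params <- function(g = (225 / 1120) / 0.1,
                        tau_i = 0.1,
                        g_up = 10.6 * 0.001 / ((1 - 1 / 45.6 - 0.001) * 0.1),
                        K_s = 0.64,
                        K_o = 15,
                        k_p = 2.1e-3,
                        k_m = 2.1e-3 * 15^2,
                        v_i = 1 - 1 / 45.6 - 0.001,
                        v_sr = 1 / 45.6,
                        v_d = 0.001,
                        B_b = 80,
                        K_b = 0.5,
                        B_SQ = 0,
                        K_SQ = 650) {
  p <- list(g = g, tau_i = tau_i, g_up = g_up, K_s = K_s, K_o = K_o,
            k_p = k_p, k_m = k_m, v_i = v_i, v_sr = v_sr, v_d = v_d,
            B_b = B_b, K_b = K_b, B_SQ = B_SQ, K_SQ = K_SQ)
  p$v <- v_i + v_sr + v_d
  class(p) <- "caru_params"
  validate_params(p)
  p
}

#' Validate a `caru_params` object
#'
#' Checks positivity/nonnegativity constraints and unit-volume consistency.
#' Called by [caru_params()] and the parameter-file reader.
#'
#' @param p A `caru_params` object.
#' @return `p`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "caru_params"))
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("non-finite or non-scalar parameter(s): ",
         paste(names(p)[!num], collapse = ", "))
  }
  nonneg <- c("g", "tau_i", "g_up", "k_p", "k_m", "v_i", "v_sr", "v_d",
              "B_b", "B_SQ")
  bad <- nonneg[vapply(nonneg, function(n) p[[n]] < 0, logical(1))]
  if (length(bad)) stop("negative parameter(s): ", paste(bad, collapse = ", "))
  pos <- c("K_o", "K_b", "K_s", "K_SQ", "tau_i")
  bad <- pos[vapply(pos, function(n) p[[n]] <= 0, logical(1))]
  if (length(bad)) {
    stop("parameter(s) must be strictly positive: ", paste(bad, collapse = ", "))
  }
  v <- p$v_i + p$v_sr + p$v_d
  if (v <= 0) stop("total unit volume v_i + v_sr + v_d must be positive")
  if (abs(p$v - v) > 1e-12 * v) stop("stored unit volume v inconsistent")
  invisible(p)
}

#' @export
print.caru_params <- function(x, ...) {
  prov <- param_provenance()
  cat("Minimal CaRU model parameters (uM, ms, volume fractions of v):\n")
  for (n in setdiff(names(x), "v")) {
    cat(sprintf("  %-6s = %-12.6g [%s]\n", n, x[[n]],
                if (n %in% names(prov)) prov[[n]] else "?"))
  }
  cat(sprintf("  %-6s = %-12.6g (derived)\n", "v", x$v))
  invisible(x)
}

#' Provenance tags of the control parameter values
#'
#' Each control value is tagged `PAPER` (printed in the source literature) or
#' `DERIVED` (fixed by the package's calibration against printed onset
#' algebra and bifurcation loci).
#'
#' @return Named character vector of tags.
#' @export
param_provenance <- function() {
  c(g = "DERIVED", tau_i = "DERIVED", g_up = "DERIVED", K_s = "DERIVED",
    K_o = "PAPER", k_p = "DERIVED", k_m = "DERIVED", v_i = "DERIVED",
    v_sr = "DERIVED", v_d = "DERIVED", B_b = "PAPER", K_b = "PAPER",
    B_SQ = "PAPER", K_SQ = "PAPER")
}

#' Read model parameters from a key = value text file
#'
#' The file format is one `name = value` pair per line; `#` starts a comment
#' (full-line or trailing). All fourteen parameter names accepted by
#' [caru_params()] must be present exactly once. The shipped control file is
#' at `system.file("extdata", "control_params.txt", package = "caosc")`.
#'
#' @param path Path to the parameter file.
#' @return A validated `caru_params` object.
#' @export
read_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed parameter line(s): ", lines[bad][1])
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, "", 2))))
  if (anyNA(vals)) stop("non-numeric value for: ", keys[is.na(vals)][1])
  if (anyDuplicated(keys)) stop("duplicated key: ", keys[duplicated(keys)][1])
  want <- setdiff(names(formals(caru_params)), character())
  missing <- setdiff(want, keys)
  if (length(missing)) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(keys, want)
  if (length(extra)) stop("unknown parameter(s): ", paste(extra, collapse = ", "))
  do.call(caru_params, as.list(stats::setNames(vals, keys))[want])
}

#' Write model parameters to a key = value text file
#'
#' Writes all fourteen parameters with their provenance tags as trailing
#' comments, in a format readable by [read_params()].
#'
#' @param p A `caru_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(p, path) {
  validate_params(p)
  prov <- param_provenance()
  ns <- setdiff(names(p), "v")
  lines <- c(
    "# Minimal CaRU model parameters (concentrations uM, time ms,",
    "# volumes as fractions of the unit volume v = v_i + v_sr + v_d)",
    sprintf("%-6s = %.15g  # %s", ns, unlist(p[ns], use.names = FALSE),
            prov[ns]))
  writeLines(lines, path)
  invisible(path)
}

#' Total-calcium load specification
#'
#' The control parameter of the model is the average total cell calcium
#' \eqn{\bar c_T = Q_T / (v_i + v_{sr})}, where \eqn{Q_T} is the total
#' calcium content of the unit (free plus buffer-bound, all compartments).
#'
#' @param cT_bar Average total calcium load (\eqn{\mu}M), nonnegative.
#' @param p A `caru_params` object (for the volume fractions).
#' @return A `load_spec` list with `cT_bar` and the implied total content
#'   `Q_T` (\eqn{\mu}M \eqn{\times} volume).
#' @export
load_spec <- function(cT_bar, p = caru_params()) {
  if (!is.numeric(cT_bar) || length(cT_bar) != 1 || !is.finite(cT_bar) ||
      cT_bar < 0) {
    stop("cT_bar must be a single nonnegative number (uM)")
  }
  structure(list(cT_bar = cT_bar, Q_T = cT_bar * (p$v_i + p$v_sr)),
            class = "load_spec")
}

# parameter vector handed to compiled code; order must match src/rhs.c
.parms_vector <- function(p, cT_bar) {
  c(p$g, p$tau_i, p$g_up, p$K_s, p$K_o, p$k_p, p$k_m,
    p$v_i, p$v_sr, p$v_d, p$B_b, p$K_b, p$B_SQ, p$K_SQ, cT_bar)
}
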