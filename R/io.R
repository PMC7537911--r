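#' Generate a synthetic trace fixture with known ground truth
#'
#' Produces `caru_trace` objects whose period and regime are known by
#' construction, for exercising [estimate_period()] and
#' [sustained_oscillation()] independently of the model dynamics. The
#' synthetic signal is written into the `c_i` column (the other columns
#' carry consistent placeholders).
#'
#' Kinds: `"sinusoid"` (pure sine), `"constant"`, `"relaxation"`
#' (spike train with sharp upstrokes and exponential recovery, mimicking
#' release/refill cycles), `"noisy_oscillation"` (spike train with jittered
#' cycle lengths of coefficient of variation `cv` and additive measurement
#' noise).
#'
#' @param kind Fixture kind (see above).
#' @param period_ms Target period (ignored for `"constant"`).
#' @param t_end,sample_dt Trace length and sampling (ms).
#' @param amplitude Peak-to-peak amplitude (\eqn{\mu}M).
#' @param baseline Baseline level (\eqn{\mu}M).
#' @param cv Cycle-length coefficient of variation for
#'   `"noisy_oscillation"`.
#' @param seed Integer seed for the jittered kinds.
#' @return A `caru_trace` whose metadata records `fixture_kind` and
#'   `true_period_ms` (`NA` for `"constant"`).
#' @export
generate_fixture <- function(kind = c("sinusoid", "constant", "relaxation",
                                      "noisy_oscillation"),
                             period_ms = 1000, t_end = 30000, sample_dt = 2,
                             amplitude = 1, baseline = 0.1, cv = 0.1,
                             seed = 1) {
  kind <- match.arg(kind)
  t <- seq(0, t_end, by = sample_dt)
  spike_train <- function(starts) {
    x <- rep(baseline, length(t))
    for (s in starts) {
      seg <- t >= s
      x[seg] <- pmax(x[seg],
                     baseline + amplitude * exp(-(t[seg] - s) /
                                                  (0.15 * period_ms)))
    }
    x
  }
  x <- switch(kind,
    sinusoid = baseline + amplitude / 2 *
      (1 + sin(2 * pi * t / period_ms)),
    constant = rep(baseline, length(t)),
    relaxation = spike_train(seq(period_ms / 2, t_end, by = period_ms)),
    noisy_oscillation = {
      set.seed(seed)
      gaps <- stats::rnorm(ceiling(2 * t_end / period_ms), mean = period_ms,
                           sd = cv * period_ms)
      gaps <- pmax(gaps, 0.2 * period_ms)
      starts <- cumsum(gaps)
      starts <- starts[starts < t_end]
      spike_train(starts) +
        stats::rnorm(length(t), sd = 0.02 * amplitude)
    })
  p <- caru_params()
  df <- data.frame(t_ms = t, c_d = 0, c_sr_tot = 0, c_sr = 0, c_i = x,
                   P_o = 0)
  new_caru_trace(df, variant = "fixture", cT_bar = 0, p = p, sigma = 0,
                 seed = seed,
                 settings = list(sample_dt = sample_dt),
                 extra = list(fixture_kind = kind,
                              true_period_ms = if (kind == "constant")
                                NA_real_ else period_ms))
}

#' Write / read a simulation trace as CSV with a JSON metadata sidecar
#'
#' Numeric columns are written with 12 significant digits, enough for a
#' write/read round trip to be bit-identical at that precision. Metadata
#' (variant, load, noise, seed, integrator settings, full parameter set) go
#' to `<path>.meta.json`.
#'
#' @param trace A `caru_trace`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "caru_trace"))
  df <- as.data.frame(lapply(trace, function(col) {
    if (is.numeric(col)) signif(col, 12) else col
  }))
  utils::write.csv(format(df, digits = 12, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(trace_metadata(trace), paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_trace
#' @param path CSV path previously written by [write_trace()].
#' @return `read_trace()`: the reconstructed `caru_trace`.
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  md <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  p <- structure(as.list(md$params), class = "caru_params")
  new_caru_trace(df, variant = md$variant, cT_bar = md$cT_bar, p = p,
                 sigma = md$sigma, seed = md$seed,
                 settings = as.list(md$settings),
                 extra = md[setdiff(names(md),
                                    c("variant", "cT_bar", "B_SQ", "sigma",
                                      "seed", "settings", "params"))])
}

#' Write a bifurcation sweep as CSV
#'
#' One row per (load, branch) for the fixed-point table, with the cycle
#' columns merged in on the load; row count is grid size \eqn{\times}
#' branches.
#'
#' @param diagram A `caru_bifurcation` from [sweep_diagram()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_diagram <- function(diagram, path) {
  stopifnot(inherits(diagram, "caru_bifurcation"))
  br <- diagram$branches
  if (!is.null(diagram$cycles)) {
    br <- merge(br, diagram$cycles, by = "cT_bar", all.x = TRUE, sort = FALSE)
  }
  br <- br[order(br$cT_bar, br$c_i), ]
  num <- vapply(br, is.numeric, logical(1))
  br[num] <- lapply(br[num], signif, digits = 12)
  utils::write.csv(br, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a short text report of the detected bifurcation loci
#'
#' @param diagram A `caru_bifurcation`.
#' @param path Output path.
#' @param locus_tol The bisection tolerance (\eqn{\mu}M) to cite.
#' @return `path`, invisibly.
#' @export
write_report <- function(diagram, path, locus_tol = 0.1) {
  stopifnot(inherits(diagram, "caru_bifurcation"))
  l <- diagram$loci
  lines <- c(
    sprintf("Bifurcation loci (%s variant), bisection tolerance %.3g uM:",
            diagram$variant, locus_tol),
    sprintf("  fold (birth of nontrivial branches): %s uM", format(l$fold)),
    sprintf("  homoclinic (first sustained cycle) : %s uM",
            format(l$homoclinic)),
    sprintf("  Hopf (upper branch changes stability): %s uM",
            format(l$hopf)))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a run configuration
#'
#' A run configuration is a flat `key = value` text file (same syntax as the
#' parameter files, but values may also be strings) selecting the model
#' variant, load, calsequestrin level, noise, seed and integrator settings.
#' A run is reproducible from its persisted configuration plus seed.
#'
#' @param path Configuration file path.
#' @return Named list of configuration values (numbers where parseable).
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2)) stop("malformed config line")
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  out <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (is.na(n)) v else n
  })
  stats::setNames(out, keys)
}

#' @rdname read_run_config
#' @param config Named list of scalar values.
#' @export
write_run_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, function(v) format(v, digits = 15), "")),
             path)
  invisible(path)
}

#' Derive independent seed streams from a single run seed
#'
#' Expands one integer seed into reproducible per-stream seeds (units,
#' realizations) with a counter-based integer hash, so stochastic sweeps can
#' run any subset of streams independently of ordering.
#'
#' @param seed Base integer seed.
#' @param n Number of streams.
#' @return Integer vector of `n` seeds in `[0, 2^31)`.
#' @export
seed_streams <- function(seed, n) {
  vapply(seq_len(n), function(i) {
    x <- (as.double(seed) * 2654435761 + i * 40503) %% 2147483647
    x <- (x * 48271) %% 2147483647
    as.integer(x)
  }, integer(1))
}
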