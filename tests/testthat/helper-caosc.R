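# Shared fixtures: the control parameter set and a small cache of expensive
# computations reused across test files.
ctrl <- caosc::caru_params()

# independent oracle for the rapid-buffer inversion: bisection on the
# forward relation c_sr + B_SQ c_sr/(K_SQ + c_sr) = c_sr_tot
bisect_free_sr <- function(c_sr_tot, B_SQ, K_SQ, tol = 1e-12) {
  f <- function(x) x + B_SQ * x / (K_SQ + x) - c_sr_tot
  lo <- 0; hi <- c_sr_tot
  while ((hi - lo) > tol * max(1, hi)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
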