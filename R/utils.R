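# Internal helpers shared across modules.

#' Mode of a positive ratio distribution
#'
#' Estimates the peak of a unimodal ratio distribution with a Gaussian
#' kernel density evaluated on a regular grid spanning the data padded by
#' three bandwidths, and returns the grid point with maximal density.
#' The Sheather-Jones plug-in bandwidth is used (it tracks a sharp
#' conserved-probe peak contaminated by a diverged-probe tail much better
#' than Silverman's rule, which over-smooths the peak toward the tail);
#' Silverman's rule is the fallback when the plug-in fails on small or
#' degenerate samples. Ties in the argmax are broken toward the smallest
#' ratio. Degenerate input (all values equal) returns that value
#' directly.
#'
#' This is the scaling-factor primitive used to normalise one sample to
#' another gene by gene: the mode of the per-probe intensity ratio is
#' driven by probes hybridising equally to both sources (conserved
#' features) and is robust to the minority of diverged probes.
#'
#' @param x numeric vector of positive ratios.
#' @param n_grid number of grid points for the density evaluation.
#' @return the estimated mode (scalar).
#' @examples
#' ratio_mode(c(rep(2, 40), rep(0.3, 10)) * exp(rnorm(50, 0, 0.01)))
#' @export
ratio_mode <- function(x, n_grid = 512L) {
  stopifnot(is.numeric(x), length(x) >= 1L)
  if (!all(is.finite(x))) stop("ratios must be finite")
  if (diff(range(x)) == 0) {
    return(x[[1L]])
  }
  bw <- tryCatch(stats::bw.SJ(x), error = function(e) stats::bw.nrd0(x))
  d <- stats::density(x, bw = bw, n = n_grid, cut = 3)
  d$x[[which.max(d$y)]]
}

# Row-wise Welch two-sample t-test on two matrices with matching rows.
# Returns a data.frame with the statistic, Welch-Satterthwaite df, and
# two-sided p. Rows where both groups have zero variance and equal means
# get NA (untestable); zero variance with unequal means gives p = 0.
welch_rows <- function(X, Y) {
  stopifnot(nrow(X) == nrow(Y), ncol(X) >= 2L, ncol(Y) >= 2L)
  nx <- ncol(X)
  ny <- ncol(Y)
  mx <- rowMeans(X)
  my <- rowMeans(Y)
  vx <- rowSums((X - mx)^2) / (nx - 1)
  vy <- rowSums((Y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tt <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  degen <- se2 == 0
  if (any(degen)) {
    same <- degen & (mx == my)
    tt[same] <- NA_real_
    p[same] <- NA_real_
    diffr <- degen & (mx != my)
    tt[diffr] <- sign(mx - my)[diffr] * Inf
    p[diffr] <- 0
  }
  data.frame(statistic = tt, df = df, p_value = p, mean_diff = mx - my)
}

# Shapiro-Wilk p-value with guards: constant vectors are treated as
# degenerate (no evidence against normality, p = NA), and n outside
# [3, 5000] returns NA.
shapiro_p <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L || length(x) > 5000L) {
    return(NA_real_)
  }
  if (diff(range(x)) == 0) {
    return(NA_real_)
  }
  stats::shapiro.test(x)$p.value
}

# Unanimous-sign check used by the replicate-robustness rule for
# diagnostic features: TRUE when every cross-replicate pairing of the two
# groups has the same sign of difference, i.e. the two sets of replicate
# values do not overlap.
unanimous_sign_rows <- function(X, Y) {
  apply(X, 1, min) > apply(Y, 1, max) | apply(X, 1, max) < apply(Y, 1, min)
}
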