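#' Geweke convergence diagnostic
#'
#' Compares the mean of an early window of an MCMC chain with the mean of a
#' late window, standardizing by spectral-density-at-zero estimates of each
#' window's long-run variance:
#' `z = (m_A - m_B) / sqrt(s_A/n_A + s_B/n_B)`. Under stationarity z is
#' approximately standard normal; `|z| > 1.96` flags non-convergence at the
#' 5% level. The spectral density is a Bartlett-tapered autocovariance sum
#' with bandwidth 4% of the window length.
#'
#' @param chain numeric vector of at least 100 MCMC draws.
#' @param frac_first fraction of the chain in the early window (default 0.1).
#' @param frac_last fraction in the late window (default 0.5).
#' @return list of class `geweke` with `z`, `p` (two-sided), and the window
#'   fractions.
#' @export
geweke_z <- function(chain, frac_first = 0.1, frac_last = 0.5) {
  n <- length(chain)
  if (n < 100) stop("chain too short for the Geweke diagnostic (need >= 100)")
  if (frac_first <= 0 || frac_last <= 0 || frac_first + frac_last > 1)
    stop("window fractions must be positive and non-overlapping")
  if (stats::sd(chain) == 0) stop("degenerate chain (zero variance)")
  na <- floor(frac_first * n)
  nb <- floor(frac_last * n)
  A <- chain[seq_len(na)]
  B <- chain[seq.int(n - nb + 1L, n)]
  z <- (mean(A) - mean(B)) / sqrt(spectrum0(A) / na + spectrum0(B) / nb)
  out <- list(z = z, p = 2 * stats::pnorm(-abs(z)),
              frac_first = frac_first, frac_last = frac_last)
  class(out) <- "geweke"
  out
}

#' @export
print.geweke <- function(x, ...) {
  cat(sprintf("Geweke z = %.3f (two-sided p = %.4f; windows %.0f%%/%.0f%%)\n",
              x$z, x$p, 100 * x$frac_first, 100 * x$frac_last))
  invisible(x)
}

# spectral density at frequency zero: Bartlett lag window over 4% of n
spectrum0 <- function(x) {
  n <- length(x)
  L <- max(1L, floor(0.04 * n))
  ac <- stats::acf(x, lag.max = L, type = "covariance", plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  w <- 1 - seq_len(L) / (L + 1)
  max(ac[1] + 2 * sum(w * ac[-1]), .Machine$double.eps * ac[1])
}

#' Posterior summary of a scalar chain
#'
#' Mean, SD and two 95% interval conventions: the central quantile interval
#' (which respects the support, e.g. stays positive for variances) and the
#' normal-approximation interval `mean +/- 1.96 SD` (which can stray outside
#' the support and is reported for comparability with tables built that way).
#'
#' @param x numeric vector of draws (length >= 2).
#' @return list with `mean`, `sd`, `ci_quantile`, `ci_normal`.
#' @export
posterior_summary <- function(x) {
  stopifnot(length(x) >= 2)
  m <- mean(x); s <- stats::sd(x)
  list(mean = m, sd = s,
       ci_quantile = unname(stats::quantile(x, c(0.025, 0.975))),
       ci_normal = c(m - 1.96 * s, m + 1.96 * s))
}
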