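#' Cross-correlation function of two binned spike trains
#'
#' `R_xy(tau) = (1/N) sum_t x(t) y(t + tau)` for lags
#' `tau = -max_lag_bins .. +max_lag_bins`. Out-of-range samples of `y` are
#' treated as zero (zero padding) and the normalization is `1/N` at every
#' lag, i.e. no renormalization by the overlap length.
#'
#' @param x,y Numeric vectors of equal length `N > 0` (spike counts).
#' @param max_lag_bins Maximum lag in bins.
#' @return Numeric vector of length `2 * max_lag_bins + 1`, named by lag.
#' @export
cross_correlation_function <- function(x, y, max_lag_bins) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n == 0L) stop("input series must be non-empty")
  if (length(y) != n) stop("x and y must have the same length")
  L <- as.integer(max_lag_bins)
  stopifnot(L >= 0L)
  lags <- -L:L
  r <- vapply(lags, function(tau) {
    if (tau >= 0) {
      idx <- seq_len(n - tau)
      if (!length(idx) || tau >= n) 0 else sum(x[idx] * y[idx + tau])
    } else {
      idx <- seq_len(n + tau)
      if (!length(idx) || -tau >= n) 0 else sum(x[idx - tau] * y[idx])
    }
  }, numeric(1)) / n
  names(r) <- lags
  r
}

#' Covariance function of two binned spike trains
#'
#' `C_xy(tau) = R_xy(tau) - mu_x mu_y`, with the means taken over the full
#' record.
#'
#' @inheritParams cross_correlation_function
#' @return Numeric vector of length `2 * max_lag_bins + 1`, named by lag.
#' @export
covariance_function <- function(x, y, max_lag_bins) {
  cross_correlation_function(x, y, max_lag_bins) - mean(x) * mean(y)
}

#' Cross-correlation coefficient function
#'
#' `rho_xy(tau) = C_xy(tau) / (sigma_x sigma_y)` with
#' `sigma_x = sqrt(C_xx(0))` taken over the full record (not
#' lag-dependent). `rho_xy(0)` is the Pearson correlation coefficient of
#' the two count vectors.
#'
#' @inheritParams cross_correlation_function
#' @return Numeric vector of length `2 * max_lag_bins + 1`, named by lag.
#' @export
cross_correlation_coefficient_function <- function(x, y, max_lag_bins) {
  sx <- sqrt(mean(x^2) - mean(x)^2)
  sy <- sqrt(mean(y^2) - mean(y)^2)
  if (sx == 0 || sy == 0) {
    stop("zero-variance input: the pair is undefined and must be masked")
  }
  covariance_function(x, y, max_lag_bins) / (sx * sy)
}

#' Construct a correlation matrix object
#'
#' @param values Symmetric numeric matrix; undefined entries `NA`.
#' @param bin_width Bin width (ms) the matrix was computed at.
#' @param kind `"CC"` (fine-scale Pearson), `"RC"` (coarse-scale rate
#'   correlation) or `"P"` (integral correlation).
#' @param valid_mask Symmetric logical matrix marking defined pairs.
#' @param neuron_ids Row/column labels.
#' @return An object of class `correlation_matrix`.
#' @export
correlation_matrix_object <- function(values, bin_width, kind, valid_mask,
                                      neuron_ids) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values),
            kind %in% c("CC", "RC", "P"),
            is.matrix(valid_mask), all(dim(valid_mask) == dim(values)),
            length(neuron_ids) == nrow(values))
  dimnames(values) <- list(neuron_ids, neuron_ids)
  dimnames(valid_mask) <- dimnames(values)
  structure(list(values = values, bin_width = as.numeric(bin_width),
                 kind = kind, valid_mask = valid_mask,
                 neuron_ids = neuron_ids),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("correlation_matrix [%s] %dx%d at %g ms bins; %d invalid pairs\n",
              x$kind, nrow(x$values), ncol(x$values), x$bin_width,
              sum(!x$valid_mask[upper.tri(x$valid_mask)])))
  invisible(x)
}

#' Zero-lag Pearson correlation matrix of binned spike trains
#'
#' All pairwise `rho_xy(0)`. The fine temporal scale uses 2 ms bins (kind
#' `CC`) and the coarse scale 100 ms bins (rate correlation, kind `RC`);
#' the kind is inferred from the bin width unless given. Pairs involving a
#' zero-variance (silent or saturated) unit are masked invalid rather than
#' propagated as NaN.
#'
#' @param binned A [bin_spike_trains()] result with at least 2 neurons.
#' @param kind Optional override of the matrix kind.
#' @return A `correlation_matrix` with unit diagonal on valid entries.
#' @export
correlation_matrix <- function(binned, kind = NULL) {
  stopifnot(inherits(binned, "binned_matrix"))
  m <- binned$counts
  if (nrow(m) < 2L) stop("at least two neurons are required")
  if (is.null(kind)) kind <- if (binned$bin_width <= 10) "CC" else "RC"
  storage.mode(m) <- "double"
  centered <- m - rowMeans(m)
  ss <- sqrt(rowSums(centered^2))
  valid_unit <- ss > 0
  n <- nrow(m)
  values <- matrix(NA_real_, n, n)
  if (sum(valid_unit) >= 1L) {
    a <- centered[valid_unit, , drop = FALSE] / ss[valid_unit]
    cc <- tcrossprod(a)
    cc[cc > 1] <- 1
    cc[cc < -1] <- -1
    diag(cc) <- 1
    values[valid_unit, valid_unit] <- cc
  }
  valid_mask <- outer(valid_unit, valid_unit, `&`)
  correlation_matrix_object(values, binned$bin_width, kind, valid_mask,
                            binned$neuron_ids)
}

#' Integral correlation matrix (summed cross-correlation coefficients)
#'
#' `P_xy = sum_{tau = -Delta}^{Delta} rho_xy(tau)`, conventionally computed
#' on 2 ms bins with `Delta = 50` (lags up to 100 ms), capturing lagged
#' pairwise coupling beyond the zero-lag coefficient. Uses the identity
#' `sum_tau R_xy(tau) = (1/N) x . s_y` with `s_y` a zero-padded rolling sum
#' of `y` over `2 Delta + 1` bins, which matches the lag-by-lag sum exactly.
#'
#' @param binned A [bin_spike_trains()] result (2 ms bins by convention).
#' @param delta_bins Half-width `Delta` of the lag window in bins.
#' @return A `correlation_matrix` of kind `"P"` (diagonal is `P_xx`, not 1).
#' @export
integral_correlation_matrix <- function(binned, delta_bins = 50L) {
  stopifnot(inherits(binned, "binned_matrix"))
  m <- binned$counts
  if (nrow(m) < 2L) stop("at least two neurons are required")
  delta <- as.integer(delta_bins)
  stopifnot(delta >= 0L)
  n <- nrow(m); N <- ncol(m)
  mu <- rowMeans(m)
  sds <- sqrt(rowMeans(m^2) - mu^2)  # sigma = sqrt(C_xx(0)), population form
  valid_unit <- sds > 0
  # zero-padded rolling sum over [t - delta, t + delta]
  storage.mode(m) <- "double"
  cs <- cbind(0, t(apply(m, 1L, cumsum)))
  hi <- pmin(N, seq_len(N) + delta)
  lo <- pmax(0L, seq_len(N) - delta - 1L)
  s <- cs[, hi + 1L, drop = FALSE] - cs[, lo + 1L, drop = FALSE]
  raw <- m %*% t(s) / N                       # sum_tau R_xy(tau)
  raw <- (raw + t(raw)) / 2                   # symmetrize float error
  values <- (raw - (2 * delta + 1) * outer(mu, mu)) / outer(sds, sds)
  values[!valid_unit, ] <- NA_real_
  values[, !valid_unit] <- NA_real_
  valid_mask <- outer(valid_unit, valid_unit, `&`)
  correlation_matrix_object(values, binned$bin_width, "P", valid_mask,
                            binned$neuron_ids)
}

#' Export a correlation matrix as delimiter-separated text
#'
#' @param C A `correlation_matrix`.
#' @param path Output path.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_correlation_matrix <- function(C, path, sep = "\t") {
  stopifnot(inherits(C, "correlation_matrix"))
  utils::write.table(C$values, path, sep = sep, quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}
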