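# CASF-style scoring-power metrics: RMSE, SD in linear correlation,
# Pearson Rp and Spearman Rs between measured and predicted affinity,
# plus the median-over-seeds summary.

#' Scoring-power metrics of a prediction set
#'
#' For predicted affinities `p` and measured affinities `y` (both pKd
#' scale, length N):
#' \itemize{
#'   \item RMSE: `sqrt(mean((y - p)^2))`;
#'   \item (a, b): intercept and slope of the least-squares line of `y`
#'     on `p` (measured regressed on predicted, the CASF convention);
#'   \item SD: `sqrt(sum((y - (a + b p))^2) / (N - 1))`, the residual
#'     standard deviation about that line (denominator configurable to N);
#'   \item Rp: Pearson correlation of p and y;
#'   \item Rs: Pearson correlation of the rank vectors, average ranks for
#'     ties (i.e. Spearman).
#' }
#' Lower RMSE/SD and higher Rp/Rs mean better scoring power. When `p` or
#' `y` has zero variance the correlation-based metrics are undefined and
#' reported as `NA` with a warning, never as 0.
#'
#' @param p numeric vector of predicted affinities.
#' @param y numeric vector of measured affinities, same length (N >= 2).
#' @param config configuration list from [vf_config()];
#'   `config$sd_denominator` is `"n-1"` (default) or `"n"`.
#' @return a one-row `data.frame` of class `vf_metrics` with columns
#'   `rmse`, `sd`, `rp`, `rs`, `n`, `a`, `b`.
#' @examples
#' y <- c(2.1, 4.5, 5.0, 6.2, 7.9)
#' compute_metrics(y, y)            # perfect: rmse 0, rp 1
#' compute_metrics((y - 3) / 2, y)  # affine: rmse > 0 but sd ~ 0, rp 1
#' @export
compute_metrics <- function(p, y, config = vf_config()) {
  if (length(p) != length(y)) stop("p and y must have equal length", call. = FALSE)
  n <- length(y)
  if (n < 2L) stop("compute_metrics needs N >= 2", call. = FALSE)
  if (any(!is.finite(p)) || any(!is.finite(y)))
    stop("p and y must be finite", call. = FALSE)
  rmse <- sqrt(mean((y - p)^2))
  denom <- if (identical(config$sd_denominator, "n")) n else n - 1L
  if (sd(p) == 0 || sd(y) == 0) {
    warning("zero-variance predictions or labels: correlation metrics undefined",
            call. = FALSE)
    a <- b <- sdv <- rp <- rs <- NA_real_
  } else {
    b <- cov(p, y) / var(p)
    a <- mean(y) - b * mean(p)
    sdv <- sqrt(sum((y - (a + b * p))^2) / denom)
    rp <- cor(p, y)
    rs <- cor(rank(p, ties.method = "average"), rank(y, ties.method = "average"))
  }
  structure(data.frame(rmse = rmse, sd = sdv, rp = rp, rs = rs,
                       n = n, a = a, b = b),
            class = c("vf_metrics", "data.frame"))
}

#' @importFrom stats cov var
NULL

#' Componentwise median of metric reports
#'
#' Summarizes the reports of a seeded model ensemble by the median of
#' each metric taken independently (the median RMSE and the median Rp may
#' come from different seeds). All reports must refer to test sets of the
#' same size.
#'
#' @param reports a list of [compute_metrics()] reports, or a data.frame
#'   of stacked reports.
#' @return a one-row `vf_metrics` data.frame.
#' @export
median_summary <- function(reports) {
  if (is.data.frame(reports)) df <- reports
  else {
    if (length(reports) == 0L) stop("empty report list", call. = FALSE)
    df <- do.call(rbind, reports)
  }
  if (length(unique(df$n)) != 1L)
    stop("median_summary requires reports with equal n", call. = FALSE)
  out <- as.data.frame(lapply(df[c("rmse", "sd", "rp", "rs", "n", "a", "b")],
                              median))
  out$n <- as.integer(out$n)
  structure(out, class = c("vf_metrics", "data.frame"))
}

#' Write / read an evaluation report CSV
#'
#' Report CSV with columns rmse, sd, rp, rs, n, a, b (plus any grouping
#' columns already present).
#'
#' @param report a `vf_metrics` (or stacked) data.frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  write.csv(report, path, row.names = FALSE)
  invisible(path)
}
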