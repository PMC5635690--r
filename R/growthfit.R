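#' Construct a growth curve
#'
#' @param time Time points in hours, strictly increasing.
#' @param od OD610 readings (dimensionless); non-positive values are allowed
#'   here but are excluded (with a warning) when fitting.
#' @param condition Condition label.
#' @param replicate Replicate id.
#' @return A list of class `growth_curve`.
#' @export
growth_curve <- function(time, od, condition = "condition", replicate = 1L) {
  time <- as.numeric(time); od <- as.numeric(od)
  if (length(time) != length(od)) stop("time and od must have equal length")
  if (any(diff(time) <= 0)) stop("time points must be strictly increasing")
  structure(list(condition = as.character(condition),
                 replicate = replicate, time = time, od = od),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> %s rep %s: %d points, t %.1f-%.1f h\n",
              x$condition, x$replicate, length(x$time), min(x$time),
              max(x$time)))
  invisible(x)
}

# Rolling OLS of y on x over all contiguous windows of length w, vectorized
# via cumulative sums. Returns slopes and r-squared per window start.
.rolling_ols <- function(x, y, w) {
  n <- length(x)
  cx <- cumsum(x); cy <- cumsum(y)
  cxx <- cumsum(x * x); cyy <- cumsum(y * y); cxy <- cumsum(x * y)
  win <- function(cs) cs[w:n] - c(0, cs)[(w:n) - w + 1L]
  sx <- win(cx); sy <- win(cy); sxx <- win(cxx); syy <- win(cyy); sxy <- win(cxy)
  ssx <- sxx - sx^2 / w
  ssy <- syy - sy^2 / w
  sxy2 <- sxy - sx * sy / w
  slope <- sxy2 / ssx
  r2 <- ifelse(ssy > 0, pmin(1, pmax(0, sxy2^2 / (ssx * ssy))), 1)
  list(slope = slope, r2 = r2, start = seq_len(n - w + 1L))
}

#' Maximal specific growth rate by rolling log-linear regression
#'
#' The "easy linear" estimator: ordinary least squares of `ln(OD)` on time
#' over every contiguous window of `window` points; the maximal slope is
#' the specific growth rate mu (per hour). Windows are first restricted to
#' well-determined fits (`r_squared >= r2_min`), which keeps noisy
#' low-signal stretches near the detection limit from spuriously winning
#' the maximum; if no window qualifies the filter is dropped. Ties are
#' broken by higher r-squared, then by the earliest window. Non-positive
#' OD readings are excluded with a warning before fitting. The filter is
#' scale- and shift-equivariant, so multiplying OD by a constant or
#' shifting time leaves mu unchanged.
#'
#' @param curve A [growth_curve()] (or numeric `time` with `od` supplied).
#' @param od If `curve` is a numeric time vector, the OD readings.
#' @param window Window length in points (default 5, minimum 2).
#' @param r2_min Minimum window r-squared for the quality filter
#'   (default 0.98).
#' @return List of class `growth_rate_estimate`: `mu` (per hour),
#'   `window_start`/`window_end` (indices into the positive-OD series),
#'   `r_squared`, `n_points`.
#' @export
#' @examples
#' t <- seq(0, 10, 0.5)
#' fit_growth_rate(growth_curve(t, 0.05 * exp(0.3 * t)))$mu  # 0.3
fit_growth_rate <- function(curve, od = NULL, window = 5L, r2_min = 0.98) {
  if (!inherits(curve, "growth_curve")) curve <- growth_curve(curve, od)
  stopifnot(window >= 2L)
  keep <- curve$od > 0
  if (!all(keep))
    warning(sum(!keep), " non-positive OD reading(s) excluded from fit")
  t <- curve$time[keep]; y <- log(curve$od[keep])
  if (length(t) < window)
    stop(sprintf("insufficient data: %d positive points < window %d",
                 length(t), window))
  fit <- .rolling_ols(t, y, window)
  ok <- fit$r2 >= r2_min
  if (!any(ok)) ok <- rep(TRUE, length(fit$r2))
  best <- which(ok)[order(-fit$slope[ok], -fit$r2[ok], fit$start[ok])[1L]]
  structure(list(
    mu = fit$slope[best],
    window_start = fit$start[best],
    window_end = fit$start[best] + window - 1L,
    r_squared = fit$r2[best],
    n_points = length(t),
    condition = curve$condition,
    replicate = curve$replicate
  ), class = "growth_rate_estimate")
}

#' @export
print.growth_rate_estimate <- function(x, ...) {
  cat(sprintf("<mu> %.4f /h  (window %d-%d, r2 %.3f, %d points)\n",
              x$mu, x$window_start, x$window_end, x$r_squared, x$n_points))
  invisible(x)
}

#' Compare growth rates between two conditions
#'
#' Two-sided Welch two-sample t-test on replicate mu values.
#'
#' @param a,b Numeric vectors of replicate growth rates, or lists of
#'   `growth_rate_estimate`s. Each group needs at least 2 replicates.
#' @return List with `difference` (mean(a) - mean(b)), `p_value`,
#'   `t_statistic`, `df`, and the group means.
#' @export
#' @examples
#' compare_rates(c(0.36, 0.35, 0.36), c(0.30, 0.29, 0.30))$p_value
compare_rates <- function(a, b) {
  as_mu <- function(x) {
    if (is.list(x)) vapply(x, function(e) e$mu, 0) else as.numeric(x)
  }
  a <- as_mu(a); b <- as_mu(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 replicates")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # degenerate: identical within-group values; zero variance
    d <- mean(a) - mean(b)
    return(list(difference = d, p_value = if (d == 0) 1 else 0,
                t_statistic = if (d == 0) 0 else sign(d) * Inf,
                df = NA_real_, mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(difference = mean(a) - mean(b), p_value = tt$p.value,
       t_statistic = unname(tt$statistic), df = unname(tt$parameter),
       mean_a = mean(a), mean_b = mean(b))
}

#' Read growth curves from delimited text
#'
#' Expects columns `condition`, `replicate`, `time_h`, `od610`.
#'
#' @param path File path (TSV).
#' @return List of [growth_curve()]s, one per (condition, replicate).
#' @export
read_growth_curves <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE)
  need <- c("condition", "replicate", "time_h", "od610")
  if (!all(need %in% names(df)))
    stop("growth table must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (key in unique(paste(df$condition, df$replicate, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- df[df$condition == parts[1] & df$replicate == parts[2], ]
    sub <- sub[order(sub$time_h), ]
    out[[length(out) + 1L]] <- growth_curve(sub$time_h, sub$od610,
                                            parts[1], parts[2])
  }
  out
}

#' Write growth curves to delimited text
#'
#' @param curves List of [growth_curve()]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_growth_curves <- function(curves, path) {
  df <- do.call(rbind, lapply(curves, function(cv)
    data.frame(condition = cv$condition, replicate = cv$replicate,
               time_h = cv$time, od610 = cv$od)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
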