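#' Align two age series on a common grid
#'
#' Linearly interpolates both series onto a shared regular age grid over
#' their overlapping span; pairs where either value is missing are dropped.
#'
#' @param a,b data frames `age_ma, value` (ages strictly monotone).
#' @param grid_step grid step in Myr (default 0.2, matching the rate bins).
#' @return data frame `age_ma, x, y` of paired values.
#' @export
align_series <- function(a, b, grid_step = 0.2) {
  stopifnot(nrow(a) >= 2, nrow(b) >= 2)
  lo <- max(min(a$age_ma), min(b$age_ma))
  hi <- min(max(a$age_ma), max(b$age_ma))
  if (hi - lo < 2 * grid_step)
    stop("series do not overlap by at least two grid steps")
  grid <- seq(lo, hi, by = grid_step)
  x <- stats::approx(a$age_ma, a$value, xout = grid, ties = mean)$y
  y <- stats::approx(b$age_ma, b$value, xout = grid, ties = mean)$y
  keep <- !is.na(x) & !is.na(y)
  data.frame(age_ma = grid[keep], x = x[keep], y = y[keep])
}

#' Spearman rank correlation with percentile bootstrap interval
#'
#' Computes Spearman's rho on average (mid) ranks, a two-tailed p value by
#' the t approximation, and a percentile bootstrap confidence interval from
#' paired i.i.d. resamples.  P values smaller than the double-precision
#' floor are reported at the floor with `p_floored = TRUE` rather than as a
#' literal zero.
#'
#' @param x,y paired numeric vectors (n >= 5).
#' @param n_boot bootstrap iterations (default 10000).
#' @param seed optional integer seed for the bootstrap.
#' @param conf confidence level (default 0.95, i.e. the 2.5th and 97.5th
#'   percentiles).
#' @return An object of class `cor_result`: `rho, p, p_floored, ci_lo,
#'   ci_hi, n, n_boot`.
#' @export
spearman_cor <- function(x, y, n_boot = 10000, seed = NULL, conf = 0.95) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 5) stop("need at least 5 paired observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("constant vector: rank correlation undefined")
  rho <- stats::cor(rank(x), rank(y))
  floor_p <- 2.2e-308
  if (abs(rho) > 1 - 1e-12) rho <- sign(rho)  # exactly monotone up to fp error
  if (abs(rho) >= 1) {
    p <- floor_p; floored <- TRUE
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    floored <- p < floor_p
    if (floored) p <- floor_p
  }
  if (!is.null(seed)) set.seed(seed)
  alpha <- (1 - conf) / 2
  br <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, replace = TRUE)
    xb <- x[idx]; yb <- y[idx]
    if (length(unique(xb)) < 2 || length(unique(yb)) < 2) return(NA_real_)
    stats::cor(rank(xb), rank(yb))
  }, numeric(1))
  ci <- stats::quantile(br, probs = c(alpha, 1 - alpha), na.rm = TRUE,
                        names = FALSE)
  structure(list(rho = rho, p = p, p_floored = floored,
                 ci_lo = ci[1], ci_hi = ci[2], n = n, n_boot = n_boot),
            class = "cor_result")
}

#' @export
print.cor_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (95%% CI %.3f, %.3f), P %s%s, n = %d\n",
              x$rho, x$ci_lo, x$ci_hi,
              if (x$p_floored) "< " else "= ",
              format(x$p, digits = 3), x$n))
  invisible(x)
}

#' Remove a linear trend by least squares
#'
#' @param series data frame `age_ma, value` (n >= 3).
#' @return The series with `value` replaced by the residuals of the
#'   best-fitting line in age; residuals have zero mean and zero slope.
#' @export
detrend_linear <- function(series) {
  stopifnot(nrow(series) >= 3)
  fit <- stats::lm(value ~ age_ma, data = series)
  out <- series
  out$value <- stats::residuals(fit)
  out
}

#' Variance inflation screening of proxy predictors
#'
#' Regresses each proxy on all others (ordinary least squares) and reports
#' VIF = 1 / (1 - R^2); proxies with VIF above `threshold` (default 10) are
#' flagged for exclusion.  A perfectly collinear proxy reports an infinite
#' VIF.
#'
#' @param proxies numeric matrix or data frame, one column per proxy,
#'   aligned on a common grid (>= 2 columns).
#' @param threshold exclusion threshold.
#' @return data frame `proxy, vif, excluded`.
#' @export
vif_screen <- function(proxies, threshold = 10) {
  m <- as.data.frame(proxies)
  stopifnot(ncol(m) >= 2)
  vif <- vapply(seq_len(ncol(m)), function(j) {
    fit <- stats::lm(m[[j]] ~ ., data = m[, -j, drop = FALSE])
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(proxy = colnames(m), vif = vif, excluded = vif > threshold,
             stringsAsFactors = FALSE)
}

#' Read a proxy series file
#'
#' CSV dialect `age_ma,value`.
#'
#' @param path CSV path.
#' @param name optional proxy name attached as an attribute.
#' @return data frame `age_ma, value` sorted by age.
#' @export
read_proxy <- function(path, name = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("age_ma", "value") %in% names(df)))
  df <- df[order(df$age_ma), , drop = FALSE]
  if (anyDuplicated(df$age_ma)) stop("proxy ages must be strictly monotone")
  rownames(df) <- NULL
  attr(df, "proxy_name") <- name %||% basename(path)
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
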