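# Virtual experiments on the sampled parameter sets: linear dependency of
# the PAT change on cuff length, controlled inflation-rate sweeps, and the
# blood-pressure regression behind PTT-based calibration.

#' Ordinary least-squares fit with R-squared
#'
#' Thin wrapper around [stats::lm()] returning a compact result object.
#' A constant response is handled as R-squared 0 with a warning (the
#' variance decomposition is degenerate); rank deficiency raises.
#'
#' @param x predictor vector, matrix or data frame.
#' @param y response vector.
#' @return An object of class `linear_fit`: `coefficients`, `r.squared`,
#'   `n`, and the underlying `lm` fit.
#' @examples
#' f <- linear_fit(1:10, 2 * (1:10) + rnorm(10, sd = 0.1))
#' coef(f); f$r.squared
#' @export
linear_fit <- function(x, y) {
  X <- as.data.frame(x)
  if (is.null(colnames(x)) && is.vector(x)) names(X) <- "x"
  stopifnot(nrow(X) == length(y))
  if (anyNA(X) || anyNA(y)) stop("missing values in predictors or response")
  if (nrow(X) < ncol(X) + 2)
    stop("need at least p + 2 observations for ", ncol(X), " predictor(s)")
  dat <- cbind(X, .y = y)
  fit <- lm(.y ~ ., data = dat)
  if (fit$rank < ncol(X) + 1)
    stop("rank-deficient predictor matrix")
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot <= .Machine$double.eps * length(y)) {
    warning("constant response; R-squared reported as 0")
    0
  } else 1 - sum(residuals(fit)^2) / ss_tot
  structure(list(coefficients = coef(fit), r.squared = r2,
                 n = length(y), fit = fit),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Linear fit (n = %d): R^2 = %.4f\n", x$n, x$r.squared))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' @export
coef.linear_fit <- function(object, ...) object$coefficients

#' @export
predict.linear_fit <- function(object, newdata, ...) {
  if (missing(newdata)) predict(object$fit)
  else predict(object$fit, newdata = as.data.frame(newdata))
}

#' @export
residuals.linear_fit <- function(object, ...) residuals(object$fit)

analysis_xy <- function(analysis, metric, predictors) {
  stopifnot(inherits(analysis, "sobol_analysis"))
  Y <- analysis$outputs
  X <- analysis$design$physical
  ok <- stats::complete.cases(Y)
  if (sum(!ok))
    message(sum(!ok), " invalid design row(s) excluded from the fit")
  list(x = as.data.frame(X[ok, predictors, drop = FALSE]),
       y = Y[ok, metric])
}

#' Cuff-length dependency of the maximum total PAT change
#'
#' Regresses the per-run `max|dPAT_total|` on cuff length over all valid
#' sampled parameter sets of a sensitivity analysis. A strong positive
#' linear dependency is expected: a longer cuff off-loads a longer
#' arterial segment, slowing the pulse over a longer path.
#'
#' @param analysis a [run_sobol_analysis()] result.
#' @return A [linear_fit()].
#' @export
experiment_cuff_length <- function(analysis) {
  d <- analysis_xy(analysis, "max_dpat_total", "cuff_length")
  linear_fit(d$x, d$y)
}

#' Blood-pressure dependency of the distal PTT drop
#'
#' Fits `max|dPTT_distal|` (a) on pulse pressure alone and (b) on pulse
#' pressure and systolic pressure jointly, over all valid sampled sets.
#' The joint fit characterizes how the expected cuff-induced distal PTT
#' change could be predicted from BP — the basis of the proposed
#' calibration strategy.
#'
#' @param analysis a [run_sobol_analysis()] result.
#' @return A list of two [linear_fit()]s: `pp_only` and `pp_sbp`.
#' @export
experiment_bp_correlation <- function(analysis) {
  a <- analysis_xy(analysis, "max_dptt_distal", "pp")
  b <- analysis_xy(analysis, "max_dptt_distal", c("pp", "sbp"))
  list(pp_only = linear_fit(a$x, a$y), pp_sbp = linear_fit(b$x, b$y))
}

#' Controlled inflation-rate sweep at reference parameters
#'
#' Sweeps the cuff inflation rate with every other parameter at its
#' reference value and reports the equilibrium pressure and the maximum
#' distal PTT drop per rate, plus the range of the latter across the
#' sweep. Slower inflations leave more time for the distal filling
#' effect, so both the equilibrium pressure and the PTT drop grow as the
#' rate falls.
#'
#' @param rates inflation rates to sweep, mmHg/s.
#' @param ... overrides passed to [simulate_arm()] (e.g. `input`, `dt`).
#' @return An object of class `rate_sweep`: data frame `results`
#'   (`rate`, `p_eq`, `max_dptt_distal`, `max_dmap`) and scalar
#'   `dptt_range_ms`.
#' @export
experiment_inflation_rate <- function(rates = seq(4, 8, by = 0.5), ...) {
  stopifnot(length(rates) >= 1, all(rates > 0))
  rows <- lapply(rates, function(r) {
    sim <- simulate_arm(protocol = cuff_protocol(rate = r), ...)
    m <- response_metrics(sim)
    data.frame(rate = r, p_eq = m$p_eq,
               max_dptt_distal = m$max_dptt_distal, max_dmap = m$max_dmap)
  })
  res <- do.call(rbind, rows)
  structure(list(results = res,
                 dptt_range_ms = diff(range(res$max_dptt_distal))),
            class = "rate_sweep")
}

#' @export
print.rate_sweep <- function(x, ...) {
  cat("Inflation-rate sweep (reference parameters)\n")
  print(round(x$results, 3), row.names = FALSE)
  cat(sprintf("range of max|dPTT_distal| across sweep: %.3f ms\n",
              x$dptt_range_ms))
  invisible(x)
}
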