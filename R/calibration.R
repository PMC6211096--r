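#' Logistic response curve
#'
#' The two-parameter logistic linking an index change x to the expected
#' defoliation fraction: y = 1 / (1 + exp(-(a + b x))). Computed
#' overflow-safely; the result always lies in (0, 1) for finite arguments
#' up to floating-point rounding.
#'
#' @param a intercept (additive term)
#' @param b slope (multiplier of x)
#' @param x index-change value(s)
#' @return fraction(s) in (0, 1)
#' @export
logistic_forward <- function(a, b, x) {
  plogis(a + b * x)
}

#' Invert the logistic at a target defoliation fraction
#'
#' Solves y = 1/(1 + exp(-(a + b x))) for x:
#' x = (ln(y / (1 - y)) - a) / b. Used to translate class-boundary
#' defoliation fractions into index-change thresholds.
#'
#' @param fit a [logistic_fit] (or any list with elements `a` and `b`)
#' @param y target fraction, strictly between 0 and 1
#' @return the x (dVI) value at which the fitted curve passes through `y`
#' @examples
#' f <- list(a = -3.3570352, b = -0.0092755)
#' round(invert_threshold(f, 0.10))  # -125
#' @export
invert_threshold <- function(fit, y) {
  if (any(y <= 0 | y >= 1)) stop("y must lie strictly in (0, 1)")
  if (fit$b == 0) stop("cannot invert a flat fit (b = 0)")
  (qlogis(y) - fit$a) / fit$b
}

## Fractional-response Bernoulli log-likelihood (cross-entropy). Well-defined
## for y in [0, 1] including the endpoints, where the vanishing term drops.
fractional_loglik <- function(a, b, x, y, eps = 1e-12) {
  p <- pmin(pmax(plogis(a + b * x), eps), 1 - eps)
  sum(ifelse(y > 0, y * log(p), 0) + ifelse(y < 1, (1 - y) * log(1 - p), 0))
}

#' Fit the logistic defoliation model to calibration samples
#'
#' Maximizes the fractional-response Bernoulli log-likelihood
#' \deqn{\ell(a,b) = \sum_i [y_i \log p_i + (1-y_i)\log(1-p_i)],\quad
#'   p_i = 1/(1+e^{-(a+b x_i)})}
#' over (a, b) by BFGS with the analytic gradient, from the deterministic
#' start a0 = logit(mean y), b0 = 0. The response y is a fraction in
#' \[0, 1\], not a 0/1 outcome; the same objective is the quasi-binomial
#' likelihood, so no pseudo-counts are invented for fractional data. The
#' null (intercept-only) log-likelihood is available in closed form because
#' the fractional likelihood is maximized at p = mean(y).
#'
#' @param samples a `calibration_samples` table ([extract_samples()]), or
#'   any data.frame with numeric columns `x` and `y`
#' @param index_name label stored on the fit (defaults to the samples'
#'   `index_name` attribute, else `""`)
#' @param max_iter BFGS iteration cap (default 500)
#' @return an object of class `logistic_fit`: list with `index_name`, `a`,
#'   `b`, `r2_mcfadden`, `n`, `loglik_full`, `loglik_null`, `iterations`
#' @export
fit_logistic <- function(samples, index_name = NULL, max_iter = 500L) {
  x <- samples$x
  y <- samples$y
  n <- length(x)
  if (is.null(index_name))
    index_name <- attr(samples, "index_name") %||% ""
  if (n < 4L) stop("need at least 4 samples to fit")
  if (any(!is.finite(x))) stop("x values must be finite")
  if (any(y < 0 | y > 1)) stop("y values must lie in [0, 1]")
  if (length(unique(x)) < 2L) stop("x values are all equal; cannot fit")
  if (length(unique(y)) < 2L)
    stop("y values are all equal; likelihood is degenerate")

  ybar <- mean(y)
  negll <- function(par) -fractional_loglik(par[1], par[2], x, y)
  grad <- function(par) {
    p <- plogis(par[1] + par[2] * x)
    r <- y - p
    -c(sum(r), sum(r * x))
  }
  start <- c(qlogis(ybar), 0)
  opt <- optim(start, negll, grad, method = "BFGS",
               control = list(maxit = max_iter, reltol = 1e-12))
  if (opt$convergence != 0)
    stop(sprintf(paste0("logistic fit did not converge (code %d, %s; ",
                        "%d function / %d gradient evaluations)"),
                 opt$convergence, opt$message %||% "no message",
                 opt$counts[1], opt$counts[2]))
  a <- opt$par[1]; b <- opt$par[2]
  ll_full <- fractional_loglik(a, b, x, y)
  ll_null <- fractional_loglik(qlogis(ybar), 0, x, y)
  fit <- structure(list(index_name = index_name, a = a, b = b,
                        r2_mcfadden = NA_real_, n = n,
                        loglik_full = ll_full, loglik_null = ll_null,
                        iterations = unname(opt$counts[1])),
                   class = "logistic_fit")
  fit$r2_mcfadden <- mcfadden_r2(fit)
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "logistic_fit %s: y = 1/(1 + exp(-(%.7g + %.7g x))), n = %d, R2 = %.3f\n",
    if (nzchar(x$index_name)) paste0("d", x$index_name) else "",
    x$a, x$b, x$n, x$r2_mcfadden))
  invisible(x)
}

#' McFadden's pseudo R-squared
#'
#' 1 - loglik_full / loglik_null, where the null model is the intercept-only
#' logistic on the same responses. Clipped to \[0, 1\] against floating-point
#' undershoot; since the null is nested in the full model the unclipped value
#' is non-negative up to optimizer tolerance.
#'
#' @param fit a `logistic_fit` (or list with `loglik_full`, `loglik_null`)
#' @return fraction in \[0, 1\]
#' @export
mcfadden_r2 <- function(fit) {
  if (fit$loglik_null == 0)
    stop("null log-likelihood is 0; McFadden's R2 undefined")
  min(max(1 - fit$loglik_full / fit$loglik_null, 0), 1)
}

#' Derive severity classification thresholds from a fitted curve
#'
#' Inverts the fitted logistic at the class-boundary defoliation fractions
#' (default 0.10, 0.35, 0.70 — the nil/low, low/medium and medium/high
#' boundaries) to obtain index-change thresholds. Thresholds are kept
#' unrounded for classification; `limits_x_rounded` (half-away-from-zero to
#' integer) is for display and tabulation. The orientation records whether
#' severity increases as x decreases (b < 0, e.g. dMSI) or increases
#' (b > 0, e.g. dNDMI).
#'
#' @param fit a `logistic_fit`
#' @param boundaries_y class-boundary fractions, strictly increasing in
#'   (0, 1); default `c(0.10, 0.35, 0.70)`
#' @return an object of class `threshold_set`: list with `index_name`,
#'   `boundaries_y`, `limits_x` (unrounded), `limits_x_rounded`,
#'   `orientation` (`"decreasing"` or `"increasing"`)
#' @export
derive_threshold_set <- function(fit, boundaries_y = c(0.10, 0.35, 0.70)) {
  stopifnot(length(boundaries_y) >= 1L)
  if (is.unsorted(boundaries_y, strictly = TRUE))
    stop("boundaries_y must be strictly increasing")
  limits <- invert_threshold(fit, boundaries_y)
  structure(list(index_name = fit$index_name,
                 boundaries_y = boundaries_y,
                 limits_x = limits,
                 limits_x_rounded = round_half_away(limits),
                 orientation = if (fit$b < 0) "decreasing" else "increasing"),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("threshold_set %s (%s): %s at y = %s\n",
              if (nzchar(x$index_name)) paste0("d", x$index_name) else "",
              x$orientation,
              paste(x$limits_x_rounded, collapse = " / "),
              paste(x$boundaries_y, collapse = " / ")))
  invisible(x)
}

#' Rank fitted models by goodness of fit
#'
#' Sorts fits by McFadden's R-squared, best first; exact ties are broken by
#' index name (lexicographic) and flagged.
#'
#' @param fits list of `logistic_fit` objects
#' @return data.frame with columns index_name, a, b, r2_mcfadden, n, rank,
#'   best (logical), tied (logical); attribute `best` holds the winning
#'   index name
#' @export
compare_models <- function(fits) {
  if (length(fits) == 0L) stop("no fits to compare")
  stopifnot(all(vapply(fits, inherits, logical(1), "logistic_fit")))
  tab <- data.frame(
    index_name = vapply(fits, function(f) f$index_name, character(1)),
    a = vapply(fits, function(f) f$a, numeric(1)),
    b = vapply(fits, function(f) f$b, numeric(1)),
    r2_mcfadden = vapply(fits, function(f) f$r2_mcfadden, numeric(1)),
    n = vapply(fits, function(f) f$n, integer(1)),
    stringsAsFactors = FALSE)
  ord <- order(-tab$r2_mcfadden, tab$index_name)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  tab$best <- tab$rank == 1L
  tab$tied <- duplicated(tab$r2_mcfadden) | duplicated(tab$r2_mcfadden,
                                                       fromLast = TRUE)
  rownames(tab) <- NULL
  attr(tab, "best") <- tab$index_name[1]
  tab
}

#' Serialize fits and threshold sets to JSON
#'
#' @param fit a `logistic_fit`
#' @param thresholds optional `threshold_set` derived from it
#' @param path output JSON path
#' @return `path`, invisibly
#' @export
write_fit_json <- function(fit, path, thresholds = NULL) {
  obj <- list(index_name = fit$index_name, a = fit$a, b = fit$b,
              r2_mcfadden = fit$r2_mcfadden, n = fit$n,
              loglik_full = fit$loglik_full, loglik_null = fit$loglik_null)
  if (!is.null(thresholds))
    obj <- c(obj, list(boundaries_y = thresholds$boundaries_y,
                       limits_x_raw = thresholds$limits_x,
                       limits_x_rounded = thresholds$limits_x_rounded,
                       orientation = thresholds$orientation))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
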