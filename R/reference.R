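#' Published reference calibration for pine processionary moth defoliation
#'
#' Logistic coefficients reported by a published Landsat-8 calibration of
#' winter defoliation by the pine processionary moth (*Thaumetopoea
#' pityocampa*) in Catalonian pine forests, fitted to 50 UAV-interpreted
#' 30 m cells. One fit per index change: y = 1/(1 + exp(-(a + b x))) with
#' x the pre-minus-post index difference on the x 10^4 integer scale and y
#' the defoliation fraction. Useful as a worked input for threshold
#' derivation and as a regression anchor in tests.
#'
#' Note: the published dNBR slope is negative while the published threshold
#' limits for dNBR are positive; the limit magnitudes match the negative
#' slope exactly, so the discrepancy is in sign only. [reference_fits()]
#' keeps the coefficients exactly as printed and flags the row (see the
#' `sign_flag` column) rather than silently correcting either value.
#'
#' @return data.frame with columns index_name, a, b, r2_mcfadden, n,
#'   sign_flag (TRUE where published threshold signs contradict the slope
#'   sign)
#' @export
reference_fits <- function() {
  data.frame(
    index_name  = c("MID", "MSI", "NDMI", "NDVI", "NBR"),
    a           = c(-3.1299111, -3.3570352, -3.5552389, -3.509468,
                    -3.6323329),
    b           = c(-0.0041928, -0.0092755, 0.0014107, 0.001767,
                    -0.0013874),
    r2_mcfadden = c(0.740, 0.815, 0.749, 0.787, 0.776),
    n           = 50L,
    sign_flag   = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

#' One published reference fit as a `logistic_fit`-like object
#'
#' Convenience wrapper around [reference_fits()] for passing a published
#' coefficient pair to [invert_threshold()] / [derive_threshold_set()].
#' Log-likelihoods are unknown (not published) and set to `NA`.
#'
#' @param index_name one of [VI_NAMES]
#' @return a `logistic_fit` object with published a, b, R2 and n
#' @export
reference_fit <- function(index_name) {
  index_name <- match.arg(index_name, VI_NAMES)
  tab <- reference_fits()
  r <- tab[tab$index_name == index_name, ]
  structure(list(index_name = r$index_name, a = r$a, b = r$b,
                 r2_mcfadden = r$r2_mcfadden, n = r$n,
                 loglik_full = NA_real_, loglik_null = NA_real_,
                 iterations = NA_integer_),
            class = "logistic_fit")
}

#' Published severity class mix of the reference calibration sample
#'
#' Number of 30 m UAV-interpreted cells per severity class in the
#' reference calibration data set (total 50). Used as the default class
#' quota of [generate_ground_truth()].
#'
#' @return named integer vector (nil, low, medium, high)
#' @export
reference_class_quotas <- function() {
  c(nil = 10L, low = 23L, medium = 8L, high = 9L)
}

#' Published confusion matrix of the reference dMSI threshold classification
#'
#' Observed (rows) vs predicted (columns) severity classes for the 50
#' reference cells classified with dMSI thresholds. Reproduces an overall
#' accuracy of 0.72 under [accuracy_metrics()].
#'
#' @return a `confusion_matrix`
#' @export
reference_confusion <- function() {
  m <- matrix(c(9, 1, 0, 0,
                2, 17, 4, 0,
                0, 3, 4, 1,
                0, 0, 3, 6),
              nrow = 4, byrow = TRUE,
              dimnames = list(observed = SEVERITY_LEVELS,
                              predicted = SEVERITY_LEVELS))
  m <- matrix(as.integer(m), 4, 4, dimnames = dimnames(m))
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' Reference threshold table derived from the published coefficients
#'
#' Inverts each published fit at the class-boundary fractions 0.10, 0.35
#' and 0.70 and rounds to integers, reproducing the published threshold
#' limits for dMID, dMSI, dNDMI and dNDVI exactly. For dNBR the published
#' table prints positive limits although the published slope is negative;
#' this function returns the signed result of the inversion and sets
#' `sign_flag`, with `abs_limits` giving the magnitudes that match the
#' published table. A warning summarizes the discrepancy.
#'
#' @param boundaries_y class-boundary fractions (default 0.10/0.35/0.70)
#' @return data.frame with columns index_name, y_10, y_35, y_70 (rounded
#'   signed limits, named after the default boundaries), sign_flag;
#'   attribute `threshold_sets` holds the full `threshold_set` per index
#' @export
reference_threshold_table <- function(boundaries_y = c(0.10, 0.35, 0.70)) {
  tab <- reference_fits()
  sets <- lapply(seq_len(nrow(tab)), function(i) {
    derive_threshold_set(reference_fit(tab$index_name[i]), boundaries_y)
  })
  lim <- t(vapply(sets, function(s) s$limits_x_rounded,
                  numeric(length(boundaries_y))))
  out <- data.frame(index_name = tab$index_name, lim,
                    sign_flag = tab$sign_flag, stringsAsFactors = FALSE)
  names(out)[1 + seq_along(boundaries_y)] <-
    paste0("y_", sub("^0\\.", "", format(boundaries_y)))
  if (any(tab$sign_flag))
    warning("published threshold limits for ",
            paste0("d", tab$index_name[tab$sign_flag], collapse = ", "),
            " disagree in sign with the published slope; ",
            "signed inversions are reported (magnitudes match the ",
            "published limits)")
  attr(out, "threshold_sets") <- stats::setNames(sets, tab$index_name)
  out
}
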