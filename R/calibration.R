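# Newton/IRLS logistic fit with a small ridge penalty so that perfectly
# separable calibration data still yields finite, monotone coefficients.
ridge_logistic <- function(x, y, lambda = 1e-4, maxit = 100L, tol = 1e-10) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(X, X * w) + diag(lambda, 2L)
    gr <- crossprod(X, y - p) - lambda * beta
    step <- solve(H, gr)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

#' Calibrate the k-mer-similarity to identity relationship
#'
#' Fits a one-predictor logistic regression for the probability that the
#' aligned percent identity of a pair meets the user-specified similarity
#' threshold, given the pair's k-mer similarity. A small ridge penalty
#' keeps the fit finite on separable data. The fitted curve defines the
#' k-mer-similarity boundary below which candidates have a predicted pass
#' probability under `floor` and are not aligned during clustering. When
#' the training pairs are all one class, or the fitted slope is not
#' positive, a conservative constant model admitting every candidate is
#' used instead.
#'
#' @param ksim K-mer similarities of the training pairs.
#' @param pass Logical: did the aligned identity meet the threshold?
#' @param threshold The similarity threshold being calibrated.
#' @param floor Predicted-probability floor for alignment (default 0.01).
#' @param lambda Ridge penalty (default 1e-4).
#' @return An object of class `identity_calibration` with coefficients,
#'   the `boundary` similarity at which the prediction crosses `floor`,
#'   and a `fallback` flag.
#' @export
calibrate_identity <- function(ksim, pass, threshold, floor = 0.01,
                               lambda = 1e-4) {
  pass <- as.logical(pass)
  keep <- is.finite(ksim) & !is.na(pass)
  ksim <- ksim[keep]
  pass <- pass[keep]
  fallback <- structure(list(intercept = NA_real_, slope = NA_real_,
                             boundary = 0, floor = floor,
                             threshold = threshold, n_pairs = length(ksim),
                             fallback = TRUE),
                        class = "identity_calibration")
  if (length(ksim) < 2L || length(unique(pass)) < 2L) return(fallback)
  beta <- ridge_logistic(ksim, as.numeric(pass), lambda = lambda)
  if (!all(is.finite(beta)) || beta[2] <= 0) return(fallback)
  boundary <- (stats::qlogis(floor) - beta[1]) / beta[2]
  structure(list(intercept = beta[1], slope = beta[2],
                 boundary = boundary, floor = floor, threshold = threshold,
                 n_pairs = length(ksim), fallback = FALSE),
            class = "identity_calibration")
}

#' Predict the probability of meeting the similarity threshold
#'
#' @param object An [calibrate_identity()] object.
#' @param ksim K-mer similarities.
#' @param ... Unused.
#' @return Predicted probabilities (1 everywhere for the fallback model).
#' @export
predict.identity_calibration <- function(object, ksim, ...) {
  if (object$fallback) return(rep(1, length(ksim)))
  stats::plogis(object$intercept + object$slope * ksim)
}

#' @export
print.identity_calibration <- function(x, ...) {
  if (x$fallback) {
    cat(sprintf("<identity_calibration> fallback (admit all), %d pairs\n",
                x$n_pairs))
  } else {
    cat(sprintf("<identity_calibration> threshold %.3f: logit(p) = %.2f + %.2f * ksim; %.0f%% boundary at ksim = %.3f (%d pairs)\n",
                x$threshold, x$intercept, x$slope, 100 * x$floor,
                x$boundary, x$n_pairs))
  }
  invisible(x)
}
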