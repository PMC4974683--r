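#' Through-origin quadratic pressure-drop/flow model
#'
#' Fits dP = A Q + B Q^2 by least squares with no intercept (a stenosis has
#' zero pressure drop at zero flow). A carries the viscous (Poiseuille-like)
#' losses, B the convective-acceleration (Bernoulli-like) losses; a steeper
#' curve means a higher stenosis resistance. The fit quality is summarized
#' by the degrees-of-freedom-corrected RMSE, sqrt(sum(residual^2) / (n - 2)).
#'
#' @param q flow values (mL/min), or a data frame with columns \code{q} and
#'   \code{dp} (e.g. from \code{\link{noisy_dpq}}).
#' @param dp pressure drops (mmHg); ignored when \code{q} is a data frame.
#' @return object of class \code{dpq_fit} with components
#'   \code{coefficients} (A, B), \code{fitted.values}, \code{residuals},
#'   \code{rmse} (NA with a warning when n = 2 leaves no residual degrees of
#'   freedom), \code{n}, \code{data}.
#' @examples
#' fit <- dpq_fit(c(30, 42, 54), c(22.53, 35.50, 52.66))
#' coef(fit)          # A ~ 0.451, B ~ 0.010
#' predict(fit, q = 48)
#' @export
dpq_fit <- function(q, dp = NULL) {
  if (is.data.frame(q)) { dp <- q$dp; q <- q$q }
  if (length(q) != length(dp)) stopf("dpq_fit: q and dp lengths differ")
  if (length(q) < 2) stopf("dpq_fit: need at least 2 points")
  if (any(q <= 0)) stopf("dpq_fit: flow values must be positive")
  if (any(!is.finite(dp))) stopf("dpq_fit: pressure drops must be finite")
  if (length(unique(q)) < 2)
    stopf("dpq_fit: singular system (need at least 2 distinct flow values)")
  X <- cbind(q = q, q2 = q^2)
  fit <- stats::lm.fit(X, dp)
  if (fit$rank < 2) stopf("dpq_fit: singular design matrix")
  ab <- unname(fit$coefficients)
  n <- length(q)
  rmse_val <- if (n > 2) sqrt(sum(fit$residuals^2) / (n - 2)) else {
    warning("dpq_fit: n = 2 leaves no residual degrees of freedom; RMSE undefined",
            call. = FALSE)
    NA_real_
  }
  structure(list(coefficients = c(A = ab[1], B = ab[2]),
                 fitted.values = as.vector(X %*% ab),
                 residuals = as.vector(dp - X %*% ab),
                 rmse = rmse_val, n = n,
                 data = data.frame(q = q, dp = dp)),
            class = "dpq_fit")
}

#' @export
print.dpq_fit <- function(x, digits = 3, ...) {
  cat("Through-origin quadratic pressure-drop/flow fit: dP = A*Q + B*Q^2\n")
  cat(sprintf("  A = %.*f mmHg.min/mL (viscous), B = %.*f mmHg.min^2/mL^2 (convective)\n",
              digits, x$coefficients["A"], digits, x$coefficients["B"]))
  cat(sprintf("  n = %d points, RMSE = %s mmHg\n", x$n,
              if (is.na(x$rmse)) "undefined (n - m = 0)" else sprintf("%.2f", x$rmse)))
  invisible(x)
}

#' @export
summary.dpq_fit <- function(object, ...) {
  out <- list(coefficients = object$coefficients, rmse = object$rmse,
              n = object$n,
              q_range = range(object$data$q),
              resistance_at_qmax = unname(
                object$coefficients["A"] +
                object$coefficients["B"] * max(object$data$q)))
  class(out) <- "summary.dpq_fit"
  out
}

#' @export
print.summary.dpq_fit <- function(x, ...) {
  cat("dP-Q quadratic fit summary\n")
  cat(sprintf("  A = %.4f, B = %.5f; RMSE = %s mmHg (n = %d)\n",
              x$coefficients["A"], x$coefficients["B"],
              if (is.na(x$rmse)) "NA" else sprintf("%.3f", x$rmse), x$n))
  cat(sprintf("  flow range [%.0f, %.0f] mL/min; stenosis resistance at Qmax = %.3f mmHg.min/mL\n",
              x$q_range[1], x$q_range[2], x$resistance_at_qmax))
  invisible(x)
}

#' @export
coef.dpq_fit <- function(object, ...) object$coefficients

#' @export
residuals.dpq_fit <- function(object, ...) object$residuals

#' @export
predict.dpq_fit <- function(object, q = object$data$q, ...) {
  unname(object$coefficients["A"] * q + object$coefficients["B"] * q^2)
}

#' @export
plot.dpq_fit <- function(x, ...) {
  q <- x$data$q
  qq <- seq(0, max(q) * 1.05, length.out = 100)
  plot.default(x$data$q, x$data$dp, xlab = "Q (mL/min)",
               ylab = expression(Delta * P ~ "(mmHg)"),
               main = sprintf("dP = %.3f Q + %.3f Q^2", x$coefficients["A"],
                              x$coefficients["B"]), ...)
  lines(qq, predict(x, qq), col = "steelblue")
  invisible(x)
}

#' Simulate pressure drops from a fitted dP-Q model
#'
#' Draws new dP values at the fitted flow points with additive Gaussian
#' noise (default scale: the fit's RMSE).
#'
#' @param object a \code{dpq_fit}.
#' @param nsim number of replicate data sets.
#' @param seed optional integer seed (global RNG state preserved).
#' @param sigma noise standard deviation (mmHg).
#' @param ... unused.
#' @return data frame of nsim columns of simulated dp values.
#' @export
simulate.dpq_fit <- function(object, nsim = 1, seed = NULL,
                             sigma = object$rmse, ...) {
  if (is.na(sigma)) stopf("simulate.dpq_fit: sigma is undefined for this fit")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  q <- object$data$q
  out <- as.data.frame(replicate(nsim, predict(object, q) + stats::rnorm(length(q), 0, sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Degrees-of-freedom-corrected root mean squared error
#'
#' sqrt( sum((y - yhat)^2) / (n - m) ) with n observations and m fitted
#' coefficients.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @param m number of fitted coefficients (default 2, the quadratic law).
#' @return RMSE in the units of the observations.
#' @export
rmse <- function(observed, predicted, m = 2) {
  n <- length(observed)
  if (length(predicted) != n) stopf("rmse: length mismatch")
  if (n <= m) stopf("rmse: need n > m (n = %d, m = %d)", n, m)
  sqrt(sum((observed - predicted)^2) / (n - m))
}

#' Export a dP-Q fit report as JSON
#'
#' @param fits named list of \code{dpq_fit} objects (names used as labels,
#'   e.g. the bifurcation angle).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_fit_report <- function(fits, path) {
  rep_ <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    list(angle = nm, A = unname(f$coefficients["A"]),
         B = unname(f$coefficients["B"]),
         rmse = if (is.na(f$rmse)) NULL else f$rmse, n = f$n)
  })
  jsonlite::write_json(rep_, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
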