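# Weibull time-to-onset model.
#
# Onset-day samples (uncensored, positive) are fitted with the two-parameter
# Weibull distribution: scale alpha (days; the 63.2% quantile of onset) and
# shape beta (dimensionless). beta describes how the onset hazard changes
# over the exposure period, and the position of its 95% confidence interval
# relative to 1 classifies the adverse event:
#   upper bound < 1  -> early failure  (hazard decreasing: front-loaded risk)
#   interval spans 1 -> random failure (hazard roughly constant)
#   lower bound > 1  -> wear-out       (hazard increasing with time on drug)

#' Fit a Weibull time-to-onset model
#'
#' Maximum-likelihood fit of the two-parameter Weibull to uncensored onset
#' samples (via [fitdistrplus::fitdist()]), with Wald 95% confidence
#' intervals computed on the log-parameter scale from the observed
#' information and back-transformed. Median and quartiles are
#' distribution-free (linear-interpolation quantiles of the samples).
#' Degenerate inputs — a single sample, or all samples identical, where the
#' shape estimate diverges — yield point summaries only, a warning, and
#' failure type `"indeterminate"`.
#'
#' @param days numeric vector of onset times in days; all positive.
#' @param level confidence level for the parameter intervals.
#' @return an object of class `weibull_tto` with components `n`,
#'   `coefficients` (`alpha`, `beta`), `vcov_log` (covariance of
#'   `log(alpha)`, `log(beta)`), `alpha_ci`, `beta_ci`, `median`, `q1`, `q3`,
#'   `failure_type`, `loglik`, `data`.
#' @seealso [classify_failure()], [confint.weibull_tto()],
#'   [simulate.weibull_tto()]
#' @examples
#' set.seed(42)
#' fit <- weibull_tto(rweibull(200, shape = 1.2, scale = 120))
#' fit
#' coef(fit)
#' confint(fit)
#' @export
weibull_tto <- function(days, level = 0.95) {
  days <- as.numeric(days)
  if (length(days) == 0) stop("no onset samples to fit", call. = FALSE)
  if (any(!is.finite(days)) || any(days <= 0)) {
    stop("onset samples must be positive and finite", call. = FALSE)
  }
  n <- length(days)
  qs <- unname(stats::quantile(days, c(0.25, 0.5, 0.75), type = 7))
  obj <- list(n = n, data = days, level = level,
              median = qs[2], q1 = qs[1], q3 = qs[3],
              coefficients = c(alpha = NA_real_, beta = NA_real_),
              vcov_log = NULL, alpha_ci = c(NA_real_, NA_real_),
              beta_ci = c(NA_real_, NA_real_), loglik = NA_real_,
              failure_type = "indeterminate")
  class(obj) <- "weibull_tto"

  if (n < 2 || stats::sd(days) == 0) {
    warning("degenerate onset sample (n < 2 or zero spread); ",
            "Weibull parameters not estimable", call. = FALSE)
    return(obj)
  }

  fit <- try(suppressWarnings(
    fitdistrplus::fitdist(days, "weibull", keepdata = FALSE)), silent = TRUE)
  if (inherits(fit, "try-error") || anyNA(fit$estimate)) {
    warning("Weibull fit did not converge; parameters not estimable",
            call. = FALSE)
    return(obj)
  }
  beta <- unname(fit$estimate["shape"])
  alpha <- unname(fit$estimate["scale"])
  obj$coefficients <- c(alpha = alpha, beta = beta)
  obj$loglik <- fit$loglik

  V <- fit$vcov
  if (!is.null(V) && all(is.finite(V))) {
    # delta method to the log scale: d log(theta) / d theta = 1/theta
    D <- diag(1 / c(alpha, beta))
    Vlog <- D %*% V[c("scale", "shape"), c("scale", "shape")] %*% D
    dimnames(Vlog) <- list(c("log_alpha", "log_beta"),
                           c("log_alpha", "log_beta"))
    if (all(diag(Vlog) > 0)) {
      obj$vcov_log <- Vlog
      z <- stats::qnorm(1 - (1 - level) / 2)
      obj$alpha_ci <- alpha * exp(c(-1, 1) * z * sqrt(Vlog[1, 1]))
      obj$beta_ci <- beta * exp(c(-1, 1) * z * sqrt(Vlog[2, 2]))
    }
  }
  obj$failure_type <- classify_failure(obj$beta_ci[1], obj$beta_ci[2])
  obj
}

#' Classify the hazard shape from the shape-parameter interval
#'
#' @param lower,upper bounds of the 95% confidence interval for the Weibull
#'   shape parameter beta.
#' @return `"early"` if `upper < 1`, `"wear_out"` if `lower > 1`, `"random"`
#'   if the interval spans 1, `"indeterminate"` if either bound is missing.
#' @export
classify_failure <- function(lower, upper) {
  if (is.na(lower) || is.na(upper)) return("indeterminate")
  if (upper < 1) return("early")
  if (lower > 1) return("wear_out")
  "random"
}

#' @export
print.weibull_tto <- function(x, digits = 2, ...) {
  cat(sprintf("Weibull time-to-onset fit (n = %d)\n", x$n))
  cat(sprintf("  median %s d (IQR %s-%s)\n",
              round_half_up(x$median, 1), round_half_up(x$q1, 1),
              round_half_up(x$q3, 1)))
  if (!is.na(x$coefficients["alpha"])) {
    cat(sprintf("  scale alpha = %s (95%%CI %s-%s) days\n",
                round_half_up(x$coefficients[["alpha"]], digits),
                round_half_up(x$alpha_ci[1], digits),
                round_half_up(x$alpha_ci[2], digits)))
    cat(sprintf("  shape beta  = %s (95%%CI %s-%s)\n",
                round_half_up(x$coefficients[["beta"]], digits),
                round_half_up(x$beta_ci[1], digits),
                round_half_up(x$beta_ci[2], digits)))
  } else {
    cat("  Weibull parameters not estimable\n")
  }
  cat("  failure type:", x$failure_type, "\n")
  invisible(x)
}

#' @export
summary.weibull_tto <- function(object, ...) object

#' @export
coef.weibull_tto <- function(object, ...) object$coefficients

#' @export
vcov.weibull_tto <- function(object, ...) {
  if (is.null(object$vcov_log)) return(NULL)
  # back-transform to the (alpha, beta) scale
  D <- diag(object$coefficients)
  V <- D %*% object$vcov_log %*% D
  dimnames(V) <- list(c("alpha", "beta"), c("alpha", "beta"))
  V
}

#' @export
logLik.weibull_tto <- function(object, ...) {
  structure(object$loglik, df = 2, nobs = object$n, class = "logLik")
}

#' Confidence intervals for Weibull time-to-onset parameters
#'
#' @param object a [weibull_tto()] fit.
#' @param parm parameters to report (`"alpha"`, `"beta"`, or both).
#' @param level confidence level.
#' @param type `"wald"` (log-scale Wald from the observed information,
#'   the default) or `"profile"` (profile likelihood, inverting the
#'   chi-squared deviance cutoff).
#' @param ... unused.
#' @return matrix with one row per parameter and columns `low`, `high`.
#' @export
confint.weibull_tto <- function(object, parm = c("alpha", "beta"),
                                level = 0.95, type = c("wald", "profile"),
                                ...) {
  type <- match.arg(type)
  parm <- match.arg(parm, several.ok = TRUE)
  if (type == "wald") {
    if (is.null(object$vcov_log)) {
      out <- matrix(NA_real_, 2, 2)
    } else {
      z <- stats::qnorm(1 - (1 - level) / 2)
      est <- object$coefficients
      se <- sqrt(diag(object$vcov_log))
      out <- cbind(est * exp(-z * se), est * exp(z * se))
    }
  } else {
    out <- rbind(profile_ci_weibull(object, "alpha", level),
                 profile_ci_weibull(object, "beta", level))
  }
  dimnames(out) <- list(c("alpha", "beta"), c("low", "high"))
  out[parm, , drop = FALSE]
}

# Profile-likelihood interval: for a fixed value of one parameter, maximize
# the log-likelihood over the other and find where the deviance crosses the
# chi-squared(1) cutoff.
profile_ci_weibull <- function(object, which = c("alpha", "beta"),
                               level = 0.95) {
  which <- match.arg(which)
  if (anyNA(object$coefficients)) return(c(NA_real_, NA_real_))
  x <- object$data
  cutoff <- object$loglik - stats::qchisq(level, 1) / 2
  prof <- function(value) {
    if (which == "beta") {
      b <- value
      a <- mean(x^b)^(1 / b)  # closed-form profile MLE of the scale
      sum(stats::dweibull(x, shape = b, scale = a, log = TRUE))
    } else {
      opt <- stats::optimize(function(lb) {
        -sum(stats::dweibull(x, shape = exp(lb), scale = value, log = TRUE))
      }, interval = log(object$coefficients[["beta"]]) + c(-8, 8))
      -opt$objective
    }
  }
  est <- object$coefficients[[which]]
  root <- function(lo, hi) {
    f <- function(v) prof(v) - cutoff
    if (f(lo) * f(hi) > 0) return(NA_real_)
    stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
  }
  lower <- upper <- NA_real_
  for (k in c(4, 16, 64, 256)) {
    if (is.na(lower)) lower <- root(est / k, est)
    if (is.na(upper)) upper <- root(est, est * k)
  }
  c(lower, upper)
}

#' Simulate onset samples from a fitted time-to-onset model
#'
#' @param object a [weibull_tto()] fit.
#' @param nsim number of replicate sample sets.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return data.frame with `nsim` columns of `n` simulated onset days each.
#' @export
simulate.weibull_tto <- function(object, nsim = 1, seed = NULL, ...) {
  if (anyNA(object$coefficients)) {
    stop("cannot simulate from a degenerate fit", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  out <- as.data.frame(replicate(nsim, stats::rweibull(
    object$n, shape = object$coefficients[["beta"]],
    scale = object$coefficients[["alpha"]])))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a time-to-onset histogram with the fitted Weibull density
#'
#' @param x a [weibull_tto()] fit.
#' @param bin_width histogram bin width in days.
#' @param ... passed to [graphics::hist()].
#' @return the histogram object, invisibly.
#' @export
plot.weibull_tto <- function(x, bin_width = 30, ...) {
  breaks <- seq(0, ceiling(max(x$data) / bin_width) * bin_width, by = bin_width)
  h <- graphics::hist(x$data, breaks = breaks, right = FALSE, freq = FALSE,
                      xlab = "days to onset", main = "Time to onset", ...)
  if (!anyNA(x$coefficients)) {
    graphics::curve(stats::dweibull(t, shape = x$coefficients[["beta"]],
                                    scale = x$coefficients[["alpha"]]),
                    xname = "t", add = TRUE, lwd = 2)
  }
  invisible(h)
}
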