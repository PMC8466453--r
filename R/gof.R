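#' Complete-sample IPL fit
#'
#' Fits the IPL distribution to an uncensored sample by maximum likelihood.
#' A complete sample is the degenerate censoring design \code{k = 1},
#' \code{R = (0, ..., 0)}, \code{m = n}, under which the PFFC likelihood
#' reduces to the ordinary i.i.d. likelihood, so this simply delegates to
#' \code{\link{fit_ipl_mle}}.
#'
#' @param data vector of positive observations.
#' @param ... passed to \code{\link{fit_ipl_mle}}.
#' @return An \code{"ipl_mle"} object.
#' @export
fit_ipl_complete <- function(data, ...) {
  data <- as.numeric(data)
  if (length(data) == 0 || any(!is.finite(data)) || any(data <= 0))
    stop("'data' must be a nonempty vector of positive values", call. = FALSE)
  n <- length(data)
  fit_ipl_mle(pffc_sample(data, censoring_scheme(1, n, n, rep(0L, n))), ...)
}

#' Information criteria for a fitted model
#'
#' Standard definitions: \code{aic = 2p - 2 loglik},
#' \code{caic = aic + 2p(p+1)/(n-p-1)} (the small-sample correction),
#' \code{bic = p log(n) - 2 loglik}, \code{hqic = 2p log(log(n)) - 2 loglik}.
#'
#' @param loglik maximized log-likelihood.
#' @param p number of fitted parameters.
#' @param n number of observations; must exceed \code{p + 1}.
#' @return Named numeric vector \code{(aic, caic, bic, hqic)}.
#' @export
information_criteria <- function(loglik, p, n) {
  if (n <= p + 1)
    stop("the corrected AIC requires n > p + 1", call. = FALSE)
  aic <- 2 * p - 2 * loglik
  c(aic = aic,
    caic = aic + 2 * p * (p + 1) / (n - p - 1),
    bic = p * log(n) - 2 * loglik,
    hqic = 2 * p * log(log(n)) - 2 * loglik)
}

#' Kolmogorov-Smirnov distance to a fitted IPL distribution
#'
#' \eqn{D = \max_i \max\{i/n - F(x_{(i)}),\; F(x_{(i)}) - (i-1)/n\}} over
#' the sorted sample, with F the IPL distribution function at the supplied
#' parameters. Ties are legal; F is evaluated once per sorted position.
#'
#' @param data vector of positive observations.
#' @param alpha,beta,lambda IPL parameters.
#' @return The KS statistic, in [0, 1].
#' @export
ks_statistic <- function(data, alpha, beta, lambda) {
  x <- sort(as.numeric(data))
  n <- length(x)
  if (n == 0) stop("'data' must be nonempty", call. = FALSE)
  Fx <- pipl(x, alpha, beta, lambda)
  i <- seq_len(n)
  max(pmax(i / n - Fx, Fx - (i - 1) / n))
}

#' Goodness-of-fit report for a complete IPL sample
#'
#' Fits the model by \code{\link{fit_ipl_complete}} and reports the
#' maximized log-likelihood, AIC/CAIC/BIC/HQIC and the KS distance at the
#' fitted parameters.
#'
#' @param data vector of positive observations.
#' @param ... passed to the fitter.
#' @return An object of class \code{"ipl_gof"}: list with \code{fit},
#'   \code{criteria}, \code{ks}, \code{n_obs}, \code{n_params}.
#' @examples
#' rep <- ipl_gof(guinea_pigs())
#' rep$criteria["aic"]
#' @export
ipl_gof <- function(data, ...) {
  fit <- fit_ipl_complete(data, ...)
  n <- length(data)
  est <- fit$params_hat
  structure(list(fit = fit,
                 criteria = information_criteria(fit$loglik, 3L, n),
                 ks = ks_statistic(data, est[1], est[2], est[3]),
                 n_obs = n, n_params = 3L),
            class = "ipl_gof")
}

#' @export
print.ipl_gof <- function(x, ...) {
  cat("IPL goodness of fit,", x$n_obs, "observations\n")
  print(round(x$fit$params_hat, 4))
  print(round(c(x$criteria, ks = x$ks), 4))
  invisible(x)
}
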