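#' The Inverse Power Lomax Distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the three-parameter inverse power Lomax (IPL) distribution with shape
#' parameters \code{alpha}, \code{beta} and scale parameter \code{lambda}.
#'
#' The IPL distribution has cumulative distribution function
#' \deqn{F(t) = (1 + \lambda^{-1} t^{-\beta})^{-\alpha}, \quad t > 0,}
#' and density
#' \deqn{f(t) = \alpha\beta\lambda^{-1} t^{-(\beta+1)}
#'   (1 + \lambda^{-1} t^{-\beta})^{-\alpha-1}.}
#' It is a flexible lifetime model accommodating non-monotone hazard shapes,
#' used here for survival times under progressive first-failure censoring.
#'
#' All evaluation is carried out in log space (via \code{log1p} of
#' \eqn{\lambda^{-1} t^{-\beta}}) so that very small \code{t} combined with a
#' large \code{beta} does not overflow.
#'
#' @param x,q vector of quantiles.
#' @param p vector of probabilities.
#' @param n number of observations.
#' @param alpha,beta positive shape parameters.
#' @param lambda positive scale parameter.
#' @param log,log.p logical; if \code{TRUE}, probabilities/densities are
#'   returned on the log scale.
#' @param lower.tail logical; if \code{TRUE} (default), probabilities are
#'   \eqn{P(X \le x)}.
#'
#' @return \code{dipl} gives the density, \code{pipl} the distribution
#'   function, \code{qipl} the quantile function and \code{ripl} random
#'   deviates. Values of \code{x} at or below zero give density 0 and
#'   probability 0.
#'
#' @examples
#' dipl(1, alpha = 1, beta = 1, lambda = 1)   # 0.25
#' pipl(1, alpha = 1, beta = 1, lambda = 1)   # 0.5
#' qipl(0.5, alpha = 1, beta = 1, lambda = 1) # 1
#' @name ipl
NULL

check_ipl_params <- function(alpha, beta, lambda) {
  if (length(alpha) != 1L || length(beta) != 1L || length(lambda) != 1L)
    stop("'alpha', 'beta' and 'lambda' must be scalars", call. = FALSE)
  if (!is.finite(alpha) || !is.finite(beta) || !is.finite(lambda) ||
      alpha <= 0 || beta <= 0 || lambda <= 0)
    stop("IPL parameters must satisfy alpha > 0, beta > 0, lambda > 0",
         call. = FALSE)
  invisible(c(alpha = alpha, beta = beta, lambda = lambda))
}

# log(1 + exp(x)), accurate over the whole real line
log1pexp <- function(x) {
  out <- x
  lo <- x <= -37
  mid <- x > -37 & x <= 18
  hig <- x > 18 & x <= 33.3
  out[lo] <- exp(x[lo])
  out[mid] <- log1p(exp(x[mid]))
  out[hig] <- x[hig] + exp(-x[hig])
  out
}

#' @rdname ipl
#' @export
dipl <- function(x, alpha, beta, lambda, log = FALSE) {
  check_ipl_params(alpha, beta, lambda)
  out <- rep(-Inf, length(x))
  pos <- is.finite(x) & x > 0
  if (any(pos)) {
    lx <- base::log(x[pos])
    u <- -beta * lx - base::log(lambda)        # log(t^-beta / lambda)
    L <- log1pexp(u)                           # log xi
    out[pos] <- base::log(alpha) + base::log(beta) + u - lx - (alpha + 1) * L
  }
  if (log) out else exp(out)
}

#' @rdname ipl
#' @export
pipl <- function(q, alpha, beta, lambda, lower.tail = TRUE, log.p = FALSE) {
  check_ipl_params(alpha, beta, lambda)
  logF <- rep(-Inf, length(q))
  pos <- is.finite(q) & q > 0
  if (any(pos)) {
    u <- -beta * base::log(q[pos]) - base::log(lambda)
    logF[pos] <- -alpha * log1pexp(u)
  }
  logF[is.na(q)] <- NA_real_
  if (lower.tail) {
    if (log.p) logF else exp(logF)
  } else {
    p <- -expm1(logF)
    if (log.p) base::log(p) else p
  }
}

#' @rdname ipl
#' @export
qipl <- function(p, alpha, beta, lambda, lower.tail = TRUE, log.p = FALSE) {
  check_ipl_params(alpha, beta, lambda)
  if (log.p) p <- exp(p)
  if (!lower.tail) p <- 1 - p
  bad <- !is.na(p) & (p <= 0 | p >= 1)
  if (any(bad))
    stop("probabilities must lie strictly inside (0, 1)", call. = FALSE)
  # t = [lambda (p^{-1/alpha} - 1)]^{-1/beta}, computed on the log scale
  logt <- -(base::log(lambda) + base::log(expm1(-base::log(p) / alpha))) / beta
  exp(logt)
}

#' @rdname ipl
#' @export
ripl <- function(n, alpha, beta, lambda) {
  qipl(stats::runif(n), alpha, beta, lambda)
}
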