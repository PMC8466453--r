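# Shared building blocks for the PFFC log-likelihood of the IPL model.
#
# Per observation, with w = x^-beta, xi = 1 + w/lambda, c = k(R+1) - 1,
# everything is expressed through u = log(w/lambda):
#   L      = log(xi)            = log1p(exp(u))
#   sigma  = (w/lambda)/xi      = plogis(u)
#   a      = alpha * L
#   logD   = log(xi^alpha - 1)  = a + log(-expm1(-a))
# so that all ratios appearing in the score and Hessian are exp() of sums of
# logs, which keeps tiny x / large beta from overflowing.
pffc_parts <- function(theta, x, cvec) {
  alpha <- theta[1]; beta <- theta[2]; lambda <- theta[3]
  lx <- log(x)
  u <- -beta * lx - log(lambda)
  L <- log1pexp(u)
  sig <- stats::plogis(u)
  a <- alpha * L
  # log(1 - xi^-alpha) = log(-expm1(-a)); -Inf when a underflows to 0
  l1mexp <- ifelse(a > 0, log(-expm1(-pmax(a, 1e-300))), -Inf)
  logD <- a + l1mexp
  list(alpha = alpha, beta = beta, lambda = lambda,
       lx = lx, L = L, sig = sig, a = a,
       l1mexp = l1mexp, logD = logD)
}

# c_i = k(R_i + 1) - 1, aligned with the sorted failure times
cens_coef <- function(scheme) scheme$k * (scheme$R + 1) - 1

as_theta <- function(params) {
  th <- as.numeric(params)
  if (length(th) != 3L)
    stop("parameters must be a vector (alpha, beta, lambda)", call. = FALSE)
  check_ipl_params(th[1], th[2], th[3])
  th
}

#' PFFC log-likelihood, score and observed-information Hessian
#'
#' The log-likelihood of an inverse power Lomax sample under progressive
#' first-failure censoring, up to the additive constant \eqn{\ln(C k^m)}
#' which does not involve the parameters:
#' \deqn{l = m\ln(\alpha\beta) - m\ln\lambda - (\beta+1)\sum \ln x_i
#'  - (\alpha+1)\sum \ln \xi_i + \sum [k(R_i+1)-1]\ln(1-\xi_i^{-\alpha}),}
#' with \eqn{\xi_i = 1 + \lambda^{-1} x_i^{-\beta}}. \code{ipl_score} and
#' \code{ipl_hessian} are the exact analytic first and second derivatives
#' with respect to \eqn{(\alpha, \beta, \lambda)}; the observed Fisher
#' information is the negative Hessian at the MLE.
#'
#' @param params numeric vector \code{c(alpha, beta, lambda)}, all positive.
#' @param sample a \code{\link{pffc_sample}}.
#' @return \code{ipl_loglik}: a scalar. \code{ipl_score}: a length-3
#'   gradient. \code{ipl_hessian}: a symmetric 3x3 matrix with rows/columns
#'   ordered (alpha, beta, lambda).
#' @examples
#' sc <- censoring_scheme(2, 30, 30, "(0*30)")
#' s <- rpffc(1.5, 1, 0.5, sc, seed = 1)
#' ipl_loglik(c(1.5, 1, 0.5), s)
#' ipl_score(c(1.5, 1, 0.5), s)
#' @export
ipl_loglik <- function(params, sample) {
  th <- as_theta(params)
  stopifnot(inherits(sample, "pffc_sample"))
  x <- sample$times
  cvec <- cens_coef(sample$scheme)
  m <- length(x)
  p <- pffc_parts(th, x, cvec)
  cterm <- cvec * p$l1mexp
  cterm[cvec == 0] <- 0            # 0 * -Inf guard
  m * log(th[1] * th[2]) - m * log(th[3]) -
    (th[2] + 1) * sum(p$lx) - (th[1] + 1) * sum(p$L) + sum(cterm)
}

#' @rdname ipl_loglik
#' @export
ipl_score <- function(params, sample) {
  th <- as_theta(params)
  stopifnot(inherits(sample, "pffc_sample"))
  x <- sample$times
  cvec <- cens_coef(sample$scheme)
  m <- length(x)
  p <- pffc_parts(th, x, cvec)
  alpha <- th[1]; beta <- th[2]; lambda <- th[3]
  E <- exp(-p$logD)                              # 1 / (xi^alpha - 1)
  cE <- cvec * E
  cE[cvec == 0] <- 0                             # 0 * Inf guard
  s_alpha <- m / alpha - sum(p$L) + sum(cE * p$L)
  K <- (alpha + 1) - alpha * cE                  # common per-obs factor
  s_beta <- m / beta - sum(p$lx) + sum(p$lx * p$sig * K)
  s_lambda <- -m / lambda + sum(p$sig * K) / lambda
  c(alpha = s_alpha, beta = s_beta, lambda = s_lambda)
}

#' @rdname ipl_loglik
#' @export
ipl_hessian <- function(params, sample) {
  th <- as_theta(params)
  stopifnot(inherits(sample, "pffc_sample"))
  x <- sample$times
  cvec <- cens_coef(sample$scheme)
  m <- length(x)
  p <- pffc_parts(th, x, cvec)
  alpha <- th[1]; beta <- th[2]; lambda <- th[3]
  E <- exp(-p$logD)                          # 1/D with D = xi^alpha - 1
  # xi^alpha / D^2 = exp(a - 2 logD)
  XaD2 <- exp(p$a - 2 * p$logD)
  cE <- cvec * E
  cXaD2 <- cvec * XaD2
  cE[cvec == 0] <- 0                         # 0 * Inf guards
  cXaD2[cvec == 0] <- 0
  sig <- p$sig; L <- p$L; lx <- p$lx

  h_aa <- -m / alpha^2 - sum(cXaD2 * L^2)

  # d(score_alpha)/dtheta, theta in {beta, lambda}:
  # (xi_theta/xi) * [-1 + c*E - c*alpha*L*xi^alpha/D^2]
  g_mix <- 1 - cE + alpha * L * cXaD2
  h_ab <- sum(lx * sig * g_mix)
  h_al <- sum(sig * g_mix) / lambda

  # second derivatives in (beta, lambda):
  # coefficient of xi_thetaphi/xi and of (xi_theta/xi)(xi_phi/xi)
  A1 <- alpha * cE - (alpha + 1)
  A2 <- (alpha + 1) - alpha * (cE + alpha * cXaD2)
  T1 <- sig * A1 + sig^2 * A2
  h_bb <- -m / beta^2 + sum(lx^2 * T1)
  h_bl <- sum(lx * (sig * A1 + sig^2 * A2)) / lambda
  h_ll <- m / lambda^2 + (sum(2 * sig * A1 + sig^2 * A2)) / lambda^2

  H <- matrix(c(h_aa, h_ab, h_al,
                h_ab, h_bb, h_bl,
                h_al, h_bl, h_ll), 3, 3,
              dimnames = list(c("alpha", "beta", "lambda"),
                              c("alpha", "beta", "lambda")))
  H
}

# Safeguarded Newton ascent on a generic objective.
# obj(theta) must return list(value, grad, hess). Steps that would leave the
# positive orthant or lower the objective are halved (up to 30 times); a
# singular/indefinite information matrix falls back to a scaled gradient
# step. Convergence is the max-norm parameter-change criterion.
# max_step (optional) caps each component of a step at
# max_step * (1 + |theta_i|): a trust region that keeps the iteration inside
# the basin of the starting local maximum, which is what a Laplace-type
# approximation needs when the surface also has a higher boundary spike.
newton_maximize <- function(obj, init, tol = 1e-5, max_iter = 500,
                            max_step = Inf) {
  theta <- as.numeric(init)
  f <- obj(theta)
  if (!is.finite(f$value))
    stop("objective not finite at the initial value", call. = FALSE)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    gnorm <- sqrt(sum(f$grad^2))
    if (gnorm < 1e-10 * (1 + abs(f$value))) { converged <- TRUE; break }
    info <- -f$hess
    damped <- FALSE
    step <- tryCatch(solve(info, f$grad), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)) ||
        sum(step * f$grad) <= 0) {
      damped <- TRUE
      # information matrix singular or indefinite: ridge-damped ascent step,
      # escalating the damping until the system is positive definite
      mu <- 1e-6 * max(1, max(abs(diag(info))))
      step <- NULL
      for (tries in 1:40) {
        step <- tryCatch(solve(info + mu * diag(3), f$grad),
                         error = function(e) NULL)
        if (!is.null(step) && all(is.finite(step)) &&
            sum(step * f$grad) > 0) break
        step <- NULL
        mu <- mu * 10
      }
      if (is.null(step)) step <- f$grad / (1 + gnorm)
    }
    # a sub-tolerance step only signals convergence when it is a genuine
    # Newton step (positive-definite information); a damped step can be
    # arbitrarily short while the gradient is still large
    if (!damped && max(abs(step)) < tol) { converged <- TRUE; break }
    if (is.finite(max_step)) {
      cap <- max_step * (1 + abs(theta))
      scl <- max(abs(step) / cap)
      if (scl > 1) step <- step / scl
    }
    fc <- NULL
    h <- 1
    for (half in 0:30) {
      cand <- theta + h * step
      if (all(cand > 0)) {
        ftry <- obj(cand)
        if (is.finite(ftry$value) && ftry$value >= f$value - 1e-12) {
          fc <- ftry
          break
        }
      }
      h <- h / 2
    }
    if (is.null(fc)) break                    # stalled; report non-converged
    delta <- max(abs(cand - theta))
    theta <- cand
    f <- fc
    if (delta < tol) { converged <- TRUE; break }
  }
  list(theta = theta, value = f$value, grad = f$grad, hess = f$hess,
       n_iter = it, converged = converged)
}
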