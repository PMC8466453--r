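#' Progressive first-failure censoring schemes
#'
#' A progressive first-failure censoring (PFFC) design puts \code{n}
#' independent groups of \code{k} items each on test. At the i-th observed
#' first failure, the failing group and \code{R[i]} further intact groups are
#' withdrawn, until \code{m} failures have been seen. The removal vector must
#' satisfy \code{n = m + sum(R)}. Setting \code{k = 1} recovers progressive
#' Type-II censoring, and \code{k = 1} with \code{R = c(0, ..., 0, n - m)}
#' recovers conventional Type-II censoring.
#'
#' @param k group size (positive integer).
#' @param n number of groups (positive integer).
#' @param m number of observed failures (positive integer, \code{m <= n}).
#' @param R removal vector: either an integer vector of length \code{m} or a
#'   scheme string such as \code{"(10, 0*25)"} (see \code{\link{parse_scheme}}).
#'
#' @return An object of class \code{"censoring_scheme"}: a list with elements
#'   \code{k}, \code{n}, \code{m}, \code{R}.
#' @seealso \code{\link{parse_scheme}}, \code{\link{pffc_sample}},
#'   \code{\link{rpffc}}
#' @examples
#' censoring_scheme(k = 2, n = 36, m = 26, R = "(10, 0*25)")
#' @export
censoring_scheme <- function(k, n, m, R) {
  if (is.character(R)) R <- parse_scheme(R, m)
  k <- as.integer(k); n <- as.integer(n); m <- as.integer(m)
  R <- as.integer(round(R))
  if (k < 1L) stop("group size 'k' must be >= 1", call. = FALSE)
  if (m < 1L || m > n) stop("'m' must satisfy 1 <= m <= n", call. = FALSE)
  if (length(R) != m) stop("removal vector must have length m", call. = FALSE)
  if (any(R < 0L)) stop("removals must be nonnegative", call. = FALSE)
  if (n != m + sum(R))
    stop(sprintf("scheme inconsistent: n = %d but m + sum(R) = %d",
                 n, m + sum(R)), call. = FALSE)
  structure(list(k = k, n = n, m = m, R = R), class = "censoring_scheme")
}

#' @export
print.censoring_scheme <- function(x, ...) {
  cat(sprintf("PFFC scheme: k = %d, n = %d groups, m = %d failures\n",
              x$k, x$n, x$m))
  cat("R =", paste(x$R, collapse = " "), "\n")
  invisible(x)
}

#' Parse a shorthand censoring-scheme string
#'
#' Expands the compact removal-vector notation used in censoring studies:
#' \code{"(0*4)"} means \code{c(0, 0, 0, 0)}, \code{"((2,0)*3)"} means
#' \code{c(2, 0, 2, 0, 2, 0)}, and \code{"(1, 0)*10"} repeats the pair ten
#' times. Whitespace and the outer parentheses are optional; repetition may
#' apply to a single integer or to a parenthesised group, inside or outside
#' the outer parentheses.
#'
#' @param text scheme string.
#' @param m expected length of the expanded removal vector.
#' @return Integer vector of length \code{m}.
#' @examples
#' parse_scheme("(0*4)", 4)
#' parse_scheme("((2,0)*3)", 6)
#' parse_scheme("(1, 0)*10", 20)
#' @export
parse_scheme <- function(text, m) {
  if (!is.character(text) || length(text) != 1L)
    stop("'text' must be a single string", call. = FALSE)
  s <- gsub("[[:space:]]", "", text)
  expand <- function(s) {
    out <- integer(0)
    i <- 1L
    nch <- nchar(s)
    while (i <= nch) {
      ch <- substr(s, i, i)
      if (ch == ",") { i <- i + 1L; next }
      if (ch == "(") {
        # find the matching close parenthesis
        depth <- 0L; j <- i
        repeat {
          cj <- substr(s, j, j)
          if (cj == "(") depth <- depth + 1L
          if (cj == ")") depth <- depth - 1L
          if (depth == 0L) break
          j <- j + 1L
          if (j > nch) stop("unbalanced parentheses in scheme string",
                            call. = FALSE)
        }
        inner <- expand(substr(s, i + 1L, j - 1L))
        i <- j + 1L
      } else {
        mt <- regmatches(substr(s, i, nch),
                         regexpr("^-?[0-9]+", substr(s, i, nch)))
        if (length(mt) == 0L)
          stop("malformed scheme string near '",
               substr(s, i, min(nch, i + 5L)), "'", call. = FALSE)
        inner <- as.integer(mt)
        i <- i + nchar(mt)
      }
      # optional *REP after an integer or a group
      if (i <= nch && substr(s, i, i) == "*") {
        rep_mt <- regmatches(substr(s, i + 1L, nch),
                             regexpr("^[0-9]+", substr(s, i + 1L, nch)))
        if (length(rep_mt) == 0L)
          stop("'*' must be followed by a repeat count", call. = FALSE)
        inner <- rep(inner, as.integer(rep_mt))
        i <- i + 1L + nchar(rep_mt)
      }
      out <- c(out, inner)
    }
    out
  }
  R <- expand(s)
  if (any(R < 0L)) stop("removals must be nonnegative", call. = FALSE)
  if (length(R) != m)
    stop(sprintf("scheme '%s' expands to length %d, expected m = %d",
                 text, length(R), m), call. = FALSE)
  R
}

#' Bind observed failure times to a censoring scheme
#'
#' Constructs a progressive first-failure censored sample: the \code{m}
#' observed first-failure times together with the design that produced them.
#' Times are sorted ascending (stably, so duplicates are legal); the i-th
#' removal \code{R[i]} refers to the i-th smallest failure time.
#'
#' @param times numeric vector of \code{m} positive failure times.
#' @param scheme a \code{\link{censoring_scheme}}.
#' @return An object of class \code{"pffc_sample"} with elements
#'   \code{times} (sorted) and \code{scheme}.
#' @export
pffc_sample <- function(times, scheme) {
  if (!inherits(scheme, "censoring_scheme"))
    stop("'scheme' must be a censoring_scheme object", call. = FALSE)
  times <- as.numeric(times)
  if (length(times) != scheme$m)
    stop(sprintf("expected %d failure times, got %d",
                 scheme$m, length(times)), call. = FALSE)
  if (any(!is.finite(times)) || any(times <= 0))
    stop("failure times must be positive and finite", call. = FALSE)
  structure(list(times = sort(times), scheme = scheme),
            class = "pffc_sample")
}

#' @export
print.pffc_sample <- function(x, ...) {
  print(x$scheme)
  cat("times:", paste(format(x$times), collapse = " "), "\n")
  invisible(x)
}

# Uniform-spacings construction of progressively censored uniforms:
# given Z ~ U(0,1)^m and removals R, returns U_1 < ... < U_m distributed as
# progressive Type-II censored uniform order statistics.
pffc_uniforms <- function(Z, R) {
  m <- length(R)
  expo <- seq_len(m) + cumsum(rev(R))       # i + R_m + ... + R_{m-i+1}
  xi <- Z^(1 / expo)
  # U_i = 1 - xi_m * xi_{m-1} * ... * xi_{m-i+1}
  1 - cumprod(rev(xi))
}

#' Simulate a progressive first-failure censored IPL sample
#'
#' Generates one PFFC sample from the inverse power Lomax distribution by
#' the uniform-spacings construction: \eqn{\xi_i =
#' Z_i^{1/(i + R_m + \cdots + R_{m-i+1})}} for independent uniforms
#' \eqn{Z_i}, \eqn{U_i = 1 - \xi_m \xi_{m-1} \cdots \xi_{m-i+1}}, and
#' \eqn{X_i = F^{*-1}(U_i)}, where \eqn{F^*(x) = 1 - (1 - F(x))^k} is the
#' distribution of a group minimum. \eqn{F^{*-1}} is evaluated exactly as
#' \code{qipl(1 - (1 - u)^(1/k))}, avoiding any root finding.
#'
#' @param alpha,beta,lambda IPL parameters of the underlying lifetimes.
#' @param scheme a \code{\link{censoring_scheme}}.
#' @param seed optional integer; if supplied, draws come from a private
#'   Mersenne-Twister stream and the caller's RNG state is untouched.
#' @return A \code{\link{pffc_sample}}.
#' @examples
#' sc <- censoring_scheme(k = 2, n = 30, m = 30, R = "(0*30)")
#' rpffc(1.5, 1, 0.5, sc, seed = 1)
#' @export
rpffc <- function(alpha, beta, lambda, scheme, seed = NULL) {
  check_ipl_params(alpha, beta, lambda)
  if (!inherits(scheme, "censoring_scheme"))
    stop("'scheme' must be a censoring_scheme object", call. = FALSE)
  Z <- with_private_rng(seed, stats::runif(scheme$m))
  U <- pffc_uniforms(Z, scheme$R)
  # group-minimum inversion: F*(x) = 1 - (1 - F(x))^k
  p <- -expm1(log1p(-U) / scheme$k)
  x <- qipl(p, alpha, beta, lambda)
  pffc_sample(sort(x), scheme)
}

# Run expr with a seeded private RNG stream (Mersenne-Twister), restoring the
# caller's .Random.seed afterwards. With seed = NULL the global stream is used.
with_private_rng <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}
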