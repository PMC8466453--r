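#' Guinea-pig survival data and derived censored samples
#'
#' Survival times (in days) of 72 guinea pigs infected with virulent
#' tubercle bacilli (Bjerkedal, 1960), a standard benchmark for lifetime
#' models, together with the first-failure subsample obtained by randomly
#' pairing the animals into 36 groups of size \code{k = 2}, and three
#' progressive first-failure censored samples drawn from that subsample with
#' \code{m = 26} under the schemes
#' \itemize{
#'   \item CS1: \code{R = (10, 0*25)} (all removals at the first failure),
#'   \item CS2: \code{R = (0*11, 3, 4, 3, 0*12)} (removals mid-test),
#'   \item CS3: \code{R = (0*25, 10)} (all removals at the last failure).
#' }
#' All values are stored exactly as reported, including one entry of 1.4 in
#' the grouped subsample (and hence in CS1/CS3) that does not occur in the
#' complete data.
#'
#' @return \code{guinea_pigs()} returns the 72 survival times.
#'   \code{guinea_pigs_first_failure()} returns the 36 group-minimum times.
#'   \code{guinea_pigs_pffc(cs)} returns a \code{\link{pffc_sample}} for
#'   \code{cs} in \code{"CS1"}, \code{"CS2"}, \code{"CS3"}.
#'   \code{pffc_fixtures()} returns all of the above in a named list.
#' @examples
#' length(guinea_pigs())          # 72
#' guinea_pigs_pffc("CS1")$scheme # k = 2, n = 36, m = 26
#' @export
guinea_pigs <- function() {
  c(0.1, 0.33, 0.44, 0.56, 0.59, 0.59, 0.72, 0.74, 0.92, 0.93, 0.96, 1,
    1, 1.02, 1.05, 1.07, 1.07, 1.08, 1.08, 1.08, 1.09, 1.12, 1.13, 1.15,
    1.16, 1.2, 1.21, 1.22, 1.22, 1.24, 1.3, 1.34, 1.36, 1.39, 1.44, 1.46,
    1.53, 1.59, 1.6, 1.63, 1.63, 1.68, 1.71, 1.72, 1.76, 1.83, 1.95, 1.96,
    1.97, 2.02, 2.13, 2.15, 2.16, 2.22, 2.3, 2.31, 2.4, 2.45, 2.51, 2.53,
    2.54, 2.54, 2.78, 2.93, 3.27, 3.42, 3.47, 3.61, 4.02, 4.32, 4.58, 5.55)
}

#' @rdname guinea_pigs
#' @export
guinea_pigs_first_failure <- function() {
  c(0.1, 0.44, 0.59, 0.74, 0.93, 1, 1.05, 1.07, 1.08, 1.12, 1.15, 1.2,
    1.22, 1.24, 1.4, 1.34, 1.39, 1.46, 1.59, 1.63, 1.68, 1.72, 1.83, 1.97,
    2.02, 2.15, 2.22, 2.31, 2.45, 2.53, 2.54, 2.78, 2.93, 3.42, 3.61, 4.02)
}

#' @rdname guinea_pigs
#' @param cs which censored sample: "CS1", "CS2" or "CS3".
#' @export
guinea_pigs_pffc <- function(cs = c("CS1", "CS2", "CS3")) {
  cs <- match.arg(cs)
  times <- switch(cs,
    CS1 = c(0.1, 1.2, 1.22, 1.24, 1.4, 1.34, 1.39, 1.46, 1.59, 1.63, 1.68,
            1.72, 1.83, 1.97, 2.02, 2.15, 2.22, 2.31, 2.45, 2.53, 2.54,
            2.78, 2.93, 3.42, 3.61, 4.02),
    CS2 = c(0.1, 0.44, 0.59, 0.74, 0.93, 1, 1.05, 1.07, 1.08, 1.12, 1.15,
            1.2, 1.22, 1.39, 1.72, 2.15, 2.22, 2.31, 2.45, 2.53, 2.54,
            2.78, 2.93, 3.42, 3.61, 4.02),
    CS3 = c(0.1, 0.44, 0.59, 0.74, 0.93, 1, 1.05, 1.07, 1.08, 1.12, 1.15,
            1.2, 1.22, 1.24, 1.4, 1.34, 1.39, 1.46, 1.59, 1.63, 1.68, 1.72,
            1.83, 1.97, 2.02, 2.15))
  R <- switch(cs,
    CS1 = "(10, 0*25)",
    CS2 = "(0*11, 3, 4, 3, 0*12)",
    CS3 = "(0*25, 10)")
  pffc_sample(times, censoring_scheme(k = 2, n = 36, m = 26, R = R))
}

#' @rdname guinea_pigs
#' @export
pffc_fixtures <- function() {
  list(guinea_pigs = guinea_pigs(),
       first_failure = guinea_pigs_first_failure(),
       CS1 = guinea_pigs_pffc("CS1"),
       CS2 = guinea_pigs_pffc("CS2"),
       CS3 = guinea_pigs_pffc("CS3"))
}
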