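#' Minimum number of annotations for a class-detection estimate
#'
#' Standard sensitivity-style sample size for an annotation campaign: to
#' estimate a detection proportion `p` to within an absolute margin `d` at a
#' given confidence, when only a fraction `prevalence` of items contain the
#' class of interest,
#' \deqn{n = \lceil z^2 \, p (1 - p) / (d^2 \cdot \mathrm{prevalence}) \rceil}
#' with `z` the two-sided normal quantile for the confidence level. The
#' result is always rounded up. `n` is largest at `p = 0.5` and shrinks with
#' the square of the margin, so halving `d` quadruples `n`.
#'
#' @param expected_sensitivity Expected detection proportion `p`, in (0, 1).
#' @param margin Absolute half-width `d` of the confidence interval, in
#'   (0, 1).
#' @param confidence Two-sided confidence level, in (0, 1); default 0.95.
#' @param prevalence Fraction of items containing the class of interest, in
#'   (0, 1]; default 1.
#' @return A list with the integer `n` and the substituted inputs
#'   (`z`, `p`, `d`, `prevalence`), so a calculation can be replayed.
#' @examples
#' minimum_annotations(expected_sensitivity = 0.8, margin = 0.05)$n
#' @export
minimum_annotations <- function(expected_sensitivity, margin,
                                confidence = 0.95, prevalence = 1) {
  p <- expected_sensitivity
  d <- margin
  if (!is.numeric(p) || p <= 0 || p >= 1) {
    stop("expected_sensitivity must lie in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(d) || d <= 0 || d >= 1) {
    stop("margin must lie in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(confidence) || confidence <= 0 || confidence >= 1) {
    stop("confidence must lie in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence > 1) {
    stop("prevalence must lie in (0, 1]", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  n <- ceiling(z^2 * p * (1 - p) / (d^2 * prevalence))
  list(n = as.integer(n), z = z, p = p, d = d, prevalence = prevalence,
       confidence = confidence)
}
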