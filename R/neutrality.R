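# Neutrality analysis: ordinary least squares of GC12 on GC3s.  Under pure
# mutation pressure all three codon positions drift together and the
# points sit on the diagonal (slope 1); selection on the first two
# positions flattens the line.  slope*100 is read as the percentage of
# codon-usage variation attributable to mutation pressure, the remainder
# to natural selection.

#' Fit the GC12 ~ GC3s neutrality regression
#'
#' @param gc3s numeric vector of silent-site GC fractions, or a data.frame
#'   with columns `gc3s` and `gc12` (e.g. from [enc_batch()]).
#' @param gc12 numeric vector, ignored when `gc3s` is a data.frame.
#' @return Object of class `cub_neutrality_fit`: slope, intercept,
#'   r_squared, two-sided p_value for slope != 0, pct_mutation
#'   (= 100*slope), pct_selection (= 100*(1-slope)), ci95_slope, and a
#'   per-point 95% confidence band of the mean response (`band`).
#' @export
#' @examples
#' fit <- neutrality_fit(c(.2, .4, .6), c(.2, .4, .6))
#' fit$pct_mutation  # 100: points on the diagonal
neutrality_fit <- function(gc3s, gc12 = NULL) {
  if (is.data.frame(gc3s)) {
    gc12 <- gc3s$gc12
    gc3s <- gc3s$gc3s
  }
  if (length(gc3s) != length(gc12))
    stop("gc3s and gc12 must have equal length")
  keep <- is.finite(gc3s) & is.finite(gc12)
  gc3s <- gc3s[keep]; gc12 <- gc12[keep]
  if (length(gc3s) < 3L)
    stop("neutrality fit requires at least 3 points")
  if (stats::var(gc3s) == 0)
    stop("neutrality fit degenerate: GC3s has zero variance")
  fit <- stats::lm(gc12 ~ gc3s)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2L])
  # p-value undefined for a perfect fit with 0 residual variance
  pval <- if (nrow(sm$coefficients) == 2L && sm$sigma > 0)
    sm$coefficients[2L, 4L] else 0
  band <- cbind(gc3s = gc3s,
                as.data.frame(stats::predict(fit, interval = "confidence")))
  structure(list(
    slope = slope,
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = sm$r.squared,
    p_value = pval,
    pct_mutation = 100 * slope,
    pct_selection = 100 * (1 - slope),
    ci95_slope = unname(stats::confint(fit)["gc3s", ]),
    band = band,
    n = length(gc3s)
  ), class = "cub_neutrality_fit")
}

#' @export
print.cub_neutrality_fit <- function(x, ...) {
  cat(sprintf("<cub_neutrality_fit> n=%d\n", x$n))
  cat(sprintf("  GC12 = %.4f + %.4f * GC3s   (R2 = %.4f, p = %.3g)\n",
              x$intercept, x$slope, x$r_squared, x$p_value))
  cat(sprintf("  mutation pressure %.1f%% / natural selection %.1f%%\n",
              x$pct_mutation, x$pct_selection))
  invisible(x)
}
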