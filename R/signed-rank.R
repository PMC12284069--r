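#' Wilcoxon signed-rank test with Pratt zero handling
#'
#' Paired/one-sample signed-rank test used throughout the pipeline (last-
#' second AC vs PC amplitudes, responsive-bin selection, onset-latency
#' differences, evoked-amplitude contrasts). Zero differences are handled by
#' the Pratt method: zeros are included when ranking the absolute
#' differences, then dropped from the signed rank sums. With no zeros and no
#' ties the exact null distribution is used for n <= 25 (via the standard
#' signed-rank distribution); otherwise a normal approximation with tie
#' correction and continuity correction is used. This fixed convention makes
#' p-values reproducible across inputs with ties.
#'
#' @param x numeric vector (differences, or first member of pairs).
#' @param y optional second member; when given the test is on `x - y`.
#' @param alternative `"two.sided"` (default), `"greater"` (x > y), or
#'   `"less"`.
#' @param exact_max largest zero/tie-free n for which the exact null is used
#'   (default 25).
#' @return list with `statistic` (V, the positive-rank sum), `p.value`, `n`
#'   (non-zero differences used), `method` (`"exact"` or `"normal"`).
#' @export
signed_rank_test <- function(x, y = NULL,
                             alternative = c("two.sided", "greater", "less"),
                             exact_max = 25L) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  d <- d[is.finite(d)]
  if (length(d) < 1L) stop("no finite differences")
  zeros <- d == 0
  ad <- abs(d)
  rk <- rank(ad)                         # Pratt: zeros participate in ranking
  vpos <- sum(rk[d > 0])
  n_nz <- sum(!zeros)
  ties <- any(duplicated(ad[!zeros])) || any(zeros)
  if (!ties && n_nz <= exact_max && n_nz >= 1L) {
    p_greater <- stats::psignrank(vpos - 1, n_nz, lower.tail = FALSE)
    p_less <- stats::psignrank(vpos, n_nz)
    method <- "exact"
  } else {
    # Pratt normal approximation: moments of the rank sum over sign flips of
    # the non-zero differences, zeros' ranks fixed (they contribute neither
    # side). E[V] and Var[V] subtract the zero block's contribution.
    n <- length(d)
    n0 <- sum(zeros)
    ev <- n * (n + 1) / 4 - n0 * (n0 + 1) / 4
    tie_tab <- table(rk[!zeros])
    vv <- n * (n + 1) * (2 * n + 1) / 24 - n0 * (n0 + 1) * (2 * n0 + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    if (vv <= 0) return(list(statistic = vpos, p.value = 1, n = n_nz, method = "normal"))
    p_greater <- stats::pnorm((vpos - ev - 0.5) / sqrt(vv), lower.tail = FALSE)
    p_less <- stats::pnorm((vpos - ev + 0.5) / sqrt(vv))
    method <- "normal"
  }
  p <- switch(alternative,
              two.sided = min(1, 2 * min(p_greater, p_less)),
              greater = p_greater,
              less = p_less)
  list(statistic = vpos, p.value = p, n = n_nz, method = method)
}

#' One-way repeated-measures ANOVA
#'
#' Thin wrapper over `aov(value ~ condition + Error(subject))` returning the
#' within-subject F test for the condition factor.
#'
#' @param value numeric response.
#' @param condition factor of within-subject conditions.
#' @param subject factor identifying the repeated unit (animal).
#' @return list with `F`, `df1`, `df2`, `p.value`.
#' @export
rm_anova_oneway <- function(value, condition, subject) {
  df <- data.frame(value = value, condition = factor(condition),
                   subject = factor(subject))
  fit <- stats::aov(value ~ condition + Error(subject), data = df)
  s <- summary(fit)
  within <- s[["Error: Within"]][[1L]]
  row <- grep("condition", rownames(within))
  list(F = within[row, "F value"], df1 = within[row, "Df"],
       df2 = within["Residuals", "Df"], p.value = within[row, "Pr(>F)"])
}
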