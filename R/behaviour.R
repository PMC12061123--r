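#' Filter behavioural trials for analysis validity
#'
#' Retains trials with a correct valence classification (response equal to
#' the target's assigned valence label) and a reaction time inside the
#' valid range, 250 ms to 2000 ms inclusive at both ends.  Exclusion counts
#' per reason are attached as attribute `"exclusions"`.
#'
#' @param log Behavioural log with columns `rt_ms`, `response`,
#'   `target_valence` (e.g. from [simulate_rt()]).
#' @param rt_range Valid reaction-time range in ms, inclusive.
#' @return The retained rows, with an `"exclusions"` attribute
#'   (named counts: `wrong_response`, `too_fast`, `too_slow`).
#' @export
filter_valid <- function(log, rt_range = c(250, 2000)) {
  need <- c("rt_ms", "response", "target_valence")
  missing_cols <- setdiff(need, names(log))
  if (length(missing_cols)) {
    stop("behavioural log lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  correct <- !is.na(log$response) & log$response == log$target_valence
  too_fast <- log$rt_ms < rt_range[1L]
  too_slow <- log$rt_ms > rt_range[2L]
  keep <- correct & !too_fast & !too_slow
  out <- log[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- c(
    wrong_response = sum(!correct),
    too_fast = sum(correct & too_fast),
    too_slow = sum(correct & too_slow)
  )
  out
}

#' Per-participant median reaction-time contrast
#'
#' Computes, for every participant, the median reaction time of valid
#' congruent and incongruent trials and their difference (congruent minus
#' incongruent).  Participants with an empty condition are dropped and
#' logged in the `"excluded"` attribute.
#'
#' @param valid Filtered behavioural log (see [filter_valid()]) with
#'   columns `participant`, `congruent`, `rt_ms`.
#' @return Data frame with `participant`, `median_congruent`,
#'   `median_incongruent`, `difference`, `n_valid_congruent`,
#'   `n_valid_incongruent`.
#' @examples
#' log <- data.frame(participant = 1,
#'                   congruent = rep(c(TRUE, FALSE), each = 3),
#'                   rt_ms = c(700, 720, 740, 730, 751, 760))
#' rt_contrast(log)$difference  # -31
#' @export
rt_contrast <- function(valid) {
  stopifnot(all(c("congruent", "rt_ms") %in% names(valid)))
  if (is.null(valid$participant)) valid$participant <- 1L
  res <- lapply(split(valid, valid$participant), function(d) {
    rc <- d$rt_ms[d$congruent]
    ri <- d$rt_ms[!d$congruent]
    data.frame(
      participant = d$participant[1L],
      median_congruent = if (length(rc)) median(rc) else NA_real_,
      median_incongruent = if (length(ri)) median(ri) else NA_real_,
      n_valid_congruent = length(rc),
      n_valid_incongruent = length(ri)
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$difference <- out$median_congruent - out$median_incongruent
  empty <- is.na(out$difference)
  excluded <- out$participant[empty]
  out <- out[!empty, , drop = FALSE]
  out <- out[, c("participant", "median_congruent", "median_incongruent",
                 "difference", "n_valid_congruent", "n_valid_incongruent")]
  attr(out, "excluded") <- excluded
  out
}

#' Paired tests on per-participant reaction-time differences
#'
#' Runs the full contrast battery on a vector of per-participant
#' differences (congruent minus incongruent): Wilcoxon signed-rank test,
#' paired t test, Cohen's d (`mean(diff) / sd(diff)`), and a JZS Bayes
#' factor with a Cauchy prior of scale 0.707 on the standardized effect.
#' The default sidedness is one-sided in the direction congruent faster
#' than incongruent (differences < 0), matching the directional hypothesis
#' of a priming experiment; sidedness is always echoed in the result.
#'
#' Zero differences are discarded before ranking (Wilcoxon's rule); the
#' exact null distribution is used for n <= 25 without ties, the normal
#' approximation with continuity correction otherwise.  If all differences
#' are zero the Wilcoxon statistic is undefined and returned as `NA` with
#' an explanatory message, while t and d are 0.
#'
#' @param differences Numeric vector, one value per participant (n >= 5).
#' @param sided `"one"` (congruent < incongruent) or `"two"`.
#' @param bf_rscale Cauchy prior scale of the Bayes factor.
#' @return Object of class `paired_test_result`: a list with
#'   `wilcoxon_statistic`, `wilcoxon_p`, `t_statistic`, `t_p`, `cohens_d`,
#'   `bf10`, `n`, `sidedness`, `bf_rscale`, and `wilcoxon_message`.
#' @export
paired_tests <- function(differences, sided = c("one", "two"),
                         bf_rscale = sqrt(2) / 2) {
  sided <- match.arg(sided)
  x <- differences[!is.na(differences)]
  n <- length(x)
  if (n < 5L) stop("need at least 5 paired differences")
  alternative <- if (sided == "one") "less" else "two.sided"

  if (all(x == 0)) {
    res <- list(
      wilcoxon_statistic = NA_real_, wilcoxon_p = NA_real_,
      t_statistic = 0, t_p = if (sided == "one") 0.5 else 1,
      cohens_d = 0, bf10 = jzs_bf(0, n, bf_rscale, alternative), n = n,
      sidedness = sided, bf_rscale = bf_rscale,
      wilcoxon_message = "all differences zero: signed-rank undefined"
    )
    return(structure(res, class = "paired_test_result"))
  }

  nz <- x[x != 0]
  exact <- length(nz) <= 25L && !any(duplicated(abs(nz)))
  wt <- suppressWarnings(
    wilcox.test(nz, alternative = alternative, exact = exact,
                correct = TRUE)
  )
  tt <- t.test(x, alternative = alternative)
  d <- mean(x) / sd(x)
  bf <- jzs_bf(unname(tt$statistic), n, bf_rscale, alternative)
  structure(
    list(
      wilcoxon_statistic = unname(wt$statistic), wilcoxon_p = wt$p.value,
      t_statistic = unname(tt$statistic), t_p = tt$p.value,
      cohens_d = d, bf10 = bf, n = n, sidedness = sided,
      bf_rscale = bf_rscale, wilcoxon_message = NA_character_
    ),
    class = "paired_test_result"
  )
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf(
    paste0("<paired_test_result> n=%d, %s-sided\n",
           "  Wilcoxon W=%.1f p=%.4g | t=%.3f p=%.4g | d=%.3f | BF10=%.3g\n"),
    x$n, x$sidedness, x$wilcoxon_statistic, x$wilcoxon_p,
    x$t_statistic, x$t_p, x$cohens_d, x$bf10
  ))
  invisible(x)
}

#' JZS Bayes factor for a one-sample (paired) t statistic
#'
#' Computes the Jeffreys-Zellner-Siow Bayes factor BF10 by numerical
#' integration of the noncentral-t likelihood against a Cauchy prior of
#' scale `rscale` on the standardized effect size.  For one-sided
#' alternatives the prior is the half-Cauchy on the corresponding side.
#'
#' @param t Observed t statistic.
#' @param n Number of pairs.
#' @param rscale Cauchy prior scale (default `sqrt(2)/2`).
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return BF10 (positive scalar).
#' @export
jzs_bf <- function(t, n, rscale = sqrt(2) / 2,
                   alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  nu <- n - 1
  lik <- function(delta) dt(t, df = nu, ncp = delta * sqrt(n))
  prior <- function(delta) dcauchy(delta, 0, rscale)
  integrand <- function(delta) lik(delta) * prior(delta)
  m0 <- dt(t, df = nu)
  # dt(ncp=) warns about full-precision loss far in the tails; harmless here
  m1 <- suppressWarnings(switch(
    alternative,
    two.sided = integrate(integrand, -Inf, 0, rel.tol = 1e-9)$value +
      integrate(integrand, 0, Inf, rel.tol = 1e-9)$value,
    less = 2 * integrate(integrand, -Inf, 0, rel.tol = 1e-9)$value,
    greater = 2 * integrate(integrand, 0, Inf, rel.tol = 1e-9)$value
  ))
  m1 / m0
}

#' Bonferroni-Holm correction
#'
#' Step-down Holm adjustment of a vector of p-values (monotone after
#' sorting, capped at 1).
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
holm_correct <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  p.adjust(pvals, method = "holm")
}

#' Pearson and Spearman correlation, side by side
#'
#' Reports both the parametric and the rank correlation with two-sided
#' p-values for one variable pair; the parametric/non-parametric
#' discrepancy is part of the analysis output, so both are always present.
#'
#' @param x,y Paired numeric vectors (n >= 4 complete pairs).
#' @param labels Length-2 character vector naming the pair.
#' @return Data frame with `var_x`, `var_y`, `n`, `pearson_r`, `pearson_p`,
#'   `spearman_rho`, `spearman_p`.
#' @export
correlate <- function(x, y, labels = c("x", "y")) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 4L) stop("need at least 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined: a variable has zero variance")
  }
  pe <- cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  data.frame(
    var_x = labels[1L], var_y = labels[2L], n = length(x),
    pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
    spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
    stringsAsFactors = FALSE
  )
}

#' Correlate questionnaire scores with behavioural/ERP outcomes
#'
#' Convenience wrapper running [correlate()] for every questionnaire column
#' against one outcome vector, with Holm-adjusted Pearson p-values across
#' the family.
#'
#' @param scores Data frame from [simulate_questionnaires()] (or matching
#'   layout) with a `participant` column.
#' @param outcome Named list or data frame column: numeric outcome per
#'   participant, aligned by position.
#' @param outcome_label Name of the outcome in the report.
#' @return Data frame, one row per questionnaire score, with a
#'   `pearson_p_holm` column.
#' @export
correlate_questionnaires <- function(scores, outcome,
                                     outcome_label = "outcome") {
  vars <- setdiff(names(scores), "participant")
  rows <- lapply(vars, function(v) {
    correlate(scores[[v]], outcome, labels = c(v, outcome_label))
  })
  out <- do.call(rbind, rows)
  out$pearson_p_holm <- holm_correct(out$pearson_p)
  out
}
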