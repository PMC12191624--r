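#' Per-subject Markov-violation scores from a ratings table
#'
#' Applies [markov_violation_score()] to every subject's ratings.
#'
#' @param ratings data frame with `subject_id`, `condition`, `query_id`,
#'   `rating`.
#' @param battery a battery carrying `markov_cells`.
#' @return data frame with `subject_id`, `condition`, `score`.
#' @export
subject_markov_scores <- function(ratings, battery) {
  subjects <- unique(ratings$subject_id)
  out <- lapply(subjects, function(s) {
    sub <- ratings[ratings$subject_id == s, ]
    data.frame(subject_id = s, condition = sub$condition[1],
               score = markov_violation_score(
                 stats::setNames(sub$rating, sub$query_id), battery))
  })
  do.call(rbind, out)
}

#' One-way between-subjects ANOVA
#'
#' Standard between/within decomposition across k independent groups,
#' computed through base R's linear-model machinery. Degrees of freedom are
#' (k - 1, N - k) and the p-value is the upper tail of the F distribution.
#'
#' @param groups a named list of numeric vectors, one per group.
#' @return list with `F`, `df_between`, `df_within`, `p`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(y) <= length(groups)) stop("total N must exceed group count")
  ssw <- sum(unlist(lapply(groups, function(v) sum((v - mean(v))^2))))
  if (ssw == 0) stop("zero within-group variance")
  tab <- stats::anova(stats::lm(y ~ g))
  list(F = tab$`F value`[1], df_between = tab$Df[1], df_within = tab$Df[2],
       p = tab$`Pr(>F)`[1])
}

#' One-sample t test
#'
#' @param values numeric vector, n >= 2, nonconstant.
#' @param null_mean null hypothesis mean (default 0).
#' @return list with `t`, `df`, `p` (two-sided), `mean`, `se`.
#' @export
one_sample_t <- function(values, null_mean = 0) {
  stopifnot(length(values) >= 2)
  if (stats::sd(values) == 0) stop("zero sample variance")
  tt <- stats::t.test(values, mu = null_mean)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean = unname(tt$estimate),
       se = unname(tt$stderr))
}

#' JZS Bayes factor for a one-sample t test
#'
#' The default Jeffreys-Zellner-Siow Bayes factor: a Cauchy prior with
#' scale `r_scale` on the standardized effect size delta, against the point
#' null delta = 0. Computed from the t statistic and sample size by
#' numerically integrating the noncentral-t likelihood over the Cauchy
#' prior:
#' `BF10 = integral dt(t; n-1, ncp = delta * sqrt(n)) dCauchy(delta; 0, r)
#'  d delta / dt(t; n-1)`.
#'
#' @param t observed t statistic.
#' @param n sample size (>= 2).
#' @param r_scale Cauchy prior scale; default `sqrt(2)/2` ("medium").
#' @return BF10, the evidence for the alternative over the null.
#' @export
jzs_bf <- function(t, n, r_scale = sqrt(2) / 2) {
  stopifnot(n >= 2, r_scale > 0)
  df <- n - 1
  # dt(, ncp) warns about precision at extreme noncentrality; harmless here
  integrand <- function(delta)
    suppressWarnings(stats::dt(t, df, ncp = delta * sqrt(n))) *
      stats::dcauchy(delta, 0, r_scale)
  num <- stats::integrate(integrand, -Inf, Inf, rel.tol = 1e-10,
                          stop.on.error = FALSE)
  if (num$message != "OK" || !is.finite(num$value) || num$value <= 0) {
    # retry on a bounded interval centred on the MLE of delta
    centre <- t / sqrt(n)
    num <- stats::integrate(integrand, centre - 50 * r_scale,
                            centre + 50 * r_scale, rel.tol = 1e-10)
    if (!is.finite(num$value) || num$value <= 0)
      stop("JZS integration failed: ", num$message,
           " (t = ", t, ", n = ", n, ")")
  }
  num$value / stats::dt(t, df)
}

#' Group-level summary of Markov-violation scores
#'
#' Reproduces the standard statistics block for a screening-off study:
#' per-condition mean score with a classical 95% t confidence interval, a
#' one-way ANOVA across conditions, and a one-sample t test plus JZS Bayes
#' factor per condition against a null of no violation.
#'
#' @param scores data frame from [subject_markov_scores()].
#' @param r_scale Cauchy prior scale for the Bayes factors.
#' @return list with `conditions` (data frame: condition, n, mean score,
#'   95% CI bounds, t, df, p, bf10) and `anova`.
#' @export
markov_stats_report <- function(scores, r_scale = sqrt(2) / 2) {
  conds <- unique(scores$condition)
  rows <- lapply(conds, function(cn) {
    v <- scores$score[scores$condition == cn]
    tt <- one_sample_t(v)
    ci <- mean(v) + stats::qt(c(0.025, 0.975), length(v) - 1) *
      stats::sd(v) / sqrt(length(v))
    data.frame(condition = cn, n = length(v), mean_score = mean(v),
               ci_lo = ci[1], ci_hi = ci[2], t = tt$t, df = tt$df,
               p = tt$p, bf10 = jzs_bf(tt$t, length(v), r_scale))
  })
  groups <- lapply(conds, function(cn) scores$score[scores$condition == cn])
  names(groups) <- conds
  list(conditions = do.call(rbind, rows), anova = one_way_anova(groups))
}
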