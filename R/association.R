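#' AUC for discriminating a binary clinical label
#'
#' Area under the ROC curve via the rank-sum (Mann-Whitney) identity with
#' midrank tie handling: the probability that a randomly chosen positive
#' sample scores above a random negative one, ties counting one half. The
#' p-value comes from the normal-approximated two-sided Wilcoxon rank-sum
#' test. For a signature oriented so that high scores predict the *negative*
#' outcome, `flip = TRUE` reports `1 - AUC`.
#'
#' @param scores Numeric per-sample scores.
#' @param labels Binary labels (logical, 0/1, or a two-level factor whose
#'   second level is the positive class).
#' @param flip Report `1 - AUC` (orientation flip), default `FALSE`.
#' @return List with `auc`, `p_value`, `n_pos`, `n_neg`.
#' @export
auc_benefit <- function(scores, labels, flip = FALSE) {
  if (length(scores) != length(labels)) stop("scores and labels lengths differ")
  if (is.factor(labels) || is.character(labels)) {
    labels <- as.factor(as.character(labels))
    if (nlevels(labels) != 2) stop("labels must have exactly two classes")
    pos <- labels == levels(labels)[2]
  } else {
    pos <- as.logical(labels)
  }
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both label classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pv <- suppressWarnings(
    stats::wilcox.test(scores[pos], scores[!pos], exact = FALSE)$p.value
  )
  list(auc = if (flip) 1 - auc else auc, p_value = pv,
       n_pos = n1, n_neg = n0, flipped = flip)
}

#' Wilcoxon rank tests for group comparisons
#'
#' Two-sided Wilcoxon rank-sum test for unpaired samples and the matched-pairs
#' signed-rank test for paired samples: the exact distribution for small
#' samples without ties, the tie-corrected normal approximation otherwise.
#' Paired data whose differences are all zero return p = 1 with a warning.
#'
#' @param x,y Numeric sample values (equal lengths when `paired`).
#' @param paired Use the matched-pairs signed-rank test, default `FALSE`.
#' @return List with `statistic`, `p_value`, `method`.
#' @export
rank_tests <- function(x, y, paired = FALSE) {
  if (paired && length(x) != length(y))
    stop("paired samples must have equal lengths")
  if (paired && all(x == y)) {
    warning("all paired differences are zero; p = 1 by convention")
    return(list(statistic = 0, p_value = 1,
                method = "Wilcoxon matched-pairs (degenerate)"))
  }
  ht <- suppressWarnings(stats::wilcox.test(x, y, paired = paired))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = ht$method)
}

#' Spearman correlation of signature scores with PFS
#'
#' Spearman's rho on midranks with the t-approximation p-value. Censoring is
#' ignored: observed times enter as-is.
#'
#' @param scores Numeric per-sample scores.
#' @param pfs Progression-free survival times (months).
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_pfs <- function(scores, pfs) {
  if (length(scores) != length(pfs)) stop("scores and pfs lengths differ")
  if (length(scores) < 4) stop("need at least 4 observations")
  if (stats::sd(scores) == 0 || stats::sd(pfs) == 0)
    stop("constant input: correlation undefined")
  ht <- suppressWarnings(
    stats::cor.test(scores, pfs, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ht$estimate), p_value = ht$p.value, n = length(scores))
}

#' Kaplan-Meier comparison with log-rank test and hazard ratio
#'
#' Product-limit survival curves per group, the log-rank chi-square test, and
#' the hazard ratio (second group level versus first) with its 95% CI from
#' the single-covariate Cox proportional-hazards partial likelihood (Efron
#' tie handling).
#'
#' @param time Event/censoring times.
#' @param event Event indicator (1 = progression/death observed, 0 =
#'   censored).
#' @param group Two-level grouping (factor or coercible).
#' @return List with `hr`, `hr_ci_low`, `hr_ci_high`, `logrank_chisq`,
#'   `logrank_p`, `median` (named per-group KM medians), and `fit` (the
#'   `survfit` object for plotting).
#' @export
km_logrank_hr <- function(time, event, group) {
  group <- if (is.factor(group)) droplevels(group) else as.factor(group)
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  if (sum(event) == 0) stop("no events in either group")
  df <- data.frame(time = time, event = event, g = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ g, data = df)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
  chisq <- sd_$chisq
  p_lr <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  med <- summary(fit)$table[, "median"]
  ev_per_group <- tapply(event, group, sum)
  if (any(ev_per_group == 0)) {
    warning("a group has no events; hazard ratio not estimable")
    hr <- hr_lo <- hr_hi <- NA_real_
  } else {
    cx <- survival::coxph(survival::Surv(time, event) ~ g, data = df,
                          ties = "efron")
    hr <- unname(exp(stats::coef(cx)))
    ci <- exp(stats::confint(cx, level = 0.95))
    hr_lo <- ci[1]; hr_hi <- ci[2]
  }
  list(hr = hr, hr_ci_low = hr_lo, hr_ci_high = hr_hi,
       logrank_chisq = unname(chisq), logrank_p = p_lr,
       median = med, fit = fit)
}
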