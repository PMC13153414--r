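#' Conditional type-I error after stage 1
#'
#' The type-I error probability left to spend after observing `s1` responses
#' in stage 1: `A(s1) = Pr(X2 >= r + 1 - s1; n - n1, p0)` for continuing
#' outcomes (`s1 > r1`), 0 when the trial stops for futility (`s1 <= r1`),
#' and 1 when stage 1 alone already reaches the positivity boundary
#' (`s1 >= r + 1`). Re-planning the second stage so that its conditional
#' rejection probability under `p0` never exceeds `A(s1)` preserves the
#' unconditional type-I error of the original design.
#'
#' @param design A [two_stage_design()].
#' @param s1 Observed stage-1 responses, integer in `[0, n1]` (vectorised).
#' @return Conditional error probability, same length as `s1`.
#' @examples
#' d <- two_stage_design(1, 12, 5, 35, p0 = 0.1, p1 = 0.3)
#' conditional_error(d, 4)  # Pr(X2 >= 2; Binomial(23, 0.1))
#' @export
conditional_error <- function(design, s1) {
  stopifnot(inherits(design, "two_stage_design"))
  if (any(s1 != round(s1)) || any(s1 < 0) || any(s1 > design$n1))
    stop("s1 must be an integer in [0, n1]")
  vapply(as.integer(s1), function(s) {
    if (s <= design$r1) return(0)
    if (s >= design$r + 1L) return(1)
    stats::pbinom(design$r - s, design$n - design$n1, design$p0,
                  lower.tail = FALSE)
  }, numeric(1))
}

#' Recalibrated positivity boundary under an attained second-stage size
#'
#' When the second stage enrols `n2_attained` patients instead of the planned
#' `n - n1`, the final decision boundary is recomputed so that the conditional
#' rejection probability under `p0`, given the observed stage-1 count, does
#' not exceed the conditional error of the original design. Returns the
#' smallest total number of responses `m` with
#' `Pr(X2 >= m - s1; n2_attained, p0) <= A(s1)`.
#'
#' @param design A [two_stage_design()].
#' @param s1 Observed stage-1 responses; the trial must have continued
#'   (`s1 > r1`).
#' @param n2_attained Attained second-stage sample size, integer >= 0.
#' @return The recalibrated minimum total responses required to reject the
#'   null, or `NA_integer_` (with a warning) when no achievable total can
#'   reject — e.g. `n2_attained = 0` with `s1 <= r`.
#' @examples
#' d <- two_stage_design(3, 17, 10, 37, p0 = 0.2, p1 = 0.4)
#' recalibrate_threshold(d, s1 = 4, n2_attained = 19)  # 36 patients attained
#' @export
recalibrate_threshold <- function(design, s1, n2_attained) {
  stopifnot(inherits(design, "two_stage_design"))
  s1 <- as.integer(s1); n2_attained <- as.integer(n2_attained)
  if (length(s1) != 1L || s1 <= design$r1 || s1 > design$n1)
    stop("s1 must be a single integer with r1 < s1 <= n1 (stage 2 opened)")
  if (length(n2_attained) != 1L || n2_attained < 0)
    stop("n2_attained must be a single non-negative integer")
  a <- conditional_error(design, s1)
  for (m in s1:(s1 + n2_attained)) {
    tail <- if (m - s1 <= 0) 1 else
      stats::pbinom(m - s1 - 1L, n2_attained, design$p0, lower.tail = FALSE)
    if (tail <= a) return(m)
  }
  warning("no achievable total response count can reject the null with ",
          "n2_attained = ", n2_attained, " and s1 = ", s1)
  NA_integer_
}

# Stagewise-ordering tail probability of the observed outcome at response
# probability p, with the second-stage tail evaluated at the attained size.
# Outcomes at least as extreme as (continue, total >= s_total) in the
# stagewise ordering: sum over continuing stage-1 counts m1 of
# b(m1; n1, p) * Pr(X2 >= s_total - m1; n2_attained, p), the tail taken as 1
# when s_total - m1 <= 0.
stagewise_tail <- function(r1, n1, n2_attained, s_total, p) {
  m1 <- (r1 + 1L):n1
  tails <- ifelse(s_total - m1 <= 0, 1,
                  stats::pbinom(s_total - m1 - 1L, n2_attained, p,
                                lower.tail = FALSE))
  sum(stats::dbinom(m1, n1, p) * tails)
}

#' Design-consistent one-sided p-value (stagewise ordering)
#'
#' One-sided p-value for the observed total response count under the
#' stagewise ordering of two-stage outcomes, evaluated at the attained
#' second-stage size (Koyama-Chen style design-consistent inference under
#' under-enrolment: the stage-1 law is unchanged; the planned second-stage
#' size is replaced by the attained one inside the second-stage tail).
#'
#' @param design A [two_stage_design()].
#' @param s1 Observed stage-1 responses; must exceed `r1`.
#' @param s_total Observed total responses, `s1 <= s_total`.
#' @param n_attained Attained total sample size (stage 1 assumed fully
#'   enrolled: `n_attained >= n1`).
#' @param p Response probability under which the tail is computed; defaults
#'   to the design's `p0`.
#' @return The one-sided p-value.
#' @examples
#' d <- two_stage_design(1, 12, 5, 35, p0 = 0.1, p1 = 0.3)
#' stagewise_p_value(d, s1 = 2, s_total = 2, n_attained = 35)
#' @export
stagewise_p_value <- function(design, s1, s_total, n_attained, p = design$p0) {
  stopifnot(inherits(design, "two_stage_design"))
  s1 <- as.integer(s1); s_total <- as.integer(s_total)
  n_attained <- as.integer(n_attained)
  if (s1 <= design$r1) stop("stage 2 did not open (s1 <= r1)")
  if (s_total < s1) stop("s_total must be at least s1")
  if (n_attained < design$n1) stop("n_attained must be at least n1")
  if (s_total > n_attained) stop("s_total cannot exceed n_attained")
  stagewise_tail(design$r1, design$n1, n_attained - design$n1, s_total, p)
}

#' Design-consistent confidence interval for the response probability
#'
#' Each bound inverts the stagewise-ordering tail probability in the true
#' response probability `p` at tail mass `(1 - level) / 2`: the lower bound
#' solves `Pr_p(outcome >= observed) = (1 - level) / 2`, the upper bound
#' solves the same tail equal to `1 - (1 - level) / 2`. The tail is monotone
#' increasing in `p`, so each bound is found by bisection to an absolute
#' tolerance of 1e-6 and clipped to `[0, 1]`.
#'
#' @inheritParams stagewise_p_value
#' @param level Two-sided confidence level in (0, 1), default 0.95.
#' @return A list with `ci_low`, `ci_high`, `point_estimate` (the attained
#'   response fraction `s_total / n_attained`), `mue` (median-unbiased
#'   estimate, tail mass 0.5), and `p_value` (one-sided at the design's p0).
#' @examples
#' d <- two_stage_design(3, 17, 10, 37, p0 = 0.2, p1 = 0.4)
#' design_consistent_ci(d, s1 = 4, s_total = 7, n_attained = 36)
#' @export
design_consistent_ci <- function(design, s1, s_total, n_attained,
                                 level = 0.95) {
  stopifnot(inherits(design, "two_stage_design"))
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  # validates inputs as a side effect
  pv <- stagewise_p_value(design, s1, s_total, n_attained)
  n2a <- as.integer(n_attained) - design$n1
  tail_at <- function(p) stagewise_tail(design$r1, design$n1, n2a,
                                        as.integer(s_total), p)
  invert <- function(target) {
    lo <- 0; hi <- 1
    f_lo <- tail_at(lo) - target; f_hi <- tail_at(hi) - target
    if (f_lo >= 0) return(0)
    if (f_hi <= 0) return(1)
    for (i in 1:60) {            # bisection: tail_at is increasing in p
      mid <- (lo + hi) / 2
      if (tail_at(mid) - target <= 0) lo <- mid else hi <- mid
      if (hi - lo < 1e-9) break
    }
    if (hi - lo > 1e-6)
      stop("confidence bound inversion failed to converge: bracket [",
           lo, ", ", hi, "] at target ", target)
    (lo + hi) / 2
  }
  a <- (1 - level) / 2
  list(
    ci_low = invert(a),
    ci_high = invert(1 - a),
    point_estimate = s_total / n_attained,
    mue = invert(0.5),
    p_value = pv,
    level = level
  )
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials, `n >= 1`.
#' @param level Two-sided confidence level, default 0.95.
#' @return A list with `ci_low`, `ci_high`, and `estimate = k / n`. The lower
#'   bound is exactly 0 when `k = 0` and the upper bound exactly 1 when
#'   `k = n`.
#' @examples
#' clopper_pearson(24, 36)
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  if (length(k) != 1L || length(n) != 1L || k != round(k) || n != round(n) ||
      n < 1 || k < 0 || k > n)
    stop("require integers 0 <= k <= n with n >= 1")
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  a <- (1 - level) / 2
  list(
    ci_low = if (k == 0) 0 else stats::qbeta(a, k, n - k + 1),
    ci_high = if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k),
    estimate = k / n,
    level = level
  )
}

#' Tumor mutational burden
#'
#' Non-synonymous somatic mutation count divided by the effective capture
#' size of the exome panel, in mutations per megabase.
#'
#' @param n_nonsyn Count of filtered non-synonymous somatic mutations.
#' @param capture_mb Effective capture size in megabases, > 0.
#' @return Mutations per megabase.
#' @export
tmb <- function(n_nonsyn, capture_mb) {
  if (any(capture_mb <= 0)) stop("capture_mb must be positive")
  if (any(n_nonsyn < 0)) stop("mutation counts cannot be negative")
  n_nonsyn / capture_mb
}
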