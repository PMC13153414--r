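#' Construct a Simon two-stage design
#'
#' A single-arm two-stage binomial design in Simon's convention: enrol `n1`
#' patients, stop for futility if the number of responses is at most `r1`;
#' otherwise enrol to a planned total of `n` and declare the regimen positive
#' if total responses reach `r + 1`.
#'
#' @param r1 Stage-1 futility boundary (stop if responses <= `r1`), integer >= 0.
#' @param n1 Stage-1 sample size, integer >= 1.
#' @param r Final boundary (positive if total responses >= `r + 1`), integer.
#' @param n Planned total sample size, integer > `n1`.
#' @param p0 Null (uninteresting) response probability.
#' @param p1 Alternative (target) response probability, `p1 > p0`.
#' @param alpha,beta Optional one-sided type-I and type-II error bounds. When
#'   both are supplied the design is checked against them exactly (error
#'   probabilities computed by binomial convolution) and construction fails if
#'   either constraint is violated.
#' @return An object of class `two_stage_design`: a list with fields
#'   `r1`, `n1`, `r`, `n`, `p0`, `p1`, and (when given) `alpha`, `beta`.
#' @examples
#' d <- two_stage_design(r1 = 3, n1 = 17, r = 10, n = 37, p0 = 0.2, p1 = 0.4)
#' reject_prob(d, 0.2)
#' @export
two_stage_design <- function(r1, n1, r, n, p0, p1, alpha = NULL, beta = NULL) {
  for (v in list(r1 = r1, n1 = n1, r = r, n = n)) {
    if (length(v) != 1L || !is.finite(v) || v != round(v))
      stop("design boundaries and sample sizes must be single integers")
  }
  r1 <- as.integer(r1); n1 <- as.integer(n1); r <- as.integer(r); n <- as.integer(n)
  if (!(0L <= r1 && r1 < n1 && n1 < n))
    stop("require 0 <= r1 < n1 < n; got r1=", r1, ", n1=", n1, ", n=", n)
  if (!(r1 <= r && r < n))
    stop("require r1 <= r < n; got r1=", r1, ", r=", r, ", n=", n)
  if (!is.numeric(p0) || !is.numeric(p1) || p0 < 0 || p0 >= 1 || p1 <= p0 || p1 > 1)
    stop("require 0 <= p0 < p1 <= 1")
  d <- structure(
    list(r1 = r1, n1 = n1, r = r, n = n, p0 = p0, p1 = p1,
         alpha = alpha, beta = beta),
    class = "two_stage_design"
  )
  if (!is.null(alpha) && !is.null(beta)) {
    if (alpha <= 0 || alpha >= 1 || beta <= 0 || beta >= 1)
      stop("require 0 < alpha < 1 and 0 < beta < 1")
    if (reject_prob(d, p0) > alpha)
      stop("design violates the type-I bound: exact size ",
           signif(reject_prob(d, p0), 4), " > alpha = ", alpha)
    if (reject_prob(d, p1) < 1 - beta)
      stop("design violates the power bound: exact power ",
           signif(reject_prob(d, p1), 4), " < 1 - beta = ", 1 - beta)
  }
  d
}

#' @export
print.two_stage_design <- function(x, ...) {
  cat(sprintf("Simon two-stage design: %d/%d (stage 1), %d/%d (total)\n",
              x$r1, x$n1, x$r, x$n))
  cat(sprintf("  continue if stage-1 responses >= %d; positive if total >= %d\n",
              x$r1 + 1L, x$r + 1L))
  cat(sprintf("  hypotheses: p0 = %g, p1 = %g", x$p0, x$p1))
  if (!is.null(x$alpha)) cat(sprintf(" (alpha = %g, beta = %g)", x$alpha, x$beta))
  cat("\n")
  oc <- operating_characteristics(x, x$p0)
  cat(sprintf("  at p0: size = %.4f, PET = %.4f, EN = %.2f\n",
              oc$reject_prob, oc$pet, oc$en))
  invisible(x)
}

#' Exact rejection probability of a two-stage design
#'
#' Probability of declaring the regimen positive at true response probability
#' `p`, by exact binomial convolution over the continuing stage-1 outcomes:
#' sum over x1 in (r1, n1] of b(x1; n1, p) * Pr(X2 >= r + 1 - x1; n - n1, p).
#'
#' @param design A [two_stage_design()].
#' @param p True response probability (vectorised).
#' @return Rejection probability, same length as `p`.
#' @export
reject_prob <- function(design, p) {
  stopifnot(inherits(design, "two_stage_design"))
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  vapply(p, function(pp) {
    if (design$r1 >= design$n1) return(0)
    x1 <- (design$r1 + 1L):design$n1
    sum(stats::dbinom(x1, design$n1, pp) *
          stats::pbinom(design$r - x1, design$n - design$n1, pp,
                        lower.tail = FALSE))
  }, numeric(1))
}

#' Operating characteristics of a two-stage design
#'
#' @param design A [two_stage_design()].
#' @param p True response probability (vectorised).
#' @return A data.frame with columns `p`, `reject_prob`, `pet` (probability of
#'   early termination, Pr(X1 <= r1)), and `en` (expected sample size,
#'   n1 + (1 - pet) * (n - n1)).
#' @export
operating_characteristics <- function(design, p) {
  stopifnot(inherits(design, "two_stage_design"))
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  pet <- stats::pbinom(design$r1, design$n1, p)
  data.frame(
    p = p,
    reject_prob = reject_prob(design, p),
    pet = pet,
    en = design$n1 + (1 - pet) * (design$n - design$n1)
  )
}

#' Exhaustive search for Simon optimal and minimax two-stage designs
#'
#' Scans all designs (r1, n1, r, n) with n <= `n_max` satisfying the exact
#' error constraints: size at `p0` at most `alpha` and power at `p1` at least
#' `1 - beta`. The optimal design minimises the expected sample size under
#' `p0`; the minimax design minimises `n` first, then EN(p0). Ties are broken
#' by smallest `n`, then smallest `n1`, so the result is deterministic.
#'
#' For each candidate (n1, n, r1) the smallest final boundary `r` meeting the
#' size constraint is located by bisection (the size is non-increasing in
#' `r`), and stage-1 configurations whose early-stopping probability under
#' `p1` already exceeds `beta` are pruned, since no final boundary can then
#' achieve the required power.
#'
#' @param p0,p1 Null and alternative response probabilities, `p0 < p1`.
#' @param alpha One-sided type-I error bound.
#' @param beta Type-II error bound.
#' @param n_max Largest total sample size scanned (default 100).
#' @return A list with elements `optimal` and `minimax`, each a
#'   [two_stage_design()] carrying `alpha` and `beta`.
#' @examples
#' simon_search(0.2, 0.4, 0.1, 0.1, n_max = 45)$optimal
#' @export
simon_search <- function(p0, p1, alpha, beta, n_max = 100) {
  if (!(p0 >= 0 && p0 < p1 && p1 <= 1)) stop("require 0 <= p0 < p1 <= 1")
  if (alpha <= 0 || alpha >= 1 || beta <= 0 || beta >= 1)
    stop("require 0 < alpha < 1 and 0 < beta < 1")
  n_max <- as.integer(n_max)

  best <- NULL  # minimal-EN design rows, one row per feasible design kept
  rows <- vector("list", 2048L); nrows <- 0L
  for (n in 2:n_max) {
    for (n1 in 1:(n - 1L)) {
      n2 <- n - n1
      d0 <- stats::dbinom(0:n1, n1, p0)
      pet1 <- stats::pbinom(0:(n1 - 1L), n1, p1)  # Pr(X1 <= r1; p1)
      for (r1 in 0:(n1 - 1L)) {
        # early termination alone must leave enough power on the table
        if (pet1[r1 + 1L] > beta) break  # pet1 increases with r1
        x1 <- (r1 + 1L):n1
        w0 <- d0[x1 + 1L]
        size_at <- function(r)
          sum(w0 * stats::pbinom(r - x1, n2, p0, lower.tail = FALSE))
        if (size_at(n - 1L) > alpha) next
        lo <- r1; hi <- n - 1L
        if (size_at(lo) <= alpha) {
          rr <- lo
        } else {
          while (hi - lo > 1L) {            # size_at is non-increasing in r
            mid <- (lo + hi) %/% 2L
            if (size_at(mid) <= alpha) hi <- mid else lo <- mid
          }
          rr <- hi
        }
        pw <- sum(stats::dbinom(x1, n1, p1) *
                    stats::pbinom(rr - x1, n2, p1, lower.tail = FALSE))
        if (pw < 1 - beta) next
        pet0 <- stats::pbinom(r1, n1, p0)
        en <- n1 + (1 - pet0) * n2
        nrows <- nrows + 1L
        if (nrows > length(rows)) rows <- c(rows, vector("list", length(rows)))
        rows[[nrows]] <- c(r1, n1, rr, n, en)
      }
    }
  }
  if (nrows == 0L)
    stop("infeasible: no two-stage design with n <= ", n_max,
         " satisfies alpha = ", alpha, ", beta = ", beta)
  feas <- do.call(rbind, rows[seq_len(nrows)])
  colnames(feas) <- c("r1", "n1", "r", "n", "en")
  pick <- function(m) {
    m <- m[order(m[, "en"], m[, "n"], m[, "n1"]), , drop = FALSE]
    two_stage_design(m[1, "r1"], m[1, "n1"], m[1, "r"], m[1, "n"],
                     p0 = p0, p1 = p1, alpha = alpha, beta = beta)
  }
  list(
    optimal = pick(feas),
    minimax = pick(feas[feas[, "n"] == min(feas[, "n"]), , drop = FALSE])
  )
}
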