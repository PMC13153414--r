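#' Simulate two-stage trial outcomes
#'
#' Replicated trials under a true response probability: stage-1 responses are
#' Binomial(n1, p_true); the trial continues when they exceed `r1`; stage-2
#' responses are Binomial(n_attained - n1, p_true); the null is rejected when
#' the total reaches the decision boundary — the original `r + 1` when the
#' planned total was attained, otherwise the conditional-error recalibrated
#' threshold for the observed stage-1 count.
#'
#' @param design A [two_stage_design()].
#' @param p_true True response probability.
#' @param n_attained Attained total sample size (default: the planned `n`).
#' @param reps Number of replicate trials.
#' @param seed Integer seed.
#' @return Data.frame with one row per replicate: `s1`, `s_total`,
#'   `continued`, `reject`.
#' @export
simulate_trial <- function(design, p_true, n_attained = design$n, reps,
                           seed) {
  stopifnot(inherits(design, "two_stage_design"))
  if (p_true < 0 || p_true > 1) stop("p_true must lie in [0, 1]")
  if (reps < 1) stop("reps must be at least 1")
  n_attained <- as.integer(n_attained)
  if (n_attained < design$n1) stop("n_attained must be at least n1")
  n2a <- n_attained - design$n1

  # decision boundary on the total, per continuing stage-1 count
  cont_s1 <- (design$r1 + 1L):design$n1
  thresh <- if (n_attained == design$n) {
    stats::setNames(rep(design$r + 1L, length(cont_s1)), cont_s1)
  } else {
    stats::setNames(
      vapply(cont_s1, function(s)
        suppressWarnings(recalibrate_threshold(design, s, n2a)),
        integer(1)),
      cont_s1)
  }

  with_local_seed(seed, {
    s1 <- stats::rbinom(reps, design$n1, p_true)
    continued <- s1 > design$r1
    s2 <- integer(reps)
    s2[continued] <- stats::rbinom(sum(continued), n2a, p_true)
    s_total <- s1 + s2
    m <- rep(NA_integer_, reps)
    m[continued] <- thresh[as.character(s1[continued])]
    reject <- continued & !is.na(m) & s_total >= m
    data.frame(s1 = s1, s_total = s_total, continued = continued,
               reject = reject)
  })
}

#' Configuration for a synthetic expression cohort
#'
#' Defaults encode a down-scaled recurrent ovarian-cancer arm: 15 clinical
#' benefit (CB) and 15 no-clinical-benefit (NCB) tumors, 2000 genes, one
#' planted 20-gene resistance program up-regulated 1 log2 unit in NCB,
#' negative-binomial counts with bulk-RNAseq-like dispersions, and
#' exponential progression-free survival whose log-hazard rises with the true
#' program activity (theta = 0.8 per SD of true score, baseline hazard 0.2
#' events/month, censoring at 24 months).
#'
#' @param n_cb,n_ncb Samples per clinical-benefit group.
#' @param n_genes Total genes.
#' @param planted_sets Named list; each element a list with `genes` (integer
#'   indices into 1..n_genes), `lfc` (log2 fold-change), and `up_in` ("CB" or
#'   "NCB").
#' @param nb_dispersion Range of per-gene NB dispersion alpha (variance =
#'   mu + alpha mu^2).
#' @param baseline_logmean_range Range of per-gene baseline log mean counts
#'   (natural log).
#' @param hazard_theta Log-hazard increase per SD of true signature score.
#' @param lambda0 Baseline hazard, events per month.
#' @param censor_time Administrative censoring time, months.
#' @param prob_platinum_resistant Probability a sample is platinum-resistant.
#' @param arm Arm label stored in the clinical table.
#' @param seed Integer seed (required).
#' @return A `synthetic_cohort_config` list.
#' @export
cohort_config <- function(n_cb = 15, n_ncb = 15, n_genes = 2000,
                          planted_sets = list(
                            ncb_program = list(genes = 1:20, lfc = 1.0,
                                               up_in = "NCB")),
                          nb_dispersion = c(0.05, 0.4),
                          baseline_logmean_range = log(c(5, 500)),
                          hazard_theta = 0.8, lambda0 = 0.2,
                          censor_time = 24,
                          prob_platinum_resistant = 0.7,
                          arm = "A", seed) {
  if (missing(seed)) stop("seed is required")
  cfg <- list(n_cb = n_cb, n_ncb = n_ncb, n_genes = n_genes,
              planted_sets = planted_sets, nb_dispersion = nb_dispersion,
              baseline_logmean_range = baseline_logmean_range,
              hazard_theta = hazard_theta, lambda0 = lambda0,
              censor_time = censor_time,
              prob_platinum_resistant = prob_platinum_resistant,
              arm = arm, seed = as.integer(seed))
  if (n_cb < 1 || n_ncb < 1 || n_genes < 2) stop("counts must be positive")
  if (censor_time <= 0) stop("censor_time must be positive")
  if (any(nb_dispersion <= 0)) stop("dispersions must be positive")
  for (nm in names(planted_sets)) {
    ps <- planted_sets[[nm]]
    if (max(ps$genes) > n_genes)
      stop("planted set '", nm, "' indexes genes beyond n_genes")
    if (!ps$up_in %in% c("CB", "NCB"))
      stop("planted set '", nm, "' must be up in CB or NCB")
  }
  structure(cfg, class = "synthetic_cohort_config")
}

#' Simulate an expression cohort with planted signature structure
#'
#' Gene-by-sample negative-binomial counts for two clinical-benefit groups
#' with planted up-regulated gene programs, plus clinical records whose
#' progression-free survival depends on the true planted-program activity:
#' per-gene baseline log-means and dispersions are drawn uniformly from the
#' configured ranges; planted genes have their mean multiplied by
#' `2^lfc` in the designated group; mild library-size variation is applied
#' per sample. Each sample's true score is the mean log2 shift over planted
#' genes; PFS is exponential with rate `lambda0 * exp(theta * z)` where `z`
#' is the standardised true score, right-censored at `censor_time`. Response
#' categories (PR/SD/PD) are drawn consistently with the group label and the
#' simulated PFS, so that [label_benefit()] reproduces the planted groups.
#'
#' @param cfg A [cohort_config()].
#' @return List with `counts` (integer matrix, genes x samples), `clinical`
#'   (data.frame: sample, arm, benefit, response, pfs_months, event,
#'   platinum_status), and `truth` (planted genes per set, per-sample true
#'   scores, and the generator parameters).
#' @export
simulate_expression_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_cohort_config"))
  n <- cfg$n_cb + cfg$n_ncb
  group <- factor(rep(c("CB", "NCB"), c(cfg$n_cb, cfg$n_ncb)),
                  levels = c("CB", "NCB"))
  samples <- sprintf("%s_S%02d", cfg$arm, seq_len(n))
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))

  base_log <- with_local_seed(sub_seed(cfg$seed, "genes"), {
    list(mu = stats::runif(cfg$n_genes, cfg$baseline_logmean_range[1],
                           cfg$baseline_logmean_range[2]),
         disp = stats::runif(cfg$n_genes, cfg$nb_dispersion[1],
                             cfg$nb_dispersion[2]))
  })

  # per-sample log2 shift matrix from the planted programs
  shift <- matrix(0, cfg$n_genes, n)
  for (ps in cfg$planted_sets)
    shift[ps$genes, group == ps$up_in] <-
      shift[ps$genes, group == ps$up_in] + ps$lfc

  cnt <- with_local_seed(sub_seed(cfg$seed, "counts"), {
    size_factor <- stats::runif(n, 0.7, 1.3)
    mu <- exp(base_log$mu) * 2^shift
    mu <- sweep(mu, 2, size_factor, "*")
    list(size_factor = size_factor,
         counts = matrix(stats::rnbinom(cfg$n_genes * n, mu = mu,
                                        size = rep(1 / base_log$disp, n)),
                         cfg$n_genes, n))
  })
  counts <- cnt$counts
  dimnames(counts) <- list(genes, samples)

  # true program activity: mean planted log2 shift per sample
  planted_idx <- sort(unique(unlist(lapply(cfg$planted_sets, `[[`, "genes"))))
  true_score <- colMeans(shift[planted_idx, , drop = FALSE])
  z <- if (stats::sd(true_score) > 0)
    (true_score - mean(true_score)) / stats::sd(true_score)
  else rep(0, n)

  clin <- with_local_seed(sub_seed(cfg$seed, "clinical"), {
    rate <- cfg$lambda0 * exp(cfg$hazard_theta * z)
    t_raw <- stats::rexp(n, rate)
    event <- as.integer(t_raw <= cfg$censor_time)
    pfs <- pmin(t_raw, cfg$censor_time)
    # response drawn consistently with the planted benefit group and PFS
    response <- character(n)
    u <- stats::runif(n)
    is_cb <- group == "CB"
    response[is_cb & pfs >= 4] <- ifelse(u[is_cb & pfs >= 4] < 0.4, "PR", "SD")
    response[is_cb & pfs < 4] <- "PR"
    response[!is_cb & pfs < 4] <- ifelse(u[!is_cb & pfs < 4] < 0.5, "PD", "SD")
    response[!is_cb & pfs >= 4] <- "PD"
    platinum <- ifelse(stats::runif(n) < cfg$prob_platinum_resistant,
                       "resistant", "sensitive")
    data.frame(sample = samples, arm = cfg$arm, benefit = group,
               response = response, pfs_months = pfs, event = event,
               platinum_status = platinum, stringsAsFactors = FALSE)
  })

  list(
    counts = counts,
    clinical = clin,
    truth = list(
      planted_genes = lapply(cfg$planted_sets,
                             function(ps) genes[ps$genes]),
      true_score = stats::setNames(true_score, samples),
      size_factor = stats::setNames(cnt$size_factor, samples),
      gene_params = data.frame(gene = genes,
                               base_log_mean = base_log$mu,
                               dispersion = base_log$disp,
                               stringsAsFactors = FALSE),
      config = cfg
    )
  )
}
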