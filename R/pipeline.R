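#' Read a genes-by-samples count matrix from TSV
#'
#' Tab-delimited, first column gene identifiers, header row of sample names.
#'
#' @param path File path.
#' @return Integer/numeric matrix with gene rownames and sample colnames.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count table needs a gene column plus samples")
  if (anyDuplicated(df[[1]])) stop("duplicate gene identifiers")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (anyDuplicated(colnames(m))) stop("duplicate sample identifiers")
  storage.mode(m) <- "numeric"
  m
}

#' @rdname read_counts_tsv
#' @param counts Matrix with dimnames.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table from CSV
#'
#' Requires columns `sample`, `benefit` (CB/NCB), `pfs_months`, `event`;
#' `arm`, `response`, `platinum_status` are carried through when present.
#'
#' @param path File path.
#' @return Data.frame, one row per sample.
#' @export
read_clinical_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample", "benefit", "pfs_months", "event")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("clinical table missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample)) stop("duplicate sample identifiers")
  bad <- setdiff(unique(df$benefit), c("CB", "NCB"))
  if (length(bad) > 0)
    stop("benefit must be CB or NCB; found: ", paste(bad, collapse = ", "))
  df$benefit <- factor(df$benefit, levels = c("CB", "NCB"))
  df
}

#' Design report for one or more trial arms
#'
#' For each arm: the optimal and minimax two-stage designs by exhaustive
#' search, operating characteristics on a grid of response probabilities,
#' and — when observed counts are supplied — the conditional-error
#' recalibrated positivity threshold and design-consistent inference at the
#' attained sample size.
#'
#' @param arms Named list; each element a list with `p0`, `p1`, `alpha`,
#'   `beta`, optional `n_max` (default 100), and optionally observed results:
#'   `s1`, `s_total`, `n_attained`.
#' @param p_grid Response probabilities for the operating-characteristic
#'   table (default `seq(0, 1, 0.05)`).
#' @param level Confidence level for the inference block (default 0.95).
#' @param out Optional path; when given the report is also written as JSON.
#' @return Nested list, one element per arm. Deterministic: identical inputs
#'   give identical reports.
#' @export
run_design_report <- function(arms, p_grid = seq(0, 1, by = 0.05),
                              level = 0.95, out = NULL) {
  if (is.null(names(arms))) stop("arms must be a named list")
  report <- lapply(names(arms), function(nm) {
    a <- arms[[nm]]
    for (f in c("p0", "p1", "alpha", "beta"))
      if (is.null(a[[f]])) stop("arm '", nm, "': missing ", f)
    found <- simon_search(a$p0, a$p1, a$alpha, a$beta,
                          n_max = if (is.null(a$n_max)) 100 else a$n_max)
    d <- found$optimal
    block <- list(
      hypotheses = a[c("p0", "p1", "alpha", "beta")],
      optimal = d[c("r1", "n1", "r", "n")],
      minimax = found$minimax[c("r1", "n1", "r", "n")],
      positivity_threshold = d$r + 1L,
      oc = operating_characteristics(d, p_grid)
    )
    if (!is.null(a$s1)) {
      n2a <- a$n_attained - d$n1
      block$observed <- a[c("s1", "s_total", "n_attained")]
      block$conditional_error <- conditional_error(d, a$s1)
      block$recalibrated_threshold <- recalibrate_threshold(d, a$s1, n2a)
      inf <- design_consistent_ci(d, a$s1, a$s_total, a$n_attained, level)
      block$inference <- inf[c("point_estimate", "ci_low", "ci_high",
                               "mue", "p_value", "level")]
    }
    block
  })
  names(report) <- names(arms)
  if (!is.null(out))
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "columns")
  report
}

#' End-to-end translational pipeline on one or more arms
#'
#' Chains the transcriptomic stages per arm: logCPM normalisation,
#' moderated-t ranking of the no-benefit group against the benefit group,
#' preranked gene-set enrichment, cross-arm leading-edge intersection over
#' the named resistance pathways, single-sample scoring of the derived
#' signature, and association of scores with benefit labels and survival
#' (rank-sum test, AUC with the resistance-orientation flip, Spearman with
#' PFS, and Kaplan-Meier / log-rank / hazard ratio at the median score
#' split).
#'
#' @param counts_by_arm Named list of count matrices (genes x samples).
#' @param clinical_by_arm Named list of clinical data.frames (see
#'   [read_clinical_csv()] for the schema).
#' @param gene_sets Named list of gene-set character vectors.
#' @param signature_pathways Character vector of set names whose leading
#'   edges are pooled and intersected across arms.
#' @param n_perm,weight,min_size,max_size,seed Enrichment parameters, passed
#'   to [preranked_gsea()].
#' @param platinum_resistant_only Restrict the association block to
#'   platinum-resistant samples (default `FALSE`).
#' @param out_dir Optional directory; when given, per-arm rankings and
#'   enrichment tables (TSV), the signature gene list, score tables (TSV) and
#'   association results (JSON) are written there.
#' @return List with `per_arm` (ranking, enrichment, scores, associations per
#'   arm) and `signature` (the derived gene vector).
#' @export
run_translational_pipeline <- function(counts_by_arm, clinical_by_arm,
                                       gene_sets, signature_pathways,
                                       n_perm = 1000, weight = 1,
                                       min_size = 5, max_size = 2000,
                                       seed,
                                       platinum_resistant_only = FALSE,
                                       out_dir = NULL) {
  if (missing(seed)) stop("seed is required")
  arms <- names(counts_by_arm)
  if (is.null(arms) || !identical(sort(arms), sort(names(clinical_by_arm))))
    stop("counts_by_arm and clinical_by_arm must share arm names")

  per_arm <- list()
  for (arm in arms) {
    counts <- counts_by_arm[[arm]]
    clin <- clinical_by_arm[[arm]]
    required <- c("sample", "benefit", "pfs_months", "event")
    missing_cols <- setdiff(required, names(clin))
    if (length(missing_cols) > 0)
      stop("arm '", arm, "': clinical table missing column(s): ",
           paste(missing_cols, collapse = ", "))
    if (!all(clin$sample %in% colnames(counts)))
      stop("arm '", arm, "': clinical samples absent from the count matrix")
    counts <- counts[, clin$sample, drop = FALSE]

    logcpm <- normalize_logcpm(counts)
    # levels (CB, NCB): statistic positive for genes up in NCB
    ranking <- moderated_t_rank(logcpm, factor(clin$benefit,
                                               levels = c("CB", "NCB")))
    enr <- preranked_gsea(ranking, gene_sets, weight = weight,
                          n_perm = n_perm,
                          seed = sub_seed(seed, paste0("gsea_", arm)),
                          min_size = min_size, max_size = max_size)
    per_arm[[arm]] <- list(logcpm = logcpm, clinical = clin,
                           ranking = ranking, enrichment = enr)
  }

  signature <- intersect_leading_edges(
    lapply(per_arm, `[[`, "enrichment"), signature_pathways)

  for (arm in arms) {
    pa <- per_arm[[arm]]
    clin <- pa$clinical
    scores <- singscore_up(pa$logcpm, signature)
    score_tab <- data.frame(sample = clin$sample, signature = "ncb_core",
                            score = unname(scores[clin$sample]),
                            clin[, setdiff(names(clin), "sample"),
                                 drop = FALSE],
                            stringsAsFactors = FALSE)
    assoc_clin <- clin
    assoc_scores <- scores[clin$sample]
    if (platinum_resistant_only) {
      if (!"platinum_status" %in% names(clin))
        stop("arm '", arm, "': platinum_status column required for the ",
             "platinum-resistant subset")
      keep <- clin$platinum_status == "resistant"
      assoc_clin <- clin[keep, , drop = FALSE]
      assoc_scores <- assoc_scores[keep]
    }
    ncb <- assoc_clin$benefit == "NCB"
    assoc <- list(
      wilcoxon_ncb_vs_cb = rank_tests(assoc_scores[ncb], assoc_scores[!ncb]),
      # high score predicts NCB: flip so the reported AUC measures NCB recall
      auc_ncb = auc_benefit(assoc_scores, assoc_clin$benefit, flip = FALSE),
      spearman_pfs = spearman_pfs(assoc_scores, assoc_clin$pfs_months),
      km = {
        hi <- assoc_scores > stats::median(assoc_scores)
        km_logrank_hr(assoc_clin$pfs_months, assoc_clin$event,
                      factor(ifelse(hi, "high", "low"),
                             levels = c("low", "high")))
      }
    )
    per_arm[[arm]]$scores <- score_tab
    per_arm[[arm]]$associations <- assoc
  }

  result <- list(per_arm = per_arm, signature = signature,
                 signature_pathways = signature_pathways, seed = seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(signature, file.path(out_dir, "signature_genes.txt"))
    for (arm in arms) {
      pa <- per_arm[[arm]]
      utils::write.table(pa$ranking,
                         file.path(out_dir, paste0("ranking_", arm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      enr_flat <- pa$enrichment
      enr_flat$leading_edge <- vapply(enr_flat$leading_edge,
                                      paste, "", collapse = ",")
      utils::write.table(enr_flat,
                         file.path(out_dir, paste0("enrichment_", arm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(pa$scores,
                         file.path(out_dir, paste0("scores_", arm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      assoc <- pa$associations
      assoc$km$fit <- NULL
      assoc$km$median <- as.list(assoc$km$median)
      jsonlite::write_json(assoc,
                           file.path(out_dir,
                                     paste0("associations_", arm, ".json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  result
}
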