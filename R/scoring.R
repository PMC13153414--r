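#' Rank-based single-sample signature score (up-set)
#'
#' For each sample, expression values are ranked within the sample (ascending,
#' average ties), the mean rank of the signature genes is divided by the
#' number of measured genes `N`, and the result is min-max normalised by its
#' theoretical bounds `(n_up + 1) / (2N)` and `(2N - n_up + 1) / (2N)`, then
#' centred by subtracting 0.5. Scores therefore lie in `[-0.5, 0.5]`, attain
#' the bounds exactly when the signature occupies the bottom or top `n_up`
#' ranks, and are invariant to any strictly monotone transform of a sample's
#' expression values.
#'
#' @param expr Numeric matrix (genes x samples) with rownames; any
#'   within-sample monotone scale (counts, logCPM, vst) gives identical
#'   scores.
#' @param set Character vector of signature genes; at least 2 must be
#'   measured.
#' @return Named numeric vector of per-sample scores.
#' @export
singscore_up <- function(expr, set) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop("expr must have gene rownames")
  present <- intersect(set, rownames(expr))
  if (length(present) < 2) {
    missing <- setdiff(set, rownames(expr))
    stop("fewer than 2 signature genes measured; missing: ",
         paste(missing, collapse = ", "))
  }
  n <- nrow(expr)
  n_up <- length(present)
  lo <- (n_up + 1) / (2 * n)
  hi <- (2 * n - n_up + 1) / (2 * n)
  apply(expr, 2, function(x) {
    raw <- mean(rank(x, ties.method = "average")[present]) / n
    (raw - lo) / (hi - lo) - 0.5
  })
}

#' Mean z-score signature score
#'
#' Each signature gene's (variance-stabilised) expression is z-scored across
#' samples using the sample (n - 1) standard deviation; the per-sample score
#' is the mean z over signature genes. Genes with zero variance are excluded
#' with a warning.
#'
#' @param expr Numeric matrix (genes x samples) of variance-stabilised
#'   expression, with rownames.
#' @param set Character vector of signature genes.
#' @return Named numeric vector of per-sample scores (mean 0 across samples).
#' @export
zscore_mean_score <- function(expr, set) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 2) stop("need at least 2 samples to z-score")
  if (is.null(rownames(expr))) stop("expr must have gene rownames")
  present <- intersect(set, rownames(expr))
  if (length(present) == 0) stop("no signature genes measured")
  sub <- expr[present, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  if (all(sds == 0)) stop("all signature genes have zero variance")
  if (any(sds == 0)) {
    warning("excluding zero-variance gene(s): ",
            paste(present[sds == 0], collapse = ", "))
    sub <- sub[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  z <- (sub - rowMeans(sub)) / sds
  colMeans(z)
}

#' Derive clinical-benefit and exceptional-responder labels
#'
#' Clinical benefit (CB) is a response of CR/PR, or SD maintained for at
#' least `cb_months`; anything else (PD, or SD shorter than `cb_months`) is
#' no clinical benefit (NCB). Exceptional responders are patients with PFS of
#' at least `exceptional_months`, regardless of response category.
#'
#' @param response Character vector with values in CR, PR, SD, PD.
#' @param pfs_months Non-negative progression-free survival in months.
#' @param cb_months CB durability threshold for SD (default 4, inclusive).
#' @param exceptional_months Exceptional-responder threshold (default 12,
#'   inclusive).
#' @return Data.frame with columns `response`, `pfs_months`, `benefit`
#'   (factor CB/NCB) and `exceptional` (logical).
#' @examples
#' label_benefit(c("PR", "SD", "SD", "PD"), c(2, 4, 3.9, 20))
#' @export
label_benefit <- function(response, pfs_months, cb_months = 4,
                          exceptional_months = 12) {
  response <- as.character(response)
  bad <- setdiff(unique(response), c("CR", "PR", "SD", "PD"))
  if (length(bad) > 0)
    stop("unknown response code(s): ", paste(bad, collapse = ", "))
  if (length(pfs_months) != length(response))
    stop("response and pfs_months lengths differ")
  if (any(pfs_months < 0)) stop("pfs_months cannot be negative")
  cb <- response %in% c("CR", "PR") |
    (response == "SD" & pfs_months >= cb_months)
  data.frame(
    response = response,
    pfs_months = pfs_months,
    benefit = factor(ifelse(cb, "CB", "NCB"), levels = c("CB", "NCB")),
    exceptional = pfs_months >= exceptional_months,
    stringsAsFactors = FALSE
  )
}
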