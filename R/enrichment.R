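#' Log counts-per-million normalisation
#'
#' `log2((count + prior) / (library_size + 2 * prior) * 1e6)` with the library
#' size taken as the column sum of raw counts.
#'
#' @param counts Numeric matrix of non-negative counts, genes x samples, with
#'   row and column names.
#' @param prior Pseudocount added to every count (default 1).
#' @return Matrix of logCPM values with the same dimnames.
#' @export
normalize_logcpm <- function(counts, prior = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    bad <- colnames(counts)[lib == 0]
    stop("all-zero library for sample(s): ",
         paste(if (is.null(bad)) which(lib == 0) else bad, collapse = ", "))
  }
  log2(sweep(counts + prior, 2, lib + 2 * prior, "/") * 1e6)
}

# Newton solve of trigamma(x) = y, y > 0 (decreasing, convex).
trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (!is.finite(yy)) return(if (yy > 0) 0 else Inf)
    if (yy <= 0) return(Inf)
    if (yy > 1e7) return(1 / sqrt(yy))
    if (yy < 1e-6) return(1 / yy)
    x <- 0.5 + 1 / yy
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (abs(dif / x) < 1e-10) break
    }
    x
  }, numeric(1))
}

#' Moderated-t gene ranking between two groups
#'
#' Per-gene two-sample comparison with empirical-Bayes variance shrinkage:
#' the pooled within-group variance `s_g^2` (d_g = n - 2 df) is shrunk toward
#' a common prior variance `s0^2` with prior df `d0`,
#' `s~_g^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)`, and the moderated t
#' statistic `(mean_B - mean_A) / (s~_g sqrt(1/nA + 1/nB))` is referred to a
#' t distribution on `d0 + d_g` df (two-sided). The hyperparameters (d0, s0)
#' are estimated by matching moments of the log gene-wise variances to a
#' scaled-F prior. Benjamini-Hochberg adjustment across genes.
#'
#' @param expr Numeric matrix (genes x samples) of normalised log-expression
#'   (e.g. [normalize_logcpm()] output), with rownames.
#' @param groups Two-level factor (or vector coercible to one) giving the
#'   group of each column. The statistic is positive for genes higher in the
#'   second factor level.
#' @param d0 Optional prior df override. `d0 = 0` disables shrinkage and
#'   reproduces the ordinary pooled-variance two-sample t; `d0 = Inf` forces
#'   every gene's variance to the prior `s0^2`. Default `NULL` estimates d0
#'   from the data.
#' @return A data.frame (one row per gene) with columns `gene`, `statistic`,
#'   `p_raw`, `p_adj`, sorted by decreasing statistic; ties are broken by
#'   gene identifier so the ranking is deterministic. The estimated `d0` and
#'   `s0_sq` are attached as attributes.
#' @export
moderated_t_rank <- function(expr, groups, d0 = NULL) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 2) stop("need at least 2 genes")
  if (is.null(rownames(expr))) stop("expr must have gene rownames")
  groups <- if (is.factor(groups)) droplevels(groups) else as.factor(groups)
  if (nlevels(groups) != 2)
    stop("groups must have exactly 2 levels, got ",
         paste(levels(groups), collapse = "/"))
  if (length(groups) != ncol(expr))
    stop("groups length must equal the number of samples")
  if (min(table(groups)) < 2) stop("need >= 2 samples per group")

  a <- groups == levels(groups)[1]
  na <- sum(a); nb <- sum(!a)
  ma <- rowMeans(expr[, a, drop = FALSE])
  mb <- rowMeans(expr[, !a, drop = FALSE])
  ssa <- rowSums((expr[, a, drop = FALSE] - ma)^2)
  ssb <- rowSums((expr[, !a, drop = FALSE] - mb)^2)
  dg <- na + nb - 2
  s2 <- (ssa + ssb) / dg

  pos <- s2 > 0
  if (is.null(d0)) {
    if (sum(pos) < 2) {
      d0 <- Inf
      s0_sq <- if (any(pos)) mean(s2[pos]) else 0
    } else {
      # moments of log variances against the scaled-F prior
      e <- log(s2[pos]) - digamma(dg / 2) + log(dg / 2)
      ev <- stats::var(e)
      excess <- ev - trigamma(dg / 2)
      if (excess > 0) {
        d0 <- 2 * trigamma_inverse(excess)
        s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
      } else {
        d0 <- Inf
        s0_sq <- exp(mean(e))
      }
    }
  } else {
    if (d0 < 0) stop("d0 must be non-negative")
    s0_sq <- if (any(pos)) exp(mean(log(s2[pos]))) else 0
  }

  s2_mod <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + dg * s2) / (d0 + dg)
  se <- sqrt(s2_mod * (1 / na + 1 / nb))
  diff <- mb - ma
  tstat <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, sign(diff) * Inf))
  df_tot <- d0 + dg
  p <- if (is.infinite(df_tot)) 2 * stats::pnorm(-abs(tstat)) else
    2 * stats::pt(-abs(tstat), df = df_tot)
  p[se == 0 & diff == 0] <- 1

  out <- data.frame(
    gene = rownames(expr),
    statistic = tstat,
    p_raw = p,
    p_adj = stats::p.adjust(p, method = "BH"),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$statistic, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  attr(out, "contrast") <- paste(levels(groups)[2], "vs", levels(groups)[1])
  out
}

#' Read and write GMT gene-set files
#'
#' Tab-delimited, one set per line: name, description, then member genes.
#'
#' @param path File path.
#' @return `read_gmt`: a named list of character vectors (unique members),
#'   with set descriptions in the `"description"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in GMT")
  attr(sets, "description") <- stats::setNames(
    vapply(fields, `[[`, "", 2L), names(sets))
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets))) stop("sets must be named")
  if (is.null(descriptions))
    descriptions <- attr(sets, "description")
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# Weighted Kolmogorov-Smirnov running sum for one gene set.
# stats: ranking statistics sorted descending; hit: logical vector of set
# membership along that order. Returns es, the peak position, and the
# leading-edge index set.
gsea_running_sum <- function(stats, hit, weight = 1) {
  n <- length(stats)
  nh <- sum(hit)
  w <- abs(stats)^weight
  nr <- sum(w[hit])
  inc <- numeric(n)
  if (nr > 0) {
    inc[hit] <- w[hit] / nr
  } else {
    inc[hit] <- 1 / nh       # all-zero statistics degenerate to unweighted
  }
  inc[!hit] <- -1 / (n - nh)
  rs <- cumsum(inc)
  i_max <- which.max(rs); i_min <- which.min(rs)
  es <- if (rs[i_max] >= -rs[i_min]) rs[i_max] else rs[i_min]
  if (es >= 0) {
    le <- which(hit & seq_len(n) <= i_max)
    peak <- i_max
  } else {
    le <- which(hit & seq_len(n) >= i_min)
    peak <- i_min
  }
  list(es = es, peak = peak, leading_idx = le)
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov enrichment on a ranked gene list: walking down
#' the ranking, set members increment the running sum proportionally to
#' `|statistic|^weight` (normalised over the set's members), non-members
#' decrement it by `1 / (N - n_hits)`; the enrichment score (ES) is the
#' extremum of the running sum. Significance by gene-label permutation: set
#' positions are redrawn uniformly `n_perm` times; the p-value is the
#' fraction of same-sign permutation scores at least as extreme, and
#' NES = ES / mean(|same-sign permutation ES|). Benjamini-Hochberg adjustment
#' across the scored sets.
#'
#' @param ranking Data.frame with columns `gene` and `statistic`, sorted by
#'   decreasing statistic ([moderated_t_rank()] output).
#' @param sets Named list of character vectors ([read_gmt()] output).
#' @param weight Statistic-weighting exponent (default 1; 0 gives the classic
#'   unweighted KS statistic).
#' @param n_perm Number of gene-label permutations (default 1000). `n_perm =
#'   0` skips the permutation test: ES and leading edges are still computed,
#'   `nes`/`p_raw`/`p_adj` are `NA`.
#' @param seed Integer seed for the permutation stream (required when
#'   `n_perm > 0`).
#' @param min_size,max_size Sets whose intersection with the ranking falls
#'   outside `[min_size, max_size]` are skipped (empty intersections with a
#'   warning).
#' @return A data.frame with one row per scored set: `set`, `n_hits`, `es`,
#'   `nes`, `p_raw`, `p_adj`, and a list-column `leading_edge` of gene
#'   identifiers (ranking order). Sets with no same-sign permutation score
#'   get `nes = NA` and are excluded from the BH adjustment.
#' @export
preranked_gsea <- function(ranking, sets, weight = 1, n_perm = 1000,
                           seed = NULL, min_size = 5, max_size = 2000) {
  if (!all(c("gene", "statistic") %in% names(ranking)))
    stop("ranking must have columns 'gene' and 'statistic'")
  if (is.unsorted(rev(ranking$statistic)))
    stop("ranking must be sorted by decreasing statistic")
  if (anyDuplicated(ranking$gene)) stop("duplicate genes in ranking")
  if (n_perm > 0 && is.null(seed))
    stop("seed is required when n_perm > 0")
  stats_v <- ranking$statistic
  genes <- ranking$gene
  n <- length(genes)

  keep <- character(0); hits_list <- list()
  for (nm in names(sets)) {
    idx <- which(genes %in% sets[[nm]])
    if (length(idx) == 0) {
      warning("gene set '", nm, "' has no genes in the ranking; skipped")
      next
    }
    if (length(idx) < min_size || length(idx) > max_size) next
    keep <- c(keep, nm)
    hits_list[[nm]] <- idx
  }
  if (length(keep) == 0)
    return(data.frame(set = character(0), n_hits = integer(0),
                      es = numeric(0), nes = numeric(0),
                      p_raw = numeric(0), p_adj = numeric(0)))

  score_one <- function(idx) {
    hit <- logical(n); hit[idx] <- TRUE
    gsea_running_sum(stats_v, hit, weight)
  }
  obs <- lapply(hits_list[keep], score_one)
  es <- vapply(obs, `[[`, numeric(1), "es")
  nh <- lengths(hits_list[keep])

  nes <- p_raw <- rep(NA_real_, length(keep))
  if (n_perm > 0) {
    sizes <- sort(unique(nh))
    perm_by_size <- with_local_seed(seed, {
      out <- list()
      for (k in sizes) {
        out[[as.character(k)]] <- vapply(seq_len(n_perm), function(i) {
          hit <- logical(n)
          hit[sample.int(n, k)] <- TRUE
          gsea_running_sum(stats_v, hit, weight)$es
        }, numeric(1))
      }
      out
    })
    for (i in seq_along(keep)) {
      pe <- perm_by_size[[as.character(nh[i])]]
      same <- pe[sign(pe) == sign(es[i])]
      if (length(same) == 0 || es[i] == 0) next
      p_raw[i] <- (1 + sum(abs(same) >= abs(es[i]))) / (1 + length(same))
      nes[i] <- es[i] / mean(abs(same))
    }
  }
  p_adj <- rep(NA_real_, length(keep))
  ok <- !is.na(p_raw)
  p_adj[ok] <- stats::p.adjust(p_raw[ok], method = "BH")

  out <- data.frame(
    set = keep, n_hits = as.integer(nh), es = es, nes = nes,
    p_raw = p_raw, p_adj = p_adj,
    row.names = NULL, stringsAsFactors = FALSE
  )
  out$leading_edge <- I(lapply(obs, function(o) genes[o$leading_idx]))
  out
}

#' Cross-arm intersection of leading-edge genes
#'
#' Within each arm, the leading edges of the named pathways are pooled
#' (union); the pooled sets are then intersected across arms. This is the
#' derivation of a shared resistance signature from pathways recurrently
#' enriched in the no-clinical-benefit group of every treatment arm.
#'
#' @param per_arm_results Named list (one element per arm) of
#'   [preranked_gsea()] result data.frames.
#' @param pathway_names Character vector of pathway (set) names to pool.
#' @return Sorted character vector of signature genes.
#' @export
intersect_leading_edges <- function(per_arm_results, pathway_names) {
  if (is.null(names(per_arm_results)) || length(per_arm_results) < 1)
    stop("per_arm_results must be a named list of enrichment results")
  pooled <- lapply(names(per_arm_results), function(arm) {
    res <- per_arm_results[[arm]]
    missing <- setdiff(pathway_names, res$set)
    if (length(missing) > 0)
      stop("pathway(s) ", paste(missing, collapse = ", "),
           " missing from arm '", arm, "'")
    unique(unlist(res$leading_edge[match(pathway_names, res$set)]))
  })
  sort(Reduce(intersect, pooled))
}
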