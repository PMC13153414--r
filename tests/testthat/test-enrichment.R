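toy_counts <- function() {
  m <- matrix(c(999998, 2, 500, 500, 100, 900), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  m
}

test_that("logCPM normalisation follows the prior-augmented CPM formula", {
  m <- matrix(c(999998, 2), ncol = 1,
              dimnames = list(c("g1", "g2"), "s1"))  # library size 1e6
  lc <- normalize_logcpm(m, prior = 1)
  expect_equal(lc["g1", "s1"], log2(999999 / 1000002 * 1e6),
               tolerance = 1e-12)
  expect_equal(lc["g1", "s1"], 19.93, tolerance = 1e-2)
})

test_that("logCPM: identical columns normalise identically, scaling is near-invariant", {
  m <- matrix(rep(c(150, 400, 900), 2), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  lc <- normalize_logcpm(m)
  expect_equal(lc[, "a"], lc[, "b"])
  m2 <- m; m2[, "b"] <- 2 * m2[, "b"]
  lc2 <- normalize_logcpm(m2)
  expect_lt(max(abs(lc2[, "b"] - lc2[, "a"])), 0.01)
})

test_that("logCPM rejects all-zero libraries by name", {
  m <- matrix(c(5, 3, 0, 0), ncol = 2,
              dimnames = list(c("g1", "g2"), c("ok", "empty")))
  expect_error(normalize_logcpm(m), "empty")
})

test_that("moderated t is zero with p = 1 when the groups are identical", {
  base <- matrix(rnorm(20), 5, 4,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  m <- cbind(base, base)
  colnames(m) <- paste0("s", 1:8)
  rk <- moderated_t_rank(m, rep(c("A", "B"), each = 4))
  expect_equal(rk$statistic, rep(0, 5))
  expect_equal(rk$p_raw, rep(1, 5))
})

test_that("d0 = 0 reproduces the ordinary pooled-variance two-sample t", {
  set.seed(101)
  m <- matrix(rnorm(40, sd = rep(c(1, 3), 10)), 5, 8,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  g <- rep(c("A", "B"), each = 4)
  rk <- moderated_t_rank(m, g, d0 = 0)
  for (gene in rownames(m)) {
    xa <- m[gene, g == "A"]; xb <- m[gene, g == "B"]
    sp2 <- (sum((xa - mean(xa))^2) + sum((xb - mean(xb))^2)) / 6
    t_cl <- (mean(xb) - mean(xa)) / sqrt(sp2 * (1 / 4 + 1 / 4))
    expect_equal(rk$statistic[rk$gene == gene], t_cl, tolerance = 1e-12)
    expect_equal(rk$p_raw[rk$gene == gene], 2 * pt(-abs(t_cl), df = 6),
                 tolerance = 1e-12)
  }
})

test_that("moderated t matches the established empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(7)
  m <- matrix(rnorm(2000 * 8) * runif(2000, 0.5, 3), 2000, 8,
              dimnames = list(sprintf("g%04d", 1:2000), paste0("s", 1:8)))
  g <- rep(c("A", "B"), each = 4)
  rk <- moderated_t_rank(m, g)
  fit <- limma::eBayes(limma::lmFit(m, model.matrix(~ g == "B")))
  expect_equal(rk$statistic, unname(fit$t[rk$gene, 2]), tolerance = 1e-9)
  expect_equal(rk$p_raw, unname(fit$p.value[rk$gene, 2]), tolerance = 1e-9)
  expect_equal(attr(rk, "d0"), fit$df.prior, tolerance = 1e-6)
})

test_that("moderated t keeps its nominal size on null data", {
  set.seed(202)
  m <- matrix(rnorm(2000 * 8) * runif(2000, 0.5, 3), 2000, 8,
              dimnames = list(sprintf("g%04d", 1:2000), paste0("s", 1:8)))
  rk <- moderated_t_rank(m, rep(c("A", "B"), each = 4))
  frac <- mean(rk$p_raw < 0.05)
  se <- sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("ranking is sorted with deterministic lexicographic tie-break", {
  base <- matrix(rnorm(12), 3, 4,
                 dimnames = list(c("gB", "gA", "gC"), paste0("s", 1:4)))
  m <- cbind(base, base); colnames(m) <- paste0("s", 1:8)
  rk <- moderated_t_rank(m, rep(c("A", "B"), each = 4))
  expect_equal(rk$gene, c("gA", "gB", "gC"))  # all statistics tie at 0
})

test_that("GMT files round-trip", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g2", "g9"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path, descriptions = c(alpha = "first", beta = "second"))
  back <- read_gmt(path)
  expect_equal(back[["alpha"]], sets$alpha)
  expect_equal(back[["beta"]], sets$beta)
  expect_equal(unname(attr(back, "description")["alpha"]), "first")
})

test_that("enrichment score: hand-enumerated worked example", {
  ranking <- data.frame(gene = paste0("g", 1:10), statistic = 10:1)
  sets <- list(top2 = c("g1", "g2"), bottom2 = c("g9", "g10"))
  res <- preranked_gsea(ranking, sets, weight = 1, n_perm = 0, min_size = 2)
  # hits contribute 10/19 then 9/19; misses 1/8 each; peak after 2nd hit
  expect_equal(res$es[res$set == "top2"], 1.0, tolerance = 1e-12)
  expect_equal(sort(res$leading_edge[res$set == "top2"][[1]]),
               c("g1", "g2"))
  expect_lt(res$es[res$set == "bottom2"], 0)
  expect_equal(sort(res$leading_edge[res$set == "bottom2"][[1]]),
               c("g10", "g9"))
})

test_that("streaming ES equals explicit running-sum enumeration", {
  set.seed(33)
  for (rep in 1:25) {
    n <- sample(10:50, 1)
    stats <- sort(rnorm(n, sd = 2), decreasing = TRUE)
    ranking <- data.frame(gene = sprintf("G%03d", 1:n), statistic = stats)
    k <- sample(2:min(8, n - 2), 1)
    hit_idx <- sort(sample(n, k))
    set_genes <- ranking$gene[hit_idx]
    w <- sample(c(0, 1), 1)
    res <- preranked_gsea(ranking, list(s = set_genes), weight = w,
                          n_perm = 0, min_size = 2)
    hit <- seq_len(n) %in% hit_idx
    expect_equal(res$es, enum_gsea_es(stats, hit, w), tolerance = 1e-12)
  }
})

test_that("weight 0 reduces to the classic unweighted KS statistic", {
  ranking <- data.frame(gene = paste0("g", 1:5), statistic = c(5, 4, 3, 2, 1))
  res <- preranked_gsea(ranking, list(s = c("g1", "g3")), weight = 0,
                        n_perm = 0, min_size = 2)
  # equal hit increments 1/2, miss decrements 1/3: peak 2/3 after g3
  expect_equal(res$es, 2 / 3, tolerance = 1e-12)
})

test_that("ES agrees with the reference preranked implementation", {
  skip_if_not_installed("fgsea")
  set.seed(5)
  stats <- sort(rnorm(100), decreasing = TRUE)
  names(stats) <- sprintf("G%03d", 1:100)
  ranking <- data.frame(gene = names(stats), statistic = unname(stats))
  sets <- list(a = names(stats)[c(3, 9, 15, 40, 77)],
               b = names(stats)[c(60, 70, 80, 90, 95)])
  res <- preranked_gsea(ranking, sets, n_perm = 0)
  for (nm in names(sets)) {
    ref <- fgsea::calcGseaStat(stats, which(names(stats) %in% sets[[nm]]),
                               gseaParam = 1)
    expect_equal(res$es[res$set == nm], ref, tolerance = 1e-12)
  }
})

test_that("permutation p-values flag a planted top-loaded set, reproducibly", {
  set.seed(9)
  n <- 200
  stats <- sort(rnorm(n, sd = 1.5), decreasing = TRUE)
  ranking <- data.frame(gene = sprintf("G%03d", 1:n), statistic = stats)
  sets <- list(planted = ranking$gene[1:12],
               random = ranking$gene[seq(10, 190, by = 18)])
  r1 <- preranked_gsea(ranking, sets, n_perm = 1000, seed = 77)
  r2 <- preranked_gsea(ranking, sets, n_perm = 1000, seed = 77)
  expect_identical(r1, r2)
  expect_lte(r1$p_raw[r1$set == "planted"], 0.01)
  expect_gt(r1$nes[r1$set == "planted"], 1)
  expect_gt(r1$p_raw[r1$set == "random"], 0.05)
})

test_that("leading edge is always inside the set and ends on a hit", {
  set.seed(44)
  n <- 60
  stats <- sort(rnorm(n), decreasing = TRUE)
  ranking <- data.frame(gene = sprintf("G%03d", 1:n), statistic = stats)
  for (rep in 1:10) {
    genes <- sample(ranking$gene, 6)
    res <- preranked_gsea(ranking, list(s = genes), n_perm = 0)
    le <- res$leading_edge[[1]]
    expect_gt(length(le), 0)           # the extremum coincides with a hit
    expect_true(all(le %in% genes))
  }
})

test_that("sets outside the size filters are skipped", {
  ranking <- data.frame(gene = paste0("g", 1:20), statistic = 20:1)
  sets <- list(tiny = c("g1", "g2"), absent = c("x1", "x2"),
               ok = paste0("g", 3:9))
  expect_warning(res <- preranked_gsea(ranking, sets, n_perm = 0,
                                       min_size = 5),
                 "absent")
  expect_equal(res$set, "ok")
})

test_that("cross-arm leading-edge intersection is plain set algebra", {
  mk <- function(le_list) {
    df <- data.frame(set = names(le_list), es = 0.5, stringsAsFactors = FALSE)
    df$leading_edge <- I(unname(le_list))
    df
  }
  armA <- mk(list(p1 = paste0("g", 1:5)))
  armB <- mk(list(p1 = paste0("g", 3:7)))
  expect_equal(intersect_leading_edges(list(A = armA, B = armB), "p1"),
               c("g3", "g4", "g5"))
  # identical arms: the union itself
  expect_equal(intersect_leading_edges(list(A = armA, B = armA), "p1"),
               paste0("g", 1:5))
  # union across pathways inside an arm
  armC <- mk(list(p1 = c("g1", "g2"), p2 = c("g3", "g4")))
  armD <- mk(list(p1 = c("g2", "g3"), p2 = c("g4", "g9")))
  expect_equal(intersect_leading_edges(list(C = armC, D = armD),
                                       c("p1", "p2")),
               c("g2", "g3", "g4"))
  expect_error(intersect_leading_edges(list(A = armA, B = armB),
                                       c("p1", "zzz")),
               "zzz.*arm 'A'")
})
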