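test_that("enrichment scores are deterministic and order-invariant", {
  set.seed(41)
  expr <- matrix(rexp(500 * 4, 1 / 10), nrow = 500,
                 dimnames = list(sprintf("gene_%04d", 1:500),
                                 paste0("s", 1:4)))
  expr[, 2] <- expr[, 1] # identical samples
  sets <- list(A = sprintf("gene_%04d", 1:20),
               B = sprintf("gene_%04d", 21:40))
  sc <- enrichment_scores(expr, sets)
  expect_equal(sc["s1", ], sc["s2", ])
  perm <- sample(nrow(expr))
  sc2 <- enrichment_scores(expr[perm, ], sets)
  expect_equal(sc, sc2)
  expect_error(enrichment_scores(expr, list(none = "not_here")),
               "no genes")
})

test_that("a top-ranked set scores higher than a bottom-ranked set", {
  set.seed(43)
  expr <- matrix(rexp(400 * 3, 1 / 10), nrow = 400,
                 dimnames = list(sprintf("g%03d", 1:400),
                                 paste0("s", 1:3)))
  ord <- order(expr[, 1], decreasing = TRUE)
  sets <- list(top = rownames(expr)[ord[1:50]],
               bottom = rownames(expr)[ord[351:400]])
  sc <- enrichment_scores(expr, sets)
  expect_gt(sc["s1", "top"], sc["s1", "bottom"])
})

test_that("consensus k-means nails degenerate two-point data", {
  X <- rbind(matrix(rep(c(0, 0, 0), 10), ncol = 3, byrow = TRUE),
             matrix(rep(c(5, 5, 5), 10), ncol = 3, byrow = TRUE))
  X <- X + matrix(rnorm(60, sd = 0.01), ncol = 3)
  rownames(X) <- paste0("s", 1:20)
  res <- consensus_kmeans(X, k_range = 2:5, n_perm = 50, gap_b = 10,
                          seed = 2)
  expect_equal(res$k, 2L)
  expect_equal(res$stability, 1, tolerance = 0.01)
  expect_equal(length(unique(res$cluster[1:10])), 1)
  expect_equal(length(unique(res$cluster[11:20])), 1)
  expect_error(consensus_kmeans(X[1:4, ], k_range = 2:8), "k_range")
})

test_that("archetype recovery: k = 4, high ARI, labels match plants", {
  fx <- archetype_scores(n_per = 15, separation = 3, noise_sd = 0.5,
                         seed = 71)
  res <- consensus_kmeans(fx$scores, n_perm = 200, seed = 3)
  expect_equal(res$k, 4L)
  expect_gte(mclust::adjustedRandIndex(res$cluster, fx$labels), 0.9)
  labs <- label_clusters(fx$scores, res$cluster)
  # planted archetypes: 1 = hot, 2 = suppressed, 3 = moderate, 4 = cold
  maj <- function(arch) {
    lab <- labs$sample_labels[fx$labels == arch]
    names(sort(table(lab), decreasing = TRUE))[1]
  }
  expect_equal(maj(1), "hot")
  expect_equal(maj(2), "suppressed")
  expect_equal(maj(3), "moderate")
  expect_equal(maj(4), "cold")
})

test_that("label_clusters falls back to C-labels off k = 4", {
  sc <- matrix(rnorm(30), nrow = 10,
               dimnames = list(paste0("s", 1:10),
                               c("Neutrophils", "T_cells_CD4",
                                 "T_cells_CD8")))
  cl <- rep(1:3, length.out = 10)
  labs <- label_clusters(sc, cl)
  expect_setequal(unique(labs$sample_labels), c("C1", "C2", "C3"))
})

test_that("neutrophil/T-cell ratio handles shifts and zero denominators", {
  sc <- cbind(Neutrophils = c(2, 4), T_cells_CD4 = c(1, 2),
              T_cells_CD8 = c(1, 2))
  rownames(sc) <- c("a", "b")
  r <- neutrophil_tcell_ratio(sc)
  expect_equal(r$ratio, c(1, 1))
  neg <- cbind(Neutrophils = c(-1, 0.5), T_cells_CD4 = c(-0.5, 0.2),
               T_cells_CD8 = c(-0.5, 0.3))
  rownames(neg) <- c("a", "b")
  rn <- neutrophil_tcell_ratio(neg)
  expect_true(all(is.finite(rn$ratio)))
  expect_gt(attr(rn, "shift"), 0)
  expect_error(neutrophil_tcell_ratio(sc[, 1:2]), "columns")
})

test_that("myeloid-high archetypes have larger neutrophil/T-cell ratios", {
  fx <- archetype_scores(n_per = 10, seed = 73)
  r <- neutrophil_tcell_ratio(fx$scores)
  expect_gt(median(r$ratio[fx$labels == 2]),  # myeloid-only archetype
            median(r$ratio[fx$labels == 3]))  # lymphoid-leaning archetype
})

test_that("differential expression is symmetric and recovers planted genes", {
  set.seed(47)
  n_gene <- 800
  expr <- matrix(rlnorm(n_gene * 40, meanlog = 4, sdlog = 0.5), nrow = n_gene,
                 dimnames = list(sprintf("g%04d", 1:n_gene),
                                 sprintf("s%02d", 1:40)))
  labels <- rep(c(1, 2), each = 20)
  ident <- differential_expression(cbind(expr[, 1:20], expr[, 1:20]),
                                   labels, 1)
  expect_true(all(ident$logFC == 0))
  expect_false(any(ident$significant))
  planted <- 1:50
  expr[planted, labels == 1] <- expr[planted, labels == 1] * 4
  de1 <- differential_expression(expr, labels, 1)
  expect_gte(mean(de1$significant[planted]), 0.9)
  de2 <- differential_expression(expr, labels, 2)
  expect_equal(de1$logFC, -de2$logFC)
  expect_equal(de1$p, de2$p)
  expect_error(differential_expression(expr[, 1:4], c(1, 1, 2, 2), 1),
               "at least 3")
})

test_that("pre-ranked GSEA behaves at the extremes and under reversal", {
  set.seed(53)
  genes <- sprintf("g%03d", 1:300)
  ranks <- setNames(sort(rnorm(300), decreasing = TRUE), genes)
  top_set <- list(top = genes[1:20])
  res <- gsea_preranked(ranks, top_set, n_perm = 500, seed = 1)
  expect_gt(res$ES, 0)
  expect_lte(res$p, 0.011)
  rev_res <- gsea_preranked(-ranks, top_set, n_perm = 500, seed = 1)
  expect_lt(rev_res$ES, 0)
  expect_warning(
    gsea_preranked(ranks, list(gone = c("x1", "x2")), n_perm = 100),
    "skipping"
  )
  expect_error(gsea_preranked(setNames(c(1, 2), c("a", "a")), top_set),
               "duplicate")
})
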