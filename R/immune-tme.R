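#' Single-sample gene-set enrichment scores (ssGSEA form)
#'
#' Per sample, genes are ranked by expression and each cell-type set is
#' scored with the weighted running-sum enrichment statistic (weight
#' exponent 0.25 on the rank, as in the ssGSEA variant of single-sample
#' scoring), normalised by the number of genes outside the set. Scores
#' are deterministic and invariant to gene order.
#'
#' @param expr genes x samples non-negative expression matrix.
#' @param sets named list of gene sets; genes absent from `expr` are
#'   dropped with a warning, sets with no overlap are an error.
#' @param alpha rank weight exponent (default 0.25).
#' @return samples x cell-type score matrix.
#' @export
enrichment_scores <- function(expr, sets, alpha = 0.25) {
  if (ncol(expr) < 2) stop("need at least two samples")
  genes <- rownames(expr)
  sets_use <- lapply(names(sets), function(nm) {
    g <- intersect(sets[[nm]], genes)
    if (length(g) == 0) stop("gene set '", nm, "' has no genes in the matrix")
    if (length(g) < length(unique(sets[[nm]]))) {
      warning("gene set '", nm, "' : ",
              length(unique(sets[[nm]])) - length(g), " gene(s) missing")
    }
    g
  })
  names(sets_use) <- names(sets)
  N <- nrow(expr)
  scores <- matrix(0, nrow = ncol(expr), ncol = length(sets_use),
                   dimnames = list(colnames(expr), names(sets_use)))
  set_idx <- lapply(sets_use, function(g) match(g, genes))
  for (j in seq_len(ncol(expr))) {
    r <- rank(expr[, j], ties.method = "average")
    ord <- order(r, decreasing = TRUE)
    w <- r[ord]^alpha
    for (s in seq_along(set_idx)) {
      inset <- logical(N)
      inset[match(set_idx[[s]], ord)] <- TRUE
      wr <- w * inset
      p_hit <- cumsum(wr) / sum(wr)
      p_miss <- cumsum(!inset) / (N - sum(inset))
      scores[j, s] <- sum(p_hit - p_miss) / (N - sum(inset))
    }
  }
  scores
}

#' Consensus k-means immune subtyping
#'
#' Standardises the enrichment scores (z-score per cell type), selects k
#' by a consensus of four criteria — elbow (largest second difference of
#' the within-cluster sum of squares), mean silhouette width (Euclidean),
#' the gap statistic (Tibshirani, `gap_b` reference sets) and the
#' Calinski-Harabasz index — requiring agreement of at least three, else
#' falling back to the silhouette winner with a warning. The final
#' assignment is the run, among `n_perm` random-restart k-means runs,
#' with the highest mean pairwise agreement with the co-assignment
#' consensus matrix; that agreement is reported as the stability.
#'
#' @param scores samples x cell-type score matrix.
#' @param k_range candidate cluster numbers (default 2:8).
#' @param n_perm number of random-restart runs for the consensus matrix
#'   (default 1000).
#' @param gap_b reference sets for the gap statistic (default 50).
#' @param seed integer seed.
#' @return list: `cluster` (named integer vector), `k`, `votes`
#'   (per-method chosen k), `stability`, `consensus` (n x n matrix).
#' @export
consensus_kmeans <- function(scores, k_range = 2:8, n_perm = 1000,
                             gap_b = 50, seed = 1) {
  X <- scale(scores)
  X[, attr(X, "scaled:scale") == 0] <- 0
  n <- nrow(X)
  if (n < max(k_range) + 1) stop("k_range too large for the sample count")
  with_seed(seed, {
    dX <- stats::dist(X)
    wss <- sil <- ch <- rep(NA_real_, length(k_range))
    for (i in seq_along(k_range)) {
      k <- k_range[i]
      km <- stats::kmeans(X, centers = k, nstart = 10, iter.max = 50)
      wss[i] <- km$tot.withinss
      sil[i] <- mean(cluster::silhouette(km$cluster, dX)[, 3])
      ch[i] <- (km$betweenss / (k - 1)) / (km$tot.withinss / (n - k))
    }
    gap_fit <- cluster::clusGap(X, FUNcluster = stats::kmeans,
                                K.max = max(k_range), B = gap_b,
                                nstart = 10, iter.max = 50,
                                verbose = FALSE)
    gtab <- gap_fit$Tab[k_range, , drop = FALSE]
    k_gap <- k_range[cluster::maxSE(gtab[, "gap"], gtab[, "SE.sim"],
                                    method = "Tibs2001SEmax")]
    k_elbow <- if (length(k_range) >= 3) {
      interior <- 2:(length(k_range) - 1)
      d2 <- wss[interior - 1] - 2 * wss[interior] + wss[interior + 1]
      k_range[interior][which.max(d2)]
    } else k_range[which.min(wss)]
    k_sil <- k_range[which.max(sil)]
    k_ch <- k_range[which.max(ch)]
    votes <- c(elbow = k_elbow, silhouette = k_sil, gap = k_gap,
               calinski_harabasz = k_ch)
    tab <- table(votes)
    if (max(tab) >= 3) {
      k <- as.integer(names(tab)[which.max(tab)])
    } else {
      warning("no 3-of-4 agreement on k; falling back to silhouette")
      k <- k_sil
    }
    # consensus over random-restart runs
    runs <- matrix(0L, nrow = n_perm, ncol = n)
    C <- matrix(0, n, n)
    for (r in seq_len(n_perm)) {
      cl <- stats::kmeans(X, centers = k, nstart = 1, iter.max = 50)$cluster
      runs[r, ] <- cl
      C <- C + outer(cl, cl, `==`)
    }
    C <- C / n_perm
    ut <- upper.tri(C)
    agree <- vapply(seq_len(n_perm), function(r) {
      same <- outer(runs[r, ], runs[r, ], `==`)
      mean(ifelse(same[ut], C[ut], 1 - C[ut]))
    }, numeric(1))
    best <- runs[which.max(agree), ]
  })
  # contiguous ids by order of first appearance
  cl <- match(best, unique(best))
  names(cl) <- rownames(scores)
  list(cluster = cl, k = as.integer(k), votes = votes,
       stability = max(agree), consensus = C)
}

#' Label immune clusters as hot / suppressed / moderate / cold
#'
#' On z-scored cell-type means per cluster: hot = highest lymphoid +
#' myeloid mean; suppressed = highest myeloid minus lymphoid contrast
#' among the rest; cold = lowest overall mean among the rest; moderate =
#' the remaining cluster. Ties break by cluster id. For k != 4 the
#' fallback labels C1..Ck are returned.
#'
#' @param scores samples x cell-type score matrix.
#' @param cluster integer cluster assignment (named by sample).
#' @param lymphoid,myeloid cell-type name lists.
#' @return list: `cluster_labels` (cluster id -> label), `sample_labels`
#'   (label per sample).
#' @export
label_clusters <- function(scores, cluster,
                           lymphoid = lymphoid_cell_types(),
                           myeloid = myeloid_cell_types()) {
  ks <- sort(unique(cluster))
  if (length(ks) != 4) {
    labs <- stats::setNames(paste0("C", ks), ks)
    return(list(cluster_labels = labs,
                sample_labels = unname(labs[as.character(cluster)])))
  }
  Z <- scale(scores)
  Z[, attr(Z, "scaled:scale") == 0] <- 0
  lym_cols <- intersect(lymphoid, colnames(Z))
  mye_cols <- intersect(myeloid, colnames(Z))
  lym <- vapply(ks, function(k) mean(Z[cluster == k, lym_cols]), numeric(1))
  mye <- vapply(ks, function(k) mean(Z[cluster == k, mye_cols]), numeric(1))
  tot <- vapply(ks, function(k) mean(Z[cluster == k, ]), numeric(1))
  labs <- stats::setNames(rep(NA_character_, 4), ks)
  hot <- which.max(lym + mye)
  labs[hot] <- "hot"
  rest <- which(is.na(labs))
  sup <- rest[which.max((mye - lym)[rest])]
  labs[sup] <- "suppressed"
  rest <- which(is.na(labs))
  cold <- rest[which.min(tot[rest])]
  labs[cold] <- "cold"
  labs[is.na(labs)] <- "moderate"
  if (length(unique(c(lym + mye, mye - lym, tot))) < 3) {
    warning("degenerate score means; labels assigned by tie-break")
  }
  list(cluster_labels = labs,
       sample_labels = unname(labs[as.character(cluster)]))
}

#' Neutrophil to T-cell enrichment ratio
#'
#' Enrichment scores can be negative, so the relevant columns are
#' shifted to be positive (common shift = min score minus a small
#' offset) before forming neutrophils / (CD4 + CD8). A zero denominator
#' yields NA.
#'
#' @param scores samples x cell-type score matrix containing
#'   `Neutrophils`, `T_cells_CD4`, `T_cells_CD8`.
#' @return data.frame (sample_id, ratio) with attribute `shift`.
#' @export
neutrophil_tcell_ratio <- function(scores) {
  need <- c("Neutrophils", "T_cells_CD4", "T_cells_CD8")
  if (!all(need %in% colnames(scores))) {
    stop("scores must contain columns: ", paste(need, collapse = ", "))
  }
  sub <- scores[, need, drop = FALSE]
  shift <- if (any(sub <= 0)) -min(sub) + 1e-6 else 0
  neu <- sub[, 1] + shift
  tc <- (sub[, 2] + shift) + (sub[, 3] + shift)
  ratio <- ifelse(tc == 0, NA_real_, neu / tc)
  out <- data.frame(sample_id = rownames(scores), ratio = ratio,
                    stringsAsFactors = FALSE)
  attr(out, "shift") <- shift
  out
}

#' Differential expression, one cluster versus the rest
#'
#' Per gene: log2 fold change of pseudocount-shifted group means
#' (pc = 1) and a two-sided Wilcoxon rank-sum p-value, BH-adjusted.
#' Significant = |logFC| > 1.5 and q < 0.05.
#'
#' @param expr genes x samples matrix.
#' @param labels cluster per sample.
#' @param cluster the cluster to contrast against the rest.
#' @param lfc_cut,q_cut significance thresholds.
#' @return data.frame: gene, logFC, p, q, significant.
#' @export
differential_expression <- function(expr, labels, cluster,
                                    lfc_cut = 1.5, q_cut = 0.05) {
  in_grp <- labels == cluster
  if (sum(in_grp) < 3 || sum(!in_grp) < 3) {
    stop("each group needs at least 3 samples")
  }
  A <- expr[, in_grp, drop = FALSE]
  B <- expr[, !in_grp, drop = FALSE]
  lfc <- log2(rowMeans(A) + 1) - log2(rowMeans(B) + 1)
  p <- vapply(seq_len(nrow(expr)), function(i) {
    stats::wilcox.test(A[i, ], B[i, ], exact = FALSE)$p.value
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  data.frame(gene = rownames(expr), logFC = lfc, p = p, q = q,
             significant = abs(lfc) > lfc_cut & q < q_cut,
             stringsAsFactors = FALSE)
}

#' Pre-ranked gene set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov running-sum enrichment on a
#' logFC-ranked gene list with a gene-label permutation null
#' (delegated to \pkg{fgsea}'s simple permutation routine, whose NES is
#' ES divided by the mean same-sign null ES); q-values are BH.
#'
#' @param ranks named numeric vector (gene -> ranking statistic), no
#'   duplicate names.
#' @param sets named list of gene sets; sets without genes in the
#'   ranking are skipped with a warning.
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @return data.frame: set, size, ES, NES, p, q.
#' @export
gsea_preranked <- function(ranks, sets, n_perm = 1000, seed = 1) {
  if (anyDuplicated(names(ranks))) stop("duplicate genes in ranking")
  overlap <- vapply(sets, function(g) length(intersect(g, names(ranks))),
                    integer(1))
  if (any(overlap == 0)) {
    warning("skipping ", sum(overlap == 0),
            " set(s) with no genes in the ranking")
    sets <- sets[overlap > 0]
  }
  res <- with_seed(seed, {
    suppressWarnings(
      fgsea::fgseaSimple(pathways = sets, stats = sort(ranks,
                                                       decreasing = TRUE),
                         nperm = n_perm, minSize = 1,
                         maxSize = length(ranks))
    )
  })
  data.frame(set = res$pathway, size = res$size, ES = res$ES,
             NES = res$NES, p = res$pval, q = res$padj,
             stringsAsFactors = FALSE)
}
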