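CONSENSUS_CELL_TYPES <- c(
  "B_cells", "Cytotoxic_cells", "Dendritic_cells", "Endothelial",
  "Eosinophils", "Fibroblasts", "Macrophages", "Macrophages_M1",
  "Macrophages_M2", "Mast_cells", "Monocytes", "Neutrophils",
  "NK_cells", "Plasma_cells", "T_cells_CD4", "T_cells_CD8",
  "T_cells_gamma_delta", "T_regulatory_cells"
)

#' Lymphoid cell-type names used for cluster labelling
#' @return character vector.
#' @export
lymphoid_cell_types <- function() {
  c("B_cells", "Cytotoxic_cells", "NK_cells", "Plasma_cells",
    "T_cells_CD4", "T_cells_CD8", "T_cells_gamma_delta",
    "T_regulatory_cells")
}

#' Myeloid cell-type names used for cluster labelling
#' @return character vector.
#' @export
myeloid_cell_types <- function() {
  c("Dendritic_cells", "Eosinophils", "Macrophages", "Macrophages_M1",
    "Macrophages_M2", "Mast_cells", "Monocytes", "Neutrophils")
}

#' Default synthetic immune cell-type gene sets
#'
#' Eighteen cell-type marker sets (names mirroring the ConsensusTME cell
#' types) over a synthetic gene universe `gene_0001..gene_<n>`. Marker
#' blocks are disjoint so planted archetype shifts are unambiguous.
#'
#' @param n_genes size of the gene universe.
#' @param genes_per_set markers per cell type.
#' @return named list of character vectors (a gene-set collection).
#' @export
default_immune_gene_sets <- function(n_genes = 2000, genes_per_set = 25) {
  need <- length(CONSENSUS_CELL_TYPES) * genes_per_set
  if (n_genes < need) stop("gene universe too small for the marker sets")
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  sets <- lapply(seq_along(CONSENSUS_CELL_TYPES), function(i) {
    genes[seq.int((i - 1) * genes_per_set + 1, i * genes_per_set)]
  })
  names(sets) <- CONSENSUS_CELL_TYPES
  sets
}

#' Simulate a bulk expression matrix with four planted immune archetypes
#'
#' Archetypes mimic the four immune clusters of the study design:
#' cluster 1 ("hot") up-shifts lymphoid and myeloid marker genes by
#' `separation` (natural-log scale), cluster 2 ("suppressed") up-shifts
#' myeloid markers only, cluster 3 ("moderate") up-shifts lymphoid
#' markers at half effect, cluster 4 ("cold") has no shift. Expression is
#' log-normal: gene baselines N(2, 1) on the log scale plus archetype
#' shift plus N(0, `noise_sd`) noise, exponentiated to a TPM-like linear
#' scale.
#'
#' @param n_genes gene universe size.
#' @param samples_per_cluster integer vector of four cluster sizes.
#' @param gene_sets named list of marker sets (see
#'   [default_immune_gene_sets()]).
#' @param separation log-scale shift magnitude.
#' @param noise_sd log-scale noise standard deviation.
#' @param seed integer seed.
#' @param lymphoid,myeloid names of the lymphoid / myeloid sets.
#' @return list with `expr` (genes x samples matrix) and `labels`
#'   (integer cluster per sample).
#' @export
simulate_expression <- function(n_genes = 2000,
                                samples_per_cluster = c(15, 15, 15, 15),
                                gene_sets = default_immune_gene_sets(n_genes),
                                separation = 3, noise_sd = 0.5, seed = 1,
                                lymphoid = lymphoid_cell_types(),
                                myeloid = myeloid_cell_types()) {
  stopifnot(length(samples_per_cluster) == 4)
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  missing <- setdiff(unique(unlist(gene_sets)), genes)
  if (length(missing) > 0) {
    stop("gene sets reference genes absent from the universe: ",
         missing[1])
  }
  lym_genes <- unique(unlist(gene_sets[intersect(lymphoid, names(gene_sets))]))
  mye_genes <- unique(unlist(gene_sets[intersect(myeloid, names(gene_sets))]))
  n_samp <- sum(samples_per_cluster)
  labels <- rep(1:4, times = samples_per_cluster)
  shift <- matrix(0, nrow = n_genes, ncol = n_samp,
                  dimnames = list(genes, NULL))
  li <- match(lym_genes, genes); mi <- match(mye_genes, genes)
  shift[li, labels == 1] <- separation
  shift[mi, labels == 1] <- separation
  shift[mi, labels == 2] <- separation
  shift[li, labels == 3] <- separation / 2
  with_seed(seed, {
    base <- stats::rnorm(n_genes, mean = 2, sd = 1)
    noise <- matrix(stats::rnorm(n_genes * n_samp, sd = noise_sd),
                    nrow = n_genes)
    expr <- exp(base + shift + noise)
  })
  dimnames(expr) <- list(genes, sprintf("Sample_%03d", seq_len(n_samp)))
  list(expr = expr, labels = labels)
}
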