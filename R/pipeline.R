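#' Default pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one list, with
#' the study defaults: signature count k = 4 (SNV) / 3 (SV), exposure
#' prune threshold 10%, kataegis window 10 kb / step 5 kb / >= 6
#' mutations / mean IMD <= 2 kb / q < 0.05, clustered-breakpoint rule
#' >= 10 breakpoints per 1 Mb bin, co-localization 1 Mb bins with the
#' mean rule, sub-clonal FDR < 0.05, HRD-sum > 42 with HRDetect > 0.7,
#' complex-event thresholds (interleaved > 10 / > 30, oscillations > 6,
#' q < 0.05 / < 0.2), presence cutoff 15%, DE |logFC| > 1.5 & q < 0.05.
#'
#' @param ... named overrides.
#' @return named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    snv_k = 4, sv_k = 3,
    nmf_restarts = 20, nmf_max_iter = 2000, nmf_tol = 1e-6,
    prune_threshold = 0.10,
    kataegis_window = 1e4, kataegis_step = 5e3,
    kataegis_min_mut = 6, kataegis_max_imd = 2000, kataegis_q = 0.05,
    sv_cluster_bin = 1e6, sv_cluster_min_bp = 10,
    coloc_bin = 1e6, coloc_z = 0,
    subclonal_fdr = 0.05,
    hrd_sum_cut = 42, hrdetect_cut = 0.7,
    complex_min_events = 1,
    presence_cutoff = 0.15,
    de_lfc = 1.5, de_q = 0.05,
    consensus_k_range = 2:8, consensus_n_perm = 1000, consensus_gap_b = 50
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) stop("unknown config value: ", unknown[1])
  cfg[names(overrides)] <- overrides
  cfg
}

read_cohort_dir <- function(input_dir) {
  vcfs <- list.files(file.path(input_dir, "vcf"), pattern = "\\.vcf$",
                     full.names = TRUE)
  snvs <- do.call(rbind, lapply(vcfs, read_vcf))
  genome <- load_genome_table(file.path(input_dir, "genome.tsv"))
  read_sig_tsv <- function(path, prov) {
    tab <- data.table::fread(path, sep = "\t", data.table = FALSE)
    prof <- t(as.matrix(tab[, -1, drop = FALSE]))
    colnames(prof) <- tab$channel
    signature_set(prof, names = rownames(prof), provenance = prov)
  }
  list(
    snvs = snvs,
    svs = read_bedpe(file.path(input_dir, "svs.bedpe")),
    segments = read_segments(file.path(input_dir, "segments.tsv")),
    expr = read_expression(file.path(input_dir, "expression.tsv")),
    gene_sets = read_gmt(file.path(input_dir, "immune_sets.gmt")),
    clinical = read_clinical(file.path(input_dir, "clinical.tsv")),
    genome = genome,
    ref_snv_signatures = read_sig_tsv(
      file.path(input_dir, "reference_signatures.tsv"), "reference"),
    ref_rs_signatures = read_sig_tsv(
      file.path(input_dir, "reference_rs.tsv"), "reference"),
    truth = if (file.exists(file.path(input_dir, "truth.json"))) {
      jsonlite::read_json(file.path(input_dir, "truth.json"),
                          simplifyVector = TRUE)
    } else NULL
  )
}

#' Run the full analysis pipeline on a cohort
#'
#' Executes every stage on a cohort (in-memory object from
#' [simulate_cohort()] or a directory of standard files written by
#' [write_cohort()]): SNV signature extraction + QP refit +
#' prune-and-reassign, kataegis detection, SV classification and
#' rearrangement signatures, kataegis-SV co-localization ranking,
#' copy-number / sub-clonality / HRD features, complex-event calls,
#' immune subtyping with differential expression and pre-ranked GSEA,
#' and survival stratifications (IPW-adjusted immune-cluster log-rank,
#' APOBEC-presence and RS-tertile comparisons, RS-in-cluster binomial
#' enrichment). Result tables are written to `out_dir` when given;
#' ground-truth recovery summaries are included when the cohort carries
#' truth.
#'
#' @param cohort cohort list or input directory path.
#' @param out_dir optional output directory for result TSVs.
#' @param seed integer seed for the stochastic stages.
#' @param config configuration list from [pipeline_config()].
#' @return list of result tables (see names of the returned list) plus
#'   `recovery` when ground truth is available.
#' @export
run_cohort_pipeline <- function(cohort, out_dir = NULL, seed = 1,
                                config = pipeline_config()) {
  if (is.character(cohort)) cohort <- read_cohort_dir(cohort)
  genome <- cohort$genome
  samples <- sort(unique(cohort$clinical$sample_id))
  res <- list()

  # --- SNV signatures ---------------------------------------------------
  catalogue <- build_snv_catalogue(cohort$snvs, samples)
  nmf <- extract_signatures_nmf(catalogue, k = config$snv_k,
                                n_restarts = config$nmf_restarts,
                                max_iter = config$nmf_max_iter,
                                tol = config$nmf_tol,
                                seed = derive_seed(seed, 11))
  matches <- match_signatures_cosine(nmf$signatures,
                                     cohort$ref_snv_signatures)
  refit <- refit_exposure_matrix(catalogue, cohort$ref_snv_signatures)
  pruned <- prune_and_reassign(refit, catalogue,
                               cohort$ref_snv_signatures,
                               threshold = config$prune_threshold)
  res$snv_catalogue <- catalogue
  res$snv_signatures <- nmf$signatures
  res$snv_matches <- matches
  res$snv_exposures <- pruned
  res$snv_recon_error <- nmf$recon_error

  # --- kataegis ---------------------------------------------------------
  loci <- do.call(rbind, lapply(samples, function(sid) {
    detect_kataegis(cohort$snvs[cohort$snvs$sample_id == sid, ,
                                drop = FALSE],
                    genome, window = config$kataegis_window,
                    step = config$kataegis_step,
                    min_mut = config$kataegis_min_mut,
                    max_imd = config$kataegis_max_imd,
                    q_cut = config$kataegis_q)
  }))
  res$kataegis_loci <- loci

  # --- SV signatures ----------------------------------------------------
  svs <- flag_clustered_breakpoints(cohort$svs,
                                    bin = config$sv_cluster_bin,
                                    min_bp = config$sv_cluster_min_bp)
  sv_cat <- build_sv_catalogue(svs, samples)
  rs <- extract_and_match_rs(sv_cat, cohort$ref_rs_signatures,
                             k = config$sv_k,
                             seed = derive_seed(seed, 12),
                             n_restarts = config$nmf_restarts,
                             max_iter = config$nmf_max_iter,
                             tol = config$nmf_tol)
  rs_refit <- refit_exposure_matrix(sv_cat, cohort$ref_rs_signatures)
  res$sv_records <- svs
  res$sv_catalogue <- sv_cat
  res$rs_signatures <- rs$signatures
  res$rs_matches <- rs$matches
  res$rs_exposures <- rs_refit

  # --- co-localization --------------------------------------------------
  coloc <- colocalization_analysis(loci, svs, samples, genome,
                                   bin = config$coloc_bin,
                                   z = config$coloc_z)
  res$colocalization <- coloc$per_chromosome
  res$coloc_mean_frequency <- coloc$mean_frequency

  # --- copy-number features and complex events --------------------------
  cn_rows <- list()
  complex_calls <- list()
  for (sid in samples) {
    seg <- cohort$segments[cohort$segments$sample_id == sid, ,
                           drop = FALSE]
    sv_s <- svs[svs$sample_id == sid, , drop = FALSE]
    pl <- compute_ploidy(seg, genome)
    sc <- subclonal_cna_percent(seg, genome,
                                fdr_cut = config$subclonal_fdr)
    hrd <- hrd_components(seg, genome)
    cx <- call_complex_events(sv_s, seg, genome,
                              min_events = config$complex_min_events)
    complex_calls[[sid]] <- cx$calls
    cn_rows[[sid]] <- data.frame(
      sample_id = sid, ploidy = pl,
      pct_genome_altered = percent_genome_altered(seg, genome),
      subclonal_pct = sc$genome_pct,
      loh = hrd$loh, tai = hrd$tai, lst = hrd$lst,
      hrd_sum = hrd$hrd_sum,
      hrd_class = classify_hrd(hrd$hrd_sum, NULL,
                               sum_cut = config$hrd_sum_cut,
                               prob_cut = config$hrdetect_cut),
      complex_genome = cx$complex_genome,
      n_complex_events = sum(cx$calls$called),
      stringsAsFactors = FALSE
    )
  }
  res$cn_features <- do.call(rbind, c(cn_rows, make.row.names = FALSE))
  res$complex_calls <- do.call(rbind, c(complex_calls,
                                        make.row.names = FALSE))

  # --- immune subtyping -------------------------------------------------
  scores <- enrichment_scores(cohort$expr, cohort$gene_sets)
  cons <- consensus_kmeans(scores, k_range = config$consensus_k_range,
                           n_perm = config$consensus_n_perm,
                           gap_b = config$consensus_gap_b,
                           seed = derive_seed(seed, 13))
  labs <- label_clusters(scores, cons$cluster)
  res$enrichment_scores <- scores
  res$immune_clusters <- data.frame(
    sample_id = rownames(scores),
    cluster = unname(cons$cluster),
    label = labs$sample_labels,
    stringsAsFactors = FALSE
  )
  res$immune_k <- cons$k
  res$immune_votes <- cons$votes
  res$immune_stability <- cons$stability
  res$nt_ratio <- neutrophil_tcell_ratio(scores)

  de_list <- list()
  gsea_list <- list()
  for (k in sort(unique(cons$cluster))) {
    de <- differential_expression(cohort$expr,
                                  cons$cluster[colnames(cohort$expr)], k,
                                  lfc_cut = config$de_lfc,
                                  q_cut = config$de_q)
    de$cluster <- k
    de_list[[as.character(k)]] <- de
    ranks <- stats::setNames(de$logFC, de$gene)
    gs <- gsea_preranked(ranks, cohort$gene_sets, n_perm = 200,
                         seed = derive_seed(seed, 140 + k))
    gs$cluster <- k
    gsea_list[[as.character(k)]] <- gs
  }
  res$differential_expression <- do.call(rbind, c(de_list,
                                                  make.row.names = FALSE))
  res$gsea <- do.call(rbind, c(gsea_list, make.row.names = FALSE))

  # --- survival ---------------------------------------------------------
  clin <- cohort$clinical[match(rownames(scores),
                                cohort$clinical$sample_id), ]
  strata <- interaction(clin$stage, clin$treatment, drop = TRUE)
  w <- ipw_weights(cons$cluster, strata)
  lr_cluster <- logrank_test(clin$os_months, clin$os_event, cons$cluster)
  lr_cluster_ipw <- logrank_test(clin$os_months, clin$os_event,
                                 cons$cluster, weights = w)
  pres <- stratify_presence(pruned[clin$sample_id, "RefSig1"],
                            cutoff = config$presence_cutoff)
  lr_presence <- if (length(unique(pres)) > 1) {
    logrank_test(clin$os_months, clin$os_event, pres)
  } else NULL
  tert <- stratify_tertiles(rs_refit[clin$sample_id, 1])
  sel <- tert != "mid"
  lr_tertile <- logrank_test(clin$os_months[sel], clin$os_event[sel],
                             droplevels(tert[sel]))
  surv_tab <- data.frame(
    comparison = c("immune_cluster", "immune_cluster_ipw",
                   "apobec_presence", "rs_tertile"),
    statistic = c(lr_cluster$statistic, lr_cluster_ipw$statistic,
                  if (is.null(lr_presence)) NA else lr_presence$statistic,
                  lr_tertile$statistic),
    p = c(lr_cluster$p, lr_cluster_ipw$p,
          if (is.null(lr_presence)) NA else lr_presence$p,
          lr_tertile$p),
    stringsAsFactors = FALSE
  )
  surv_tab$q <- bh_adjust(surv_tab$p)
  res$survival <- surv_tab
  # RS presence enrichment in the suppressed cluster (binomial test)
  rs1_pres <- rs_refit[clin$sample_id, 1] >= config$presence_cutoff
  sup_cluster <- as.integer(names(labs$cluster_labels)[
    labs$cluster_labels == "suppressed"][1])
  if (!is.na(sup_cluster)) {
    in_sup <- cons$cluster == sup_cluster
    res$rs_enrichment <- data.frame(
      cluster = sup_cluster,
      k = sum(rs1_pres & in_sup), n = sum(in_sup),
      expected = mean(rs1_pres),
      p = binomial_enrichment_test(sum(rs1_pres & in_sup), sum(in_sup),
                                   max(mean(rs1_pres), 1e-9))
    )
  }

  # --- ground-truth recovery -------------------------------------------
  if (!is.null(cohort$truth)) {
    truth <- cohort$truth
    true_expo <- as.matrix(as.data.frame(truth$exposures))
    rec <- list()
    rec$exposure_mae <- mean(abs(refit[truth$samples, ] - true_expo))
    plan <- as.data.frame(truth$kataegis_plan)
    found <- 0
    if (nrow(plan) > 0 && nrow(loci) > 0) {
      for (j in seq_len(nrow(plan))) {
        hit <- loci$sample_id == plan$sample_id[j] &
          loci$chrom == plan$chrom[j] &
          loci$start <= plan$centre[j] + 5e4 &
          loci$end >= plan$centre[j] - 5e4
        if (any(hit)) found <- found + 1
      }
    }
    rec$kataegis_sensitivity <- if (nrow(plan) > 0) found / nrow(plan)
                                else NA
    rec$ploidy_max_error <- max(abs(res$cn_features$ploidy - truth$ploidy))
    rec$subclonal_max_error <- max(abs(res$cn_features$subclonal_pct -
                                         truth$subclonal_pct))
    rec$hotspot_rank <- res$colocalization$rank[
      res$colocalization$chrom == truth$hotspot_chrom]
    rec$immune_k <- cons$k
    rec$immune_ari <- mclust::adjustedRandIndex(cons$cluster,
                                                truth$immune_cluster)
    rec$complex_flag_agreement <- mean(res$cn_features$complex_genome ==
                                         truth$complex)
    res$recovery <- rec
  }

  if (!is.null(out_dir)) write_pipeline_results(res, out_dir)
  res
}

write_pipeline_results <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, nm) {
    data.table::fwrite(as.data.frame(x), file.path(out_dir, nm),
                       sep = "\t", row.names = FALSE)
  }
  wtm <- function(m, nm, key) {
    df <- data.frame(rownames(m), as.data.frame(m), check.names = FALSE)
    names(df)[1] <- key
    data.table::fwrite(df, file.path(out_dir, nm), sep = "\t")
  }
  wtm(res$snv_catalogue, "snv_catalogue.tsv", "sample")
  wtm(res$snv_exposures, "snv_exposures.tsv", "sample")
  wtm(res$sv_catalogue, "sv_catalogue.tsv", "sample")
  wtm(res$rs_exposures, "rs_exposures.tsv", "sample")
  wtm(res$enrichment_scores, "enrichment_scores.tsv", "sample")
  wt(res$snv_matches, "snv_signature_matches.tsv")
  wt(res$rs_matches, "rs_signature_matches.tsv")
  wt(res$kataegis_loci, "kataegis_loci.tsv")
  wt(res$colocalization, "colocalization.tsv")
  wt(res$cn_features, "cn_features.tsv")
  wt(res$complex_calls, "complex_calls.tsv")
  wt(res$immune_clusters, "immune_clusters.tsv")
  wt(res$nt_ratio, "neutrophil_tcell_ratio.tsv")
  wt(res$differential_expression, "differential_expression.tsv")
  wt(res$gsea, "gsea.tsv")
  wt(res$survival, "survival.tsv")
  if (!is.null(res$recovery)) {
    jsonlite::write_json(res$recovery, file.path(out_dir, "recovery.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out_dir)
}
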