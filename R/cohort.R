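#' Simulate a full synthetic cohort with known ground truth
#'
#' Generates, for `n_samples` tumours, SNV catalogues drawn from four
#' synthetic reference signatures (Dirichlet exposures) with planted
#' APOBEC kataegis clusters biased toward a hotspot chromosome, SV sets
#' drawn from mixtures of reference rearrangement signatures (with a
#' clustered-breakpoint region on the hotspot chromosome for complex
#' samples), clonal + sub-clonal copy-number profiles with known ploidy
#' (complex samples carry an oscillating chromosome), an expression
#' matrix with four planted immune archetypes, and clinical records with
#' cluster-dependent hazards. All ground truth is returned (and written
#' as `truth.json` when `out_dir` is given) so every downstream module
#' can be checked for recovery.
#'
#' @param n_samples cohort size (default 60).
#' @param genome a `genome_model` (default 22 x 100 Mb toy genome).
#' @param seed integer seed.
#' @param out_dir optional directory; when given, writes per-sample VCFs,
#'   a cohort BEDPE, segment/expression/clinical TSVs, the immune gene
#'   sets (GMT), the reference signature TSVs and `truth.json`.
#' @param n_mut background SNVs per sample.
#' @param n_sv SVs per sample.
#' @param kataegis_rate mean planted APOBEC kataegis loci per sample
#'   (Poisson).
#' @param hotspot_chrom chromosome receiving elevated kataegis with
#'   co-localised breakpoints (default: chr8 when present, else the last
#'   chromosome).
#' @param complex_chrom chromosome carrying the oscillating copy-number
#'   profile and the clustered SV region in complex samples (default:
#'   chr18 when present).
#' @param complex_fraction fraction of samples planted as complex
#'   genomes.
#' @param separation,noise_sd immune archetype effect size and noise.
#' @param hazard_by_cluster per-archetype event rates per month.
#' @return list: `snvs`, `svs`, `segments`, `expr`, `gene_sets`,
#'   `clinical`, `samples`, `genome`, `ref_snv_signatures`,
#'   `ref_rs_signatures`, `truth`.
#' @export
simulate_cohort <- function(n_samples = 60,
                            genome = generate_genome(22, 1e8, seed = seed),
                            seed = 1,
                            out_dir = NULL,
                            n_mut = 2000,
                            n_sv = 200,
                            kataegis_rate = 3,
                            hotspot_chrom = NULL,
                            complex_chrom = NULL,
                            complex_fraction = 0.4,
                            separation = 3,
                            noise_sd = 0.5,
                            hazard_by_cluster = c(0.02, 0.08, 0.04, 0.05)) {
  samples <- sprintf("Sample_%03d", seq_len(n_samples))
  ref_sigs <- synthetic_reference_signatures(4, seed = 99)
  ref_rs <- synthetic_reference_rs(3, seed = 7)
  chroms <- genome$chromosomes$chrom
  # default hotspot/complex chromosomes: chr8 and chr18 when present
  if (is.null(hotspot_chrom)) {
    hotspot_chrom <- chroms[min(8L, length(chroms))]
  }
  if (is.null(complex_chrom)) {
    complex_chrom <- chroms[min(18L, length(chroms))]
    if (complex_chrom == hotspot_chrom) complex_chrom <- chroms[1]
  }
  stopifnot(hotspot_chrom %in% chroms, complex_chrom %in% chroms)
  n_genes <- 2000

  with_seed(derive_seed(seed, 1), {
    true_expo <- t(vapply(seq_len(n_samples), function(i) {
      g <- stats::rgamma(4, shape = 1)
      g / sum(g)
    }, numeric(4)))
    n_loci <- stats::rpois(n_samples, kataegis_rate)
    complex_flag <- stats::runif(n_samples) < complex_fraction
    ploidy <- sample(c(2, 2.5, 3, 3.5), n_samples, replace = TRUE,
                     prob = c(0.3, 0.25, 0.3, 0.15))
    subclonal <- round(stats::runif(n_samples, 5, 40), 1)
    rs_expo <- t(vapply(seq_len(n_samples), function(i) {
      g <- stats::rgamma(3, shape = 1)
      g / sum(g)
    }, numeric(3)))
  })
  colnames(true_expo) <- ref_sigs$names
  colnames(rs_expo) <- ref_rs$names

  snv_list <- vector("list", n_samples)
  sv_list <- vector("list", n_samples)
  seg_list <- vector("list", n_samples)
  kat_plan_list <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    si <- derive_seed(seed, 100 + i)
    plan <- NULL
    if (n_loci[i] > 0) {
      plan <- with_seed(derive_seed(seed, 200 + i), {
        # hotspot chromosome receives ~40% of planted loci
        pchrom <- ifelse(chroms == hotspot_chrom, 0.4,
                         0.6 / (length(chroms) - 1))
        data.frame(
          chrom = sample(chroms, n_loci[i], replace = TRUE, prob = pchrom),
          centre = round(stats::runif(n_loci[i], 2e6,
                                      min(genome$chromosomes$length) - 2e6)),
          n = sample(8:12, n_loci[i], replace = TRUE),
          apobec = TRUE,
          stringsAsFactors = FALSE
        )
      })
    }
    kat_plan_list[[i]] <- if (is.null(plan)) NULL else
      cbind(sample_id = samples[i], plan)
    snv_list[[i]] <- simulate_snvs(genome, ref_sigs, true_expo[i, ],
                                   n_mut = n_mut, kataegis_plan = plan,
                                   seed = si, sample_id = samples[i])
    # SV class weights = mixture of reference RS profiles; complex
    # samples add clustered mass placed on the hotspot chromosome
    w <- as.numeric(rs_expo[i, ] %*% ref_rs$profiles)
    clustered_region <- NULL
    cl_idx <- parse_sv_channel(sv_channels())$clustered
    if (complex_flag[i]) {
      # clustered breakpoints land on the oscillating chromosome so the
      # planted event carries both SV and copy-number evidence
      w[cl_idx] <- w[cl_idx] + 0.6 / sum(cl_idx)
      Lc <- chrom_length_of(genome, complex_chrom)
      clustered_region <- list(chrom = complex_chrom,
                               start = round(0.6 * Lc),
                               end = round(0.6 * Lc) + 2e6)
    } else {
      w[cl_idx] <- 0 # quiet genomes carry no clustered classes
    }
    w <- w / sum(w)
    sv_i <- simulate_svs(genome, w, n_sv = n_sv,
                         clustered_region = clustered_region,
                         seed = derive_seed(seed, 300 + i),
                         sample_id = samples[i])
    # kataegis frequently sits at rearrangement breakpoints: each planted
    # hotspot locus gets an accompanying small deletion
    if (!is.null(plan) && any(plan$chrom == hotspot_chrom)) {
      hp <- plan[plan$chrom == hotspot_chrom, , drop = FALSE]
      co_sv <- with_seed(derive_seed(seed, 500 + i), {
        sz <- sample.int(5000L, nrow(hp), replace = TRUE) + 1000L
        data.frame(sample_id = samples[i], chrom1 = hotspot_chrom,
                   pos1 = hp$centre + 500L, chrom2 = hotspot_chrom,
                   pos2 = hp$centre + 500L + sz, sv_type = "DEL",
                   size = sz, orientation = NA_character_,
                   clustered = NA, stringsAsFactors = FALSE)
      })
      sv_i <- rbind(sv_i, co_sv)
    }
    sv_list[[i]] <- sv_i
    seg_list[[i]] <- simulate_cn_profile(
      genome, target_ploidy = ploidy[i], subclonal_pct = subclonal[i],
      complex_chrom = if (complex_flag[i]) complex_chrom else NULL,
      seed = derive_seed(seed, 400 + i), sample_id = samples[i]
    )
  }
  snvs <- do.call(rbind, snv_list)
  svs <- do.call(rbind, sv_list)
  segments <- do.call(rbind, seg_list)

  gene_sets <- default_immune_gene_sets(n_genes)
  per_cluster <- rep(n_samples %/% 4, 4)
  per_cluster[seq_len(n_samples %% 4)] <- per_cluster[seq_len(n_samples %% 4)] + 1
  sim_expr <- simulate_expression(n_genes, per_cluster, gene_sets,
                                  separation = separation,
                                  noise_sd = noise_sd,
                                  seed = derive_seed(seed, 2))
  # shuffle archetype assignment across samples
  perm <- with_seed(derive_seed(seed, 3), sample(n_samples))
  expr <- sim_expr$expr[, order(perm), drop = FALSE]
  colnames(expr) <- samples
  labels <- sim_expr$labels[order(perm)]
  clinical <- simulate_clinical(labels,
                                hazard_by_cluster = hazard_by_cluster,
                                seed = derive_seed(seed, 4),
                                sample_ids = samples)

  kat_plans <- do.call(rbind, kat_plan_list)
  if (is.null(kat_plans)) {
    kat_plans <- data.frame(sample_id = character(0), chrom = character(0),
                            centre = numeric(0), n = integer(0),
                            apobec = logical(0))
  }
  truth <- list(
    samples = samples,
    exposures = true_expo,
    rs_exposures = rs_expo,
    kataegis_plan = kat_plans,
    n_kataegis = n_loci,
    complex = complex_flag,
    ploidy = ploidy,
    subclonal_pct = subclonal,
    immune_cluster = labels,
    hotspot_chrom = hotspot_chrom,
    complex_chrom = complex_chrom,
    hazard_by_cluster = hazard_by_cluster
  )
  cohort <- list(snvs = snvs, svs = svs, segments = segments, expr = expr,
                 gene_sets = gene_sets, clinical = clinical,
                 samples = samples, genome = genome,
                 ref_snv_signatures = ref_sigs, ref_rs_signatures = ref_rs,
                 truth = truth)
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' Write a simulated cohort to standard files
#'
#' Per-sample VCFs under `vcf/`, a cohort BEDPE, segments / expression /
#' clinical TSVs, the immune gene sets as GMT, the reference signature
#' matrices as TSV, the genome table, and `truth.json`.
#'
#' @param cohort result of [simulate_cohort()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(file.path(out_dir, "vcf"), recursive = TRUE,
             showWarnings = FALSE)
  for (sid in cohort$samples) {
    write_vcf(cohort$snvs[cohort$snvs$sample_id == sid, , drop = FALSE],
              file.path(out_dir, "vcf", paste0(sid, ".vcf")))
  }
  write_bedpe(cohort$svs, file.path(out_dir, "svs.bedpe"))
  write_segments(cohort$segments, file.path(out_dir, "segments.tsv"))
  write_expression(cohort$expr, file.path(out_dir, "expression.tsv"))
  write_clinical(cohort$clinical, file.path(out_dir, "clinical.tsv"))
  write_gmt(cohort$gene_sets, file.path(out_dir, "immune_sets.gmt"))
  sig_tab <- data.frame(channel = colnames(cohort$ref_snv_signatures$profiles),
                        t(cohort$ref_snv_signatures$profiles),
                        check.names = FALSE)
  data.table::fwrite(sig_tab, file.path(out_dir, "reference_signatures.tsv"),
                     sep = "\t")
  rs_tab <- data.frame(channel = colnames(cohort$ref_rs_signatures$profiles),
                       t(cohort$ref_rs_signatures$profiles),
                       check.names = FALSE)
  data.table::fwrite(rs_tab, file.path(out_dir, "reference_rs.tsv"),
                     sep = "\t")
  data.table::fwrite(cohort$genome$chromosomes,
                     file.path(out_dir, "genome.tsv"), sep = "\t")
  truth <- cohort$truth
  truth$exposures <- as.data.frame(truth$exposures)
  truth$rs_exposures <- as.data.frame(truth$rs_exposures)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(out_dir)
}
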