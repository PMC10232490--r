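#' Per-bin kataegis and SV breakpoint counts (cohort-pooled)
#'
#' Divides every chromosome into fixed `bin`-width bins and counts, over
#' the whole cohort, (a) APOBEC kataegis loci — a locus increments every
#' bin it overlaps — and (b) SV breakpoints — each SV contributes both of
#' its breakends.
#'
#' @param loci cohort kataegis loci (typically APOBEC class only).
#' @param svs cohort SV records.
#' @param genome a `genome_model`.
#' @param bin bin width in bp (default 1 Mb).
#' @return data.frame: chrom, bin_start, kataegis, breakpoints.
#' @export
bin_counts <- function(loci, svs, genome, bin = 1e6) {
  chroms <- genome$chromosomes
  grids <- lapply(seq_len(nrow(chroms)), function(i) {
    n_bin <- ceiling(chroms$length[i] / bin)
    data.frame(chrom = chroms$chrom[i],
               bin_start = (seq_len(n_bin) - 1) * bin,
               kataegis = 0L, breakpoints = 0L,
               stringsAsFactors = FALSE)
  })
  names(grids) <- chroms$chrom
  bump <- function(chrom, b, col, add = 1L) {
    g <- grids[[chrom]]
    if (is.null(g)) stop("coordinates outside genome: ", chrom)
    if (any(b < 0 | b >= nrow(g))) stop("coordinates outside genome")
    tt <- table(b)
    g[[col]][as.integer(names(tt)) + 1L] <-
      g[[col]][as.integer(names(tt)) + 1L] + as.integer(tt)
    grids[[chrom]] <<- g
    invisible(NULL)
  }
  if (nrow(loci) > 0) {
    for (chrom in unique(loci$chrom)) {
      lc <- loci[loci$chrom == chrom, , drop = FALSE]
      # a locus increments every bin it overlaps
      b <- unlist(lapply(seq_len(nrow(lc)), function(j) {
        seq.int((lc$start[j] - 1) %/% bin, (lc$end[j] - 1) %/% bin)
      }))
      bump(chrom, b, "kataegis")
    }
  }
  if (nrow(svs) > 0) {
    ends <- rbind(
      data.frame(chrom = svs$chrom1, pos = svs$pos1),
      data.frame(chrom = svs$chrom2, pos = svs$pos2)
    )
    for (chrom in unique(ends$chrom)) {
      b <- (ends$pos[ends$chrom == chrom] - 1) %/% bin
      bump(chrom, b, "breakpoints")
    }
  }
  out <- do.call(rbind, grids)
  rownames(out) <- NULL
  out
}

#' Flag co-localised bins against genome-wide means
#'
#' A bin is flagged iff its kataegis count strictly exceeds the
#' genome-wide mean kataegis count per bin AND its breakpoint count
#' strictly exceeds the genome-wide mean breakpoint count per bin. With
#' `z > 0` the thresholds become mean + z * sd (Gaussian-threshold
#' variant). The genome-wide mean co-localised frequency is the mean over
#' chromosomes of the per-chromosome flagged-bin percentage.
#'
#' @param grid result of [bin_counts()].
#' @param z optional z-score threshold multiplier (default 0 = mean
#'   rule).
#' @return list: `grid` (with `colocalized` flag), `per_chromosome`
#'   (chrom, n_bins, n_flagged, coloc_freq in percent), `mean_frequency`
#'   (percent).
#' @export
flag_colocalized_bins <- function(grid, z = 0) {
  if (nrow(grid) == 0) stop("empty grid")
  thr_k <- mean(grid$kataegis) + z * stats::sd(grid$kataegis)
  thr_s <- mean(grid$breakpoints) + z * stats::sd(grid$breakpoints)
  grid$colocalized <- grid$kataegis > thr_k & grid$breakpoints > thr_s
  per <- do.call(rbind, lapply(split(grid, grid$chrom), function(g) {
    data.frame(chrom = g$chrom[1], n_bins = nrow(g),
               n_flagged = sum(g$colocalized),
               coloc_freq = 100 * mean(g$colocalized),
               stringsAsFactors = FALSE)
  }))
  per <- per[match(unique(grid$chrom), per$chrom), , drop = FALSE]
  rownames(per) <- NULL
  list(grid = grid, per_chromosome = per,
       mean_frequency = mean(per$coloc_freq))
}

#' Flag chromosomes enriched for co-localised events
#'
#' A chromosome is enriched iff its co-localised frequency strictly
#' exceeds the genome-wide mean frequency (recomputed from the data,
#' never hard-coded).
#'
#' @param per_chromosome per-chromosome table from
#'   [flag_colocalized_bins()].
#' @param mean_frequency genome-wide mean co-localised frequency
#'   (percent).
#' @return `per_chromosome` with an `enriched` logical column.
#' @export
chromosome_enrichment <- function(per_chromosome, mean_frequency) {
  per_chromosome$enriched <- per_chromosome$coloc_freq > mean_frequency
  per_chromosome
}

#' Per-chromosome kataegis frequency across a cohort
#'
#' Proportion of cohort samples with at least one APOBEC kataegis locus
#' on the chromosome, as a percent.
#'
#' @param loci cohort kataegis loci (APOBEC class).
#' @param samples all cohort sample ids (defines the denominator).
#' @param genome a `genome_model`.
#' @return data.frame: chrom, kataegis_freq (percent).
#' @export
kataegis_frequency <- function(loci, samples, genome) {
  out <- data.frame(chrom = genome$chromosomes$chrom,
                    kataegis_freq = 0, stringsAsFactors = FALSE)
  if (nrow(loci) > 0) {
    for (i in seq_len(nrow(out))) {
      ch <- out$chrom[i]
      with_locus <- unique(loci$sample_id[loci$chrom == ch])
      out$kataegis_freq[i] <- 100 * length(intersect(with_locus, samples)) /
        length(samples)
    }
  }
  out
}

#' Combined-percent ranking of chromosomes
#'
#' Multiplies (a) the per-chromosome kataegis frequency by (b) the
#' per-chromosome co-localised bin frequency (both as proportions) and
#' ranks the resulting combined percent from high to low; ties share the
#' minimum rank.
#'
#' @param kataegis_freq data.frame from [kataegis_frequency()].
#' @param per_chromosome per-chromosome co-localisation table.
#' @return data.frame: chrom, kataegis_freq, coloc_freq,
#'   combined_percent, rank.
#' @export
combined_percent_ranking <- function(kataegis_freq, per_chromosome) {
  tab <- merge(kataegis_freq, per_chromosome[, c("chrom", "coloc_freq")],
               by = "chrom", sort = FALSE)
  tab$combined_percent <- tab$kataegis_freq * tab$coloc_freq / 100
  tab$rank <- rank(-tab$combined_percent, ties.method = "min")
  tab[order(tab$rank, match(tab$chrom, kataegis_freq$chrom)), ,
      drop = FALSE] -> tab
  rownames(tab) <- NULL
  tab
}

#' Full kataegis-SV co-localisation analysis
#'
#' @param loci cohort kataegis loci; only rows with class "APOBEC" are
#'   used.
#' @param svs cohort SV records.
#' @param samples cohort sample ids.
#' @param genome a `genome_model`.
#' @param bin bin width (default 1 Mb).
#' @param z Gaussian-threshold multiplier (default 0 = mean rule).
#' @return list: `grid`, `per_chromosome` (with enrichment flags and
#'   combined-percent ranking), `mean_frequency`.
#' @export
colocalization_analysis <- function(loci, svs, samples, genome,
                                    bin = 1e6, z = 0) {
  apo <- loci[loci$class == "APOBEC", , drop = FALSE]
  grid <- bin_counts(apo, svs, genome, bin = bin)
  fl <- flag_colocalized_bins(grid, z = z)
  per <- chromosome_enrichment(fl$per_chromosome, fl$mean_frequency)
  kf <- kataegis_frequency(apo, samples, genome)
  ranked <- combined_percent_ranking(kf, per)
  per <- merge(per, ranked[, c("chrom", "kataegis_freq",
                               "combined_percent", "rank")],
               by = "chrom", sort = FALSE)
  list(grid = fl$grid, per_chromosome = per,
       mean_frequency = fl$mean_frequency)
}
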