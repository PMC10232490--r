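#' Length-weighted mean total copy number (ploidy)
#'
#' @param segments one sample's CN segments.
#' @param genome a `genome_model` (coverage check: warns when segments
#'   cover <90% of the genome).
#' @return numeric ploidy.
#' @export
compute_ploidy <- function(segments, genome = NULL) {
  if (nrow(segments) == 0) stop("empty copy-number profile")
  len <- segments$end - segments$start
  if (!is.null(genome)) {
    if (sum(len) < 0.9 * genome_length(genome)) {
      warning("segments cover <90% of the genome")
    }
  }
  sum(segments$total_cn * len) / sum(len)
}

#' Categorise integer copy numbers
#'
#' 0 = homozygous deletion, 1 = loss, >= 6 = gain/amplification,
#' otherwise neutral-range.
#'
#' @param cn integer copy number vector (>= 0).
#' @return character vector of categories.
#' @export
categorize_cna <- function(cn) {
  if (any(cn < 0)) stop("negative copy number")
  out <- rep("neutral-range", length(cn))
  out[cn == 0] <- "homozygous-deletion"
  out[cn == 1] <- "loss"
  out[cn >= 6] <- "gain-amplification"
  out
}

#' Ploidy-corrected gene amplification call
#'
#' A gene is amplified when ploidy < 2.7 and its copy number is >= 6, or
#' ploidy >= 2.7 and its copy number is >= 9.
#'
#' @param gene_cn gene copy number (>= 0).
#' @param ploidy sample ploidy (> 0).
#' @return logical vector.
#' @export
gene_amplified <- function(gene_cn, ploidy) {
  if (any(gene_cn < 0)) stop("negative copy number")
  if (any(ploidy <= 0)) stop("ploidy must be positive")
  (ploidy < 2.7 & gene_cn >= 6) | (ploidy >= 2.7 & gene_cn >= 9)
}

#' Percent of the covered genome with altered copy number
#'
#' 100 x (bases with total_cn != 2) / (covered bases).
#'
#' @param segments one sample's CN segments.
#' @param genome optional `genome_model` for the coverage warning.
#' @return percent in \[0, 100\].
#' @export
percent_genome_altered <- function(segments, genome = NULL) {
  if (nrow(segments) == 0) stop("empty copy-number profile")
  len <- segments$end - segments$start
  if (!is.null(genome) && sum(len) < 0.9 * genome_length(genome)) {
    warning("segments cover <90% of the genome")
  }
  100 * sum(len[segments$total_cn != 2]) / sum(len)
}

#' Sub-clonal copy-number burden per chromosome and genome-wide
#'
#' Only segments with `subclonal_q < fdr_cut` count. Chromosome percent =
#' 100 x (summed significant segment length) / (chromosome length);
#' genome percent uses the total genome length.
#'
#' @param segments one sample's CN segments (with `subclonal_q`).
#' @param genome a `genome_model`.
#' @param fdr_cut FDR threshold (default 0.05).
#' @return list: `per_chromosome` (chrom, subclonal_pct), `genome_pct`.
#' @export
subclonal_cna_percent <- function(segments, genome, fdr_cut = 0.05) {
  chroms <- genome$chromosomes
  len <- segments$end - segments$start
  if (any(len > chrom_length_of(genome, segments$chrom))) {
    stop("segment longer than its chromosome")
  }
  sig <- !is.na(segments$subclonal_q) & segments$subclonal_q < fdr_cut
  per <- data.frame(chrom = chroms$chrom, subclonal_pct = 0,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(chroms))) {
    sel <- sig & segments$chrom == chroms$chrom[i]
    per$subclonal_pct[i] <- 100 * sum(len[sel]) / chroms$length[i]
  }
  list(per_chromosome = per,
       genome_pct = 100 * sum(len[sig]) / genome_length(genome))
}

# Smooth a chromosome's segments for LST counting: drop segments shorter
# than `min_len`, extend the surviving neighbours over the gap, and merge
# adjacent segments with identical (total, minor) state.
smooth_segments <- function(seg, min_len = 3e6) {
  seg <- seg[order(seg$start), , drop = FALSE]
  keep <- (seg$end - seg$start) >= min_len
  seg <- seg[keep, , drop = FALSE]
  if (nrow(seg) <= 1) return(seg)
  out <- seg[1, , drop = FALSE]
  for (i in 2:nrow(seg)) {
    last <- nrow(out)
    if (seg$total_cn[i] == out$total_cn[last] &&
        seg$minor_cn[i] == out$minor_cn[last]) {
      out$end[last] <- seg$end[i]
    } else {
      # close the gap left by dropped segments at the midpoint
      mid <- (out$end[last] + seg$start[i]) / 2
      out$end[last] <- mid
      seg$start[i] <- mid
      out <- rbind(out, seg[i, , drop = FALSE])
    }
  }
  out
}

#' HRD component scores (LOH, tAI, LST) and HRD-sum
#'
#' Component definitions follow the standard genomic-scar conventions:
#' LOH = segments with minor copy number 0, longer than `loh_min` (15 Mb)
#' and not spanning the whole chromosome; tAI = allelic-imbalance
#' segments (minor != major) reaching a telomere, not crossing the
#' centromere, longer than `tai_min` (11 Mb); LST = breakpoints between
#' adjacent segments both >= `lst_min` (10 Mb) after smoothing away
#' segments shorter than `smooth_min` (3 Mb). HRD-sum is the unweighted
#' sum of the three counts.
#'
#' @param segments one sample's allele-specific CN segments.
#' @param genome a `genome_model` with centromere positions.
#' @param loh_min,tai_min,lst_min,smooth_min length thresholds in bp.
#' @return list: loh, tai, lst, hrd_sum.
#' @export
hrd_components <- function(segments, genome, loh_min = 15e6,
                           tai_min = 11e6, lst_min = 10e6,
                           smooth_min = 3e6) {
  if (is.null(genome$chromosomes$centromere)) stop("missing centromere")
  loh <- 0L; tai <- 0L; lst <- 0L
  for (i in seq_len(nrow(genome$chromosomes))) {
    chrom <- genome$chromosomes$chrom[i]
    L <- genome$chromosomes$length[i]
    cent <- genome$chromosomes$centromere[i]
    seg <- segments[segments$chrom == chrom, , drop = FALSE]
    if (nrow(seg) == 0) next
    seg <- seg[order(seg$start), , drop = FALSE]
    len <- seg$end - seg$start
    whole <- seg$start <= 0 & seg$end >= L
    # LOH
    loh <- loh + sum(seg$minor_cn == 0 & seg$total_cn > 0 &
                       len > loh_min & !whole)
    # tAI
    major <- seg$total_cn - seg$minor_cn
    imbalanced <- seg$minor_cn != major
    telomeric <- seg$start <= 0 | seg$end >= L
    crosses_cent <- seg$start < cent & seg$end > cent
    tai <- tai + sum(imbalanced & telomeric & !crosses_cent &
                       len > tai_min & !whole)
    # LST on smoothed profile
    sm <- smooth_segments(seg, min_len = smooth_min)
    if (nrow(sm) >= 2) {
      smlen <- sm$end - sm$start
      for (j in 2:nrow(sm)) {
        state_change <- sm$total_cn[j] != sm$total_cn[j - 1] ||
          sm$minor_cn[j] != sm$minor_cn[j - 1]
        if (state_change && smlen[j] >= lst_min && smlen[j - 1] >= lst_min) {
          lst <- lst + 1L
        }
      }
    }
  }
  list(loh = as.integer(loh), tai = as.integer(tai), lst = as.integer(lst),
       hrd_sum = as.integer(loh + tai + lst))
}

#' Classify a sample as HRD
#'
#' HRD iff HRD-sum > 42 AND HRDetect probability > 0.7; indeterminate
#' when the HRDetect probability is absent but HRD-sum > 42; not-HRD
#' otherwise. The HRDetect probability is an external input (trained
#' classifier), never computed here.
#'
#' @param hrd_sum HRD-sum count.
#' @param hrdetect_prob HRDetect probability in \[0, 1\], or NA/NULL.
#' @param sum_cut,prob_cut call thresholds (defaults 42 and 0.7).
#' @return one of "HRD", "not-HRD", "indeterminate".
#' @export
classify_hrd <- function(hrd_sum, hrdetect_prob = NULL, sum_cut = 42,
                         prob_cut = 0.7) {
  if (is.null(hrdetect_prob) || is.na(hrdetect_prob)) {
    return(if (hrd_sum > sum_cut) "indeterminate" else "not-HRD")
  }
  if (hrdetect_prob < 0 || hrdetect_prob > 1) {
    stop("hrdetect_prob must be in [0, 1]")
  }
  if (hrd_sum > sum_cut && hrdetect_prob > prob_cut) "HRD" else "not-HRD"
}
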