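#' Simulate an allele-specific copy-number profile
#'
#' Builds per-chromosome integer segments whose length-weighted mean total
#' copy number equals `target_ploidy` (mixing `floor` and `floor + 1`
#' states in the exact proportions), with a planted sub-clonal block
#' covering `subclonal_pct` percent of each chromosome (flagged with
#' `subclonal_q` < 0.05 and carrying +1/-1 copy-number alterations that
#' cancel in the mean), and an optional chromothripsis-like chromosome
#' oscillating between two copy-number states.
#'
#' @param genome a `genome_model`.
#' @param target_ploidy desired length-weighted mean total copy number
#'   (>= 1).
#' @param subclonal_pct percent of the genome to flag sub-clonal, in
#'   \[0, 100\].
#' @param complex_chrom NULL or a chromosome name to fill with >= 7
#'   oscillations between two states.
#' @param seed integer seed.
#' @param sample_id sample identifier.
#' @return data.frame of segments: sample_id, chrom, start, end (0-based
#'   half-open), total_cn, minor_cn, subclonal_q (NA = clonal).
#' @export
simulate_cn_profile <- function(genome, target_ploidy = 2,
                                subclonal_pct = 0, complex_chrom = NULL,
                                seed = 1, sample_id = "S1") {
  stopifnot(inherits(genome, "genome_model"))
  if (subclonal_pct < 0 || subclonal_pct > 100) {
    stop("subclonal_pct must be in [0, 100]")
  }
  if (target_ploidy < 1) stop("target_ploidy must be >= 1")
  if (!is.null(complex_chrom) &&
      !complex_chrom %in% genome$chromosomes$chrom) {
    stop("unknown complex_chrom: ", complex_chrom)
  }

  split_mean <- function(total_mass, len) {
    # segments with integer CN whose length-weighted mean = total_mass/len
    m <- total_mass / len
    lo <- floor(m); hi <- lo + 1
    f <- m - lo
    hi_len <- round(f * len)
    segs <- list()
    if (len - hi_len > 0) segs[[1]] <- c(cn = lo, len = len - hi_len)
    if (hi_len > 0) segs[[length(segs) + 1]] <- c(cn = hi, len = hi_len)
    segs
  }

  out <- list()
  with_seed(seed, {
    for (i in seq_len(nrow(genome$chromosomes))) {
      chrom <- genome$chromosomes$chrom[i]
      L <- genome$chromosomes$length[i]
      P <- round(subclonal_pct / 100 * L)
      segs <- data.frame(start = numeric(0), end = numeric(0),
                         total_cn = integer(0), q = numeric(0))
      add_seg <- function(start, len, cn, q = NA_real_) {
        if (len <= 0) return(invisible(NULL))
        segs <<- rbind(segs, data.frame(start = start, end = start + len,
                                        total_cn = as.integer(cn), q = q))
        invisible(NULL)
      }
      if (identical(chrom, complex_chrom)) {
        # oscillating chromosome: 16 alternating segments of two states
        lo <- floor(target_ploidy); hi <- lo + 1
        f <- max(target_ploidy - lo, 0.04)
        n_pairs <- 8
        hi_len <- round(f * L / n_pairs)
        lo_len <- round(L / n_pairs) - hi_len
        pos <- 0
        for (p in seq_len(n_pairs)) {
          add_seg(pos, lo_len, lo); pos <- pos + lo_len
          add_seg(pos, hi_len, hi); pos <- pos + hi_len
        }
        if (pos < L) add_seg(pos, L - pos, lo)
        if (P > 0) {
          cut <- P
          segs$q <- ifelse(segs$start < cut, stats::runif(nrow(segs), 0, 0.049),
                           NA_real_)
          # split segments straddling the sub-clonal boundary
          hit <- which(segs$start < cut & segs$end > cut)
          if (length(hit) == 1) {
            s <- segs[hit, ]
            segs <- segs[-hit, ]
            segs <- rbind(segs,
                          data.frame(start = s$start, end = cut,
                                     total_cn = s$total_cn,
                                     q = stats::runif(1, 0, 0.049)),
                          data.frame(start = cut, end = s$end,
                                     total_cn = s$total_cn, q = NA_real_))
          }
        }
      } else {
        base <- floor(target_ploidy)
        if (P > 0 && base >= 1) {
          # balanced +1/-1 sub-clonal alteration block (mean = base)
          h1 <- floor(P / 2); h2 <- P - h1
          add_seg(0, h1, base + 1, q = stats::runif(1, 0, 0.049))
          add_seg(h1, h2, max(base - 1, 0), q = stats::runif(1, 0, 0.049))
          if (base - 1 < 0) segs$total_cn[nrow(segs)] <- base # safety
          rest_mass <- target_ploidy * L - base * P
        } else {
          P <- 0
          rest_mass <- target_ploidy * L
        }
        pos <- P
        for (s in split_mean(rest_mass, L - P)) {
          add_seg(pos, s["len"], s["cn"])
          pos <- pos + s["len"]
        }
      }
      segs <- segs[order(segs$start), , drop = FALSE]
      out[[i]] <- data.frame(
        sample_id = sample_id, chrom = chrom,
        start = segs$start, end = segs$end,
        total_cn = segs$total_cn,
        minor_cn = pmin(segs$total_cn %/% 2L, segs$total_cn),
        subclonal_q = segs$q,
        stringsAsFactors = FALSE
      )
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
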