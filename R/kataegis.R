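# BH step-up when only the s smallest of m p-values are materialised
# (the remaining m - s tests all have p = 1 and never lower a q-value).
bh_adjust_partial <- function(p, m) {
  s <- length(p)
  if (s == 0) return(numeric(0))
  if (m < s) stop("m must be >= length(p)")
  ord <- order(p)
  ranked <- p[ord] * m / seq_len(s)
  q <- rev(cummin(rev(pmin(ranked, 1))))
  out <- numeric(s)
  out[ord] <- q
  out
}

#' Sliding-window hypermutation statistics for one sample
#'
#' Scans fixed sliding windows along every chromosome and computes, for
#' each window holding at least one mutation, the exact binomial
#' upper-tail p-value of its mutation count under a uniform per-bp rate
#' (that chromosome's mutation total divided by its length), plus the
#' smallest of the 32 per-trinucleotide exact binomial p-values (window
#' trinucleotide composition against the chromosome's trinucleotide
#' frequencies). Windows with zero mutations have p = 1 and are not
#' materialised, but they count toward the family size used for BH
#' adjustment.
#'
#' @param snvs SNV records of a single sample.
#' @param genome a `genome_model`.
#' @param window window width in bp (default 10 kb).
#' @param step step between window starts in bp (default 5 kb).
#' @return data.frame (chrom, start, end, n_mut, p_count, p_trinuc_min)
#'   with attribute `n_windows_total` = number of windows scanned.
#' @export
scan_windows <- function(snvs, genome, window = 1e4, step = 5e3) {
  if (window <= 0 || step <= 0) stop("window and step must be positive")
  if (length(unique(snvs$sample_id)) > 1) {
    stop("scan_windows expects a single sample")
  }
  tri_levels <- trinucleotides_32()
  res <- list()
  n_windows_total <- 0
  for (ci in seq_len(nrow(genome$chromosomes))) {
    chrom <- genome$chromosomes$chrom[ci]
    L <- genome$chromosomes$length[ci]
    n_win <- max(0L, floor((L - window) / step) + 1)
    n_windows_total <- n_windows_total + n_win
    muts <- snvs[snvs$chrom == chrom, , drop = FALSE]
    n_c <- nrow(muts)
    if (n_c == 0 || n_win == 0) next
    pos <- muts$pos
    # window j (0-based) covers (j*step, j*step + window]
    j_hi <- pmin((pos - 1) %/% step, n_win - 1)
    j_lo <- pmax(ceiling((pos - window) / step), 0)
    span <- max(j_hi - j_lo) + 1
    hits <- integer(0); mut_of <- integer(0)
    for (r in seq_len(span) - 1L) {
      j <- j_lo + r
      ok <- j <= j_hi
      hits <- c(hits, j[ok])
      mut_of <- c(mut_of, which(ok))
    }
    counts <- table(hits)
    widx <- as.integer(names(counts))
    k <- as.integer(counts)
    rate <- n_c / L
    p_count <- stats::pbinom(k - 1, size = window, prob = rate,
                             lower.tail = FALSE)
    # trinucleotide composition tests per materialised window
    tri_idx <- match(muts$context3, tri_levels)
    p0 <- genome$trinuc_freq[chrom, ]
    grp <- match(hits, widx)
    tri_counts <- matrix(0L, nrow = length(widx), ncol = 32)
    for (t in seq_len(32)) {
      sel <- tri_idx[mut_of] == t
      if (any(sel)) {
        tt <- table(grp[sel])
        tri_counts[as.integer(names(tt)), t] <- as.integer(tt)
      }
    }
    p_tri <- matrix(stats::pbinom(tri_counts - 1,
                                  size = rep(k, times = 32),
                                  prob = rep(p0, each = length(widx)),
                                  lower.tail = FALSE),
                    nrow = length(widx))
    res[[length(res) + 1]] <- data.frame(
      chrom = chrom,
      start = widx * step,
      end = widx * step + window,
      n_mut = k,
      p_count = p_count,
      p_trinuc_min = apply(p_tri, 1, min),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(res) > 0) do.call(rbind, res) else {
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               n_mut = integer(0), p_count = numeric(0),
               p_trinuc_min = numeric(0))
  }
  rownames(out) <- NULL
  attr(out, "n_windows_total") <- n_windows_total
  out
}

#' Call kataegis loci from window statistics
#'
#' BH-adjusts the window count p-values (pooled across all windows of
#' the sample, including empty ones), merges overlapping significant
#' windows, and keeps a merged region as a kataegis locus iff it holds at
#' least `min_mut` mutations whose mean inter-mutation distance is at
#' most `max_imd`. Loci are trimmed to their member-mutation span and
#' classified APOBEC/non-APOBEC via [classify_apobec()].
#'
#' @param snvs the same single-sample SNV records passed to
#'   [scan_windows()].
#' @param windows result of [scan_windows()].
#' @param genome a `genome_model`.
#' @param min_mut minimum mutations per locus (default 6).
#' @param max_imd maximum mean inter-mutation distance in bp
#'   (default 2000).
#' @param q_cut FDR cutoff on window q-values (default 0.05).
#' @param apobec_cutoff APOBEC score classification cutoff (default 0.5).
#' @return data.frame of loci: sample_id, chrom, start, end, n_mut,
#'   hypermutation_score, apobec_score, q_value, class.
#' @export
call_kataegis_loci <- function(snvs, windows, genome, min_mut = 6,
                               max_imd = 2000, q_cut = 0.05,
                               apobec_cutoff = 0.5) {
  empty <- data.frame(sample_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      n_mut = integer(0), hypermutation_score = numeric(0),
                      apobec_score = numeric(0), q_value = numeric(0),
                      class = character(0), stringsAsFactors = FALSE)
  if (nrow(windows) == 0) return(empty)
  m <- attr(windows, "n_windows_total") %||% nrow(windows)
  windows$q <- bh_adjust_partial(windows$p_count, m)
  sig <- windows[windows$q < q_cut, , drop = FALSE]
  if (nrow(sig) == 0) return(empty)
  sid <- unique(snvs$sample_id)
  loci <- list()
  for (chrom in unique(sig$chrom)) {
    sw <- sig[sig$chrom == chrom, , drop = FALSE]
    L <- chrom_length_of(genome, chrom)
    n_chrom <- sum(snvs$chrom == chrom)
    merged <- IRanges::reduce(IRanges::IRanges(start = sw$start + 1,
                                               end = sw$end))
    for (i in seq_len(length(merged))) {
      lo <- IRanges::start(merged)[i]; hi <- IRanges::end(merged)[i]
      mem <- snvs[snvs$chrom == chrom & snvs$pos >= lo & snvs$pos <= hi, ,
                  drop = FALSE]
      n <- nrow(mem)
      if (n < min_mut) next
      imd <- mean(diff(sort(mem$pos)))
      if (imd > max_imd) next
      start <- min(mem$pos); end <- max(mem$pos) + 1
      dens <- n / (end - start)
      score <- dens / (n_chrom / L)
      apo <- classify_apobec(mem, cutoff = apobec_cutoff)
      loci[[length(loci) + 1]] <- data.frame(
        sample_id = sid, chrom = chrom, start = start, end = end,
        n_mut = n, hypermutation_score = score,
        apobec_score = apo$score,
        q_value = min(sw$q[sw$start + 1 <= hi & sw$end >= lo]),
        class = apo$class, stringsAsFactors = FALSE
      )
    }
  }
  if (length(loci) == 0) return(empty)
  out <- do.call(rbind, loci)
  rownames(out) <- NULL
  out
}

#' APOBEC classification of a kataegis locus
#'
#' The APOBEC score is the fraction of member mutations that are C>T or
#' C>G at a TCA or TCT (TpCpW) pyrimidine-strand context; the locus is
#' APOBEC iff the score reaches `cutoff` (boundary inclusive).
#'
#' @param mutations member SNV records (must carry `context3`,
#'   `subst_class`).
#' @param cutoff classification cutoff (default 0.5).
#' @return list with `score` and `class` ("APOBEC"/"non-APOBEC").
#' @export
classify_apobec <- function(mutations, cutoff = 0.5) {
  if (nrow(mutations) == 0) stop("empty locus")
  hit <- mutations$subst_class %in% c("C>T", "C>G") &
    mutations$context3 %in% APOBEC_CONTEXTS
  score <- mean(hit)
  list(score = score,
       class = if (score >= cutoff) "APOBEC" else "non-APOBEC")
}

#' Detect kataegis loci for one sample
#'
#' Convenience wrapper: [scan_windows()] then [call_kataegis_loci()].
#'
#' @inheritParams scan_windows
#' @inheritParams call_kataegis_loci
#' @return data.frame of kataegis loci.
#' @export
detect_kataegis <- function(snvs, genome, window = 1e4, step = 5e3,
                            min_mut = 6, max_imd = 2000, q_cut = 0.05,
                            apobec_cutoff = 0.5) {
  w <- scan_windows(snvs, genome, window = window, step = step)
  call_kataegis_loci(snvs, w, genome, min_mut = min_mut,
                     max_imd = max_imd, q_cut = q_cut,
                     apobec_cutoff = apobec_cutoff)
}
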