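#' Clusters of interleaved SVs on one chromosome
#'
#' Two intra-chromosomal SVs interleave when their breakend intervals
#' overlap without one containing the other. Clusters are the connected
#' components of the interleaving graph.
#'
#' @param svs intra-chromosomal SV records of one sample and chromosome.
#' @return list: `membership` (cluster id per SV), `clusters` data.frame
#'   (cluster, n_interleaved, span_start, span_end).
#' @export
detect_interleaved_clusters <- function(svs) {
  n <- nrow(svs)
  if (n == 0) {
    return(list(membership = integer(0),
                clusters = data.frame(cluster = integer(0),
                                      n_interleaved = integer(0),
                                      span_start = numeric(0),
                                      span_end = numeric(0))))
  }
  lo <- pmin(svs$pos1, svs$pos2)
  hi <- pmax(svs$pos1, svs$pos2)
  edges <- integer(0)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        interleave <- (lo[i] < lo[j] && lo[j] < hi[i] && hi[i] < hi[j]) ||
          (lo[j] < lo[i] && lo[i] < hi[j] && hi[j] < hi[i])
        if (interleave) edges <- c(edges, i, j)
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  membership <- as.integer(comp$membership)
  clusters <- do.call(rbind, lapply(seq_len(comp$no), function(cid) {
    idx <- which(membership == cid)
    data.frame(cluster = cid, n_interleaved = length(idx),
               span_start = min(lo[idx]), span_end = max(hi[idx]))
  }))
  list(membership = membership, clusters = clusters)
}

# longest run of consecutive alternations confined to at most
# `max_states` distinct copy-number values; returns alternation steps
osc_steps <- function(states, max_states) {
  n <- length(states)
  best <- 0L
  for (i in seq_len(n)) {
    vals <- states[i]
    j <- i
    while (j < n && states[j + 1] != states[j]) {
      vals2 <- union(vals, states[j + 1])
      if (length(vals2) > max_states) break
      vals <- vals2
      j <- j + 1
    }
    best <- max(best, j - i)
  }
  as.integer(best)
}

#' Copy-number oscillation counts for one chromosome
#'
#' Longest run of consecutive alternating segments confined to two
#' distinct copy-number states, and separately to at most three,
#' returned as numbers of alternation steps.
#'
#' @param segments CN segments of one chromosome, ordered by position.
#' @return list: `two_state`, `three_state`.
#' @export
count_oscillations <- function(segments) {
  if (nrow(segments) == 0) stop("empty segment list")
  states <- segments$total_cn[order(segments$start)]
  list(two_state = osc_steps(states, 2L),
       three_state = osc_steps(states, 3L))
}

.exp_ks_null_cache <- new.env(parent = emptyenv())

exp_ks_stat <- function(gaps) {
  # KS distance between the gap ECDF and Exp(1/mean(gaps)); the statistic
  # is scale-free, so its null distribution depends on n only
  n <- length(gaps)
  x <- sort(gaps) / mean(gaps)
  cdf <- 1 - exp(-x)
  max(pmax(abs(seq_len(n) / n - cdf), abs(cdf - (seq_len(n) - 1) / n)))
}

#' Exponential goodness-of-fit test for breakpoint spacings
#'
#' Tests the inter-breakpoint distances against the exponential law
#' implied by a homogeneous placement of the breakpoints. With
#' `region_length` supplied (the usual case: the chromosome carrying the
#' breakpoints), the null rate is known — breakpoint count divided by
#' region length — and a one-sample Kolmogorov-Smirnov test applies
#' directly; locally clustered breakpoints then produce far shorter
#' spacings than the chromosome-wide rate predicts and the test rejects.
#' Without `region_length`, the rate is estimated from the spacings
#' themselves and the (scale-free) KS statistic is compared with a
#' cached Monte-Carlo null.
#'
#' @param positions breakpoint positions (>= 3 required).
#' @param region_length optional length of the region the breakpoints
#'   could have fallen in (defines the known null rate).
#' @param n_sim Monte-Carlo replicates for the estimated-rate fall-back
#'   (default 500).
#' @return p-value, or NA ("not testable") for fewer than 3 breakpoints.
#' @export
breakpoint_exponential_test <- function(positions, region_length = NULL,
                                        n_sim = 500) {
  if (length(positions) < 3) return(NA_real_)
  gaps <- diff(sort(positions))
  gaps <- pmax(gaps, 1e-9)
  if (!is.null(region_length)) {
    rate <- length(positions) / region_length
    return(suppressWarnings(
      stats::ks.test(gaps, "pexp", rate = rate)$p.value))
  }
  D <- exp_ks_stat(gaps)
  key <- paste0("n", length(gaps), "_", n_sim)
  null <- .exp_ks_null_cache[[key]]
  if (is.null(null)) {
    null <- with_seed(20431L + length(gaps), {
      vapply(seq_len(n_sim), function(i) {
        exp_ks_stat(stats::rexp(length(gaps)))
      }, numeric(1))
    })
    .exp_ks_null_cache[[key]] <- null
  }
  (1 + sum(null >= D)) / (n_sim + 1)
}

#' Chromosomal breakpoint enrichment test
#'
#' Binomial upper-tail test of each chromosome's breakpoint count with
#' success probability = chromosome length / genome length, BH-adjusted
#' across chromosomes.
#'
#' @param bp_counts named integer vector, breakpoints per chromosome.
#' @param genome a `genome_model`.
#' @return data.frame: chrom, n_bp, p, q.
#' @export
chromosomal_enrichment_test <- function(bp_counts, genome) {
  chroms <- genome$chromosomes
  counts <- stats::setNames(rep(0L, nrow(chroms)), chroms$chrom)
  counts[names(bp_counts)] <- as.integer(bp_counts)
  N <- sum(counts)
  p <- vapply(seq_len(nrow(chroms)), function(i) {
    if (N == 0) return(1)
    stats::pbinom(counts[i] - 1, size = N,
                  prob = chroms$length[i] / sum(chroms$length),
                  lower.tail = FALSE)
  }, numeric(1))
  data.frame(chrom = chroms$chrom, n_bp = as.integer(counts), p = p,
             q = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Fragment-joins composition test for an SV cluster
#'
#' Multinomial goodness-of-fit of the four join types (DEL-like,
#' DUP-like, head-to-head inversion, tail-to-tail inversion) against
#' equal proportions; chi-square with a simulated p-value when expected
#' counts are small. Inversions without an orientation are split evenly
#' between the two inversion join types.
#'
#' @param svs SV records of one cluster (>= 1 record).
#' @return p-value in \[0, 1\].
#' @export
fragment_joins_test <- function(svs) {
  if (nrow(svs) == 0) stop("cluster must contain at least one SV")
  counts <- c(del = sum(svs$sv_type == "DEL"),
              dup = sum(svs$sv_type == "DUP"),
              h2h = 0L, t2t = 0L)
  inv <- svs$sv_type == "INV"
  ori <- svs$orientation[inv]
  counts["h2h"] <- sum(ori == "h2h", na.rm = TRUE)
  counts["t2t"] <- sum(ori == "t2t", na.rm = TRUE)
  n_na <- sum(is.na(ori) | !ori %in% c("h2h", "t2t"))
  if (n_na > 0) { # even split, remainder to h2h
    counts["h2h"] <- counts["h2h"] + ceiling(n_na / 2)
    counts["t2t"] <- counts["t2t"] + floor(n_na / 2)
  }
  n <- sum(counts)
  if (n == 0) return(1) # translocation-only cluster: no joins to test
  if (min(n / 4) < 5) {
    with_seed(57L, {
      p <- stats::chisq.test(counts, p = rep(0.25, 4),
                             simulate.p.value = TRUE, B = 2000)$p.value
    })
  } else {
    p <- stats::chisq.test(counts, p = rep(0.25, 4))$p.value
  }
  p
}

#' Call complex (chromothripsis-like) events for one sample
#'
#' Per chromosome, gathers the component evidence — largest interleaved
#' SV cluster size, copy-number oscillation steps (two/three states),
#' chromosomal breakpoint enrichment q, exponential-spacing q (computed
#' on the chromosome's breakpoints, BH across tested chromosomes), and
#' fragment-joins q for the largest cluster — and calls an event under
#' criterion A (interleaved > 10, oscillations > 6, q_enrichment < 0.05,
#' q_exponential < 0.05, q_joins < 0.2) or criterion B (interleaved > 30
#' and q_exponential < 0.05). The sample is a complex genome when at
#' least `min_events` chromosomes are called.
#'
#' @param svs one sample's SV records.
#' @param segments the sample's CN segments.
#' @param genome a `genome_model`.
#' @param min_events called events needed for the complex-genome flag
#'   (default 1).
#' @return list: `calls` (per-chromosome evidence data.frame),
#'   `complex_genome` (logical).
#' @export
call_complex_events <- function(svs, segments, genome, min_events = 1) {
  chroms <- genome$chromosomes$chrom
  # breakpoints per chromosome (both breakends)
  ends <- rbind(data.frame(chrom = svs$chrom1, pos = svs$pos1),
                data.frame(chrom = svs$chrom2, pos = svs$pos2))
  bp_counts <- table(factor(ends$chrom, levels = chroms))
  enr <- chromosomal_enrichment_test(bp_counts, genome)
  rows <- list()
  p_exp <- rep(NA_real_, length(chroms))
  p_joins <- rep(NA_real_, length(chroms))
  for (i in seq_along(chroms)) {
    ch <- chroms[i]
    intra <- svs[svs$chrom1 == ch & svs$chrom2 == ch, , drop = FALSE]
    cl <- detect_interleaved_clusters(intra)
    if (nrow(cl$clusters) > 0) {
      top <- which.max(cl$clusters$n_interleaved)
      n_inter <- cl$clusters$n_interleaved[top]
      members <- which(cl$membership == top)
      p_joins[i] <- fragment_joins_test(intra[members, , drop = FALSE])
    } else {
      n_inter <- 0L
    }
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    osc <- if (nrow(seg) > 0) count_oscillations(seg) else
      list(two_state = 0L, three_state = 0L)
    pos <- ends$pos[ends$chrom == ch]
    p_exp[i] <- breakpoint_exponential_test(
      pos, region_length = genome$chromosomes$length[i])
    rows[[i]] <- data.frame(
      sample_id = if (nrow(svs) > 0) svs$sample_id[1] else NA_character_,
      chrom = ch, n_breakpoints = as.integer(bp_counts[i]),
      n_interleaved = as.integer(n_inter),
      osc_two_state = osc$two_state, osc_three_state = osc$three_state,
      stringsAsFactors = FALSE
    )
  }
  calls <- do.call(rbind, rows)
  calls$q_enrichment <- enr$q
  tested <- !is.na(p_exp)
  calls$q_exponential <- NA_real_
  calls$q_exponential[tested] <- stats::p.adjust(p_exp[tested],
                                                 method = "BH")
  tested_j <- !is.na(p_joins)
  calls$q_joins <- NA_real_
  calls$q_joins[tested_j] <- stats::p.adjust(p_joins[tested_j],
                                             method = "BH")
  osc_max <- pmax(calls$osc_two_state, calls$osc_three_state)
  crit_a <- calls$n_interleaved > 10 & osc_max > 6 &
    !is.na(calls$q_enrichment) & calls$q_enrichment < 0.05 &
    !is.na(calls$q_exponential) & calls$q_exponential < 0.05 &
    !is.na(calls$q_joins) & calls$q_joins < 0.2
  crit_b <- calls$n_interleaved > 30 &
    !is.na(calls$q_exponential) & calls$q_exponential < 0.05
  calls$criterion <- ifelse(crit_a, "A", ifelse(crit_b, "B", NA))
  calls$called <- crit_a | crit_b
  list(calls = calls, complex_genome = sum(calls$called) >= min_events)
}
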