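channel_to_record <- function(channel) {
  # "A[C>T]G" -> list(context3 = "ACG", subst_class = "C>T")
  f5 <- substr(channel, 1, 1)
  cls <- substr(channel, 3, 5)
  f3 <- substr(channel, 7, 7)
  list(context3 = paste0(f5, substr(cls, 1, 1), f3), subst_class = cls)
}

new_snv_table <- function(n = 0) {
  data.frame(sample_id = character(n), chrom = character(n),
             pos = integer(n), ref = character(n), alt = character(n),
             context3 = character(n), subst_class = character(n),
             stringsAsFactors = FALSE)
}

#' Simulate somatic SNVs from signature exposures with planted kataegis
#'
#' Background mutations are drawn i.i.d. from the exposure-weighted
#' mixture of the 96-context signature distributions; chromosomes are
#' chosen proportional to length and positions uniformly. Each planted
#' kataegis cluster places its `n` mutations with successive
#' inter-mutation distances drawn uniformly from 1..2000 bp; APOBEC
#' clusters use only C>T/C>G substitutions at TCA/TCT contexts,
#' non-APOBEC clusters draw from the background mixture with those
#' channels removed. Reference and alternate alleles are reported on the
#' pyrimidine strand (no reference FASTA is consulted; the 3-base context
#' travels with the record).
#'
#' @param genome a `genome_model`.
#' @param signatures a `signature_set` over the 96 channels.
#' @param exposures simplex vector, one weight per signature.
#' @param n_mut number of background mutations (>= 0).
#' @param kataegis_plan NULL or data.frame with columns `chrom`, `centre`,
#'   `n`, `apobec` (logical).
#' @param seed integer seed.
#' @param sample_id sample identifier stored on every record.
#' @return data.frame of SNV records (sample_id, chrom, pos, ref, alt,
#'   context3, subst_class), sorted by chromosome then position.
#' @export
simulate_snvs <- function(genome, signatures, exposures, n_mut,
                          kataegis_plan = NULL, seed = 1,
                          sample_id = "S1") {
  stopifnot(inherits(genome, "genome_model"),
            inherits(signatures, "signature_set"))
  if (length(exposures) != nrow(signatures$profiles)) {
    stop("exposures must match the signature count")
  }
  assert_simplex(exposures, "exposures")
  if (n_mut < 0) stop("n_mut must be >= 0")
  ch <- snv_channels()
  mix <- as.numeric(exposures %*% signatures$profiles)
  mix <- mix / sum(mix)
  apobec_ch <- c("T[C>T]A", "T[C>T]T", "T[C>G]A", "T[C>G]T")

  with_seed(seed, {
    parts <- list()
    if (n_mut > 0) {
      chan <- sample(ch, n_mut, replace = TRUE, prob = mix)
      lens <- genome$chromosomes$length
      ci <- sample(seq_along(lens), n_mut, replace = TRUE,
                   prob = lens / sum(lens))
      pos <- 1L + as.integer(floor(stats::runif(n_mut) * (lens[ci] - 1)))
      parts[[1]] <- data.frame(chrom = genome$chromosomes$chrom[ci],
                               pos = pos, channel = chan,
                               stringsAsFactors = FALSE)
    }
    if (!is.null(kataegis_plan) && nrow(kataegis_plan) > 0) {
      for (i in seq_len(nrow(kataegis_plan))) {
        kp <- kataegis_plan[i, ]
        L <- chrom_length_of(genome, kp$chrom)
        n <- kp$n
        gaps <- if (n > 1) sample.int(2000L, n - 1, replace = TRUE) else integer(0)
        pos <- as.integer(kp$centre) + c(0L, cumsum(gaps))
        pos <- pmin(pmax(pos, 1L), L)
        if (isTRUE(kp$apobec)) {
          chan <- sample(apobec_ch, n, replace = TRUE,
                         prob = c(0.4, 0.4, 0.1, 0.1))
        } else {
          w <- mix
          w[ch %in% apobec_ch] <- 0
          if (sum(w) == 0) w <- rep(1, 96) * !(ch %in% apobec_ch)
          chan <- sample(ch, n, replace = TRUE, prob = w / sum(w))
        }
        parts[[length(parts) + 1L]] <-
          data.frame(chrom = kp$chrom, pos = pos, channel = chan,
                     stringsAsFactors = FALSE)
      }
    }
  })
  if (length(parts) == 0) return(new_snv_table(0))
  tab <- do.call(rbind, parts)
  info <- channel_to_record(tab$channel)
  out <- data.frame(
    sample_id = sample_id,
    chrom = tab$chrom,
    pos = tab$pos,
    ref = substr(info$context3, 2, 2),
    alt = substr(info$subst_class, 3, 3),
    context3 = info$context3,
    subst_class = info$subst_class,
    stringsAsFactors = FALSE
  )
  out[order(match(out$chrom, genome$chromosomes$chrom), out$pos), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
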