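#' Build a toy genome model
#'
#' A genome model carries chromosome names, lengths, centromere positions
#' and per-chromosome pyrimidine-strand trinucleotide frequencies. The
#' default desk-scale genome is 22 chromosomes of 100 Mb each; GRCh37
#' lengths can be loaded with [load_genome_table()]. Trinucleotide
#' proportions are drawn from a symmetric Dirichlet(5) per chromosome:
#' mildly non-uniform, strictly positive.
#'
#' @param n_chrom number of chromosomes (>= 1).
#' @param chrom_length chromosome length in bp (single value or one per
#'   chromosome, each >= 10 Mb).
#' @param seed integer seed; the model is deterministic given the seed.
#' @return object of class `genome_model`: list with `chromosomes`
#'   (data.frame: chrom, length, centromere) and `trinuc_freq`
#'   (n_chrom x 32 matrix, rows sum to 1).
#' @export
generate_genome <- function(n_chrom = 22, chrom_length = 1e8, seed = 1) {
  if (n_chrom < 1) stop("n_chrom must be >= 1")
  if (any(chrom_length < 1e7)) stop("chrom_length must be >= 10,000,000")
  lens <- rep_len(chrom_length, n_chrom)
  with_seed(seed, {
    cent <- round(lens * stats::runif(n_chrom, 0.3, 0.7))
    tri <- t(vapply(seq_len(n_chrom), function(i) {
      g <- stats::rgamma(32, shape = 5)
      g / sum(g)
    }, numeric(32)))
  })
  colnames(tri) <- trinucleotides_32()
  chroms <- data.frame(
    chrom = paste0("chr", seq_len(n_chrom)),
    length = lens,
    centromere = cent,
    stringsAsFactors = FALSE
  )
  rownames(tri) <- chroms$chrom
  structure(list(chromosomes = chroms, trinuc_freq = tri),
            class = "genome_model")
}

#' Load a genome model from a chromosome table
#'
#' Reads a TSV with columns `chrom`, `length`, `centromere` (for example
#' the bundled GRCh37 table at
#' `system.file("extdata", "grch37_chromosomes.tsv", package = "somaticTME")`)
#' and attaches Dirichlet trinucleotide frequencies as in
#' [generate_genome()].
#'
#' @param path TSV path.
#' @param seed seed for the trinucleotide frequencies.
#' @return a `genome_model`.
#' @export
load_genome_table <- function(path, seed = 1) {
  tab <- data.table::fread(path, sep = "\t", data.table = FALSE)
  stopifnot(all(c("chrom", "length", "centromere") %in% names(tab)))
  if (any(tab$length <= 0)) stop("chromosome lengths must be positive")
  if (any(tab$centromere <= 0 | tab$centromere >= tab$length)) {
    stop("centromere must lie strictly inside the chromosome")
  }
  n <- nrow(tab)
  with_seed(seed, {
    tri <- t(vapply(seq_len(n), function(i) {
      g <- stats::rgamma(32, shape = 5)
      g / sum(g)
    }, numeric(32)))
  })
  colnames(tri) <- trinucleotides_32()
  rownames(tri) <- tab$chrom
  structure(list(chromosomes = tab[, c("chrom", "length", "centromere")],
                 trinuc_freq = tri),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", nrow(x$chromosomes), "chromosomes,",
      format(sum(x$chromosomes$length), big.mark = ","), "bp total\n")
  invisible(x)
}

genome_length <- function(genome) sum(genome$chromosomes$length)

chrom_length_of <- function(genome, chrom) {
  i <- match(chrom, genome$chromosomes$chrom)
  if (anyNA(i)) stop("unknown chromosome: ", chrom[which(is.na(i))[1]])
  genome$chromosomes$length[i]
}
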