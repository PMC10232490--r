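#' Read somatic SNVs from a VCF
#'
#' Parses a VCF 4.x (via \pkg{vcfR}) and returns SNV records with
#' pyrimidine-strand substitution class and 3-base context. Only
#' single-base substitution lines are consumed; indels and multi-allelic
#' lines are skipped and counted (reported via attribute `n_skipped` and
#' a message). The 3-base context is taken from the INFO tag `TNC`
#' (middle base = REF as written); if `TNC` is absent a reference FASTA
#' must be supplied so the context can be computed.
#'
#' @param path VCF path.
#' @param sample_id sample identifier (default: file name without
#'   extension).
#' @param fasta optional reference FASTA used only when `TNC` is missing.
#' @return data.frame of SNV records with attribute `n_skipped`.
#' @export
read_vcf <- function(path, sample_id = NULL, fasta = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  }
  raw <- readLines(path)
  body_idx <- which(!startsWith(raw, "#") & nzchar(raw))
  if (length(body_idx) == 0) {
    out <- new_snv_table(0)
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  # light structural validation with line numbers before delegating
  for (i in body_idx) {
    f <- strsplit(raw[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) stop("malformed VCF line ", i, ": fewer than 8 fields")
    pos <- suppressWarnings(as.numeric(f[2]))
    if (is.na(pos) || pos < 1) stop("malformed VCF line ", i, ": bad POS")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  tnc <- vcfR::extract.info(vcf, element = "TNC")
  is_snv <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% BASES & fix$ALT %in% BASES
  n_skipped <- sum(!is_snv)
  if (n_skipped > 0) {
    message("read_vcf: skipped ", n_skipped, " non-SNV line(s)")
  }
  fix <- fix[is_snv, , drop = FALSE]
  tnc <- tnc[is_snv]
  if (nrow(fix) == 0) {
    out <- new_snv_table(0)
    attr(out, "n_skipped") <- as.integer(n_skipped)
    return(out)
  }
  if (anyNA(tnc)) {
    if (is.null(fasta)) {
      stop("context-unavailable: INFO tag TNC missing and no FASTA supplied")
    }
    ref_seq <- Biostrings::readDNAStringSet(fasta)
    names(ref_seq) <- sub("\\s.*", "", names(ref_seq))
    need <- which(is.na(tnc))
    pos <- as.integer(fix$POS[need])
    tnc[need] <- vapply(seq_along(need), function(j) {
      ch <- fix$CHROM[need[j]]
      as.character(Biostrings::subseq(ref_seq[[ch]], pos[j] - 1, pos[j] + 1))
    }, character(1))
  }
  if (any(nchar(tnc) != 3 | substr(tnc, 2, 2) != fix$REF)) {
    stop("TNC context inconsistent with REF")
  }
  norm <- normalize_substitution(fix$REF, fix$ALT, tnc)
  out <- data.frame(
    sample_id = sample_id,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = substr(norm$context3, 2, 2),
    alt = substr(norm$subst_class, 3, 3),
    context3 = norm$context3,
    subst_class = norm$subst_class,
    stringsAsFactors = FALSE
  )
  attr(out, "n_skipped") <- as.integer(n_skipped)
  out
}

#' Write SNV records to a VCF
#'
#' Emits a minimal VCF 4.2 with the pyrimidine-strand context in the INFO
#' tag `TNC`, so that `read_vcf(write_vcf(x))` round-trips exactly.
#'
#' @param records SNV record data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=TNC,Number=1,Type=String,Description=\"Trinucleotide context (pyrimidine strand)\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  body <- if (nrow(records) > 0) {
    paste(records$chrom, records$pos, ".", records$ref, records$alt, ".",
          "PASS", paste0("TNC=", records$context3), sep = "\t")
  } else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}
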