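#' Read structural variants from a BEDPE file
#'
#' BEDPE coordinates are 0-based half-open; internal breakend positions
#' are 1-based points, so `pos1 = start1 + 1`. Expected columns: the six
#' BEDPE coordinates, `name` (sample id), `score`, `strand1`, `strand2`,
#' then `sv_type` and optionally `orientation`.
#'
#' @param path BEDPE path.
#' @return data.frame of SV records.
#' @export
read_bedpe <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
            "name", "sv_type")
  if (!all(need %in% names(tab))) {
    stop("BEDPE missing required column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  if (any(tab$start1 < 0 | tab$start2 < 0)) {
    stop("parse error: negative coordinates in BEDPE")
  }
  pos1 <- as.integer(tab$start1) + 1L
  pos2 <- as.integer(tab$start2) + 1L
  intra <- tab$chrom1 == tab$chrom2
  if (any(intra & tab$sv_type == "TRA")) {
    stop("TRA records must be inter-chromosomal")
  }
  if (any(!intra & tab$sv_type != "TRA")) {
    stop("inter-chromosomal records must have sv_type TRA")
  }
  data.frame(
    sample_id = tab$name,
    chrom1 = tab$chrom1, pos1 = pos1,
    chrom2 = tab$chrom2, pos2 = pos2,
    sv_type = tab$sv_type,
    size = ifelse(intra, abs(pos2 - pos1), NA_integer_),
    orientation = if ("orientation" %in% names(tab)) {
      ifelse(tab$orientation %in% c("h2h", "t2t"), tab$orientation,
             NA_character_)
    } else NA_character_,
    clustered = NA,
    stringsAsFactors = FALSE
  )
}

#' Write structural variants to a BEDPE file
#' @param svs SV record data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(svs, path) {
  out <- data.frame(
    chrom1 = svs$chrom1, start1 = svs$pos1 - 1L, end1 = svs$pos1,
    chrom2 = svs$chrom2, start2 = svs$pos2 - 1L, end2 = svs$pos2,
    name = svs$sample_id, score = ".", strand1 = ".", strand2 = ".",
    sv_type = svs$sv_type,
    orientation = ifelse(is.na(svs$orientation), ".", svs$orientation),
    stringsAsFactors = FALSE
  )
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read copy-number segments from a TSV
#'
#' Columns: sample, chrom, start, end (0-based half-open), total_cn,
#' minor_cn, subclonal_q (empty/NA = clonal).
#'
#' @param path TSV path.
#' @return data.frame of segments.
#' @export
read_segments <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  need <- c("sample", "chrom", "start", "end", "total_cn", "minor_cn")
  if (!all(need %in% names(tab))) {
    stop("segments TSV missing column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  if (any(tab$start < 0)) stop("parse error: negative coordinates")
  if (any(tab$end <= tab$start)) stop("parse error: end must exceed start")
  if (any(tab$total_cn < 0)) stop("parse error: negative copy number")
  data.frame(
    sample_id = tab$sample, chrom = tab$chrom,
    start = as.numeric(tab$start), end = as.numeric(tab$end),
    total_cn = as.integer(tab$total_cn),
    minor_cn = as.integer(tab$minor_cn),
    subclonal_q = if ("subclonal_q" %in% names(tab)) {
      as.numeric(tab$subclonal_q)
    } else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Write copy-number segments to a TSV
#' @param segments segment data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  out <- data.frame(
    sample = segments$sample_id, chrom = segments$chrom,
    start = segments$start, end = segments$end,
    total_cn = segments$total_cn, minor_cn = segments$minor_cn,
    subclonal_q = segments$subclonal_q,
    stringsAsFactors = FALSE
  )
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a genes x samples expression matrix from TSV
#'
#' First column = gene id, remaining columns = samples. Duplicate gene
#' ids are a hard error.
#'
#' @param path TSV path.
#' @return numeric matrix (genes x samples).
#' @export
read_expression <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  genes <- tab[[1]]
  if (anyDuplicated(genes)) {
    stop("duplicate-key error: duplicated gene id '",
         genes[duplicated(genes)][1], "'")
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- genes
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("expression values must be non-negative")
  m
}

#' Write a genes x samples expression matrix to TSV
#' @param expr numeric matrix with gene rownames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  out <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read gene sets from a GMT file
#' @param path GMT path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical table from TSV
#'
#' Required columns: sample_id, os_months, os_event; optional:
#' pfs_months, pfs_event, stage, treatment, pet_response, cluster.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_clinical <- function(path) {
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  need <- c("sample_id", "os_months", "os_event")
  if (!all(need %in% names(tab))) {
    stop("clinical TSV missing column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  if (any(tab$os_months < 0, na.rm = TRUE)) {
    stop("parse error: negative survival time")
  }
  tab
}

#' Write a clinical table to TSV
#' @param clinical clinical data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  data.table::fwrite(clinical, path, sep = "\t")
  invisible(path)
}
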