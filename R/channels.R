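BASES <- c("A", "C", "G", "T")
SUBST_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
APOBEC_CONTEXTS <- c("TCA", "TCT")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over A/C/G/T strings.
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

#' The 96 single-base-substitution channels
#'
#' Fixed lexicographic channel order: substitution class major
#' (C>A, C>G, C>T, T>A, T>C, T>G), then 5' flank, then 3' flank.
#' Names follow the conventional `A[C>A]A` form.
#'
#' @return character vector of 96 channel names.
#' @export
snv_channels <- function() {
  out <- character(0)
  for (cls in SUBST_CLASSES) {
    ref <- substr(cls, 1, 1)
    for (f5 in BASES) for (f3 in BASES) {
      out <- c(out, paste0(f5, "[", cls, "]", f3))
    }
  }
  out
}

#' The 32 pyrimidine-strand trinucleotides
#'
#' Order: middle base C then T, 5' flank major, 3' flank minor.
#'
#' @return character vector of 32 trinucleotides.
#' @export
trinucleotides_32 <- function() {
  out <- character(0)
  for (mid in c("C", "T")) for (f5 in BASES) for (f3 in BASES) {
    out <- c(out, paste0(f5, mid, f3))
  }
  out
}

#' Channel name for a substitution class and context
#' @param subst_class one of the six pyrimidine substitution classes.
#' @param context3 3-base pyrimidine-strand context.
#' @return channel name, e.g. `"T[C>T]A"`.
#' @export
snv_channel_of <- function(subst_class, context3) {
  stopifnot(nchar(context3) == 3)
  paste0(substr(context3, 1, 1), "[", subst_class, "]", substr(context3, 3, 3))
}

#' Pyrimidine-strand normalisation of a substitution
#'
#' Substitutions with a purine reference are mapped to the reverse
#' complement strand so that every record is expressed as one of the six
#' C/T classes with a matching 3-base context.
#'
#' @param ref,alt single reference/alternate bases.
#' @param context3 3-base context on the reported strand (middle = ref).
#' @return list with `subst_class`, `context3` (pyrimidine strand).
#' @export
normalize_substitution <- function(ref, alt, context3) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(context3) == n)
  bad <- !(ref %in% BASES) | !(alt %in% BASES) | ref == alt
  if (any(bad)) {
    stop("invalid substitution record(s) at index ", which(bad)[1])
  }
  if (any(substr(context3, 2, 2) != ref)) {
    stop("context3 middle base must equal ref")
  }
  flip <- ref %in% c("A", "G")
  ref2 <- ref
  alt2 <- alt
  ctx2 <- context3
  if (any(flip)) {
    ref2[flip] <- chartr("ACGT", "TGCA", ref[flip])
    alt2[flip] <- chartr("ACGT", "TGCA", alt[flip])
    ctx2[flip] <- revcomp(context3[flip])
  }
  list(subst_class = paste0(ref2, ">", alt2), context3 = ctx2)
}

#' The 32 structural-variant classes
#'
#' {clustered, non-clustered} major; within each: deletions, duplications
#' and inversions in five size bins (1-10 kb, 10-100 kb, 100 kb-1 Mb,
#' 1-10 Mb, >10 Mb) plus translocations without a size bin.
#'
#' @return character vector of 32 class labels.
#' @export
sv_channels <- function() {
  bins <- c("1-10kb", "10-100kb", "100kb-1Mb", "1-10Mb", ">10Mb")
  out <- character(0)
  for (cl in c("clustered", "non-clustered")) {
    for (ty in c("del", "dup", "inv")) {
      out <- c(out, paste(ty, bins, cl, sep = "/"))
    }
    out <- c(out, paste("tra", cl, sep = "/"))
  }
  out
}

SV_SIZE_BREAKS <- c(1e3, 1e4, 1e5, 1e6, 1e7, Inf)
SV_SIZE_LABELS <- c("1-10kb", "10-100kb", "100kb-1Mb", "1-10Mb", ">10Mb")

# Run code with a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Small deterministic sub-seed derivation, kept < 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_simplex <- function(x, what = "vector", tol = 1e-8) {
  if (any(x < -tol) || abs(sum(x) - 1) > 1e-6) {
    stop(what, " must be non-negative and sum to 1")
  }
  invisible(TRUE)
}
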