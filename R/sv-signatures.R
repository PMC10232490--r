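#' Flag clustered SV breakpoints
#'
#' Assigns both breakends of every SV to fixed, non-overlapping 1 Mb
#' genome bins (per sample) and flags an SV as clustered iff either of
#' its breakends falls in a bin holding at least `min_bp` of that
#' sample's breakends.
#'
#' @param svs SV record data.frame (any number of samples).
#' @param bin bin width in bp (default 1 Mb).
#' @param min_bp minimum breakpoints per bin to call a cluster
#'   (default 10).
#' @return `svs` with the `clustered` column filled.
#' @export
flag_clustered_breakpoints <- function(svs, bin = 1e6, min_bp = 10) {
  if (nrow(svs) == 0) {
    svs$clustered <- logical(0)
    return(svs)
  }
  svs$clustered <- FALSE
  for (sid in unique(svs$sample_id)) {
    idx <- which(svs$sample_id == sid)
    key1 <- paste0(svs$chrom1[idx], ":", (svs$pos1[idx] - 1) %/% bin)
    key2 <- paste0(svs$chrom2[idx], ":", (svs$pos2[idx] - 1) %/% bin)
    counts <- table(c(key1, key2))
    hot <- names(counts)[counts >= min_bp]
    svs$clustered[idx] <- key1 %in% hot | key2 %in% hot
  }
  svs
}

#' Classify an SV into the 32-class scheme
#'
#' Type (del/dup/inv/tra) x size bin x clustered flag. Size bins are
#' half-open `[low, high)` in bp: \[1 kb, 10 kb), \[10 kb, 100 kb),
#' \[100 kb, 1 Mb), \[1 Mb, 10 Mb), \[10 Mb, Inf); sizes below 1 kb are
#' clamped into the lowest bin with a warning. Translocations carry no
#' size bin.
#'
#' @param svs SV records with the `clustered` flag set.
#' @return character vector of class labels (levels of
#'   [sv_channels()]).
#' @export
classify_sv <- function(svs) {
  if (nrow(svs) == 0) return(character(0))
  if (anyNA(svs$clustered)) {
    stop("clustered flag must be set before classification")
  }
  known <- c("DEL", "DUP", "INV", "TRA")
  if (!all(svs$sv_type %in% known)) {
    stop("unknown sv_type: ",
         setdiff(unique(svs$sv_type), known)[1])
  }
  cl <- ifelse(svs$clustered, "clustered", "non-clustered")
  ty <- c(DEL = "del", DUP = "dup", INV = "inv", TRA = "tra")[svs$sv_type]
  lab <- character(nrow(svs))
  tra <- svs$sv_type == "TRA"
  lab[tra] <- paste("tra", cl[tra], sep = "/")
  if (any(!tra)) {
    size <- svs$size[!tra]
    if (any(size < 1e3)) {
      warning("clamping ", sum(size < 1e3), " SV(s) <1 kb into the lowest bin")
      size <- pmax(size, 1e3)
    }
    bin <- SV_SIZE_LABELS[findInterval(size, SV_SIZE_BREAKS)]
    lab[!tra] <- paste(ty[!tra], bin, cl[!tra], sep = "/")
  }
  lab
}

#' Build the 32-class SV catalogue
#'
#' @param svs SV records with clustered flags set.
#' @param samples ordered sample identifiers.
#' @return samples x 32 integer count matrix.
#' @export
build_sv_catalogue <- function(svs, samples) {
  ch <- sv_channels()
  m <- matrix(0L, nrow = length(samples), ncol = 32,
              dimnames = list(samples, ch))
  if (nrow(svs) == 0) return(m)
  unknown <- setdiff(unique(svs$sample_id), samples)
  if (length(unknown) > 0) stop("unknown sample: ", unknown[1])
  lab <- classify_sv(svs)
  tab <- table(factor(svs$sample_id, levels = samples),
               factor(lab, levels = ch))
  m[] <- as.integer(tab)
  m
}

#' Extract rearrangement signatures and match to a reference set
#'
#' Runs the same NMF machinery as the SNV module on the 32-class SV
#' catalogue and matches the extracted signatures to a reference
#' rearrangement-signature set by cosine similarity; matches with cosine
#' below 0.80 are reported with a "-like" suffix. No exposure pruning is
#' applied to rearrangement signatures.
#'
#' @param catalogue samples x 32 count matrix.
#' @param reference a `signature_set` over the 32 SV classes.
#' @param k number of signatures to extract.
#' @param seed integer seed.
#' @param n_restarts,max_iter,tol NMF controls (see
#'   [extract_signatures_nmf()]).
#' @return list: `signatures`, `exposures`, `recon_error`, `matches`.
#' @export
extract_and_match_rs <- function(catalogue, reference, k, seed = 1,
                                 n_restarts = 50, max_iter = 10000,
                                 tol = 1e-6) {
  fit <- extract_signatures_nmf(catalogue, k, n_restarts = n_restarts,
                                max_iter = max_iter, tol = tol,
                                seed = seed)
  matches <- match_signatures_cosine(fit$signatures, reference,
                                     like_cutoff = 0.80)
  c(fit, list(matches = matches))
}
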