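#' Construct a signature set
#'
#' A signature set is a named collection of probability profiles over a
#' fixed channel order (96 SNV channels or 32 SV classes).
#'
#' @param profiles k x n_channels matrix; rows are normalised to sum to 1.
#' @param names signature names (default S1..Sk).
#' @param provenance `"extracted"` or `"reference"`.
#' @return object of class `signature_set`.
#' @export
signature_set <- function(profiles,
                          names = NULL,
                          provenance = c("reference", "extracted")) {
  provenance <- match.arg(provenance)
  profiles <- as.matrix(profiles)
  if (any(profiles < 0)) stop("signature profiles must be non-negative")
  rs <- rowSums(profiles)
  if (any(rs == 0)) stop("signature profiles must have positive mass")
  profiles <- profiles / rs
  if (is.null(names)) names <- paste0("S", seq_len(nrow(profiles)))
  rownames(profiles) <- names
  structure(list(names = names, profiles = profiles,
                 provenance = provenance),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat("signature_set (", x$provenance, "): ", length(x$names),
      " signatures x ", ncol(x$profiles), " channels\n", sep = "")
  invisible(x)
}

#' Synthetic reference SNV signatures
#'
#' Builds `k` synthetic 96-channel reference signatures with known,
#' well-separated profiles. The first signature is APOBEC-like: almost
#' all of its mass sits on C>T and C>G at TpCpW (TCA/TCT) contexts,
#' mimicking the shape of COSMIC signatures 2/13. Remaining signatures
#' are sparse Dirichlet draws over disjoint-leaning channel blocks, so
#' pairwise cosines stay low and planted mixtures are identifiable.
#'
#' @param k number of signatures (>= 2).
#' @param seed integer seed.
#' @return a `signature_set` with provenance `"reference"`.
#' @export
synthetic_reference_signatures <- function(k = 4, seed = 99) {
  stopifnot(k >= 2)
  ch <- snv_channels()
  apobec_ch <- c("T[C>T]A", "T[C>T]T", "T[C>G]A", "T[C>G]T")
  with_seed(seed, {
    prof <- matrix(0, nrow = k, ncol = 96)
    prof[1, match(apobec_ch, ch)] <- c(0.35, 0.35, 0.125, 0.125)
    prof[1, ] <- prof[1, ] + 0.01 / 96 # faint flat background
    blocks <- split(sample(setdiff(seq_len(96), match(apobec_ch, ch))),
                    rep_len(seq_len(k - 1), 92))
    for (j in 2:k) {
      idx <- blocks[[j - 1]]
      prof[j, idx] <- stats::rgamma(length(idx), shape = 0.8)
      prof[j, ] <- prof[j, ] + 1e-5
    }
  })
  colnames(prof) <- ch
  signature_set(prof, names = paste0("RefSig", seq_len(k)),
                provenance = "reference")
}

#' Synthetic reference rearrangement signatures
#'
#' `k` sparse 32-class reference rearrangement signatures (Dirichlet-style
#' block profiles over the SV class channels).
#'
#' @param k number of signatures.
#' @param seed integer seed.
#' @return a `signature_set` over the 32 SV classes.
#' @export
synthetic_reference_rs <- function(k = 3, seed = 7) {
  stopifnot(k >= 1)
  ch <- sv_channels()
  with_seed(seed, {
    prof <- matrix(1e-4, nrow = k, ncol = 32)
    blocks <- split(sample(seq_len(32)), rep_len(seq_len(k), 32))
    for (j in seq_len(k)) {
      idx <- blocks[[j]]
      prof[j, idx] <- prof[j, idx] + stats::rgamma(length(idx), shape = 1)
    }
  })
  colnames(prof) <- ch
  signature_set(prof, names = paste0("RS", seq_len(k)),
                provenance = "reference")
}

#' Cosine similarity between two vectors
#' @param a,b numeric vectors of equal length.
#' @return cosine similarity in \[-1, 1\] (\[0, 1\] for non-negative input).
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}
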