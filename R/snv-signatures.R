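#' Build a 96-context mutational catalogue
#'
#' Counts each sample's SNVs into the fixed 96-channel order of
#' [snv_channels()]. Samples without records get zero rows; totals are
#' conserved.
#'
#' @param records SNV record data.frame (must carry `context3` and
#'   `subst_class`).
#' @param samples ordered sample identifiers defining the rows.
#' @return samples x 96 integer matrix.
#' @export
build_snv_catalogue <- function(records, samples) {
  ch <- snv_channels()
  m <- matrix(0L, nrow = length(samples), ncol = 96,
              dimnames = list(samples, ch))
  if (nrow(records) == 0) return(m)
  unknown <- setdiff(unique(records$sample_id), samples)
  if (length(unknown) > 0) stop("unknown sample: ", unknown[1])
  chan <- snv_channel_of(records$subst_class, records$context3)
  tab <- table(factor(records$sample_id, levels = samples),
               factor(chan, levels = ch))
  m[] <- as.integer(tab)
  m
}

# Frobenius multiplicative-update NMF, single restart.
nmf_once <- function(V, k, max_iter, tol) {
  n <- nrow(V); p <- ncol(V)
  eps <- 1e-12
  W <- matrix(stats::runif(n * k, 0.1, 1), n, k) * sqrt(mean(V) / k)
  H <- matrix(stats::runif(k * p, 0.1, 1), k, p) * sqrt(mean(V) / k)
  err_old <- Inf
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W) %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    if (it %% 10 == 0 || it == max_iter) {
      err <- sqrt(sum((V - W %*% H)^2))
      if (is.finite(err_old) && (err_old - err) <= tol * max(err_old, eps)) {
        break
      }
      err_old <- err
    }
  }
  list(W = W, H = H, err = sqrt(sum((V - W %*% H)^2)))
}

#' Extract mutational signatures by NMF
#'
#' Frobenius-objective non-negative matrix factorisation with
#' multiplicative updates, best of `n_restarts` random restarts by
#' reconstruction error. Signature rows are normalised to probabilities
#' with exposures rescaled accordingly, and signatures are ordered by
#' total attributed mutations (largest first) for determinism.
#'
#' @param catalogue samples x channels count matrix.
#' @param k number of signatures (<= min(n_samples, n_channels)).
#' @param n_restarts random restarts.
#' @param max_iter maximum update iterations per restart.
#' @param tol relative reconstruction-error change for convergence.
#' @param seed integer seed.
#' @return list: `signatures` (a `signature_set`), `exposures`
#'   (samples x k proportion matrix), `exposure_counts` (attributed
#'   mutation counts), `recon_error` (relative Frobenius error).
#' @export
extract_signatures_nmf <- function(catalogue, k, n_restarts = 50,
                                   max_iter = 10000, tol = 1e-6,
                                   seed = 1) {
  V <- as.matrix(catalogue)
  if (all(V == 0)) stop("all-zero catalogue")
  if (k > min(dim(V))) {
    warning("k exceeds min(dim(catalogue)); proceeding")
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      fit <- nmf_once(V, k, max_iter, tol)
      if (is.null(best) || fit$err < best$err) best <- fit
    }
  })
  W <- best$W; H <- best$H
  s <- rowSums(H)
  s[s == 0] <- 1
  H <- H / s
  W <- sweep(W, 2, s, `*`)
  ord <- order(colSums(W), decreasing = TRUE)
  W <- W[, ord, drop = FALSE]; H <- H[ord, , drop = FALSE]
  colnames(H) <- colnames(V)
  sigs <- signature_set(H, names = paste0("Sig", seq_len(k)),
                        provenance = "extracted")
  rs <- rowSums(W)
  expo <- W / ifelse(rs == 0, 1, rs)
  dimnames(expo) <- list(rownames(V), sigs$names)
  dimnames(W) <- dimnames(expo)
  list(signatures = sigs, exposures = expo, exposure_counts = W,
       recon_error = best$err / sqrt(sum(V^2)))
}

#' Match extracted signatures to a reference set by cosine similarity
#'
#' Each extracted signature is paired with its best-matching reference
#' profile; ties are broken by reference order. Matches with cosine below
#' `like_cutoff` are labelled `"<reference>-like"`.
#'
#' @param extracted,reference `signature_set`s over the same channels.
#' @param like_cutoff cosine below which the match name gets a "-like"
#'   suffix (default 0.80).
#' @return data.frame: extracted, reference, cosine, label.
#' @export
match_signatures_cosine <- function(extracted, reference,
                                    like_cutoff = 0.80) {
  if (ncol(extracted$profiles) != ncol(reference$profiles)) {
    stop("channel dimension mismatch")
  }
  res <- lapply(seq_len(nrow(extracted$profiles)), function(i) {
    cs <- vapply(seq_len(nrow(reference$profiles)), function(j) {
      cosine_similarity(extracted$profiles[i, ], reference$profiles[j, ])
    }, numeric(1))
    best <- which.max(cs) # which.max takes the first = reference order
    data.frame(
      extracted = extracted$names[i],
      reference = reference$names[best],
      cosine = cs[best],
      label = if (cs[best] < like_cutoff) {
        paste0(reference$names[best], "-like")
      } else reference$names[best],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}

#' Refit signature exposures by constrained quadratic programming
#'
#' Minimises `|| m/||m||_1 - t(S) e ||_2^2` subject to `e >= 0` and
#' `sum(e) = 1` (non-negative least squares on a sum-to-one-augmented
#' system, then exact renormalisation). A zero-count row returns the
#' zero vector with attribute `zero_sample = TRUE`.
#'
#' @param counts one catalogue row (96 counts) or a vector of channel
#'   counts matching the signature channels.
#' @param signatures a `signature_set`.
#' @return exposure vector on the simplex with attribute `objective`
#'   (the achieved squared residual norm).
#' @export
refit_exposures <- function(counts, signatures) {
  S <- signatures$profiles
  if (nrow(S) < 1) stop("need at least one signature")
  if (length(counts) != ncol(S)) stop("channel dimension mismatch")
  tot <- sum(counts)
  if (tot == 0) {
    e <- stats::setNames(rep(0, nrow(S)), signatures$names)
    attr(e, "zero_sample") <- TRUE
    attr(e, "objective") <- 0
    return(e)
  }
  m <- counts / tot
  w <- 1e4 # weight enforcing the sum-to-one constraint
  C <- rbind(t(S), rep(w, nrow(S)))
  d <- c(m, w)
  e <- pracma::lsqnonneg(C, d)$x
  if (sum(e) == 0) e <- rep(1 / nrow(S), nrow(S))
  e <- e / sum(e)
  e <- stats::setNames(as.numeric(e), signatures$names)
  attr(e, "objective") <- sum((m - as.numeric(t(S) %*% e))^2)
  attr(e, "zero_sample") <- FALSE
  e
}

#' Refit exposures for every catalogue row
#'
#' @param catalogue samples x channels count matrix.
#' @param signatures a `signature_set`.
#' @return samples x signatures exposure matrix (rows on the simplex, or
#'   zero for zero-count samples).
#' @export
refit_exposure_matrix <- function(catalogue, signatures) {
  V <- as.matrix(catalogue)
  out <- t(apply(V, 1, function(row) {
    as.numeric(refit_exposures(row, signatures))
  }))
  dimnames(out) <- list(rownames(V), signatures$names)
  out
}

#' Prune low signature exposures and reassign mutations
#'
#' Applies the overfitting guard of the signature refit: per sample,
#' iteratively drop the smallest exposure below `threshold` (ties broken
#' by signature index) and refit on the remaining signatures, until every
#' retained exposure is at least `threshold` or a single signature
#' remains. Rows stay on the simplex; pruned signatures get exposure 0.
#'
#' @param exposures samples x signatures exposure matrix.
#' @param catalogue matching count matrix (used for refitting).
#' @param signatures the `signature_set` the exposures refer to.
#' @param threshold pruning proportion in (0, 1); default 0.10.
#' @return exposure matrix of the same shape.
#' @export
prune_and_reassign <- function(exposures, catalogue, signatures,
                               threshold = 0.10) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  V <- as.matrix(catalogue)
  k <- nrow(signatures$profiles)
  out <- exposures
  for (i in seq_len(nrow(out))) {
    if (sum(V[i, ]) == 0) next
    active <- seq_len(k)
    e <- out[i, ]
    repeat {
      low <- active[e[active] < threshold]
      if (length(low) == 0 || length(active) == 1) break
      drop_idx <- low[which.min(e[low])]
      active <- setdiff(active, drop_idx)
      sub <- signature_set(signatures$profiles[active, , drop = FALSE],
                           names = signatures$names[active],
                           provenance = signatures$provenance)
      e_sub <- refit_exposures(V[i, ], sub)
      e <- rep(0, k)
      e[active] <- as.numeric(e_sub)
    }
    full <- rep(0, k)
    full[active] <- e[active] / sum(e[active])
    out[i, ] <- full
  }
  out
}
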