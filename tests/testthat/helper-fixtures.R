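# Shared fixtures, all built in code at test time.

tiny_genome <- function(n_chrom = 2, len = 2e7, seed = 1) {
  generate_genome(n_chrom, len, seed = seed)
}

ref_sigs4 <- synthetic_reference_signatures(4, seed = 99)
ref_rs3 <- synthetic_reference_rs(3, seed = 7)

# best signature-to-signature cosine assignment over all permutations
# (k is small in every test); returns the mean and per-pair cosines
match_permute <- function(extracted, planted) {
  k <- nrow(extracted)
  perms <- combinat_perms(k)
  best <- NULL
  for (p in perms) {
    cs <- vapply(seq_len(k), function(i) {
      cosine_similarity(extracted[i, ], planted[p[i], ])
    }, numeric(1))
    if (is.null(best) || mean(cs) > mean(best)) best <- cs
  }
  best
}

combinat_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (sub in combinat_perms(k - 1)) {
      rest <- setdiff(seq_len(k), i)
      out[[length(out) + 1]] <- c(i, rest[sub])
    }
  }
  out
}

# dense simplex grid search oracle for 3-signature exposure refits
grid_refit_oracle <- function(m, S, step = 0.01) {
  m <- m / sum(m)
  best <- NULL
  for (a in seq(0, 1, by = step)) {
    for (b in seq(0, 1 - a, by = step)) {
      e <- c(a, b, 1 - a - b)
      obj <- sum((m - as.numeric(t(S) %*% e))^2)
      if (is.null(best) || obj < best$obj) best <- list(e = e, obj = obj)
    }
  }
  best
}

# balanced 4-cluster enrichment-score fixture via planted archetypes
archetype_scores <- function(n_per = 15, separation = 3, noise_sd = 0.5,
                             seed = 1) {
  sim <- simulate_expression(2000, rep(n_per, 4),
                             separation = separation, noise_sd = noise_sd,
                             seed = seed)
  list(scores = enrichment_scores(sim$expr, default_immune_gene_sets(2000)),
       labels = sim$labels)
}
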