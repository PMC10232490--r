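test_that("catalogue construction conserves counts and channel placement", {
  rec <- data.frame(sample_id = "S1", chrom = "chr1", pos = 10L,
                    ref = "C", alt = "T", context3 = "ACA",
                    subst_class = "C>T", stringsAsFactors = FALSE)
  cat1 <- build_snv_catalogue(rec, "S1")
  expect_equal(sum(cat1), 1)
  expect_equal(cat1[1, "A[C>T]A"], 1)
  cat2 <- build_snv_catalogue(rbind(rec, rec), "S1")
  expect_equal(cat2[1, "A[C>T]A"], 2)
  expect_equal(sum(cat2), 2)
  # zero row for a sample without records
  cat3 <- build_snv_catalogue(rec, c("S1", "S2"))
  expect_equal(sum(cat3["S2", ]), 0)
  expect_error(build_snv_catalogue(rec, "Sx"), "unknown sample")
})

test_that("simulated catalogues converge to their generating signature", {
  g <- tiny_genome()
  snv <- simulate_snvs(g, ref_sigs4, c(0, 1, 0, 0), 1000, seed = 11)
  cat1 <- build_snv_catalogue(snv, "S1")
  expect_gte(cosine_similarity(cat1[1, ] / 1000, ref_sigs4$profiles[2, ]),
             0.95)
})

test_that("NMF recovers a planted factorisation", {
  set.seed(42)
  k <- 3
  # disjoint-support (orthogonal) planted signatures: identifiable
  planted <- matrix(0, k, 96)
  for (j in 1:k) {
    idx <- ((j - 1) * 32 + 1):(j * 32)
    planted[j, idx] <- rgamma(32, 1)
    planted[j, ] <- planted[j, ] / sum(planted[j, ])
  }
  # sparse exposures with pure anchor samples make the factorisation
  # identifiable (separability), as in real dominant-signature cohorts
  E <- matrix(rgamma(20 * k, 0.3), 20, k)
  E <- E / rowSums(E) * 5000
  E[1:3, ] <- diag(3) * 5000
  V <- E %*% planted
  fit <- extract_signatures_nmf(V, k, n_restarts = 10, max_iter = 5000,
                                tol = 1e-9, seed = 5)
  cs <- match_permute(fit$signatures$profiles, planted)
  expect_true(all(cs >= 0.99))
  expect_lte(fit$recon_error, 1e-3)
})

test_that("rank-1 catalogues and reruns behave deterministically", {
  prof <- ref_sigs4$profiles[2, , drop = FALSE]
  V <- outer(c(100, 200, 50), prof[1, ])
  fit <- extract_signatures_nmf(V, 1, n_restarts = 5, seed = 1)
  expect_gte(cosine_similarity(fit$signatures$profiles[1, ], prof[1, ]),
             0.9999)
  fit2 <- extract_signatures_nmf(V, 1, n_restarts = 5, seed = 1)
  expect_identical(fit$signatures$profiles, fit2$signatures$profiles)
  expect_error(extract_signatures_nmf(matrix(0, 3, 96), 2), "zero")
})

test_that("cosine matching agrees with the direct dot-product formula", {
  s <- ref_sigs4
  self <- match_signatures_cosine(s, s)
  expect_equal(self$cosine, rep(1, 4), tolerance = 1e-12)
  expect_equal(self$reference, s$names)
  one_hot <- matrix(0, 2, 96)
  one_hot[1, 1] <- 1; one_hot[2, 2] <- 1
  oh <- signature_set(one_hot, names = c("a", "b"))
  expect_equal(cosine_similarity(one_hot[1, ], one_hot[2, ]), 0)
  mix <- signature_set(rbind(0.9 * s$profiles[1, ] + 0.1 * s$profiles[2, ]),
                       names = "m")
  got <- match_signatures_cosine(mix, s)$cosine
  a <- mix$profiles[1, ]; b <- s$profiles[1, ]
  expect_equal(got, sum(a * b) / sqrt(sum(a^2) * sum(b^2)),
               tolerance = 1e-12)
})

test_that("QP refit reproduces exact mixtures and matches the grid oracle", {
  S3 <- signature_set(ref_sigs4$profiles[1:3, ], names = paste0("s", 1:3))
  pure <- 100 * S3$profiles[2, ]
  e <- refit_exposures(pure, S3)
  expect_equal(unname(e[2]), 1, tolerance = 1e-6)
  mix <- 0.7 * S3$profiles[1, ] + 0.3 * S3$profiles[2, ]
  e2 <- refit_exposures(mix * 500, S3)
  expect_equal(as.numeric(e2), c(0.7, 0.3, 0), tolerance = 1e-6)
  # row far from the signature span: solution still matches a dense
  # simplex grid search within the grid resolution
  set.seed(3)
  m <- rgamma(96, 1)
  e3 <- refit_exposures(m, S3)
  oracle <- grid_refit_oracle(m, S3$profiles, step = 0.01)
  expect_lte(attr(e3, "objective"), oracle$obj + 1e-9)
  expect_lt(max(abs(as.numeric(e3) - oracle$e)), 0.02)
  # zero-count sample contract
  ez <- refit_exposures(rep(0, 96), S3)
  expect_true(attr(ez, "zero_sample"))
  expect_equal(sum(ez), 0)
})

test_that("prune-and-reassign iterates the <10% rule to a fixed point", {
  S2 <- signature_set(ref_sigs4$profiles[1:2, ], names = c("a", "b"))
  m <- (0.95 * S2$profiles[1, ] + 0.05 * S2$profiles[2, ]) * 1000
  expo <- refit_exposure_matrix(rbind(S1 = m), S2)
  pruned <- prune_and_reassign(expo, rbind(S1 = m), S2)
  expect_equal(unname(pruned[1, ]), c(1, 0), tolerance = 1e-9)
  # already above threshold: unchanged
  m2 <- (0.5 * S2$profiles[1, ] + 0.5 * S2$profiles[2, ]) * 1000
  expo2 <- refit_exposure_matrix(rbind(S1 = m2), S2)
  expect_equal(prune_and_reassign(expo2, rbind(S1 = m2), S2), expo2)
  # three-signature toy pruned stepwise: all retained >= 0.10 or single
  S3 <- signature_set(ref_sigs4$profiles[1:3, ], names = paste0("s", 1:3))
  m3 <- (0.08 * S3$profiles[1, ] + 0.09 * S3$profiles[2, ] +
           0.83 * S3$profiles[3, ]) * 1000
  expo3 <- refit_exposure_matrix(rbind(S1 = m3), S3)
  pr3 <- prune_and_reassign(expo3, rbind(S1 = m3), S3)
  kept <- pr3[1, pr3[1, ] > 0]
  expect_true(all(kept >= 0.10) || length(kept) == 1)
  expect_equal(sum(pr3[1, ]), 1, tolerance = 1e-9)
})

test_that("exposure rows stay on the simplex across random refits", {
  set.seed(8)
  V <- matrix(rpois(20 * 96, 5), nrow = 20)
  colnames(V) <- snv_channels()
  rownames(V) <- paste0("S", 1:20)
  expo <- refit_exposure_matrix(V, ref_sigs4)
  expect_true(all(expo >= -1e-12))
  expect_equal(unname(rowSums(expo)), rep(1, 20), tolerance = 1e-9)
  pruned <- prune_and_reassign(expo, V, ref_sigs4)
  expect_equal(unname(rowSums(pruned)), rep(1, 20), tolerance = 1e-9)
  expect_true(all(pruned[pruned > 0] >= 0.10 - 1e-9 |
                    rowSums(pruned > 0)[row(pruned)[pruned > 0]] == 1))
})
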