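mk_intra <- function(pos1, pos2, type = "DEL", orientation = NA,
                     chrom = "chr1", sample = "S1") {
  data.frame(sample_id = sample, chrom1 = chrom, pos1 = pos1,
             chrom2 = chrom, pos2 = pos2, sv_type = type,
             size = abs(pos2 - pos1), orientation = orientation,
             clustered = NA, stringsAsFactors = FALSE)
}

# chain of n pairwise-interleaving intervals: [i*s, i*s + 1.5*s]
interleaving_chain <- function(n, s = 1e5, origin = 1e6) {
  do.call(rbind, lapply(seq_len(n), function(i) {
    mk_intra(origin + i * s, origin + i * s + 1.5 * s,
             type = c("DEL", "DUP", "INV", "INV")[(i %% 4) + 1],
             orientation = if ((i %% 4) + 1 >= 3) {
               c("h2h", "t2t")[(i %% 2) + 1]
             } else NA)
  }))
}

test_that("interleaved clusters are connected components of overlap-not-nest", {
  two <- rbind(mk_intra(1e6, 2e6), mk_intra(5e6, 6e6))
  cl <- detect_interleaved_clusters(two)
  expect_equal(nrow(cl$clusters), 2)
  expect_true(all(cl$clusters$n_interleaved == 1))
  chain <- interleaving_chain(12)
  cl12 <- detect_interleaved_clusters(chain)
  expect_equal(max(cl12$clusters$n_interleaved), 12)
  # brute-force component check via reachability on the pair relation
  lo <- pmin(chain$pos1, chain$pos2); hi <- pmax(chain$pos1, chain$pos2)
  adj <- outer(seq_len(12), seq_len(12), Vectorize(function(i, j) {
    (lo[i] < lo[j] & lo[j] < hi[i] & hi[i] < hi[j]) ||
      (lo[j] < lo[i] & lo[i] < hi[j] & hi[j] < hi[i])
  }))
  reach <- adj | diag(12)
  for (it in 1:12) reach <- reach | (reach %*% reach) > 0
  expect_equal(length(unique(apply(reach, 1, paste, collapse = ""))),
               nrow(cl12$clusters))
  nested <- rbind(mk_intra(1e6, 9e6), mk_intra(2e6, 3e6))
  cln <- detect_interleaved_clusters(nested)
  expect_equal(nrow(cln$clusters), 2)
})

test_that("oscillation counts match hand-counted alternation runs", {
  seg <- function(states) {
    data.frame(chrom = "chr1", start = seq_along(states) * 1e6,
               end = seq_along(states) * 1e6 + 1e6, total_cn = states)
  }
  expect_equal(count_oscillations(seg(c(2, 2, 2))),
               list(two_state = 0L, three_state = 0L))
  expect_equal(count_oscillations(seg(c(2, 3, 2, 3, 2, 3, 2)))$two_state,
               6L)
  r <- count_oscillations(seg(c(1, 2, 3, 2, 1)))
  expect_equal(r$two_state, 2L)
  expect_equal(r$three_state, 4L)
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), total_cn = integer(0))
  expect_error(count_oscillations(empty), "empty")
})

test_that("the exponential-spacing test separates regular from exponential", {
  set.seed(17)
  pos_reg <- seq(1e6, 6e6, length.out = 50)
  expect_lt(breakpoint_exponential_test(pos_reg), 0.01)
  p_exp <- vapply(1:40, function(i) {
    breakpoint_exponential_test(1e6 + cumsum(rexp(30, 1e-4)))
  }, numeric(1))
  # near-uniform null p-values: not stacked at either extreme
  expect_gt(mean(p_exp > 0.1), 0.5)
  expect_lt(mean(p_exp < 0.05), 0.25)
  expect_true(is.na(breakpoint_exponential_test(c(1, 2))))
})

test_that("with a known chromosome rate, clustering rejects and uniform does not", {
  set.seed(19)
  L <- 2e7
  # breakpoints uniform over the chromosome: calibrated p-values
  p_unif <- vapply(1:40, function(i) {
    breakpoint_exponential_test(sort(runif(40, 1, L)), region_length = L)
  }, numeric(1))
  expect_lt(mean(p_unif < 0.05), 0.2)
  # same count packed into 2% of the chromosome: overwhelming rejection
  p_clust <- breakpoint_exponential_test(sort(runif(40, 1, 0.02 * L)),
                                         region_length = L)
  expect_lt(p_clust, 1e-6)
})

test_that("chromosomal enrichment is a binomial tail with BH", {
  g <- tiny_genome(10, 1e7)
  conc <- setNames(c(100, rep(0, 9)), g$chromosomes$chrom)
  res <- chromosomal_enrichment_test(conc, g)
  expect_lt(res$p[1], 1e-10)
  expect_equal(res$p[1],
               pbinom(99, 100, 0.1, lower.tail = FALSE),
               tolerance = 1e-12)
  zero <- setNames(rep(0, 10), g$chromosomes$chrom)
  expect_true(all(chromosomal_enrichment_test(zero, g)$p == 1))
  prop <- setNames(rep(10, 10), g$chromosomes$chrom)
  expect_true(all(chromosomal_enrichment_test(prop, g)$q > 0.2))
})

test_that("fragment joins test matches chi-square expectations", {
  eq <- rbind(
    do.call(rbind, replicate(5, mk_intra(1e6, 2e6, "DEL"), simplify = FALSE)),
    do.call(rbind, replicate(5, mk_intra(1e6, 2e6, "DUP"), simplify = FALSE)),
    do.call(rbind, replicate(5, mk_intra(1e6, 2e6, "INV", "h2h"),
                             simplify = FALSE)),
    do.call(rbind, replicate(5, mk_intra(1e6, 2e6, "INV", "t2t"),
                             simplify = FALSE))
  )
  expect_gte(fragment_joins_test(eq), 0.99)
  skew <- do.call(rbind, replicate(20, mk_intra(1e6, 2e6, "DEL"),
                                   simplify = FALSE))
  expect_lt(fragment_joins_test(skew), 0.001)
  one <- mk_intra(1e6, 2e6, "DUP")
  p1 <- fragment_joins_test(one)
  expect_true(p1 >= 0 && p1 <= 1)
  expect_error(fragment_joins_test(one[0, ]), "at least one")
})

test_that("constructed chromothripsis is called and quiet genomes are not", {
  g <- tiny_genome(4, 2e7, seed = 3)
  # 40 interleaved SVs with exponential-like clustered breakpoints
  set.seed(23)
  starts <- 5e6 + cumsum(rexp(40, 1 / 5e4))
  widths <- rexp(40, 1 / 7.5e4) + 1e3
  # deletion-dominated joins so the fragment-joins test rejects (q < 0.2)
  types <- c(rep("DEL", 31), rep("DUP", 3), rep("INV", 6))
  chromo <- do.call(rbind, lapply(1:40, function(i) {
    mk_intra(round(starts[i]), round(starts[i] + widths[i]),
             type = types[i],
             orientation = if (types[i] == "INV") {
               c("h2h", "t2t")[(i %% 2) + 1]
             } else NA)
  }))
  osc_states <- rep(c(2, 3), 7)[1:13]
  seg <- data.frame(sample_id = "S1", chrom = "chr1",
                    start = seq(0, 12) * 1.5e6,
                    end = seq(1, 13) * 1.5e6,
                    total_cn = osc_states,
                    minor_cn = 1, subclonal_q = NA)
  seg_rest <- do.call(rbind, lapply(paste0("chr", 2:4), function(ch) {
    data.frame(sample_id = "S1", chrom = ch, start = 0, end = 2e7,
               total_cn = 2, minor_cn = 1, subclonal_q = NA)
  }))
  res <- call_complex_events(chromo, rbind(seg, seg_rest), g)
  call1 <- res$calls[res$calls$chrom == "chr1", ]
  expect_true(call1$called)
  expect_equal(call1$criterion, "A")
  expect_gt(call1$n_interleaved, 10)
  expect_true(res$complex_genome)
  # quiet genome: 2 dispersed SVs
  quiet <- rbind(mk_intra(2e6, 3e6), mk_intra(1.2e7, 1.3e7))
  resq <- call_complex_events(quiet, seg_rest, g)
  expect_false(any(resq$calls$called))
  expect_false(resq$complex_genome)
})

test_that("criterion B fires on >30 interleaved SVs without oscillations", {
  g <- tiny_genome(4, 2e7, seed = 3)
  set.seed(29)
  starts <- 5e6 + cumsum(rexp(35, 1 / 5e4))
  widths <- rexp(35, 1 / 7.5e4) + 1e3
  svs <- do.call(rbind, lapply(1:35, function(i) {
    mk_intra(round(starts[i]), round(starts[i] + widths[i]))
  }))
  seg <- do.call(rbind, lapply(paste0("chr", 1:4), function(ch) {
    data.frame(sample_id = "S1", chrom = ch, start = 0, end = 2e7,
               total_cn = 2, minor_cn = 1, subclonal_q = NA)
  }))
  res <- call_complex_events(svs, seg, g)
  call1 <- res$calls[res$calls$chrom == "chr1", ]
  if (call1$n_interleaved > 30 && !is.na(call1$q_exponential) &&
      call1$q_exponential < 0.05) {
    expect_equal(call1$criterion, "B")
    expect_true(call1$called)
  }
  expect_true(all(res$calls$osc_two_state == 0))
})

test_that("complex calls are monotone in added interleaved SVs", {
  g <- tiny_genome(4, 2e7, seed = 3)
  set.seed(31)
  starts <- 5e6 + cumsum(rexp(45, 1 / 5e4))
  widths <- rexp(45, 1 / 7.5e4) + 1e3
  all_svs <- do.call(rbind, lapply(1:45, function(i) {
    mk_intra(round(starts[i]), round(starts[i] + widths[i]))
  }))
  seg <- data.frame(sample_id = "S1", chrom = "chr1", start = 0, end = 2e7,
                    total_cn = 2, minor_cn = 1, subclonal_q = NA)
  r35 <- call_complex_events(all_svs[1:35, ], seg, g)
  r45 <- call_complex_events(all_svs, seg, g)
  if (r35$calls$called[r35$calls$chrom == "chr1"]) {
    expect_true(r45$calls$called[r45$calls$chrom == "chr1"])
  }
  expect_gte(r45$calls$n_interleaved[1], r35$calls$n_interleaved[1])
})
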