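test_that("genome generation is deterministic, normalised and positive", {
  g1 <- generate_genome(1, 1e7, seed = 1)
  g2 <- generate_genome(1, 1e7, seed = 1)
  expect_identical(g1, g2)
  g <- generate_genome(22, 1e8, seed = 7)
  expect_equal(nrow(g$chromosomes), 22)
  expect_equal(unname(rowSums(g$trinuc_freq)), rep(1, 22), tolerance = 1e-9)
  expect_true(all(g$trinuc_freq > 0))
  expect_true(all(g$chromosomes$centromere > 0 &
                    g$chromosomes$centromere < g$chromosomes$length))
  expect_error(generate_genome(0, 1e8), "n_chrom")
  expect_error(generate_genome(2, 1e6), "chrom_length")
})

test_that("background SNVs reproduce the planted signature mixture", {
  g <- tiny_genome(2, 5e7)
  snv <- simulate_snvs(g, ref_sigs4, c(1, 0, 0, 0), 50000, seed = 3)
  cat <- build_snv_catalogue(snv, "S1")
  emp <- cat[1, ] / sum(cat[1, ])
  expect_gte(cosine_similarity(emp, ref_sigs4$profiles[1, ]), 0.99)
})

test_that("SNV simulation handles empty input and rejects bad exposures", {
  g <- tiny_genome()
  expect_equal(nrow(simulate_snvs(g, ref_sigs4, c(1, 0, 0, 0), 0)), 0)
  expect_error(simulate_snvs(g, ref_sigs4, c(0.5, 0.2, 0, 0), 10),
               "simplex|sum to 1")
  expect_error(simulate_snvs(g, ref_sigs4, c(0.5, 0.5), 10), "match")
})

test_that("planted APOBEC kataegis clusters have the promised structure", {
  g <- tiny_genome()
  plan <- data.frame(chrom = "chr1", centre = 5e6, n = 10, apobec = TRUE)
  snv <- simulate_snvs(g, ref_sigs4, c(0.25, 0.25, 0.25, 0.25), 0,
                       kataegis_plan = plan, seed = 5)
  expect_equal(nrow(snv), 10)
  expect_lte(max(snv$pos) - min(snv$pos), 2e4)
  expect_true(all(snv$subst_class %in% c("C>T", "C>G")))
  expect_true(all(snv$context3 %in% c("TCA", "TCT")))
})

test_that("SV simulation respects class weights and determinism", {
  g <- tiny_genome()
  expect_equal(nrow(simulate_svs(g, rep(1 / 32, 32), 0,
                                 clustered_region = list(chrom = "chr1",
                                                         start = 1e6,
                                                         end = 3e6))), 0)
  w <- rep(0, 32)
  w[match("del/1-10kb/non-clustered", sv_channels())] <- 1
  svs <- simulate_svs(g, w, 40, seed = 2)
  expect_true(all(svs$sv_type == "DEL"))
  expect_true(all(svs$size >= 1e3 & svs$size <= 1e4))
  expect_identical(svs, simulate_svs(g, w, 40, seed = 2))
  expect_error(simulate_svs(g, rep(1, 32), 5), "simplex|sum to 1")
})

test_that("clustered-region SVs are flagged clustered downstream", {
  g <- tiny_genome()
  w <- rep(0, 32)
  w[match("del/1-10kb/clustered", sv_channels())] <- 1
  svs <- simulate_svs(g, w, 12,
                      clustered_region = list(chrom = "chr2", start = 4e6,
                                              end = 6e6),
                      seed = 4)
  svs <- flag_clustered_breakpoints(svs)
  expect_true(all(svs$clustered))
})

test_that("CN profiles recover ploidy, sub-clonality and oscillations", {
  g <- tiny_genome(4, 2e7)
  seg0 <- simulate_cn_profile(g, 2, 0, seed = 1)
  expect_true(all(seg0$total_cn == 2))
  expect_true(all(is.na(seg0$subclonal_q)))
  seg <- simulate_cn_profile(g, 3, 25, seed = 2)
  expect_equal(compute_ploidy(seg, g), 3, tolerance = 0.1)
  expect_equal(subclonal_cna_percent(seg, g)$genome_pct, 25,
               tolerance = 2)
  segc <- simulate_cn_profile(g, 2.5, 0, complex_chrom = "chr3", seed = 3)
  osc <- count_oscillations(segc[segc$chrom == "chr3", ])
  expect_gt(osc$two_state, 6)
  expect_error(simulate_cn_profile(g, 2, 101), "subclonal_pct")
})

test_that("expression archetypes are reproducible and vanish at zero separation", {
  s1 <- simulate_expression(600, c(5, 5, 5, 5), separation = 0,
                            gene_sets = default_immune_gene_sets(600, 10),
                            seed = 9)
  s2 <- simulate_expression(600, c(5, 5, 5, 5), separation = 0,
                            gene_sets = default_immune_gene_sets(600, 10),
                            seed = 9)
  expect_identical(s1$expr, s2$expr)
  # at zero separation the four archetypes are exchangeable
  grp_means <- tapply(colMeans(log(s1$expr)), s1$labels, mean)
  expect_lt(diff(range(grp_means)), 0.2)
  expect_error(
    simulate_expression(600, c(5, 5, 5, 5),
                        gene_sets = list(bad = "not_a_gene")),
    "absent"
  )
})

test_that("clinical simulation honours censoring contracts", {
  cl <- simulate_clinical(rep(1:4, each = 5), censor_rate = 0,
                          max_follow_up = Inf, seed = 1)
  expect_true(all(cl$os_event == 1))
  expect_true(all(cl$os_months >= 0))
  expect_error(simulate_clinical(rep(1, 5), hazard_by_cluster = c(0, 1, 1, 1)),
               "positive")
})

test_that("cluster-dependent hazards give log-rank power, equal hazards do not", {
  n_rep <- 60
  p_alt <- p_null <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    lab <- rep(c(1, 2), each = 30)
    alt <- simulate_clinical(lab, hazard_by_cluster = c(0.02, 0.06, 0.04, 0.05),
                             censor_rate = 0.005, seed = 1000 + r)
    nul <- simulate_clinical(lab, hazard_by_cluster = rep(0.04, 4),
                             censor_rate = 0.005, seed = 2000 + r)
    p_alt[r] <- logrank_test(alt$os_months, alt$os_event, lab)$p
    p_null[r] <- logrank_test(nul$os_months, nul$os_event, lab)$p
  }
  expect_gte(mean(p_alt < 0.05), 0.8)   # HR 3 between the groups
  expect_lte(mean(p_null < 0.05), 0.15) # near-nominal type I error
})
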