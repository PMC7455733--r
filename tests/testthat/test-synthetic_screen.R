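test_that("expected_log2_enrichment matches a Monte-Carlo sorting oracle", {
  # independent oracle: sort simulated cells at the fixed null quartile
  mc_oracle <- function(delta, q, n = 2e6) {
    z <- rnorm(n) + delta
    thr <- qnorm(1 - q)
    log2(mean(z > thr) / mean(z < -thr))
  }
  set.seed(101)
  for (d in c(0.5, 1)) {
    expect_lt(abs(expected_log2_enrichment(d, 0.25) - mc_oracle(d, 0.25)),
              0.03)
  }
  # frozen value from the oracle (z_0.25 ~= 0.6745)
  expect_equal(expected_log2_enrichment(1, 0.25), 3.7386, tolerance = 1e-4)
  expect_identical(expected_log2_enrichment(0, 0.25), 0)
})

test_that("expected_log2_enrichment is antisymmetric, monotone, and guarded", {
  d <- seq(-3, 3, by = 0.25)
  expect_equal(expected_log2_enrichment(d, 0.2),
               -expected_log2_enrichment(-d, 0.2))
  expect_true(all(diff(expected_log2_enrichment(d, 0.25)) > 0))
  expect_error(expected_log2_enrichment(1, 0), "\\(0, 0.5]")
  expect_error(expected_log2_enrichment(1, 0.6), "\\(0, 0.5]")
})

test_that("simulator is reproducible and symmetric under the null", {
  s1 <- small_sim(artifact_frac = 0)
  s2 <- small_sim(artifact_frac = 0)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$truth, s2$truth)

  sc <- score_screen(s1$counts)
  ph <- sc$guides$phenotype_live
  ph <- ph[!is.na(ph)]
  expect_lt(abs(mean(ph)), 3 * sd(ph) / sqrt(length(ph)))
})

test_that("empirical guide phenotypes agree with the closed-form oracle", {
  cfg <- sim_config(n_genes = 5, guides_per_gene = 4, n_nontargeting = 200,
                    effects = c(G00001 = 1), efficacy_shape = NULL,
                    reads_per_guide = 1e4, artifact_frac = 0, seed = 9)
  sim <- simulate_sorted_screen(cfg)
  sc <- score_screen(sim$counts)
  g <- sc$guides[!is.na(sc$guides$gene_id) & sc$guides$gene_id == "G00001", ]
  expect_lt(abs(mean(g$phenotype_live) - expected_log2_enrichment(1, 0.25)),
            0.15)
})

test_that("dead channel carries artifacts but not ATP effects", {
  cfg <- sim_config(n_genes = 50, n_nontargeting = 300,
                    effects = c(G00001 = 2), efficacy_shape = NULL,
                    artifact_frac = 0.05, artifact_shift = 1,
                    reads_per_guide = 2000, seed = 3)
  sim <- simulate_sorted_screen(cfg)
  sc <- score_screen(sim$counts)
  g <- sc$guides
  art <- sim$truth$sgrna_id[sim$truth$artifact_shift != 0]
  # artifact guides are flagged from the dead channel
  expect_true(all(g$dead_flag[g$sgrna_id %in% art] != 0))
  # guides of the delta = 2 gene show no dead-sensor phenotype
  hit_guides <- g[g$gene_id %in% "G00001" & !(g$sgrna_id %in% art), ]
  nt_dead <- g$phenotype_dead[is.na(g$gene_id) & g$dead_flag == 0]
  expect_true(all(abs(hit_guides$phenotype_dead - mean(nt_dead)) <
                    4 * sd(nt_dead)))
})

test_that("paired assays honour their rate semantics", {
  cfg <- sim_config(n_genes = 40, n_nontargeting = 200,
                    reads_per_guide = 5000, artifact_frac = 0, seed = 5)
  # null growth: all rates equal => fold changes ~= 1
  g0 <- simulate_paired_assay(cfg, rates = 1, assay = "growth")
  t0 <- score_paired_assay(g0$counts)
  expect_lt(abs(median(t0$fold_change) - 1), 0.02)

  # one gene with doubled post-growth abundance => fold ~= 2
  g2 <- simulate_paired_assay(cfg, rates = c(G00007 = 2), assay = "growth")
  t2 <- score_paired_assay(g2$counts)
  expect_equal(mean(t2$fold_change[t2$gene_id %in% "G00007"]), 2,
               tolerance = 0.1)
  expect_true(all(t2$hit[t2$gene_id %in% "G00007"] == "high"))

  # consumption sign convention: slow consumer stays in the high fraction
  cc <- simulate_paired_assay(cfg, rates = c(G00001 = 0.5, G00002 = 2),
                              assay = "consumption")
  tc <- score_paired_assay(cc$counts)
  slow <- mean(tc$fold_change[tc$gene_id %in% "G00001"])
  fast <- mean(tc$fold_change[tc$gene_id %in% "G00002"])
  expect_gt(slow, 1)
  expect_lt(fast, 1)

  expect_error(simulate_paired_assay(cfg, rates = -1, assay = "growth"),
               "nonnegative")
})

test_that("sim_config validates its domain", {
  expect_error(sim_config(10, q = 0.7), "q")
  expect_error(sim_config(10, effects = 1), "named")
  expect_error(sim_config(0), "n_genes")
})
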