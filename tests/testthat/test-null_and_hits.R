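test_that("build_quasi_genes: degenerate null, count contract, reproducibility", {
  q0 <- build_quasi_genes(rep(0, 50), n_quasi = 20, seed = 1)
  expect_true(all(q0$phenotype == 0))
  expect_identical(q0$sd, 0)

  # one quasi-gene per targeting transcript in the sublibrary
  q <- build_quasi_genes(rnorm(100), n_quasi = 3020, seed = 1)
  expect_length(q$phenotype, 3020)

  nt <- rnorm(100)
  qa <- build_quasi_genes(nt, 50, seed = 7)
  qb <- build_quasi_genes(nt, 50, seed = 7)
  expect_identical(qa$phenotype, qb$phenotype)

  expect_error(build_quasi_genes(rnorm(5), 10, guides_per_quasi = 10),
               "at least 10")
})

test_that("quasi null matches a brute-force Monte-Carlo oracle", {
  # oracle: fresh 10-guide draws, top-3 by |value|, signed mean -
  # implemented independently of the package's summarizer
  set.seed(31)
  oracle <- apply(matrix(rnorm(1e5 * 10), ncol = 10), 1, function(v) {
    mean(v[order(-abs(v))][1:3])
  })
  nt <- rnorm(5e4)
  q <- build_quasi_genes(nt, n_quasi = 2e4, seed = 13)
  # mean tolerance covers finite-pool + resampling error (~3 sigma)
  expect_lt(abs(q$mean - mean(oracle)), 0.04)
  expect_lt(abs(q$sd - sd(oracle)) / sd(oracle), 0.02)
})

test_that("quasi-null SD stabilizes with nontargeting pool size", {
  set.seed(17)
  nt <- rnorm(1400)
  sd_sub <- build_quasi_genes(nt[1:500], n_quasi = 2e4, seed = 5)$sd
  sd_full <- build_quasi_genes(nt, n_quasi = 2e4, seed = 5)$sd
  expect_lt(abs(sd_sub - sd_full) / sd_full, 0.05)
})

test_that("z_score arithmetic and guard", {
  expect_identical(z_score(0.7, 0.7, 2), 0)
  expect_equal(z_score(0.1 + 3 * 0.8, 0.1, 0.8), 3)
  expect_equal(z_score(2.5, 0.1, 0.8), 3)
  expect_error(z_score(1, 0, 0), "positive")
})

test_that("mw_concordance: exact small-sample value, ties, guards", {
  # 3 fully separated vs 3: 2 extreme arrangements of C(6,3) = 20
  expect_equal(mw_concordance(c(4, 5, 6), c(1, 2, 3)), 0.10)
  expect_identical(mw_concordance(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_error(mw_concordance(numeric(0), 1:3), "nonempty")
  # large-sample path returns a sane two-sided p
  set.seed(4)
  p <- mw_concordance(rnorm(10, 2), rnorm(1400))
  expect_lt(p, 1e-4)
})

test_that("call_hits implements the per-condition rules", {
  set.seed(8)
  nt_live <- rnorm(1000, 0, 0.1)
  nt_dead <- rnorm(1000, 0, 0.1)
  m <- mean(nt_live); s <- sd(nt_live)
  mk <- function(gene, live, dead = rep(0, length(live))) {
    data.frame(sgrna_id = paste0(gene, "_", seq_along(live)),
               gene_id = gene, phenotype_live = live,
               phenotype_dead = dead, stringsAsFactors = FALSE)
  }
  # 2 guides at +4 SD, 8 at the NT mean
  g2 <- mk("A", c(rep(m + 4 * s, 2), rep(m, 8)))
  resp <- call_hits(g2, nt_live, nt_dead, hit_rule("respiratory"))
  expect_identical(resp$call, "high")
  glyc <- call_hits(g2, nt_live, nt_dead, hit_rule("glycolytic"))
  expect_identical(glyc$call, "none")

  # same-direction dead-sensor phenotype excludes the respiratory hit
  md <- mean(nt_dead); sd_d <- sd(nt_dead)
  g_art <- mk("B", c(rep(m + 4 * s, 2), rep(m, 8)),
              c(rep(md + 4 * sd_d, 2), rep(md, 8)))
  resp_art <- call_hits(g_art, nt_live, nt_dead, hit_rule("respiratory"))
  expect_identical(resp_art$call, "none")
  expect_true(resp_art$dead_excluded)
  # opposite-direction dead phenotype does not exclude
  g_opp <- mk("C", c(rep(m + 4 * s, 2), rep(m, 8)),
              c(rep(md - 4 * sd_d, 2), rep(md, 8)))
  expect_identical(call_hits(g_opp, nt_live, nt_dead,
                             hit_rule("respiratory"))$call, "high")

  # glycolytic mode removes dead-flagged guides before counting
  g_rm <- mk("D", c(rep(m + 4 * s, 3), rep(m, 7)),
             c(md + 3 * sd_d, rep(md, 9)))
  glyc_rm <- call_hits(g_rm, nt_live, nt_dead, hit_rule("glycolytic"))
  expect_identical(glyc_rm$call, "none")  # only 2 surviving guides beyond
  expect_identical(glyc_rm$n_high, 2L)

  # low-direction calls work symmetrically
  g_low <- mk("E", c(rep(m - 4 * s, 3), rep(m, 7)))
  expect_identical(call_hits(g_low, nt_live, nt_dead,
                             hit_rule("glycolytic"))$call, "low")
})

test_that("estimate_specificity arithmetic", {
  expect_identical(estimate_specificity(0, 3000), 100)
  expect_identical(estimate_specificity(12, 3000), 99.6)
  expect_identical(estimate_specificity(c("high", "none", "low"), 3), 100 / 3)
})

test_that("screen_hits: MW filter is monotone; hit calling monotone in effect", {
  # deltas spanning the detection ramp (NT SD is ~0.075 log2 units, so the
  # 3 SD guide threshold sits near a 0.06 SD cell-level shift)
  deltas <- c(0.02, 0.05, 0.12, 0.4)
  eff <- setNames(rep(deltas, each = 20), sprintf("G%05d", 1:80))
  cfg <- sim_config(n_genes = 160, n_nontargeting = 400, effects = eff,
                    seed = 12)
  sim <- simulate_sorted_screen(cfg)
  sc <- score_screen(sim$counts)
  hits <- screen_hits(sc, seed = 21)
  g <- hits$genes
  expect_lte(sum(g$call_mw != "none"), sum(g$call != "none"))
  sens <- vapply(deltas, function(d) {
    genes <- names(eff)[eff == d]
    mean(g$call[g$gene_id %in% genes] == "high")
  }, 0)
  expect_true(all(diff(sens) >= 0))
  expect_equal(sens[4], 1)
  # z-scores against the quasi null agree in direction with the calls
  expect_true(all(g$z[g$call == "high"] > 0))
})
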