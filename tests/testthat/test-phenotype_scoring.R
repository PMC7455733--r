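test_that("normalize_to_nontargeting follows the declared pseudocount rule", {
  is_nt <- c(FALSE, TRUE, TRUE)
  # NT total 1000, guide count 10, no pseudocount -> 0.01
  expect_equal(normalize_to_nontargeting(c(10, 400, 600), is_nt, 0)[1], 0.01)
  # invariance under global rescaling of the sample
  v <- c(10, 400, 600)
  expect_equal(normalize_to_nontargeting(2 * v, is_nt, 0),
               normalize_to_nontargeting(v, is_nt, 0))
  # zero count with pseudocount 1 and NT total (incl. pseudocounts) 1018
  out <- normalize_to_nontargeting(c(0, 416, 600), is_nt, 1)
  expect_equal(out[1], 1 / 1018)
  # guard
  expect_error(normalize_to_nontargeting(c(5, 0, 0), is_nt, 0),
               "nontargeting total is zero")
})

test_that("sgrna_phenotype is a guarded log2 ratio", {
  expect_identical(sgrna_phenotype(0.3, 0.3), 0)
  expect_identical(sgrna_phenotype(4, 1), 2)
  # raw high 40, raw low 0, equal NT totals 1000 (with pseudocounts),
  # pseudocount 1 -> log2(41/1)
  expect_equal(sgrna_phenotype(41 / 1000, 1 / 1000), log2(41),
               tolerance = 1e-12)
  expect_error(sgrna_phenotype(0, 1), "positive")
})

test_that("dead-sensor flags follow the 2 SD rule with direction", {
  nt <- c(-0.1, 0.05, 0, 0.1, -0.05, 0.02, -0.02, 0.08)
  m <- mean(nt); s <- sd(nt)
  dead <- c(0, m + 2.5 * s, m - 1.9 * s, m - 3 * s, NA)
  expect_identical(flag_dead_sensor_artifacts(dead, nt),
                   c(0L, 1L, 0L, -1L, 0L))
  expect_identical(flag_dead_sensor_artifacts(rep(0, 4), nt),
                   rep(0L, 4))
  expect_warning(f <- flag_dead_sensor_artifacts(c(1, 2), c(0.5, 0.5)),
                 "degenerate")
  expect_identical(f, c(0L, 0L))
  expect_error(flag_dead_sensor_artifacts(1, numeric(0)), ">= 2")
})

test_that("gene_phenotype applies exclusion-then-top-k with signed averaging", {
  v <- setNames(rep(2.5, 10), sprintf("g%02d", 1:10))
  expect_equal(gene_phenotype(v)$phenotype, 2.5)

  v2 <- setNames(c(5, 4, 3, rep(0.1, 7)), sprintf("g%02d", 1:10))
  expect_equal(gene_phenotype(v2)$phenotype, 4)

  v3 <- setNames(c(5, 4, 3, 2, rep(0.1, 6)), sprintf("g%02d", 1:10))
  flags <- c(1L, rep(0L, 9))
  gp <- gene_phenotype(v3, flags)
  expect_equal(gp$phenotype, 3)
  expect_identical(gp$guides, c("g02", "g03", "g04"))
  expect_false(gp$low_confidence)

  # fewer than k eligible guides: value from the remainder, low confidence
  gp2 <- gene_phenotype(setNames(c(2, 1), c("a", "b")))
  expect_equal(gp2$phenotype, 1.5)
  expect_true(gp2$low_confidence)
  expect_true(is.na(gene_phenotype(setNames(NA_real_, "a"))$phenotype))

  # absolute ranking mixes signs; dominant ranking stays one-sided
  v4 <- setNames(c(-5, 4, 3, 2, 0.1), letters[1:5])
  expect_equal(gene_phenotype(v4, mode = "absolute")$phenotype,
               (-5 + 4 + 3) / 3)
  expect_equal(gene_phenotype(v4, mode = "dominant")$phenotype, 3)
})

test_that("gene_phenotype is monotone for high-direction genes", {
  set.seed(2)
  for (i in 1:20) {
    v <- setNames(abs(rnorm(8)), sprintf("g%d", 1:8))
    base <- gene_phenotype(v)$phenotype
    j <- sample(8, 1)
    v[j] <- v[j] + runif(1, 0, 2)
    expect_gte(gene_phenotype(v)$phenotype, base - 1e-12)
  }
})

test_that("score_screen: scale invariance and fraction-swap antisymmetry", {
  lib <- toy_library()
  high <- c(40, 35, 10, 12, 100, 110)
  low <- c(10, 12, 38, 41, 105, 95)
  x <- toy_counts(high, low, lib)
  sc <- suppressWarnings(score_screen(x, min_counts = 0))

  x_scaled <- toy_counts(high * 7, low, lib)
  sc_scaled <- suppressWarnings(score_screen(x_scaled, min_counts = 0,
                                             pseudocount = 0))
  sc_unscaled <- suppressWarnings(score_screen(x, min_counts = 0,
                                               pseudocount = 0))
  expect_equal(sc_scaled$guides$phenotype_live,
               sc_unscaled$guides$phenotype_live, tolerance = 1e-12)

  x_swap <- toy_counts(low, high, lib)
  sc_swap <- suppressWarnings(score_screen(x_swap, min_counts = 0))
  expect_equal(sc_swap$guides$phenotype_live, -sc$guides$phenotype_live,
               tolerance = 1e-12)
})

test_that("low-count filter and replicate averaging behave as declared", {
  lib <- toy_library()
  m <- cbind(r1_high = c(40, 2, 10, 12, 100, 110),
             r1_low = c(10, 3, 38, 41, 105, 95),
             r2_high = c(44, 0, 11, 10, 95, 100),
             r2_low = c(9, 1, 40, 39, 110, 100))
  rownames(m) <- lib$sgrna_id
  sheet <- sample_sheet(colnames(m), "respiratory",
                        rep(c("high", "low"), 2), rep(1:2, each = 2),
                        "live", "atp")
  x <- sorted_count_set(m, lib, sheet)
  sc <- suppressWarnings(score_screen(x, min_counts = 10))
  g <- sc$guides
  # guide 2 never reaches 10 reads across a pair: NA after averaging
  expect_true(is.na(g$phenotype_live[g$sgrna_id == "GENE1_g2"]))
  # averaged phenotype equals mean of the per-replicate phenotypes
  per_rep <- sc$sgrna[sc$sgrna$sgrna_id == "GENE1_g1" &
                        sc$sgrna$replicate != "avg", "phenotype"]
  avg <- sc$sgrna[sc$sgrna$sgrna_id == "GENE1_g1" &
                    sc$sgrna$replicate == "avg", "phenotype"]
  expect_equal(avg, mean(per_rep))
})
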