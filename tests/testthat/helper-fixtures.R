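# Shared fixture builders: everything generated in code, nothing on disk
# except through tempfiles.

# Tiny hand-built library: 2 genes x 2 guides + 2 nontargeting guides.
toy_library <- function() {
  library_table(c("GENE1_g1", "GENE1_g2", "GENE2_g1", "GENE2_g2",
                  "NT_1", "NT_2"),
                c("GENE1", "GENE1", "GENE2", "GENE2", NA, NA))
}

toy_sheet <- function(condition = "respiratory", sensor = "live") {
  sample_sheet(c("s_high", "s_low"), condition, c("high", "low"), 1L,
               sensor, "atp")
}

toy_counts <- function(high, low, lib = toy_library()) {
  m <- cbind(s_high = high, s_low = low)
  rownames(m) <- lib$sgrna_id
  sorted_count_set(m, lib, toy_sheet())
}

# Write a library TSV (NT sentinel spelled out) and return the path.
write_library_tsv <- function(lib, path = tempfile(fileext = ".tsv")) {
  df <- as.data.frame(lib)
  df$gene_id[is.na(df$gene_id)] <- NT_LABEL
  write_results(df, path)
  path
}

# The published mini-library shape: 246 targeting guides over 150 genes
# plus 18 nontargeting guides (96 genes x 2 guides + 54 genes x 1).
mini_library <- function() {
  genes <- sprintf("MG%03d", 1:150)
  per_gene <- rep(c(2L, 1L), c(96L, 54L))
  gid <- rep(genes, per_gene)
  sg <- paste0(gid, "_g", unlist(lapply(per_gene, seq_len)))
  library_table(c(sg, sprintf("MNT_%02d", 1:18)),
                c(gid, rep(NA, 18)))
}

# Small simulated screen used by several suites.
small_sim <- function(effects = numeric(0), seed = 42, ...) {
  cfg <- sim_config(n_genes = 100, n_nontargeting = 300,
                    effects = effects, seed = seed, ...)
  simulate_sorted_screen(cfg)
}
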