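#' @title Generative model of a FACS-sorted biosensor screen
#' @description Simulates sorted-screen read counts with known ground truth.
#'   Each guide shifts the (standard-normal) cell-level biosensor readout by
#'   its true effect; cells in the top and bottom `q` population quantiles
#'   are collected, and reads per fraction are drawn multinomially with
#'   probabilities proportional to guide abundance times the probability of
#'   a cell landing in that fraction. The dead-sensor channel carries no ATP
#'   effects but retains sensor artifacts, mirroring the screen's control
#'   arm.
#' @name synthetic_screen
NULL

#' Expected log2 enrichment of a shifted guide under quantile sorting
#'
#' For a guide shifting the cell-level readout by `delta` population
#' standard deviations, the expected log2 ratio of its representation in
#' the top-q versus bottom-q sorted fractions is
#' `log2[(1 - F(z_q - delta)) / F(-z_q - delta)]`, where `F` is the
#' standard-normal CDF and `z_q` the upper-q quantile. Antisymmetric in
#' `delta`; zero at `delta = 0`.
#'
#' @param delta numeric vector of effects in population-SD units.
#' @param q sort fraction in (0, 0.5]; 0.25 collects quartiles.
#' @return expected phenotype(s) in log2 units.
#' @examples
#' expected_log2_enrichment(1, 0.25)  # ~= 3.74
#' @export
expected_log2_enrichment <- function(delta, q = 0.25) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0 || q > 0.5)
    stop("q must lie in (0, 0.5]")
  zq <- stats::qnorm(q, lower.tail = FALSE)
  # log-space for numerical stability at large |delta|
  (stats::pnorm(zq - delta, lower.tail = FALSE, log.p = TRUE) -
     stats::pnorm(-zq - delta, log.p = TRUE)) / log(2)
}

#' Configuration for the sorted-screen simulator
#'
#' Defaults mirror the screened libraries: ten sgRNAs per gene, ~1400
#' nontargeting guides per sublibrary, quartile sorting, two replicates.
#'
#' @param n_genes number of targeting genes.
#' @param guides_per_gene guides per gene (default 10).
#' @param n_nontargeting number of nontargeting control guides (default 1400).
#' @param effects named numeric vector gene -> true effect delta in
#'   population-SD units; genes not named have delta 0. Guides of a hit
#'   gene draw per-guide efficacies in [0,1] scaling delta.
#' @param efficacy_shape Beta shape parameters for per-guide efficacy
#'   (default c(5, 2): most guides effective, a tail of weak ones); NULL
#'   fixes every efficacy at 1 (exact effects, useful against the
#'   closed-form oracle).
#' @param q sort fraction in (0, 0.5] (default 0.25, quartiles).
#' @param reads_per_guide mean sequencing reads per guide per fraction
#'   sample (default 400).
#' @param n_replicates biological replicates (default 2).
#' @param artifact_frac fraction of guides given a sensor artifact shift
#'   applied to BOTH live and dead channels (default 0.01).
#' @param artifact_shift magnitude (SD units) of artifact shifts; sign
#'   random per guide.
#' @param abundance_sdlog log-normal sigma of guide abundances (default
#'   0.3, mild representation skew typical of pooled libraries).
#' @param overdispersion optional Dirichlet concentration; `NULL` (default)
#'   gives plain multinomial sequencing noise.
#' @param condition condition label stamped on the samples.
#' @param seed integer RNG seed; all randomness derives from it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_genes, guides_per_gene = 10L, n_nontargeting = 1400L,
                       effects = numeric(0), efficacy_shape = c(5, 2),
                       q = 0.25, reads_per_guide = 400,
                       n_replicates = 2L, artifact_frac = 0.01,
                       artifact_shift = 0.5, abundance_sdlog = 0.3,
                       overdispersion = NULL,
                       condition = "respiratory", seed = 1L) {
  stopifnot(n_genes >= 1, guides_per_gene >= 1, n_nontargeting >= 1,
            q > 0, q <= 0.5, reads_per_guide > 0, n_replicates >= 1,
            artifact_frac >= 0, artifact_frac <= 1, abundance_sdlog >= 0)
  if (length(effects) && is.null(names(effects)))
    stop("effects must be a named vector (gene -> delta)")
  if (!is.null(overdispersion) && overdispersion <= 0)
    stop("overdispersion concentration must be positive")
  structure(list(n_genes = as.integer(n_genes),
                 guides_per_gene = as.integer(guides_per_gene),
                 n_nontargeting = as.integer(n_nontargeting),
                 effects = effects, efficacy_shape = efficacy_shape,
                 q = q, reads_per_guide = reads_per_guide,
                 n_replicates = as.integer(n_replicates),
                 artifact_frac = artifact_frac,
                 artifact_shift = artifact_shift,
                 abundance_sdlog = abundance_sdlog,
                 overdispersion = overdispersion,
                 condition = condition, seed = as.integer(seed)),
            class = "sim_config")
}

sim_library_ <- function(config) {
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  tg <- paste0(rep(genes, each = config$guides_per_gene), "_g",
               sprintf("%02d", seq_len(config$guides_per_gene)))
  nt <- sprintf("NT_%05d", seq_len(config$n_nontargeting))
  library_table(c(tg, nt),
                c(rep(genes, each = config$guides_per_gene),
                  rep(NA_character_, config$n_nontargeting)))
}

# Ground truth per guide: ATP shift (live channel only) and artifact shift
# (both channels). Consumes RNG.
sim_truth_ <- function(config, library) {
  n <- nrow(library)
  delta_gene <- rep(0, n)
  if (length(config$effects)) {
    idx <- match(library$gene_id, names(config$effects))
    delta_gene[!is.na(idx)] <- config$effects[idx[!is.na(idx)]]
  }
  efficacy <- rep(1, n)
  hit <- delta_gene != 0
  if (any(hit) && !is.null(config$efficacy_shape))
    efficacy[hit] <- stats::rbeta(sum(hit), config$efficacy_shape[1L],
                                  config$efficacy_shape[2L])
  delta_guide <- delta_gene * efficacy
  artifact <- rep(0, n)
  n_art <- round(config$artifact_frac * n)
  if (n_art > 0) {
    pick <- sample.int(n, n_art)
    artifact[pick] <- config$artifact_shift * sample(c(-1, 1), n_art,
                                                     replace = TRUE)
  }
  cls <- ifelse(artifact != 0, "artifact",
                ifelse(delta_gene > 0, "high_atp",
                       ifelse(delta_gene < 0, "low_atp", "null")))
  data.frame(sgrna_id = library$sgrna_id, gene_id = library$gene_id,
             delta_gene = delta_gene, delta_guide = delta_guide,
             artifact_shift = artifact, class = cls,
             stringsAsFactors = FALSE)
}

# One fraction sample: multinomial reads with probabilities
# abundance * P(cell sorted into fraction | guide shift).
sim_fraction_counts_ <- function(shift, abundance, q, total_reads,
                                 fraction = c("high", "low"),
                                 overdispersion = NULL) {
  fraction <- match.arg(fraction)
  zq <- stats::qnorm(q, lower.tail = FALSE)
  p_sort <- if (fraction == "high") {
    stats::pnorm(zq - shift, lower.tail = FALSE)
  } else {
    stats::pnorm(-zq - shift)
  }
  w <- abundance * p_sort
  p <- w / sum(w)
  if (!is.null(overdispersion)) {
    g <- stats::rgamma(length(p), shape = overdispersion * p, rate = 1)
    p <- g / sum(g)
  }
  as.numeric(stats::rmultinom(1L, size = round(total_reads), prob = p))
}

#' Simulate a sorted biosensor screen with known ground truth
#'
#' Generates live and dead sensor channels: the live channel applies each
#' guide's true ATP shift plus any artifact shift; the dead channel applies
#' artifact shifts only. Reproducible given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (a [sorted_count_set()]) and `truth`
#'   (per-guide data.frame of true effects and classes).
#' @export
simulate_sorted_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  library <- sim_library_(config)
  truth <- sim_truth_(config, library)
  abundance <- stats::rlnorm(nrow(library), 0, config$abundance_sdlog)
  total <- config$reads_per_guide * nrow(library)

  ids <- character(0); cond <- character(0); frac <- character(0)
  reps <- integer(0); sens <- character(0)
  cols <- list()
  for (sensor in c("live", "dead")) {
    shift <- truth$artifact_shift +
      if (sensor == "live") truth$delta_guide else 0
    for (r in seq_len(config$n_replicates)) {
      for (fr in c("high", "low")) {
        sid <- sprintf("%s_r%d_%s_%s", substr(config$condition, 1, 4), r,
                       sensor, fr)
        cols[[sid]] <- sim_fraction_counts_(shift, abundance, config$q,
                                            total, fr,
                                            config$overdispersion)
        ids <- c(ids, sid); cond <- c(cond, config$condition)
        frac <- c(frac, fr); reps <- c(reps, r); sens <- c(sens, sensor)
      }
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- library$sgrna_id
  samples <- sample_sheet(ids, cond, frac, reps, sens, "atp")
  list(counts = sorted_count_set(m, library, samples), truth = truth)
}

#' Simulate a paired (pre/post or high/low) derived assay
#'
#' Emulates the mini-library follow-up assays with a per-guide rate:
#' \describe{
#'   \item{growth}{`pre`/`post` abundance samples; post-growth abundance is
#'     multiplied by the guide's rate (fold growth relative to baseline), so
#'     a rate of 2 doubles representation.}
#'   \item{mito}{`high`/`low` sort on mitochondrial content; the sort shift
#'     is `log2(rate)` SD units (rate = content multiplier; rate 1 = null).}
#'   \item{consumption}{`high`/`low` ATP sort after blocking ATP
#'     production; the post-depletion sort shift is `-log2(rate)` (rate =
#'     relative consumption rate; slow consumers, rate < 1, stay enriched
#'     in the high-ATP fraction).}
#' }
#'
#' @param config a [sim_config()]; `effects` are ignored for growth/mito
#'   and set the pre-depletion shifts for consumption.
#' @param rates named or unnamed numeric vector of per-guide nonnegative
#'   rates (recycled over targeting guides if named by gene); guides not
#'   covered get rate 1.
#' @param assay one of "growth", "mito", "consumption".
#' @return list with `counts` (a [sorted_count_set()], samples labelled
#'   with the assay) and `truth` (per-guide rates).
#' @export
simulate_paired_assay <- function(config, rates,
                                  assay = c("growth", "mito", "consumption")) {
  assay <- match.arg(assay)
  stopifnot(inherits(config, "sim_config"))
  if (any(rates < 0, na.rm = TRUE)) stop("rates must be nonnegative")
  set.seed(config$seed)
  library <- sim_library_(config)
  rate <- rep(1, nrow(library))
  if (!is.null(names(rates))) {
    bygene <- match(library$gene_id, names(rates))
    rate[!is.na(bygene)] <- rates[bygene[!is.na(bygene)]]
    byguide <- match(library$sgrna_id, names(rates))
    rate[!is.na(byguide)] <- rates[byguide[!is.na(byguide)]]
  } else {
    rate <- rep_len(rates, nrow(library))
  }
  abundance <- stats::rlnorm(nrow(library), 0, config$abundance_sdlog)
  total <- config$reads_per_guide * nrow(library)
  mult_draw <- function(w) {
    as.numeric(stats::rmultinom(1L, round(total), w / sum(w)))
  }

  ids <- character(0); frac <- character(0); reps <- integer(0)
  cols <- list()
  for (r in seq_len(config$n_replicates)) {
    if (assay == "growth") {
      pair <- list(pre = mult_draw(abundance),
                   post = mult_draw(abundance * rate))
    } else {
      shift <- if (assay == "mito") log2(rate) else -log2(rate)
      pair <- list(
        high = sim_fraction_counts_(shift, abundance, config$q, total,
                                    "high", config$overdispersion),
        low = sim_fraction_counts_(shift, abundance, config$q, total,
                                   "low", config$overdispersion))
    }
    for (fr in names(pair)) {
      sid <- sprintf("%s_r%d_%s", assay, r, fr)
      cols[[sid]] <- pair[[fr]]
      ids <- c(ids, sid); frac <- c(frac, fr); reps <- c(reps, r)
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- library$sgrna_id
  samples <- sample_sheet(ids, config$condition, frac, reps, "live", assay)
  truth <- data.frame(sgrna_id = library$sgrna_id,
                      gene_id = library$gene_id, rate = rate,
                      stringsAsFactors = FALSE)
  list(counts = sorted_count_set(m, library, samples), truth = truth)
}
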