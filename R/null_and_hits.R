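#' @title Quasi-gene null, Z-scores, hit rules, concordance, specificity
#' @description The screen's statistical machinery: a resampling null built
#'   from nontargeting guides ("quasi-genes" summarized exactly like real
#'   genes), Z-scores against that null, condition-specific guide-count hit
#'   rules with dead-sensor exclusion, Mann-Whitney guide-concordance
#'   p-values, and specificity estimated from the quasi-gene hit rate.
#' @name null_and_hits
NULL

#' Build the quasi-gene resampling null
#'
#' Each quasi-gene draws `guides_per_quasi` nontargeting guide phenotypes
#' (without replacement within a quasi-gene, with replacement across
#' quasi-genes) and is summarized with the same top-k rule as real genes,
#' so the null distribution is directly comparable to gene phenotypes.
#'
#' @param nt_phenotypes replicate-averaged nontargeting guide phenotypes
#'   (dead-flagged guides already removed), length >= `guides_per_quasi`.
#' @param n_quasi number of quasi-genes, conventionally the number of
#'   targeting genes in the sublibrary.
#' @param guides_per_quasi guides per quasi-gene (default 10, the library's
#'   guides-per-gene).
#' @param k top-k summarization (default 3), matching [gene_phenotype()].
#' @param seed integer seed; the null is reproducible given it.
#' @param mode top-k ranking mode, see [gene_phenotype()].
#' @return a `quasi_null`: list with `phenotype` (length `n_quasi`),
#'   `assignment` (n_quasi x guides_per_quasi index matrix into
#'   `nt_phenotypes`), `mean`, `sd`, `seed`, `guides_per_quasi`, `k`.
#' @export
build_quasi_genes <- function(nt_phenotypes, n_quasi,
                              guides_per_quasi = 10L, k = 3L, seed = 1L,
                              mode = c("absolute", "dominant")) {
  mode <- match.arg(mode)
  nt_phenotypes <- as.numeric(nt_phenotypes)
  n <- length(nt_phenotypes)
  if (n < guides_per_quasi)
    stop("need at least ", guides_per_quasi, " nontargeting phenotypes, got ", n)
  stopifnot(n_quasi >= 1)
  set.seed(seed)
  assignment <- t(vapply(seq_len(n_quasi),
                         function(i) sample.int(n, guides_per_quasi),
                         integer(guides_per_quasi)))
  phen <- apply(assignment, 1L, function(ix) {
    v <- nt_phenotypes[ix]
    mean(v[top_k_idx_(v, k, mode)])
  })
  structure(list(phenotype = phen, assignment = assignment,
                 guides_per_quasi = as.integer(guides_per_quasi),
                 k = as.integer(k), seed = as.integer(seed),
                 mean = mean(phen), sd = stats::sd(phen)),
            class = "quasi_null")
}

#' @export
print.quasi_null <- function(x, ...) {
  cat(sprintf("quasi_null: %d quasi-genes of %d guides (top-%d), mean %.4g, sd %.4g, seed %d\n",
              length(x$phenotype), x$guides_per_quasi, x$k, x$mean, x$sd,
              x$seed))
  invisible(x)
}

#' Standard score of a gene phenotype against a reference distribution
#' @param gene_value phenotype value(s).
#' @param ref_mean,ref_sd reference mean and (positive) SD, e.g. of the
#'   quasi-gene null or the nontargeting guides.
#' @return `(gene_value - ref_mean) / ref_sd`.
#' @export
z_score <- function(gene_value, ref_mean, ref_sd) {
  if (!is.finite(ref_sd) || ref_sd <= 0) stop("ref_sd must be positive")
  (gene_value - ref_mean) / ref_sd
}

#' Mann-Whitney concordance p-value of a gene's guides
#'
#' Two-sided Mann-Whitney U test of a gene's guide phenotypes against the
#' nontargeting guides; a small p indicates concordant displacement of the
#' gene's guides from the null and raises confidence in the phenotype.
#' Exact for small untied samples, normal approximation with tie and
#' continuity correction otherwise.
#'
#' @param targeting one gene's guide phenotypes (nonempty).
#' @param nontargeting nontargeting guide phenotypes (nonempty).
#' @return two-sided p-value.
#' @export
mw_concordance <- function(targeting, nontargeting) {
  targeting <- targeting[!is.na(targeting)]
  nontargeting <- nontargeting[!is.na(nontargeting)]
  if (!length(targeting) || !length(nontargeting))
    stop("both samples must be nonempty")
  if (length(unique(c(targeting, nontargeting))) == 1L) return(1)
  p <- suppressWarnings(
    stats::wilcox.test(targeting, nontargeting, correct = TRUE)$p.value)
  if (!is.finite(p)) 1 else min(p, 1)
}

#' Condition-specific hit-calling rule
#'
#' The respiratory condition (wider nontargeting distribution) calls a hit
#' from two or more guides beyond 3 SD of the nontargeting guides and
#' excludes genes meeting the same rule in the same direction on the dead
#' sensor. The glycolytic and basal conditions (narrower null) require
#' three or more guides and instead remove individual guides beyond 2 SD
#' on the dead sensor before counting.
#'
#' @param condition "respiratory", "glycolytic" or "basal".
#' @param min_guides_beyond override the per-condition guide count.
#' @param guide_sd_multiple live-sensor threshold in NT SD units (default 3).
#' @param dead_sd_multiple dead-sensor threshold for per-guide removal
#'   (default 2).
#' @param dead_exclusion_mode override: "same_rule_same_direction"
#'   (gene-level, respiratory default) or "per_guide_removal"
#'   (glycolytic/basal default).
#' @return a `hit_rule` list.
#' @export
hit_rule <- function(condition = c("respiratory", "glycolytic", "basal"),
                     min_guides_beyond = NULL, guide_sd_multiple = 3,
                     dead_sd_multiple = 2, dead_exclusion_mode = NULL) {
  condition <- match.arg(condition)
  if (is.null(min_guides_beyond))
    min_guides_beyond <- if (condition == "respiratory") 2L else 3L
  if (is.null(dead_exclusion_mode))
    dead_exclusion_mode <- if (condition == "respiratory")
      "same_rule_same_direction" else "per_guide_removal"
  dead_exclusion_mode <- match.arg(dead_exclusion_mode,
                                   c("same_rule_same_direction",
                                     "per_guide_removal"))
  stopifnot(min_guides_beyond >= 1, guide_sd_multiple > 0,
            dead_sd_multiple > 0)
  structure(list(condition = condition,
                 min_guides_beyond = as.integer(min_guides_beyond),
                 guide_sd_multiple = guide_sd_multiple,
                 dead_sd_multiple = dead_sd_multiple,
                 dead_exclusion_mode = dead_exclusion_mode),
            class = "hit_rule")
}

count_beyond_ <- function(values, gene, m, s, mult, direction) {
  thr <- if (direction > 0) values > m + mult * s else values < m - mult * s
  thr[is.na(thr)] <- FALSE
  cnt <- rowsum(as.integer(thr), gene)
  stats::setNames(cnt[, 1L], rownames(cnt))
}

#' Apply a guide-count hit rule to per-gene guide phenotypes
#'
#' Counts, per gene and direction, guides beyond `guide_sd_multiple` SD of
#' the live nontargeting distribution and calls a high/low hit when the
#' count reaches the rule's minimum. Dead-sensor handling follows the
#' rule's mode: gene-level same-direction exclusion, or per-guide removal
#' of dead-flagged guides before counting.
#'
#' @param guides data.frame with columns `sgrna_id`, `gene_id`,
#'   `phenotype_live`, `phenotype_dead` (NA allowed), and optionally
#'   `dead_flag` (used by per-guide removal; recomputed from
#'   `phenotype_dead` if absent). Nontargeting rows (gene_id NA) are
#'   ignored.
#' @param nt_live nontargeting live-sensor phenotypes defining the
#'   thresholds (>= 2 values).
#' @param nt_dead nontargeting dead-sensor phenotypes (may be NULL when no
#'   dead channel exists; exclusion is then skipped with a warning).
#' @param rule a [hit_rule()].
#' @return data.frame: `gene_id`, `n_high`, `n_low`, `call`
#'   ("high"/"low"/"none"), `dead_excluded`.
#' @export
call_hits <- function(guides, nt_live, nt_dead = NULL, rule = hit_rule()) {
  stopifnot(inherits(rule, "hit_rule"))
  nt_live <- nt_live[!is.na(nt_live)]
  if (length(nt_live) < 2L) stop("need >= 2 nontargeting live phenotypes")
  g <- guides[!is.na(guides$gene_id), , drop = FALSE]
  m <- mean(nt_live); s <- stats::sd(nt_live)
  if (s == 0) stop("degenerate nontargeting SD (= 0)")
  has_dead <- !is.null(nt_dead) && sum(!is.na(nt_dead)) >= 2L &&
    any(!is.na(g$phenotype_dead))
  if (!has_dead && (!is.null(nt_dead) || any(!is.na(g$phenotype_dead))))
    warning("insufficient dead-sensor data; hit calling proceeds without exclusions")

  live <- g$phenotype_live
  if (rule$dead_exclusion_mode == "per_guide_removal" && has_dead) {
    flag <- if (!is.null(g$dead_flag)) g$dead_flag else
      flag_dead_sensor_artifacts(g$phenotype_dead, nt_dead,
                                 rule$dead_sd_multiple)
    live[flag != 0L] <- NA_real_
  }
  n_high <- count_beyond_(live, g$gene_id, m, s, rule$guide_sd_multiple, +1)
  n_low <- count_beyond_(live, g$gene_id, m, s, rule$guide_sd_multiple, -1)
  genes <- names(n_high)
  call <- rep("none", length(genes))
  hi <- n_high >= rule$min_guides_beyond
  lo <- n_low >= rule$min_guides_beyond
  call[hi & !lo] <- "high"
  call[lo & !hi] <- "low"
  both <- hi & lo
  call[both] <- ifelse(n_high[both] >= n_low[both], "high", "low")

  dead_excluded <- rep(FALSE, length(genes))
  if (rule$dead_exclusion_mode == "same_rule_same_direction" && has_dead) {
    ntd <- nt_dead[!is.na(nt_dead)]
    md <- mean(ntd); sd_d <- stats::sd(ntd)
    if (sd_d > 0) {
      d_high <- count_beyond_(g$phenotype_dead, g$gene_id, md, sd_d,
                              rule$guide_sd_multiple, +1)
      d_low <- count_beyond_(g$phenotype_dead, g$gene_id, md, sd_d,
                             rule$guide_sd_multiple, -1)
      dead_excluded <- (call == "high" & d_high[genes] >= rule$min_guides_beyond) |
        (call == "low" & d_low[genes] >= rule$min_guides_beyond)
      call[dead_excluded] <- "none"
    }
  }
  data.frame(gene_id = genes, n_high = as.integer(n_high),
             n_low = as.integer(n_low), call = call,
             dead_excluded = dead_excluded,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Specificity from the quasi-gene hit rate
#'
#' Quasi-genes are built from nontargeting guides, so any quasi-gene hit is
#' a false positive; specificity is `100 * (1 - quasi_hits / n_quasi)` in
#' percent.
#'
#' @param quasi_calls either a character vector of quasi-gene calls (hits
#'   are values other than "none") or a single hit count.
#' @param n_quasi number of quasi-genes tested.
#' @return specificity in percent.
#' @export
estimate_specificity <- function(quasi_calls, n_quasi) {
  stopifnot(n_quasi > 0)
  hits <- if (is.character(quasi_calls)) sum(quasi_calls != "none")
  else as.numeric(quasi_calls)
  100 * (1 - hits / n_quasi)
}

#' Full hit analysis of a scored screen
#'
#' For each condition: builds the quasi-gene null from the (artifact-free)
#' nontargeting guides, applies the condition's guide-count rule to real
#' genes and quasi-genes, attaches quasi-null Z-scores and (for called
#' hits) Mann-Whitney concordance p-values, and estimates specificity from
#' the quasi-gene hit rate with and without the concordance filter.
#'
#' @param scored a `scored_screen` from [score_screen()].
#' @param rule a [hit_rule()]; if NULL, the per-condition default.
#' @param seed seed for the quasi-gene resampling.
#' @param mw_alpha Mann-Whitney significance for the optional concordance
#'   filter (default 0.05); the unfiltered calls are always reported.
#' @param mw compute concordance p-values for "hits" only (default),
#'   "all" genes, or "none".
#' @param n_quasi number of quasi-genes; default = number of targeting
#'   genes.
#' @return a `screen_hits` list: `genes` (per-gene table with phenotype,
#'   z, mw_p, counts, `call` and `call_mw`), `quasi` (per-condition
#'   [build_quasi_genes()] results with their calls), `specificity`
#'   (per-condition data.frame with and without the MW filter).
#' @export
screen_hits <- function(scored, rule = NULL, seed = 1L, mw_alpha = 0.05,
                        mw = c("hits", "all", "none"), n_quasi = NULL) {
  mw <- match.arg(mw)
  stopifnot(inherits(scored, "scored_screen"))
  out_genes <- list(); out_quasi <- list(); out_spec <- list()
  for (cond in unique(scored$guides$condition)) {
    g <- scored$guides[scored$guides$condition == cond, , drop = FALSE]
    r <- if (is.null(rule)) hit_rule(cond) else rule
    nt <- is.na(g$gene_id)
    keep_nt <- nt & g$dead_flag == 0L & !is.na(g$phenotype_live)
    nt_live <- g$phenotype_live[keep_nt]
    nt_dead <- g$phenotype_dead[keep_nt]
    if (all(is.na(nt_dead))) nt_dead <- NULL
    nq <- if (is.null(n_quasi))
      length(unique(g$gene_id[!nt])) else n_quasi
    quasi <- build_quasi_genes(nt_live, nq, seed = seed)

    calls <- call_hits(g, nt_live, nt_dead, r)
    qg <- data.frame(
      sgrna_id = sprintf("q%07d", seq_along(quasi$assignment)),
      gene_id = rep(sprintf("Q%05d", seq_len(nq)), quasi$guides_per_quasi),
      phenotype_live = nt_live[as.vector(quasi$assignment)],
      phenotype_dead = if (is.null(nt_dead)) NA_real_ else
        nt_dead[as.vector(quasi$assignment)],
      stringsAsFactors = FALSE)
    qcalls <- call_hits(qg, nt_live, nt_dead, r)

    mw_for <- function(tab, guide_tab, which_genes) {
      p <- rep(NA_real_, nrow(tab))
      idx <- which(tab$gene_id %in% which_genes)
      for (i in idx) {
        v <- guide_tab$phenotype_live[guide_tab$gene_id == tab$gene_id[i]]
        p[i] <- mw_concordance(v, nt_live)
      }
      p
    }
    want <- switch(mw, none = character(0),
                   hits = calls$gene_id[calls$call != "none"],
                   all = calls$gene_id)
    calls$mw_p <- mw_for(calls, g, want)
    qwant <- switch(mw, none = character(0),
                    qcalls$gene_id[qcalls$call != "none"])
    qcalls$mw_p <- mw_for(qcalls, qg, qwant)
    calls$call_mw <- ifelse(calls$call != "none" & !is.na(calls$mw_p) &
                              calls$mw_p < mw_alpha, calls$call, "none")
    qcalls$call_mw <- ifelse(qcalls$call != "none" & !is.na(qcalls$mw_p) &
                               qcalls$mw_p < mw_alpha, qcalls$call, "none")

    gt <- scored$genes[scored$genes$condition == cond, , drop = FALSE]
    gt <- merge(gt, calls, by = "gene_id", sort = TRUE)
    gt$z <- z_score(gt$phenotype, quasi$mean, quasi$sd)
    gt$z_hit <- abs(gt$z) > r$guide_sd_multiple
    out_genes[[cond]] <- gt
    quasi$calls <- qcalls
    out_quasi[[cond]] <- quasi
    out_spec[[cond]] <- data.frame(
      condition = cond, n_quasi = nq,
      quasi_hits = sum(qcalls$call != "none"),
      specificity = estimate_specificity(qcalls$call, nq),
      quasi_hits_mw = sum(qcalls$call_mw != "none"),
      specificity_mw = estimate_specificity(qcalls$call_mw, nq),
      stringsAsFactors = FALSE)
  }
  structure(list(genes = do.call(rbind, c(out_genes, make.row.names = FALSE)),
                 quasi = out_quasi,
                 specificity = do.call(rbind, c(out_spec,
                                                make.row.names = FALSE))),
            class = "screen_hits")
}

#' @export
print.screen_hits <- function(x, ...) {
  for (i in seq_len(nrow(x$specificity))) {
    s <- x$specificity[i, ]
    n_hit <- sum(x$genes$call != "none" & x$genes$condition == s$condition)
    cat(sprintf("%s: %d hits; specificity %.2f%% (%.2f%% with MW filter)\n",
                s$condition, n_hit, s$specificity, s$specificity_mw))
  }
  invisible(x)
}
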