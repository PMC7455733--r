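#' @title From sorted counts to sgRNA and gene ATP phenotypes
#' @description The scoring chain: per-sample normalization to the
#'   nontargeting-guide total, per-guide log2 high/low enrichment, replicate
#'   averaging, dead-sensor artifact flagging, and the top-3-guide gene
#'   summary.
#' @name phenotype_scoring
NULL

#' Normalize one sample's counts to its nontargeting-guide total
#'
#' `value_i = (count_i + pseudocount) / sum_NT(count + pseudocount)`.
#' Normalizing to the nontargeting total (rather than the sample total)
#' makes control guides center at the same abundance in every sample and
#' leaves the result invariant under global rescaling of the sample.
#'
#' @param counts nonnegative count vector for one sample.
#' @param is_nt logical vector (same length) marking nontargeting guides,
#'   or a [library_table()] aligned with `counts`.
#' @param pseudocount nonnegative value added to every raw count before
#'   normalization (default 1; keeps downstream logs finite).
#' @return normalized abundances, same length as `counts`.
#' @export
normalize_to_nontargeting <- function(counts, is_nt, pseudocount = 1) {
  if (inherits(is_nt, "library_table")) is_nt <- is_nontargeting(is_nt)
  stopifnot(length(is_nt) == length(counts), pseudocount >= 0)
  denom <- sum(counts[is_nt] + pseudocount)
  if (denom <= 0)
    stop("nontargeting total is zero; cannot normalize ",
         "(increase pseudocount or check the library)")
  (counts + pseudocount) / denom
}

#' Per-guide log2 enrichment between two normalized abundances
#'
#' @param norm_high,norm_low positive normalized abundances; positive
#'   output means enrichment in the high fraction.
#' @return `log2(norm_high / norm_low)`.
#' @export
sgrna_phenotype <- function(norm_high, norm_low) {
  if (any(norm_high <= 0 | norm_low <= 0, na.rm = TRUE))
    stop("abundances must be positive (apply a pseudocount upstream)")
  log2(norm_high / norm_low)
}

#' Flag guides whose dead-sensor phenotype marks a FRET artifact
#'
#' Guides whose phenotype with the non-ATP-binding (dead) sensor lies
#' beyond `sd_multiple` standard deviations of the nontargeting dead-sensor
#' distribution respond to something other than ATP and are excluded from
#' analysis.
#'
#' @param dead_phenotypes per-guide dead-sensor phenotypes (NA allowed).
#' @param nt_dead nontargeting dead-sensor phenotypes (>= 2 values).
#' @param sd_multiple threshold in NT SD units (default 2).
#' @return integer vector: +1 flagged high, -1 flagged low, 0 unflagged.
#' @export
flag_dead_sensor_artifacts <- function(dead_phenotypes, nt_dead,
                                       sd_multiple = 2) {
  nt_dead <- nt_dead[!is.na(nt_dead)]
  if (length(nt_dead) < 2L)
    stop("need >= 2 nontargeting dead-sensor phenotypes")
  m <- mean(nt_dead); s <- stats::sd(nt_dead)
  flags <- integer(length(dead_phenotypes))
  if (s == 0) {
    if (any(dead_phenotypes != m, na.rm = TRUE))
      warning("degenerate nontargeting dead-sensor SD (= 0); no flags set")
    return(flags)
  }
  hi <- !is.na(dead_phenotypes) & dead_phenotypes > m + sd_multiple * s
  lo <- !is.na(dead_phenotypes) & dead_phenotypes < m - sd_multiple * s
  flags[hi] <- 1L
  flags[lo] <- -1L
  flags
}

# Indices of the k strongest values; mode "absolute" ranks by |value|,
# "dominant" ranks within the direction holding the majority of eligible
# guides (ties broken toward the direction with the larger |top-k mean|).
# Ranking ties broken by the order of `ids` (lexicographic upstream).
top_k_idx_ <- function(values, k, mode = c("absolute", "dominant"),
                       ids = NULL) {
  mode <- match.arg(mode)
  if (is.null(ids)) ids <- as.character(seq_along(values))
  keep <- which(!is.na(values))
  if (!length(keep)) return(integer(0))
  pick <- function(cand) {
    ord <- cand[order(-abs(values[cand]), ids[cand])]
    utils::head(ord, k)
  }
  if (mode == "absolute") return(pick(keep))
  pos <- keep[values[keep] >= 0]
  neg <- keep[values[keep] < 0]
  if (length(pos) > length(neg)) return(pick(pos))
  if (length(neg) > length(pos)) return(pick(neg))
  tp <- pick(pos); tn <- pick(neg)
  mp <- if (length(tp)) mean(values[tp]) else -Inf
  mn <- if (length(tn)) mean(values[tn]) else Inf
  if (abs(mp) >= abs(mn)) tp else tn
}

#' Gene phenotype: mean of the strongest k eligible guide phenotypes
#'
#' Guides flagged by the dead sensor (and NAs from low-count filtering) are
#' excluded first; the k remaining guides with the largest phenotypes are
#' averaged with sign. With fewer than k eligible guides the mean of all
#' remaining guides is returned and marked low-confidence; with none, NA.
#'
#' @param guide_values replicate-averaged sgRNA phenotypes for one gene,
#'   named by sgrna_id (names break ranking ties deterministically).
#' @param flags integer/logical exclusion flags aligned with
#'   `guide_values` (nonzero/TRUE = excluded), e.g. from
#'   [flag_dead_sensor_artifacts()].
#' @param k number of guides averaged (default 3).
#' @param mode "absolute" (default) ranks guides by |phenotype|;
#'   "dominant" ranks within the majority direction only.
#' @return list: `phenotype`, `n_eligible`, `low_confidence`, `guides`
#'   (ids used).
#' @export
gene_phenotype <- function(guide_values, flags = NULL, k = 3,
                           mode = c("absolute", "dominant")) {
  mode <- match.arg(mode)
  ids <- names(guide_values)
  if (is.null(ids)) ids <- sprintf("g%03d", seq_along(guide_values))
  if (is.null(flags)) flags <- integer(length(guide_values))
  v <- ifelse(flags != 0, NA_real_, as.numeric(guide_values))
  n_eligible <- sum(!is.na(v))
  idx <- top_k_idx_(v, k, mode, ids)
  list(phenotype = if (length(idx)) mean(v[idx]) else NA_real_,
       n_eligible = n_eligible,
       low_confidence = n_eligible < k,
       guides = ids[idx])
}

# Phenotypes for one (condition, sensor, replicate) fraction pair.
# Numerator fraction is "high" (or "post"), denominator "low" (or "pre").
pair_phenotype_ <- function(x, sel, pseudocount, min_counts) {
  sm <- x$samples[sel, , drop = FALSE]
  num <- sm$sample_id[sm$fraction %in% c("high", "post")]
  den <- sm$sample_id[sm$fraction %in% c("low", "pre")]
  stopifnot(length(num) == 1L, length(den) == 1L)
  nt <- is_nontargeting(x$library)
  a <- normalize_to_nontargeting(x$counts[, num], nt, pseudocount)
  b <- normalize_to_nontargeting(x$counts[, den], nt, pseudocount)
  ph <- sgrna_phenotype(a, b)
  low <- (x$counts[, num] + x$counts[, den]) < min_counts
  ph[low] <- NA_real_
  ph
}

#' Score a sorted count set into sgRNA and gene phenotypes
#'
#' Runs the full per-screen scoring chain for every condition present:
#' normalization, per-replicate log2 enrichment, a low-count filter,
#' replicate averaging, dead-sensor flagging, and the top-k gene summary.
#'
#' @param x a [sorted_count_set()].
#' @param pseudocount added to every raw count (default 1).
#' @param min_counts guides with fewer total raw reads than this across a
#'   fraction pair are set NA for that replicate (default 10).
#' @param k guides averaged per gene (default 3).
#' @param mode top-k ranking mode, see [gene_phenotype()].
#' @param dead_sd dead-sensor flag threshold in NT SD units (default 2).
#' @return a `scored_screen` list:
#'   \describe{
#'     \item{sgrna}{long table of per-replicate and replicate-averaged
#'       (`replicate == "avg"`) guide phenotypes per condition and sensor.}
#'     \item{guides}{wide per-guide table: averaged `phenotype_live`,
#'       `phenotype_dead`, and `dead_flag` per condition.}
#'     \item{genes}{per-gene top-k summaries with eligibility counts.}
#'     \item{nt_stats}{mean/SD of averaged nontargeting phenotypes per
#'       condition and sensor, after removing dead-flagged NT guides.}
#'   }
#' @export
score_screen <- function(x, pseudocount = 1, min_counts = 10, k = 3,
                         mode = c("absolute", "dominant"), dead_sd = 2) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "sorted_count_set"))
  sm <- x$samples
  lib <- x$library
  sgrna_rows <- list()
  guides_rows <- list()
  genes_rows <- list()
  nt_rows <- list()
  for (cond in unique(sm$condition)) {
    avg <- list()
    for (sensor in intersect(SENSOR_LEVELS, sm$sensor)) {
      sel0 <- sm$condition == cond & sm$sensor == sensor
      if (!any(sel0)) next
      reps <- sort(unique(sm$replicate[sel0]))
      mat <- matrix(NA_real_, nrow(lib), length(reps),
                    dimnames = list(lib$sgrna_id, reps))
      for (j in seq_along(reps)) {
        sel <- sel0 & sm$replicate == reps[j]
        mat[, j] <- pair_phenotype_(x, sel, pseudocount, min_counts)
        sgrna_rows[[length(sgrna_rows) + 1L]] <- data.frame(
          sgrna_id = lib$sgrna_id, gene_id = lib$gene_id,
          condition = cond, sensor = sensor,
          replicate = as.character(reps[j]), phenotype = mat[, j],
          stringsAsFactors = FALSE)
      }
      av <- rowMeans(mat, na.rm = TRUE)
      av[is.nan(av)] <- NA_real_
      avg[[sensor]] <- av
      sgrna_rows[[length(sgrna_rows) + 1L]] <- data.frame(
        sgrna_id = lib$sgrna_id, gene_id = lib$gene_id,
        condition = cond, sensor = sensor, replicate = "avg",
        phenotype = av, stringsAsFactors = FALSE)
    }
    live <- avg[["live"]]
    dead <- if (!is.null(avg[["dead"]])) avg[["dead"]] else
      rep(NA_real_, nrow(lib))
    nt <- is_nontargeting(lib)
    if (all(is.na(dead))) {
      warning("no dead-sensor samples for condition '", cond,
              "'; proceeding without artifact exclusion")
      flags <- integer(nrow(lib))
    } else {
      flags <- flag_dead_sensor_artifacts(dead, dead[nt], dead_sd)
    }
    guides_rows[[length(guides_rows) + 1L]] <- data.frame(
      sgrna_id = lib$sgrna_id, gene_id = lib$gene_id, condition = cond,
      phenotype_live = live, phenotype_dead = dead, dead_flag = flags,
      stringsAsFactors = FALSE)
    for (sensor in names(avg)) {
      keep <- nt & flags == 0L & !is.na(avg[[sensor]])
      nt_rows[[length(nt_rows) + 1L]] <- data.frame(
        condition = cond, sensor = sensor,
        mean = mean(avg[[sensor]][keep]), sd = stats::sd(avg[[sensor]][keep]),
        n = sum(keep), stringsAsFactors = FALSE)
    }
    gl <- split(seq_len(nrow(lib))[!nt], lib$gene_id[!nt])
    gp <- lapply(gl, function(ix) {
      v <- live[ix]; names(v) <- lib$sgrna_id[ix]
      gene_phenotype(v, flags[ix], k, mode)
    })
    genes_rows[[length(genes_rows) + 1L]] <- data.frame(
      gene_id = names(gl), condition = cond,
      phenotype = vapply(gp, `[[`, 0, "phenotype"),
      n_guides = lengths(gl),
      n_eligible = vapply(gp, `[[`, 0L, "n_eligible"),
      low_confidence = vapply(gp, `[[`, TRUE, "low_confidence"),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(list(sgrna = do.call(rbind, sgrna_rows),
                 guides = do.call(rbind, guides_rows),
                 genes = do.call(rbind, genes_rows),
                 nt_stats = do.call(rbind, nt_rows)),
            class = "scored_screen")
}

#' @export
print.scored_screen <- function(x, ...) {
  cat(sprintf("scored_screen: %d genes, %d guides, conditions: %s\n",
              length(unique(x$genes$gene_id)),
              length(unique(x$guides$sgrna_id)),
              paste(unique(x$genes$condition), collapse = ", ")))
  invisible(x)
}
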