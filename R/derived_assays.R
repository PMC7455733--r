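#' @title Derived phenotypes: consumption, mitochondrial content, growth
#' @description Paired fold-change phenotypes for the mini-library
#'   follow-up assays, the ATP-consumption ratio, robust-regression (ROUT)
#'   outlier removal, and Pearson correlation with an F-test for nonzero
#'   slope.
#' @name derived_assays
NULL

#' Per-guide fold change between two normalized samples
#'
#' Both inputs are abundances normalized to the nontargeting total (see
#' [normalize_to_nontargeting()]), so nontargeting guides center at a fold
#' change of 1 by construction. `log2()` of the result equals the
#' difference of log2 abundances, i.e. the fold change is the linearized
#' sgRNA phenotype.
#'
#' @param norm_a numerator abundances (e.g. high-MitoTracker fraction, or
#'   post-growth).
#' @param norm_b denominator abundances (low fraction, or pre-growth).
#' @return per-guide fold changes.
#' @export
paired_fold_phenotype <- function(norm_a, norm_b) {
  if (any(norm_b == 0, na.rm = TRUE))
    stop("zero denominator abundance; apply a pseudocount upstream")
  norm_a / norm_b
}

#' ATP consumption phenotype: post- versus pre-depletion ATP phenotype
#'
#' The ratio of a guide's ATP phenotype after acutely blocking all ATP
#' production to its phenotype before the block. Enrichment in the
#' high-ATP fraction post-depletion (large ratio) indicates slower ATP
#' consumption. The ratio of two log-scale phenotypes is unstable when the
#' pre-depletion phenotype is near zero, so values with `|pre| < eps` are
#' returned NA (flagged undefined) rather than propagated; the alternative
#' reading, a post-minus-pre difference, is available via `mode`.
#'
#' @param pre,post ATP phenotypes (log2 enrichment) before/after the block.
#' @param eps stability floor on `|pre|` for the ratio (default 0.05 log2
#'   units).
#' @param mode "ratio" (default, post/pre) or "difference" (post - pre).
#' @return numeric vector; NA where undefined, with the flagged positions
#'   in `attr(, "undefined")`.
#' @export
consumption_phenotype <- function(pre, post, eps = 0.05,
                                  mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  stopifnot(length(pre) == length(post), eps >= 0)
  if (mode == "difference") {
    out <- post - pre
    attr(out, "undefined") <- rep(FALSE, length(out))
    return(out)
  }
  undef <- is.na(pre) | abs(pre) < eps
  out <- ifelse(undef, NA_real_, post / pre)
  if (any(undef))
    warning(sum(undef), " guide(s) with |pre| < ", eps,
            " flagged undefined and excluded")
  attr(out, "undefined") <- undef
  out
}

# Robust line fit by iteratively reweighted least squares with Lorentzian
# weights w = 1/(1 + (r/RSDR)^2); RSDR is the 68.27th percentile of
# absolute residuals with the n/(n - K) small-sample correction (K = 2
# fitted coefficients).
robust_line_ <- function(x, y, max_iter = 50L, tol = 1e-10) {
  n <- length(x)
  fit <- stats::lm.fit(cbind(1, x), y)
  beta <- fit$coefficients
  for (i in seq_len(max_iter)) {
    r <- y - beta[1L] - beta[2L] * x
    rsdr <- stats::quantile(abs(r), 0.6827, names = FALSE) * n / (n - 2L)
    if (rsdr <= 0) break
    w <- 1 / (1 + (r / rsdr)^2)
    newbeta <- stats::lm.wfit(cbind(1, x), y, w)$coefficients
    if (max(abs(newbeta - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- newbeta
      break
    }
    beta <- newbeta
  }
  r <- y - beta[1L] - beta[2L] * x
  rsdr <- stats::quantile(abs(r), 0.6827, names = FALSE) * n / (n - 2L)
  list(coef = beta, residuals = r, rsdr = rsdr)
}

#' ROUT outlier detection for a linear relationship
#'
#' Fits a robust line (iteratively reweighted least squares, Lorentzian
#' weights), scales residuals by the robust standard deviation (68.27th
#' percentile of |residuals| with small-sample correction), converts them
#' to two-tailed t-tail p-values and removes the points selected by a
#' Benjamini-Hochberg step at FDR `Q` percent.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @param Q false-discovery rate in percent (default 1).
#' @return logical inlier mask (TRUE = retained). With n < 5 no removal is
#'   attempted (all TRUE, with a warning).
#' @export
rout_filter <- function(x, y, Q = 1) {
  stopifnot(length(x) == length(y), Q > 0, Q < 100)
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3L) stop("need at least 3 finite points")
  keep <- ok
  if (n < 5L) {
    warning("fewer than 5 points; no outlier removal attempted")
    return(keep)
  }
  fit <- robust_line_(x[ok], y[ok])
  if (fit$rsdr <= 0) return(keep)  # exactly collinear: nothing to remove
  t_stat <- abs(fit$residuals) / fit$rsdr
  p <- 2 * stats::pt(-t_stat, df = n - 2L)
  ord <- order(p)
  thr <- (seq_len(n) / n) * (Q / 100)
  below <- p[ord] <= thr
  n_out <- if (any(below)) max(which(below)) else 0L
  if (n_out > 0L) {
    drop_idx <- which(ok)[ord[seq_len(n_out)]]
    keep[drop_idx] <- FALSE
  }
  keep
}

#' Pearson correlation with ROUT outlier removal and F-test
#'
#' Removes outliers with [rout_filter()] (unless `rout_q` is NULL), then
#' computes the Pearson coefficient on retained points and the F-test
#' p-value for a nonzero regression slope.
#'
#' @param x,y numeric vectors (n >= 3 after outlier removal).
#' @param rout_q ROUT FDR in percent (default 1); NULL skips removal.
#' @return a `correlation_result` list: `r`, `n`, `p`,
#'   `outliers_removed` (indices into the input).
#' @export
correlate <- function(x, y, rout_q = 1) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 points")
  if (stats::sd(x, na.rm = TRUE) == 0 || stats::sd(y, na.rm = TRUE) == 0)
    stop("constant x or y: correlation undefined")
  keep <- if (is.null(rout_q)) is.finite(x) & is.finite(y)
  else rout_filter(x, y, rout_q)
  xr <- x[keep]; yr <- y[keep]
  if (length(xr) < 3L) stop("fewer than 3 points retained")
  if (stats::sd(xr) == 0 || stats::sd(yr) == 0)
    stop("constant x or y after outlier removal")
  r <- stats::cor(xr, yr)
  fit <- stats::lm(yr ~ xr)
  fs <- summary(fit)$fstatistic
  p <- stats::pf(fs[1L], fs[2L], fs[3L], lower.tail = FALSE)
  structure(list(r = unname(r), n = length(xr), p = unname(p),
                 outliers_removed = which(!keep)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d, F-test p = %.3g, %d outlier(s) removed)\n",
              x$r, x$n, x$p, length(x$outliers_removed)))
  invisible(x)
}

#' Score a paired derived assay into per-guide fold changes
#'
#' Applies nontargeting normalization and [paired_fold_phenotype()] to
#' every replicate pair of a paired count set (growth pre/post, or a
#' high/low sort), averages fold changes across replicates, and calls
#' guides beyond `sd_multiple` SD of the nontargeting fold-change
#' distribution.
#'
#' @param x a [sorted_count_set()] whose samples pair pre/post or high/low.
#' @param pseudocount added to raw counts (default 1).
#' @param sd_multiple hit threshold in NT SD units (default 3).
#' @return data.frame: `sgrna_id`, `gene_id`, `fold_change` (replicate
#'   mean), `log2_fold`, `hit` ("high"/"low"/"none").
#' @export
score_paired_assay <- function(x, pseudocount = 1, sd_multiple = 3) {
  stopifnot(inherits(x, "sorted_count_set"))
  sm <- x$samples
  nt <- is_nontargeting(x$library)
  key <- interaction(sm$condition, sm$replicate, sm$sensor, sm$assay,
                     drop = TRUE)
  folds <- sapply(levels(key), function(gk) {
    sel <- key == gk
    num <- sm$sample_id[sel & sm$fraction %in% c("high", "post")]
    den <- sm$sample_id[sel & sm$fraction %in% c("low", "pre")]
    a <- normalize_to_nontargeting(x$counts[, num], nt, pseudocount)
    b <- normalize_to_nontargeting(x$counts[, den], nt, pseudocount)
    paired_fold_phenotype(a, b)
  })
  fc <- rowMeans(folds)
  m <- mean(fc[nt]); s <- stats::sd(fc[nt])
  hit <- rep("none", length(fc))
  if (is.finite(s) && s > 0) {
    hit[fc > m + sd_multiple * s] <- "high"
    hit[fc < m - sd_multiple * s] <- "low"
  }
  data.frame(sgrna_id = x$library$sgrna_id, gene_id = x$library$gene_id,
             fold_change = fc, log2_fold = log2(fc), hit = hit,
             stringsAsFactors = FALSE, row.names = NULL)
}
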