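#' @title Natural-abundance 13C correction of mass-isotopologue
#'   distributions
#' @description Corrects measured metabolite isotopologue intensity
#'   vectors (M+0 ... M+n) for natural 13C abundance by deconvolving the
#'   binomial natural-labeling matrix, and derives pool sizes and
#'   fractional labeling from corrected profiles.
#' @name isotope_correction
NULL

#' Natural-abundance correction matrix
#'
#' Column j (tracer-labeled state M+j) spreads into measured mass shifts
#' M+i (i >= j) because each of the `n - j` unlabeled carbons is 13C with
#' probability `p13`:
#' `M[i, j] = choose(n - j, i - j) * p13^(i - j) * (1 - p13)^(n - i)`.
#' Columns are binomial distributions and sum to one.
#'
#' @param n_carbons number of carbons in the metabolite (>= 1).
#' @param p13 natural 13C abundance (default 0.0107).
#' @return an (n+1) x (n+1) lower-triangular column-stochastic matrix of
#'   class `correction_matrix` with attributes `n_carbons` and `p13`.
#' @export
correction_matrix <- function(n_carbons, p13 = 0.0107) {
  if (!is.numeric(p13) || length(p13) != 1L || is.na(p13) ||
      p13 < 0 || p13 >= 1)
    stop("p13 must lie in [0, 1)")
  stopifnot(n_carbons >= 1, n_carbons == round(n_carbons))
  n <- as.integer(n_carbons)
  i <- 0:n
  M <- outer(i, i, function(ii, jj) {
    ifelse(ii >= jj, stats::dbinom(ii - jj, pmax(n - jj, 0L), p13), 0)
  })
  dimnames(M) <- list(paste0("M+", i), paste0("M+", i))
  structure(M, class = c("correction_matrix", "matrix"),
            n_carbons = n, p13 = p13)
}

# Lawson-Hanson active-set nonnegative least squares: min ||Ax - b|| s.t.
# x >= 0. Problems here are tiny (n_carbons + 1 <= ~50), so a plain R
# implementation suffices.
nnls_ <- function(A, b, tol = 1e-12) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- crossprod(A, b - A %*% x)
  iter <- 0L
  while (any(!passive & w > tol) && iter < 30L * n) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      Ap <- A[, passive, drop = FALSE]
      s[passive] <- qr.coef(qr(Ap), b)
      s[passive][is.na(s[passive])] <- 0
      if (all(s[passive] > tol)) break
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    x <- s
    w <- crossprod(A, b - A %*% x)
  }
  as.numeric(x)
}

#' Construct a mass-isotopologue profile
#'
#' @param metabolite metabolite name.
#' @param intensities nonnegative intensity vector of length
#'   `n_carbons + 1` (M+0 ... M+n).
#' @param n_carbons carbon count; default inferred from the vector length.
#' @param cell_number optional positive cell count for normalization.
#' @param corrected has natural-abundance correction been applied?
#' @return an `isotopologue_profile` list.
#' @export
isotopologue_profile <- function(metabolite, intensities, n_carbons = NULL,
                                 cell_number = NULL, corrected = FALSE) {
  if (is.null(n_carbons)) n_carbons <- length(intensities) - 1L
  if (length(intensities) != n_carbons + 1L)
    stop("intensities must have length n_carbons + 1")
  if (any(is.na(intensities)) || any(intensities < 0))
    stop("intensities must be nonnegative")
  if (!is.null(cell_number) && cell_number <= 0)
    stop("cell_number must be positive")
  structure(list(metabolite = as.character(metabolite),
                 n_carbons = as.integer(n_carbons),
                 intensities = as.numeric(intensities),
                 cell_number = cell_number, corrected = corrected),
            class = "isotopologue_profile")
}

#' Correct a measured profile for natural 13C abundance
#'
#' Solves `M x = measured` for the tracer-labeled distribution `x` under
#' nonnegativity (Lawson-Hanson NNLS, absorbing measurement noise without
#' producing negative isotopologues). For noiseless synthetic inputs,
#' exact triangular back-substitution is available via `method =
#' "backsub"` (may return negative values on noisy data).
#'
#' @param profile an [isotopologue_profile()] (or bare intensity vector).
#' @param matrix a [correction_matrix()]; default built from the profile's
#'   carbon count at `p13`.
#' @param p13 natural 13C abundance used when `matrix` is NULL.
#' @param method "nnls" (default) or "backsub".
#' @return the corrected profile (same class as the input).
#' @export
correct_profile <- function(profile, matrix = NULL, p13 = 0.0107,
                            method = c("nnls", "backsub")) {
  method <- match.arg(method)
  bare <- !inherits(profile, "isotopologue_profile")
  y <- if (bare) as.numeric(profile) else profile$intensities
  n <- length(y) - 1L
  if (is.null(matrix)) matrix <- correction_matrix(max(n, 1L), p13)
  if (attr(matrix, "n_carbons") != n)
    stop("correction matrix is for ", attr(matrix, "n_carbons"),
         " carbons but the profile has ", n)
  x <- if (method == "nnls") nnls_(unclass(matrix), y)
  else as.numeric(forwardsolve(unclass(matrix), y))
  if (bare) return(x)
  out <- profile
  out$intensities <- x
  out$corrected <- TRUE
  out
}

#' Pool size and fractional labeling of a corrected profile
#'
#' Pool size is the sum over all isotopologues (normalized to cell number
#' when available); fractional labeling is the labeled-carbon fraction
#' `sum(i * x_i) / (n * sum(x))`.
#'
#' @param profile a corrected [isotopologue_profile()].
#' @return list: `pool_size`, `fractional_labeling` (NA with a warning for
#'   an empty pool), `fractions` (isotopologue fractions summing to 1).
#' @export
pool_and_labeling <- function(profile) {
  stopifnot(inherits(profile, "isotopologue_profile"))
  if (!profile$corrected)
    warning("profile is uncorrected; pool and labeling reflect raw intensities")
  x <- profile$intensities
  n <- profile$n_carbons
  total <- sum(x)
  pool <- if (!is.null(profile$cell_number)) total / profile$cell_number
  else total
  if (total <= 0) {
    warning("zero pool; fractional labeling undefined")
    return(list(pool_size = pool, fractional_labeling = NA_real_,
                fractions = rep(NA_real_, n + 1L)))
  }
  list(pool_size = pool,
       fractional_labeling = sum((0:n) * x) / (n * total),
       fractions = x / total)
}

#' Read a long-format isotopologue table
#'
#' @param path TSV with header columns `metabolite`, `n_carbons`,
#'   `mass_shift` (0 ... n_carbons), `intensity`, and optionally
#'   `cell_number`.
#' @return named list of [isotopologue_profile()]s.
#' @export
read_isotopologues <- function(path) {
  df <- read_tsv_(path)
  need <- c("metabolite", "n_carbons", "mass_shift", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("isotopologue file missing columns: ", paste(miss, collapse = ", "))
  out <- lapply(split(df, df$metabolite), function(d) {
    n <- unique(d$n_carbons)
    if (length(n) != 1L)
      stop("inconsistent n_carbons for ", d$metabolite[1L])
    v <- numeric(n + 1L)
    if (any(d$mass_shift < 0 | d$mass_shift > n))
      stop("mass_shift out of range for ", d$metabolite[1L])
    v[d$mass_shift + 1L] <- d$intensity
    cn <- if ("cell_number" %in% names(d)) unique(d$cell_number)[1L] else NULL
    isotopologue_profile(d$metabolite[1L], v, n, cn)
  })
  out
}

#' Correct, summarize and tabulate a set of isotopologue profiles
#'
#' @param profiles list of [isotopologue_profile()]s (e.g. from
#'   [read_isotopologues()]).
#' @param p13 natural 13C abundance (default 0.0107).
#' @param method solver passed to [correct_profile()].
#' @return wide data.frame: one row per metabolite with corrected
#'   intensities (`M0 ...`), `pool_size` and `fractional_labeling`.
#' @export
correct_isotopologues <- function(profiles, p13 = 0.0107,
                                  method = c("nnls", "backsub")) {
  method <- match.arg(method)
  rows <- lapply(profiles, function(p) {
    cp <- correct_profile(p, p13 = p13, method = method)
    s <- pool_and_labeling(cp)
    nmax <- cp$n_carbons
    d <- data.frame(metabolite = cp$metabolite, n_carbons = nmax,
                    pool_size = s$pool_size,
                    fractional_labeling = s$fractional_labeling,
                    stringsAsFactors = FALSE)
    for (i in 0:nmax) d[[paste0("M", i)]] <- cp$intensities[i + 1L]
    d
  })
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(d) {
    d[setdiff(cols, names(d))] <- NA_real_
    d[cols]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
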