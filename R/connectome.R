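#' ROI time-series container
#'
#' Bundles one subject's extracted region-of-interest (ROI) time series for a
#' single recording condition. Rows are timepoints (TRs), columns are regions.
#' Values are in arbitrary BOLD units; any upstream preprocessing (motion
#' regression, filtering) is assumed to have happened before extraction.
#'
#' @param values Numeric matrix, timepoints x regions; no missing values,
#'   at least 3 timepoints and 2 regions.
#' @param roi_names Character vector of unique region names, one per column.
#' @param subject_id Subject identifier.
#' @param condition Recording condition, `"movie"` or `"rest"`.
#' @param tr_seconds Sampling interval (repetition time) in seconds.
#' @return An object of class `roi_ts`.
#' @export
roi_ts <- function(values, roi_names = colnames(values), subject_id = NA_character_,
                   condition = c("movie", "rest"), tr_seconds = 2) {
  condition <- match.arg(condition)
  values <- as.matrix(values)
  if (anyNA(values) || !is.numeric(values)) {
    stop("time series must be numeric with no missing values")
  }
  if (nrow(values) < 3L) stop("need at least 3 timepoints")
  if (ncol(values) < 2L) stop("need at least 2 regions")
  if (is.null(roi_names)) roi_names <- paste0("ROI", seq_len(ncol(values)))
  roi_names <- as.character(roi_names)
  if (length(roi_names) != ncol(values) || anyDuplicated(roi_names)) {
    stop("roi_names must be unique and match the number of columns")
  }
  dimnames(values) <- list(NULL, roi_names)
  structure(
    list(values = values, roi_names = roi_names, subject_id = subject_id,
         condition = condition, tr_seconds = tr_seconds),
    class = "roi_ts"
  )
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("<roi_ts> subject %s, %s: %d TRs x %d ROIs (%s)\n",
              x$subject_id, x$condition, nrow(x$values), ncol(x$values),
              paste(x$roi_names, collapse = ", ")))
  invisible(x)
}

#' Fisher z-transform of correlation coefficients
#'
#' Variance-stabilizing transform `z = atanh(r)`. Correlations with
#' `|r| >= 1 - clamp` are clamped to `+/-(1 - clamp)` with a warning so that
#' numerically perfect correlations in short series stay finite; values at or
#' beyond `|r| = 1` after clamping are rejected.
#'
#' @param r Numeric vector of correlation coefficients in (-1, 1).
#' @param clamp Clamping window below 1 (default `1e-7`).
#' @return `atanh` of the (possibly clamped) input.
#' @examples
#' fisher_z(0.5)  # 0.5493
#' @export
fisher_z <- function(r, clamp = 1e-7) {
  if (!is.numeric(r) || anyNA(r)) stop("r must be numeric with no missing values")
  if (any(abs(r) > 1)) {
    bad <- which(abs(r) > 1)
    stop("correlation out of [-1, 1] at position ", paste(bad, collapse = ", "))
  }
  hit <- abs(r) >= 1 - clamp
  if (any(hit)) {
    warning(sum(hit), " correlation(s) with |r| >= 1 - ", format(clamp),
            " clamped before Fisher z-transform")
    r[hit] <- sign(r[hit]) * (1 - clamp)
  }
  atanh(r)
}

#' Subject functional-connectivity matrix
#'
#' Pairwise Pearson correlations between all region pairs, Fisher
#' z-transformed. The diagonal is stored as 0 by convention (self-correlation
#' excluded); every downstream summary uses off-diagonal entries only.
#'
#' @param ts A [roi_ts] object; every column must have nonzero variance.
#' @param clamp Clamping window passed to [fisher_z()].
#' @return An object of class `fc_matrix` with fields `z` (regions x regions,
#'   symmetric, zero diagonal), `roi_names` and `subject_id`.
#' @export
compute_fc <- function(ts, clamp = 1e-7) {
  stopifnot(inherits(ts, "roi_ts"))
  sds <- apply(ts$values, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant time series for ROI(s): ",
         paste(ts$roi_names[sds == 0], collapse = ", "))
  }
  r <- stats::cor(ts$values)
  z <- r
  ut <- upper.tri(r)
  z[ut] <- fisher_z(r[ut], clamp = clamp)
  z[lower.tri(z)] <- t(z)[lower.tri(z)]
  diag(z) <- 0
  structure(
    list(z = z, roi_names = ts$roi_names, subject_id = ts$subject_id),
    class = "fc_matrix"
  )
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("<fc_matrix> subject %s: %d ROIs, %d edges\n",
              x$subject_id, length(x$roi_names),
              length(x$roi_names) * (length(x$roi_names) - 1L) / 2L))
  invisible(x)
}

#' Vectorize the strict upper triangle of a connectivity matrix
#'
#' Flattens the `R(R-1)/2` unique edges into a named vector. Ordering is
#' row-major over the strict upper triangle in the matrix's ROI order:
#' (1,2), (1,3), ..., (1,R), (2,3), ... This ordering is stable across calls
#' and is the one used for per-edge reports; Euclidean distances do not
#' depend on it.
#'
#' @param fc An `fc_matrix`, or a plain symmetric matrix.
#' @return Named numeric vector of edge values (names `"roiA|roiB"`).
#' @export
vectorize_upper <- function(fc) {
  m <- if (inherits(fc, "fc_matrix")) fc$z else as.matrix(fc)
  nm <- if (inherits(fc, "fc_matrix")) fc$roi_names else rownames(m)
  if (is.null(nm)) nm <- paste0("ROI", seq_len(ncol(m)))
  # t(m)[lower.tri(m)] walks the upper triangle of m in row-major order
  v <- t(m)[lower.tri(m)]
  idx <- which(lower.tri(m), arr.ind = TRUE)  # (row=j, col=i) of t(m)
  names(v) <- paste(nm[idx[, "col"]], nm[idx[, "row"]], sep = "|")
  v
}

#' Rebuild a symmetric matrix from its vectorized upper triangle
#'
#' Inverse of [vectorize_upper()]; the diagonal is set to 0.
#'
#' @param v Edge vector of length `R(R-1)/2`.
#' @param roi_names Optional region names (length `R`).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
unvectorize_upper <- function(v, roi_names = NULL) {
  p <- length(v)
  R <- (1 + sqrt(1 + 8 * p)) / 2
  if (R != round(R)) stop("length ", p, " is not a triangular number")
  R <- as.integer(R)
  m <- matrix(0, R, R)
  tm <- t(m)
  tm[lower.tri(tm)] <- v
  m <- t(tm)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  if (!is.null(roi_names)) dimnames(m) <- list(roi_names, roi_names)
  m
}

#' Strength centrality of each region
#'
#' The strength centrality of a region is the sum of its Fisher-z
#' connectivity values with all other regions in the network, i.e. the row
#' sum of the off-diagonal connectivity matrix.
#'
#' @param fc An `fc_matrix`.
#' @return Named numeric vector, one strength per region.
#' @export
strength_centrality <- function(fc) {
  stopifnot(inherits(fc, "fc_matrix"))
  s <- rowSums(fc$z)  # diagonal is 0, so this is the off-diagonal row sum
  names(s) <- fc$roi_names
  s
}

#' Temporal inter-subject correlation (ISC)
#'
#' Pearson correlation between two subjects' time series, region by region,
#' for the same stimulus/condition.
#'
#' @param ts_i,ts_j [roi_ts] objects with identical shape and ROI order.
#' @return Named numeric vector of per-ROI correlations.
#' @export
temporal_isc <- function(ts_i, ts_j) {
  stopifnot(inherits(ts_i, "roi_ts"), inherits(ts_j, "roi_ts"))
  if (!identical(dim(ts_i$values), dim(ts_j$values)) ||
      !identical(ts_i$roi_names, ts_j$roi_names)) {
    stop("time series must have identical shape and ROI order")
  }
  r <- vapply(seq_along(ts_i$roi_names), function(k) {
    stats::cor(ts_i$values[, k], ts_j$values[, k])
  }, numeric(1))
  names(r) <- ts_i$roi_names
  r
}

#' Extract a TR window from a time series
#'
#' Windows are 1-based and inclusive on both ends, so `(1, 50)` keeps the
#' first 50 TRs.
#'
#' @param ts A [roi_ts].
#' @param start,end First and last TR to retain.
#' @return A [roi_ts] with rows `start..end`.
#' @export
segment_ts <- function(ts, start, end) {
  stopifnot(inherits(ts, "roi_ts"))
  T <- nrow(ts$values)
  if (start < 1 || end > T || start > end) {
    stop("window [", start, ", ", end, "] out of range for ", T, " TRs")
  }
  roi_ts(ts$values[start:end, , drop = FALSE], roi_names = ts$roi_names,
         subject_id = ts$subject_id, condition = ts$condition,
         tr_seconds = ts$tr_seconds)
}

#' Within- vs outside-network connectivity contrast
#'
#' For each subject, the mean seed connectivity to in-network regions minus
#' the mean to out-of-network regions, followed by a one-sample t-test of the
#' differences across subjects.
#'
#' @param seed_z Numeric matrix, subjects x regions, of seed-to-region
#'   Fisher-z connectivity values (already averaged over seeds if several).
#' @param in_network Logical vector, one entry per region, `TRUE` for
#'   in-network regions. Both classes must be non-empty.
#' @return List with per-subject `diff`, `t`, `df`, `p` (one-sided, greater)
#'   and a `degenerate` flag set when the differences have zero variance.
#' @export
network_contrast <- function(seed_z, in_network) {
  seed_z <- as.matrix(seed_z)
  in_network <- as.logical(in_network)
  if (length(in_network) != ncol(seed_z)) {
    stop("in_network must label every region (one per column)")
  }
  if (!any(in_network) || all(in_network)) stop("both region classes must be non-empty")
  if (nrow(seed_z) < 2L) stop("need at least 2 subjects")
  d <- rowMeans(seed_z[, in_network, drop = FALSE]) -
    rowMeans(seed_z[, !in_network, drop = FALSE])
  if (stats::sd(d) == 0) {
    return(list(diff = d, t = NA_real_, df = length(d) - 1L, p = NA_real_,
                degenerate = TRUE))
  }
  tt <- stats::t.test(d, alternative = "greater")
  list(diff = d, t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}
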