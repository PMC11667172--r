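#' Time-dynamics dissimilarity between two subjects for one region
#'
#' One minus the Pearson correlation of two single-region time series,
#' bounded in [0, 2]: 0 for identical dynamics, 2 for exactly anti-correlated
#' ones.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return Scalar dissimilarity `1 - r`.
#' @export
td_dissim <- function(x, y) {
  if (length(x) != length(y)) stop("series must have equal length")
  if (length(x) < 3L) stop("need at least 3 timepoints")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero-variance series")
  1 - stats::cor(x, y)
}

#' Global functional-connectivity profile dissimilarity
#'
#' Euclidean distance between two subjects' vectorized edge profiles
#' (see [vectorize_upper()]).
#'
#' @param v_i,v_j Numeric edge vectors of equal length.
#' @return Scalar Euclidean distance.
#' @export
fc_profile_dissim <- function(v_i, v_j) {
  if (length(v_i) != length(v_j)) stop("edge vectors must have equal length")
  sqrt(sum((v_i - v_j)^2))
}

#' Per-edge dissimilarity
#'
#' Elementwise absolute difference of two edge vectors; in one dimension the
#' Euclidean distance reduces to the absolute value of the difference. The
#' squared global profile dissimilarity equals the sum of these squared
#' per-edge values.
#'
#' @param v_i,v_j Numeric edge vectors of equal length.
#' @return Numeric vector `|v_i - v_j|`, names preserved from `v_i`.
#' @export
edge_dissim <- function(v_i, v_j) {
  if (length(v_i) != length(v_j)) stop("edge vectors must have equal length")
  abs(v_i - v_j)
}

#' Strength-centrality dissimilarity (global and per region)
#'
#' Global index: Euclidean distance between the two subjects' strength
#' vectors. Per-region index: absolute difference per region.
#'
#' @param s_i,s_j Named numeric strength vectors over the same regions in the
#'   same order.
#' @return List with `global` (scalar) and `per_region` (named vector).
#' @export
centrality_dissim <- function(s_i, s_j) {
  if (length(s_i) != length(s_j)) stop("strength vectors must have equal length")
  if (!is.null(names(s_i)) && !is.null(names(s_j)) &&
      !identical(names(s_i), names(s_j))) {
    stop("ROI order mismatch between strength vectors")
  }
  d <- abs(s_i - s_j)
  list(global = sqrt(sum(d^2)), per_region = d)
}

#' Gaze-trajectory container
#'
#' Frame-by-frame gaze positions on the display, with a validity flag per
#' frame. Missing samples are `NA` coordinates; `valid` marks frames usable
#' for dyadic comparison (set by [preprocess_gaze()]).
#'
#' @param x,y Pixel coordinates per frame (`NA` = missing sample).
#' @param frames Strictly increasing integer frame index (default `1..n`).
#' @param valid Optional logical flag per frame; defaults to "coordinates
#'   present".
#' @param frame_width_px,frame_height_px Video frame size in pixels.
#' @param fps Frame rate (frames per second).
#' @return An object of class `gaze_trace` (a data frame with attributes).
#' @export
gaze_trace <- function(x, y, frames = seq_along(x), valid = NULL,
                       frame_width_px = 1280, frame_height_px = 790, fps = 24) {
  if (length(x) != length(y) || length(x) != length(frames)) {
    stop("x, y and frames must have equal length")
  }
  if (any(diff(frames) <= 0)) stop("frames must be strictly increasing")
  if (is.null(valid)) valid <- !(is.na(x) | is.na(y))
  df <- data.frame(frame = as.integer(frames), x = as.numeric(x),
                   y = as.numeric(y), valid = as.logical(valid))
  structure(df, class = c("gaze_trace", "data.frame"),
            frame_width_px = frame_width_px, frame_height_px = frame_height_px,
            fps = fps)
}

#' Preprocess a gaze trace: interpolate short gaps, drop blinks and
#' off-screen samples
#'
#' Runs of missing samples no longer than `gap_frames` that are flanked by
#' valid samples are filled by linear interpolation; longer runs are treated
#' as eye blinks and invalidated. At 24 fps the defaults implement the
#' "under 75 ms interpolated, 2 frames or more = blink" rule. Samples falling
#' outside the video frame are invalidated with their coordinates left
#' untouched. The operation is idempotent.
#'
#' @param trace A [gaze_trace].
#' @param gap_frames Longest missing run (in frames) that is interpolated.
#' @param blink_frames Shortest missing run treated as a blink; defaults to
#'   `gap_frames + 1`.
#' @return The preprocessed [gaze_trace]; errors if no valid frame remains.
#' @export
preprocess_gaze <- function(trace, gap_frames = 1, blink_frames = gap_frames + 1) {
  stopifnot(inherits(trace, "gaze_trace"))
  if (attr(trace, "fps") <= 0) stop("fps must be positive")
  w <- attr(trace, "frame_width_px"); h <- attr(trace, "frame_height_px")
  x <- trace$x; y <- trace$y; valid <- trace$valid
  miss <- is.na(x) | is.na(y)
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n <- length(x)
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    a <- starts[k]; b <- ends[k]
    len <- b - a + 1L
    flanked <- a > 1L && b < n && !miss[a - 1L] && !miss[b + 1L]
    if (len <= gap_frames && len < blink_frames && flanked) {
      fr <- trace$frame
      x[a:b] <- stats::approx(fr[c(a - 1L, b + 1L)], x[c(a - 1L, b + 1L)],
                              xout = fr[a:b])$y
      y[a:b] <- stats::approx(fr[c(a - 1L, b + 1L)], y[c(a - 1L, b + 1L)],
                              xout = fr[a:b])$y
      valid[a:b] <- TRUE
    } else {
      valid[a:b] <- FALSE  # blink (or unflanked edge gap): removed
    }
  }
  off <- !is.na(x) & !is.na(y) & (x < 0 | x > w | y < 0 | y > h)
  valid[off] <- FALSE
  if (!any(valid)) stop("no valid gaze samples remain after preprocessing")
  gaze_trace(x, y, frames = trace$frame, valid = valid,
             frame_width_px = w, frame_height_px = h, fps = attr(trace, "fps"))
}

#' Gaze-trajectory dissimilarity between two subjects
#'
#' Pearson correlations of the horizontal and vertical gaze positions are
#' computed on the frames where both traces are valid (the dyad's
#' intersection), and the dissimilarity is `1 - (r_x + r_y) / 2`, in [0, 2].
#'
#' @param trace_i,trace_j Preprocessed [gaze_trace] objects on the same frame
#'   grid.
#' @param min_overlap Minimum fraction of frames that must be jointly valid
#'   (default 0.1); dyads below it are rejected.
#' @return Scalar dissimilarity.
#' @export
gaze_dissim <- function(trace_i, trace_j, min_overlap = 0.1) {
  stopifnot(inherits(trace_i, "gaze_trace"), inherits(trace_j, "gaze_trace"))
  common <- intersect(trace_i$frame, trace_j$frame)
  ii <- match(common, trace_i$frame); jj <- match(common, trace_j$frame)
  both <- trace_i$valid[ii] & trace_j$valid[jj]
  n_total <- max(length(trace_i$frame), length(trace_j$frame))
  if (sum(both) < max(3, min_overlap * n_total)) {
    stop("insufficient valid frame overlap for this dyad (",
         sum(both), "/", n_total, ")")
  }
  xi <- trace_i$x[ii][both]; yi <- trace_i$y[ii][both]
  xj <- trace_j$x[jj][both]; yj <- trace_j$y[jj][both]
  if (stats::sd(xi) == 0 || stats::sd(xj) == 0 ||
      stats::sd(yi) == 0 || stats::sd(yj) == 0) {
    stop("zero variance on the intersecting frames")
  }
  1 - (stats::cor(xi, xj) + stats::cor(yi, yj)) / 2
}

#' Semantic dissimilarity of two document embeddings
#'
#' One minus the cosine similarity of the two vectors, in [0, 2].
#'
#' @param v_i,v_j Nonzero numeric vectors of equal dimension.
#' @return Scalar dissimilarity `1 - cos(v_i, v_j)`.
#' @export
semantic_dissim <- function(v_i, v_j) {
  if (length(v_i) != length(v_j)) stop("embedding dimensions differ")
  ni <- sqrt(sum(v_i^2)); nj <- sqrt(sum(v_j^2))
  if (ni == 0 || nj == 0) stop("zero embedding vector")
  1 - sum(v_i * v_j) / (ni * nj)
}

#' Deterministic bag-of-words embedder (test fallback)
#'
#' L2-normalized term-frequency vector over a fixed vocabulary. This is a
#' deterministic stand-in used in tests and examples; it is not equivalent to
#' a sentence-embedding model and carries none of its semantics.
#'
#' @param text Character scalar.
#' @param vocab Character vector defining the embedding dimensions.
#' @return Unit-norm numeric vector of length `length(vocab)` (zero vector if
#'   no vocabulary word occurs).
#' @export
toy_embedder <- function(text, vocab) {
  words <- tolower(unlist(strsplit(text, "[^[:alnum:]]+")))
  words <- words[nzchar(words)]
  v <- vapply(tolower(vocab), function(w) sum(words == w), numeric(1))
  n <- sqrt(sum(v^2))
  if (n > 0) v <- v / n
  unname(v)
}

#' Assemble a subject-by-subject dissimilarity matrix
#'
#' Applies a pairwise metric to every unordered pair of subjects and returns
#' a symmetric matrix with zero diagonal.
#'
#' @param features Named list, one feature object per subject.
#' @param metric Function of two feature objects returning a scalar
#'   dissimilarity.
#' @param index_name Label for the index (e.g. `"fc_profile"`).
#' @param allow_missing If `TRUE`, pairs where the metric errors are stored
#'   as `NA` and reported in the `failures` attribute; if `FALSE` (default)
#'   the first failure aborts.
#' @return An object of class `dissim_matrix` with fields `index_name`,
#'   `subject_ids` and `d`.
#' @export
build_dissim_matrix <- function(features, metric, index_name = "dissim",
                                allow_missing = FALSE) {
  ids <- names(features)
  if (is.null(ids) || anyDuplicated(ids)) stop("features must be uniquely named by subject")
  n <- length(ids)
  if (n < 2L) stop("need at least 2 subjects")
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  failures <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      val <- tryCatch(metric(features[[i]], features[[j]]), error = function(e) e)
      if (inherits(val, "error")) {
        if (!allow_missing) {
          stop("dissimilarity failed for dyad (", ids[i], ", ", ids[j], "): ",
               conditionMessage(val))
        }
        failures <- c(failures, paste0(ids[i], "|", ids[j], ": ",
                                       conditionMessage(val)))
        val <- NA_real_
      }
      d[i, j] <- d[j, i] <- val
    }
  }
  structure(
    list(index_name = index_name, subject_ids = ids, d = d),
    class = "dissim_matrix", failures = failures
  )
}

#' @export
print.dissim_matrix <- function(x, ...) {
  cat(sprintf("<dissim_matrix> '%s': %d subjects, %d dyads\n",
              x$index_name, length(x$subject_ids),
              length(x$subject_ids) * (length(x$subject_ids) - 1L) / 2L))
  invisible(x)
}

#' Subset a dissimilarity matrix to a set of subjects
#'
#' @param dm A `dissim_matrix`.
#' @param ids Subject ids to retain (order preserved as given).
#' @return A `dissim_matrix` over `ids`.
#' @export
subset_dissim <- function(dm, ids) {
  stopifnot(inherits(dm, "dissim_matrix"))
  if (!all(ids %in% dm$subject_ids)) stop("unknown subject id(s)")
  structure(
    list(index_name = dm$index_name, subject_ids = ids,
         d = dm$d[ids, ids, drop = FALSE]),
    class = "dissim_matrix"
  )
}

#' Exclude dissimilarity outliers
#'
#' For each subject, its mean dissimilarity with all other subjects is
#' z-scored across subjects; subjects more than `z_threshold` standard
#' deviations from the mean are excluded. The rule is applied once per index
#' (no re-iteration after removal).
#'
#' @param dm A `dissim_matrix` with at least 4 subjects.
#' @param z_threshold Exclusion threshold on `|z|` (default 3).
#' @return List with `retained` (a `dissim_matrix` over the kept subjects),
#'   `excluded` (data frame of excluded ids with mean dissimilarity and z),
#'   and `z` (all subjects' z-scores).
#' @export
exclude_outliers <- function(dm, z_threshold = 3) {
  stopifnot(inherits(dm, "dissim_matrix"))
  n <- length(dm$subject_ids)
  if (n < 4L) stop("need at least 4 subjects for outlier screening")
  m <- dm$d
  diag(m) <- NA
  avg <- rowMeans(m, na.rm = TRUE)
  s <- stats::sd(avg)
  if (s == 0) {
    warning("zero spread in mean dissimilarities; no outliers excluded")
    z <- rep(0, n)
  } else {
    z <- (avg - mean(avg)) / s
  }
  names(z) <- dm$subject_ids
  out <- abs(z) > z_threshold
  excluded <- data.frame(subject_id = dm$subject_ids[out],
                         mean_dissim = unname(avg[out]), z = unname(z[out]),
                         stringsAsFactors = FALSE)
  keep <- dm$subject_ids[!out]
  list(retained = subset_dissim(dm, keep), excluded = excluded, z = z)
}
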