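#' Simulation configuration for synthetic cohorts
#'
#' Collects every knob of the cohort generator. Defaults mirror the study
#' design the analysis targets: 6 mentalizing-network ROIs, 151 movie TRs
#' (180 at rest), trait scores on the 10-28 perspective-taking scale,
#' 7203 gaze frames on a 1280 x 790 display at 24 fps, and 768-dimensional
#' document embeddings.
#'
#' Inter-subject idiosyncrasy is injected additively in Fisher-z space with
#' standard deviation `sigma0 + sigma1 * trait_norm`, where `trait_norm` is
#' the trait score rescaled to [0, 1]. `mode = "annak"` uses `sigma1` as
#' given; `mode = "null"` forces the effective slope to 0 so spread is
#' trait-independent. Analogous slopes govern gaze (pixel-scale deviation
#' from a canonical trajectory) and embeddings (angular concentration
#' `kappa0 - kappa1 * trait_norm`).
#'
#' @param n_subjects Number of subjects (>= 4).
#' @param n_rois Number of network regions (default 6).
#' @param n_timepoints Movie TRs per subject (default 151).
#' @param rest_timepoints Resting-state TRs (default 180).
#' @param trait_range Inclusive integer trait range (default `c(10, 28)`).
#' @param template_fc Population-level correlation matrix (symmetric, unit
#'   diagonal, positive definite); default compound symmetry with r = 0.4.
#' @param sigma0 Baseline idiosyncrasy SD in Fisher-z units (>= 0).
#' @param sigma1 Trait slope of the idiosyncrasy SD (ignored when
#'   `mode = "null"`); `sigma0 + sigma1` must be >= 0.
#' @param mode `"annak"` (spread increases with trait) or `"null"`.
#' @param gaze List of gaze settings: `n_frames`, `frame_width_px`,
#'   `frame_height_px`, `fps`, `blink_rate` (per frame), `offscreen_rate`
#'   (per frame), `dropout_rate` (per-frame 1-frame missing samples),
#'   `sigma0_px`, `sigma1_px` (baseline / trait-slope of the deviation SD in
#'   pixels).
#' @param embed_dim Embedding dimension (default 768).
#' @param kappa0,kappa1 Embedding concentration intercept and trait slope;
#'   `kappa0 - kappa1` must be >= 0.
#' @param covariate_spec Named numeric vector of target correlations with
#'   the trait, one per simulated covariate (Gaussian copula on the latent
#'   scale).
#' @param seed Integer seed; the generator expands it into per-subject child
#'   seeds so cohorts are stable under subject-count changes.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects,
                       n_rois = 6,
                       n_timepoints = 151,
                       rest_timepoints = 180,
                       trait_range = c(10L, 28L),
                       template_fc = NULL,
                       sigma0 = 0.05,
                       sigma1 = 0.2,
                       mode = c("annak", "null"),
                       gaze = list(),
                       embed_dim = 768,
                       kappa0 = 60,
                       kappa1 = 45,
                       covariate_spec = c(fantasy = 0.45, empathy = 0.4,
                                          age = 0),
                       seed = 1L) {
  mode <- match.arg(mode)
  if (n_subjects < 4) stop("n_subjects must be at least 4")
  if (sigma0 < 0) stop("sigma0 must be non-negative")
  if (mode == "annak" && sigma0 + sigma1 < 0) {
    stop("sigma0 + sigma1 must be non-negative (SD at the top of the trait range)")
  }
  if (kappa0 < 0 || kappa0 - kappa1 < 0) {
    stop("embedding concentration must stay non-negative over the trait range")
  }
  if (trait_range[1] >= trait_range[2]) stop("trait_range must be increasing")
  gaze_defaults <- list(n_frames = 7203, frame_width_px = 1280,
                        frame_height_px = 790, fps = 24,
                        blink_rate = 0.01, offscreen_rate = 0.002,
                        dropout_rate = 0.003,
                        sigma0_px = 15, sigma1_px = 60)
  gaze <- utils::modifyList(gaze_defaults, gaze)
  if (is.null(template_fc)) {
    template_fc <- matrix(0.4, n_rois, n_rois)
    diag(template_fc) <- 1
  }
  template_fc <- as.matrix(template_fc)
  if (nrow(template_fc) != n_rois || !isSymmetric(template_fc) ||
      any(abs(diag(template_fc) - 1) > 1e-12)) {
    stop("template_fc must be a symmetric n_rois x n_rois matrix with unit diagonal")
  }
  if (min(eigen(template_fc, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("template_fc must be positive definite")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), n_rois = as.integer(n_rois),
         n_timepoints = as.integer(n_timepoints),
         rest_timepoints = as.integer(rest_timepoints),
         trait_range = as.integer(trait_range), template_fc = template_fc,
         sigma0 = sigma0, sigma1 = if (mode == "null") 0 else sigma1,
         mode = mode, gaze = gaze, embed_dim = as.integer(embed_dim),
         kappa0 = kappa0, kappa1 = if (mode == "null") 0 else kappa1,
         covariate_spec = covariate_spec, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Nearest-correlation repair: eigenvalues clipped at a small floor, then the
# matrix is rescaled to unit diagonal. Deterministic.
nearest_correlation <- function(m, eig_floor = 1e-6) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, eig_floor)
  out <- e$vectors %*% diag(vals, length(vals)) %*% t(e$vectors)
  d <- 1 / sqrt(diag(out))
  out <- out * tcrossprod(d)
  (out + t(out)) / 2
}

#' Simulate one subject's functional-connectivity matrix
#'
#' Adds symmetric Gaussian noise with SD `sigma0 + sigma1 * trait_norm` to a
#' Fisher-z template and maps back through `tanh`. With zero noise the output
#' is exactly `tanh(template_z)` (unit diagonal restored). If the result is
#' not positive semi-definite it is repaired by eigenvalue clipping and
#' re-normalization to unit diagonal.
#'
#' Randomness comes from R's global RNG; call `set.seed()` for
#' reproducibility.
#'
#' @param template_z Symmetric matrix with zero diagonal, in Fisher-z space.
#' @param trait_norm Normalized trait in [0, 1].
#' @param sigma0,sigma1 Baseline SD and trait slope (their sum must be >= 0).
#' @return A valid correlation matrix (unit diagonal, PSD).
#' @export
simulate_subject_fc <- function(template_z, trait_norm, sigma0, sigma1) {
  template_z <- as.matrix(template_z)
  if (!isSymmetric(template_z) || any(diag(template_z) != 0)) {
    stop("template_z must be symmetric with zero diagonal")
  }
  if (trait_norm < 0 || trait_norm > 1) stop("trait_norm must be in [0, 1]")
  sigma <- sigma0 + sigma1 * trait_norm
  if (sigma0 < 0 || sigma0 + sigma1 < 0) {
    stop("sigma0 and sigma0 + sigma1 must be non-negative")
  }
  R <- nrow(template_z)
  E <- matrix(0, R, R)
  noise <- stats::rnorm(R * (R - 1) / 2)
  E[upper.tri(E)] <- noise
  E <- E + t(E)
  C <- tanh(template_z + sigma * E)
  diag(C) <- 1
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 0) C <- nearest_correlation(C)
  C
}

#' Simulate a multivariate time series with a given correlation
#'
#' Zero-mean, unit-variance Gaussian draws whose population correlation is
#' `corr`; the empirical correlation converges to `corr` as the number of
#' timepoints grows.
#'
#' @param corr Valid correlation matrix (PSD, unit diagonal).
#' @param n_timepoints Number of rows to draw.
#' @return Numeric matrix, `n_timepoints` x `ncol(corr)`.
#' @export
simulate_timeseries <- function(corr, n_timepoints) {
  corr <- as.matrix(corr)
  ch <- tryCatch(chol(corr), error = function(e) {
    stop("corr is not positive definite; repair it first ",
         "(see nearest-correlation clipping in simulate_subject_fc)")
  })
  Z <- matrix(stats::rnorm(n_timepoints * ncol(corr)), n_timepoints)
  Z %*% ch
}

#' Canonical gaze trajectory for a configuration
#'
#' A smooth, deterministic Lissajous-style path inside the video frame,
#' shared by all subjects; individual traces deviate from it with
#' trait-scaled amplitude.
#'
#' @param gaze Gaze settings list (see [sim_config()]).
#' @return Matrix `n_frames` x 2 of (x, y) pixel positions.
#' @export
canonical_gaze <- function(gaze) {
  t <- seq_len(gaze$n_frames) / gaze$fps
  x <- gaze$frame_width_px * (0.5 + 0.3 * sin(2 * pi * 0.05 * t) +
                                0.08 * sin(2 * pi * 0.21 * t))
  y <- gaze$frame_height_px * (0.5 + 0.25 * cos(2 * pi * 0.04 * t) +
                                 0.08 * cos(2 * pi * 0.17 * t))
  cbind(x = x, y = y)
}

# Smooth random deviation: a sum of low-frequency sinusoids with random
# phases/amplitudes, standardized to unit SD.
smooth_deviation <- function(n_frames, fps, n_components = 12) {
  t <- seq_len(n_frames) / fps
  freqs <- stats::runif(n_components, 0.01, 0.5)
  phases <- stats::runif(n_components, 0, 2 * pi)
  amps <- stats::rnorm(n_components)
  dev <- drop(sin(outer(2 * pi * t, freqs) + rep(phases, each = n_frames)) %*% amps)
  dev / stats::sd(dev)
}

#' Simulate one subject's gaze trace
#'
#' The trace is the canonical trajectory plus a smooth random deviation with
#' pixel SD `sigma0 + sigma1 * trait_norm`, clipped to the frame. Missing
#' samples are then inserted: single-frame dropouts (interpolatable), blink
#' runs of 2-5 frames, and off-screen excursions, at the configured per-frame
#' rates, to exercise gaze preprocessing.
#'
#' @param canonical Matrix `n_frames` x 2 from [canonical_gaze()].
#' @param trait_norm Normalized trait in [0, 1].
#' @param sigma0,sigma1 Deviation SD intercept and trait slope, in pixels.
#' @param gaze Gaze settings list (see [sim_config()]).
#' @return A [gaze_trace].
#' @export
simulate_gaze <- function(canonical, trait_norm, sigma0, sigma1, gaze) {
  if (nrow(canonical) != gaze$n_frames) stop("canonical length must equal n_frames")
  sigma <- sigma0 + sigma1 * trait_norm
  if (sigma < 0) stop("gaze deviation SD must be non-negative")
  n <- gaze$n_frames
  x <- canonical[, 1]; y <- canonical[, 2]
  if (sigma > 0) {
    x <- x + sigma * smooth_deviation(n, gaze$fps)
    y <- y + sigma * smooth_deviation(n, gaze$fps)
  }
  x <- pmin(pmax(x, 0), gaze$frame_width_px)
  y <- pmin(pmax(y, 0), gaze$frame_height_px)
  if (gaze$offscreen_rate > 0) {
    off <- which(stats::runif(n) < gaze$offscreen_rate)
    x[off] <- gaze$frame_width_px + stats::runif(length(off), 1, 50)
  }
  if (gaze$dropout_rate > 0) {
    drop1 <- which(stats::runif(n) < gaze$dropout_rate)
    x[drop1] <- NA; y[drop1] <- NA
  }
  if (gaze$blink_rate > 0) {
    starts <- which(stats::runif(n) < gaze$blink_rate / 3.5)  # ~blink_rate frames affected
    for (s in starts) {
      len <- sample(2:5, 1)
      idx <- s:min(s + len - 1L, n)
      x[idx] <- NA; y[idx] <- NA
    }
  }
  gaze_trace(x, y, frame_width_px = gaze$frame_width_px,
             frame_height_px = gaze$frame_height_px, fps = gaze$fps)
}

#' Simulate one subject's document embedding
#'
#' Draws a unit vector around a population direction `mu` with angular
#' concentration `kappa = kappa0 - kappa1 * trait_norm` (higher trait, more
#' dispersed): the vector `kappa * mu + z`, `z` standard Gaussian, is
#' L2-normalized. `kappa = Inf` returns `mu` exactly; `kappa` must stay
#' non-negative.
#'
#' @param mu Unit-norm direction vector.
#' @param trait_norm Normalized trait in [0, 1].
#' @param kappa0,kappa1 Concentration intercept and trait slope.
#' @return Unit-norm numeric vector of length `length(mu)`.
#' @export
simulate_embedding <- function(mu, trait_norm, kappa0, kappa1) {
  if (abs(sqrt(sum(mu^2)) - 1) > 1e-8) stop("mu must be unit-norm")
  kappa <- kappa0 - kappa1 * trait_norm
  if (is.nan(kappa) || kappa < 0) stop("embedding concentration kappa is negative")
  if (is.infinite(kappa)) return(mu)
  v <- kappa * mu + stats::rnorm(length(mu))
  v / sqrt(sum(v^2))
}

#' Simulate a full synthetic cohort
#'
#' Draws trait scores and covariates, then per subject: a movie
#' functional-connectivity matrix whose idiosyncrasy grows with trait in
#' `"annak"` mode (trait-independent in `"null"` mode), a rest matrix with
#' trait-independent spread, movie and rest time series realizing those
#' matrices, a gaze trace, and a document embedding. The master seed is
#' expanded into per-subject child seeds, so enlarging the cohort leaves the
#' first subjects unchanged.
#'
#' @param config A [sim_config()].
#' @return An object of class `cohort` with fields `subject_ids`, `trait`,
#'   `covariates` (data frame), `timeseries` (`$movie`, `$rest`: lists of
#'   [roi_ts]), `gaze` (list of [gaze_trace]), `embedding` (list of unit
#'   vectors) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  ids <- sprintf("S%03d", seq_len(n))
  roi_names <- paste0("ROI", seq_len(config$n_rois))
  template_z <- atanh(config$template_fc)
  diag(template_z) <- 0

  set.seed(config$seed)
  mu <- stats::rnorm(config$embed_dim)
  mu <- mu / sqrt(sum(mu^2))
  child <- sample.int(.Machine$integer.max - 1L, n, replace = TRUE)
  canon <- canonical_gaze(config$gaze)

  trait <- integer(n)
  covs <- matrix(NA_real_, n, length(config$covariate_spec),
                 dimnames = list(ids, names(config$covariate_spec)))
  ts_movie <- ts_rest <- gaze <- emb <- vector("list", n)
  lo <- config$trait_range[1]; hi <- config$trait_range[2]

  for (i in seq_len(n)) {
    set.seed(child[i])
    l_trait <- stats::rnorm(1)
    # integer-uniform trait via the latent normal's quantile (Gaussian copula)
    u <- stats::pnorm(l_trait)
    trait[i] <- lo + min(floor(u * (hi - lo + 1)), hi - lo)
    for (k in seq_along(config$covariate_spec)) {
      rho <- config$covariate_spec[k]
      covs[i, k] <- rho * l_trait + sqrt(max(0, 1 - rho^2)) * stats::rnorm(1)
    }
    tn <- (trait[i] - lo) / (hi - lo)
    fc_movie <- simulate_subject_fc(template_z, tn, config$sigma0, config$sigma1)
    fc_rest <- simulate_subject_fc(template_z, tn, config$sigma0, 0)
    ts_movie[[i]] <- roi_ts(simulate_timeseries(fc_movie, config$n_timepoints),
                            roi_names = roi_names, subject_id = ids[i],
                            condition = "movie")
    ts_rest[[i]] <- roi_ts(simulate_timeseries(fc_rest, config$rest_timepoints),
                           roi_names = roi_names, subject_id = ids[i],
                           condition = "rest")
    gaze[[i]] <- simulate_gaze(canon, tn, config$gaze$sigma0_px,
                               if (config$mode == "null") 0 else config$gaze$sigma1_px,
                               config$gaze)
    emb[[i]] <- simulate_embedding(mu, tn, config$kappa0, config$kappa1)
  }
  names(ts_movie) <- names(ts_rest) <- names(gaze) <- names(emb) <- ids
  structure(
    list(subject_ids = ids, trait = stats::setNames(trait, ids),
         covariates = as.data.frame(covs),
         timeseries = list(movie = ts_movie, rest = ts_rest),
         gaze = gaze, embedding = emb, config = config),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%s mode), trait %d-%d, %d ROIs, %d TRs\n",
              length(x$subject_ids), x$config$mode, min(x$trait), max(x$trait),
              x$config$n_rois, x$config$n_timepoints))
  invisible(x)
}

#' Write a cohort to disk as plain-text files
#'
#' Layout: `manifest.csv` (subject_id, pt, covariates, file paths), one TSV
#' per subject per condition (header = ROI names, rows = TRs),
#' `gaze_<id>.csv` (frame, x, y with blanks for missing samples),
#' `embeddings.csv` (subject_id, v1..vD) and `config.yaml`.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- cohort$subject_ids
  ts_files <- list()
  for (cond in names(cohort$timeseries)) {
    ts_files[[cond]] <- file.path(dir, paste0("ts_", cond, "_", ids, ".tsv"))
    for (i in seq_along(ids)) {
      utils::write.table(cohort$timeseries[[cond]][[i]]$values,
                         ts_files[[cond]][i], sep = "\t", row.names = FALSE,
                         quote = FALSE)
    }
  }
  gaze_files <- file.path(dir, paste0("gaze_", ids, ".csv"))
  for (i in seq_along(ids)) {
    g <- cohort$gaze[[i]]
    utils::write.csv(data.frame(frame = g$frame, x = g$x, y = g$y),
                     gaze_files[i], row.names = FALSE, na = "")
  }
  emb <- do.call(rbind, cohort$embedding)
  emb_df <- data.frame(subject_id = ids, emb)
  names(emb_df) <- c("subject_id", paste0("v", seq_len(ncol(emb))))
  utils::write.csv(emb_df, file.path(dir, "embeddings.csv"), row.names = FALSE)
  manifest <- data.frame(subject_id = ids, pt = unname(cohort$trait),
                         cohort$covariates,
                         ts_movie = basename(ts_files$movie),
                         ts_rest = basename(ts_files$rest),
                         gaze = basename(gaze_files), row.names = NULL)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  cfg <- cohort$config
  cfg$template_fc <- as.vector(cfg$template_fc)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.csv` and companion files.
#' @return A `cohort` object (with `config` as read from `config.yaml`, when
#'   present).
#' @export
read_cohort <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) stop("no manifest.csv in ", dir)
  manifest <- utils::read.csv(man_path, stringsAsFactors = FALSE)
  ids <- manifest$subject_id
  cfg <- NULL
  cfg_path <- file.path(dir, "config.yaml")
  gz <- list(frame_width_px = 1280, frame_height_px = 790, fps = 24)
  if (file.exists(cfg_path)) {
    cfg <- yaml::read_yaml(cfg_path)
    if (!is.null(cfg$template_fc)) {
      cfg$template_fc <- matrix(unlist(cfg$template_fc), cfg$n_rois)
    }
    gz <- utils::modifyList(gz, cfg$gaze[c("frame_width_px", "frame_height_px", "fps")])
  }
  read_ts <- function(f, id, cond) {
    if (is.null(f)) return(NULL)
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing time-series file: ", path)
    vals <- tryCatch(as.matrix(utils::read.delim(path, check.names = FALSE)),
                     warning = function(w) stop("malformed time-series file: ", path))
    if (!is.numeric(vals) || anyNA(vals)) stop("malformed time-series file: ", path)
    roi_ts(vals, subject_id = id, condition = cond)
  }
  ts_movie <- stats::setNames(lapply(seq_along(ids), function(i)
    read_ts(manifest$ts_movie[i], ids[i], "movie")), ids)
  ts_rest <- if ("ts_rest" %in% names(manifest)) {
    stats::setNames(lapply(seq_along(ids), function(i)
      read_ts(manifest$ts_rest[i], ids[i], "rest")), ids)
  } else NULL
  gaze <- NULL
  if ("gaze" %in% names(manifest)) {
    gaze <- stats::setNames(lapply(seq_along(ids), function(i) {
      g <- utils::read.csv(file.path(dir, manifest$gaze[i]))
      gaze_trace(g$x, g$y, frames = g$frame, frame_width_px = gz$frame_width_px,
                 frame_height_px = gz$frame_height_px, fps = gz$fps)
    }), ids)
  }
  emb <- NULL
  emb_path <- file.path(dir, "embeddings.csv")
  if (file.exists(emb_path)) {
    e <- utils::read.csv(emb_path)
    emb <- stats::setNames(lapply(seq_len(nrow(e)), function(i)
      as.numeric(e[i, -1])), e$subject_id)[ids]
  }
  cov_cols <- setdiff(names(manifest),
                      c("subject_id", "pt", "ts_movie", "ts_rest", "gaze"))
  structure(
    list(subject_ids = ids, trait = stats::setNames(manifest$pt, ids),
         covariates = manifest[, cov_cols, drop = FALSE],
         timeseries = list(movie = ts_movie, rest = ts_rest),
         gaze = gaze, embedding = emb, config = cfg),
    class = "cohort"
  )
}
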