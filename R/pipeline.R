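#' Analysis run configuration
#'
#' Bundles everything [run_pipeline()] needs: where the cohort comes from
#' (simulated from a [sim_config()] or ingested from a [write_cohort()]
#' directory), which dissimilarity indices to compute, how to handle
#' confounds, and the model options. Defaults follow the reference study
#' design: 10,000 Mantel permutations, screening at alpha = 0.05, outlier
#' threshold |z| > 3, movie segments 1-50 / 51-110 / 111-151 TRs.
#'
#' @param mode `"simulate"` or `"ingest"`.
#' @param sim A [sim_config()] (simulate mode).
#' @param input_dir Cohort directory (ingest mode).
#' @param indices Character subset of
#'   `c("fc_profile", "centrality", "td", "gaze", "semantic")`.
#' @param segments Optional named list of inclusive TR windows, e.g.
#'   `list(background = c(1, 50), bird = c(51, 110), cloud = c(111, 151))`,
#'   for segment-wise FC-profile models.
#' @param confound_policy `"screen"` (auto-screen the manifest covariates)
#'   or `"explicit"`.
#' @param confounds Covariate names used when `confound_policy = "explicit"`.
#' @param alpha Screening significance level.
#' @param z_threshold Outlier-exclusion threshold.
#' @param k_convention Degrees-of-freedom convention, see [fit_group_lme()].
#' @param n_perm Mantel permutations.
#' @param mantel_alternative Mantel alternative hypothesis.
#' @param seed Seed for every stochastic step of the run.
#' @param output_dir Optional directory for CSV/JSON outputs.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "ingest"), sim = NULL,
                       input_dir = NULL,
                       indices = c("fc_profile", "centrality", "td", "gaze",
                                   "semantic"),
                       segments = NULL,
                       confound_policy = c("screen", "explicit"),
                       confounds = character(0), alpha = 0.05,
                       z_threshold = 3,
                       k_convention = "focal", n_perm = 10000,
                       mantel_alternative = "greater", seed = 1L,
                       output_dir = NULL) {
  mode <- match.arg(mode)
  confound_policy <- match.arg(confound_policy)
  indices <- match.arg(indices, several.ok = TRUE)
  if (mode == "simulate" && !inherits(sim, "sim_config")) {
    stop("simulate mode needs a sim_config")
  }
  if (mode == "ingest" && (is.null(input_dir) || !dir.exists(input_dir))) {
    stop("ingest mode needs an existing input_dir")
  }
  structure(
    list(mode = mode, sim = sim, input_dir = input_dir, indices = indices,
         segments = segments, confound_policy = confound_policy,
         confounds = confounds, alpha = alpha, z_threshold = z_threshold,
         k_convention = k_convention, n_perm = n_perm,
         mantel_alternative = mantel_alternative, seed = as.integer(seed),
         output_dir = output_dir),
    class = "run_config"
  )
}

#' Compute the dissimilarity matrices of a cohort
#'
#' Per-subject features (functional connectivity, strength centrality) are
#' derived from the movie time series, then each requested index is turned
#' into a subject-by-subject dissimilarity matrix and screened for outliers.
#'
#' @param cohort A `cohort`.
#' @param indices Which indices to compute (see [run_config()]); `"td"`
#'   produces one matrix per ROI, named `td_<roi>`.
#' @param z_threshold Outlier-exclusion threshold (`Inf` disables).
#' @param condition Which time-series condition feeds the neural indices.
#' @param window Optional inclusive TR window applied before the neural
#'   indices.
#' @return List with `matrices` (named list of retained `dissim_matrix`
#'   objects) and `exclusions` (per-index data frames of excluded subjects).
#' @export
cohort_dissim <- function(cohort, indices = c("fc_profile", "centrality"),
                          z_threshold = 3, condition = "movie",
                          window = NULL) {
  ts <- cohort$timeseries[[condition]]
  if (is.null(ts) && any(c("fc_profile", "centrality", "td") %in% indices)) {
    stop("cohort has no '", condition, "' time series")
  }
  if (!is.null(window)) ts <- lapply(ts, segment_ts, start = window[1], end = window[2])
  matrices <- list()
  if (any(c("fc_profile", "centrality") %in% indices)) {
    fc <- lapply(ts, compute_fc)
    if ("fc_profile" %in% indices) {
      edges <- lapply(fc, vectorize_upper)
      matrices$fc_profile <- build_dissim_matrix(edges, fc_profile_dissim,
                                                 "fc_profile")
    }
    if ("centrality" %in% indices) {
      strengths <- lapply(fc, strength_centrality)
      matrices$centrality <- build_dissim_matrix(
        strengths, function(a, b) centrality_dissim(a, b)$global, "centrality")
    }
  }
  if ("td" %in% indices) {
    roi_names <- ts[[1]]$roi_names
    for (k in seq_along(roi_names)) {
      cols <- lapply(ts, function(s) s$values[, k])
      matrices[[paste0("td_", roi_names[k])]] <-
        build_dissim_matrix(cols, td_dissim, paste0("td_", roi_names[k]))
    }
  }
  if ("gaze" %in% indices) {
    if (is.null(cohort$gaze)) stop("cohort has no gaze traces")
    pre <- lapply(cohort$gaze, preprocess_gaze)
    matrices$gaze <- build_dissim_matrix(pre, gaze_dissim, "gaze",
                                         allow_missing = TRUE)
  }
  if ("semantic" %in% indices) {
    if (is.null(cohort$embedding)) stop("cohort has no embeddings")
    matrices$semantic <- build_dissim_matrix(cohort$embedding, semantic_dissim,
                                             "semantic")
  }
  exclusions <- list()
  for (nm in names(matrices)) {
    scr <- exclude_outliers(matrices[[nm]], z_threshold = z_threshold)
    matrices[[nm]] <- scr$retained
    exclusions[[nm]] <- scr$excluded
  }
  list(matrices = matrices, exclusions = exclusions)
}

#' Run the full dyad-level idiosyncrasy analysis
#'
#' Simulates or ingests a cohort, computes the requested dissimilarity
#' indices (with per-index outlier exclusion), screens covariates for
#' confounding, builds the dyad table, fits the doubled-data dyadic mixed
#' model (group contrasts with FDR, plus the continuous-trait slope) for
#' every index, and runs Mantel tests relating the semantic index to each
#' neural index (confound dyad means residualized out first). With
#' `segments` set, segment-wise FC-profile group models are added. All
#' stochastic steps derive from `config$seed`.
#'
#' @param config A [run_config()].
#' @return An object of class `run_report`: list with `group_fits`,
#'   `continuous_fits`, `mantel`, `segments`, `exclusions`, `screening`,
#'   `confounds`, `dyad_table`, `n_subjects`, `seed`, `config` and
#'   `version`. Written to `config$output_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  cohort <- if (config$mode == "simulate") simulate_cohort(config$sim)
            else read_cohort(config$input_dir)

  diss <- cohort_dissim(cohort, indices = config$indices,
                        z_threshold = config$z_threshold)

  screening <- NULL
  confounds <- config$confounds
  if (config$confound_policy == "screen" && ncol(cohort$covariates) > 0) {
    screening <- screen_covariates(cohort$covariates, unname(cohort$trait),
                                   alpha = config$alpha)
    confounds <- screening$name[which(screening$confound)]
  }
  confounds <- intersect(confounds,
                         names(cohort$covariates)[vapply(cohort$covariates,
                                                         is.numeric, TRUE)])

  table <- build_dyad_table(cohort$trait, diss$matrices,
                            covariates = cohort$covariates,
                            confounds = confounds)

  group_fits <- list(); continuous_fits <- list()
  for (nm in names(diss$matrices)) {
    group_fits[[nm]] <- fit_group_lme(table, nm, covariates = confounds,
                                      k_convention = config$k_convention)
    continuous_fits[[nm]] <- fit_continuous_lme(table, nm,
                                                covariates = confounds,
                                                k_convention = config$k_convention)
  }
  # FDR across the whole contrast family: all indices x all contrasts
  all_p <- unlist(lapply(group_fits, function(f) f$contrasts$p))
  all_adj <- fdr_adjust(all_p)
  i <- 0
  for (nm in names(group_fits)) {
    nc <- nrow(group_fits[[nm]]$contrasts)
    group_fits[[nm]]$contrasts$p_fdr_family <- all_adj[i + seq_len(nc)]
    i <- i + nc
  }

  mantel <- list()
  if ("semantic" %in% names(diss$matrices)) {
    for (nm in intersect(c("fc_profile", "centrality", "gaze"),
                         names(diss$matrices))) {
      common <- intersect(diss$matrices$semantic$subject_ids,
                          diss$matrices[[nm]]$subject_ids)
      if (length(common) < 4) next
      dm_a <- subset_dissim(diss$matrices[[nm]], common)
      dm_b <- subset_dissim(diss$matrices$semantic, common)
      if (length(confounds)) {
        dm_a <- residualize_dissim(dm_a, cohort, confounds)
        dm_b <- residualize_dissim(dm_b, cohort, confounds)
      }
      mantel[[paste0(nm, "_vs_semantic")]] <-
        mantel_test(dm_a, dm_b, n_perm = config$n_perm,
                    alternative = config$mantel_alternative,
                    seed = config$seed + 1L)
    }
  }

  segments <- list()
  if (!is.null(config$segments) && "fc_profile" %in% config$indices) {
    for (seg in names(config$segments)) {
      sd_ <- cohort_dissim(cohort, indices = "fc_profile",
                           z_threshold = config$z_threshold,
                           window = config$segments[[seg]])
      seg_tab <- build_dyad_table(cohort$trait, sd_$matrices,
                                  covariates = cohort$covariates,
                                  confounds = confounds)
      segments[[seg]] <- fit_group_lme(seg_tab, "fc_profile",
                                       covariates = confounds,
                                       k_convention = config$k_convention)
    }
  }

  report <- structure(
    list(group_fits = group_fits, continuous_fits = continuous_fits,
         mantel = mantel, segments = segments, exclusions = diss$exclusions,
         screening = screening, confounds = confounds, dyad_table = table,
         n_subjects = length(cohort$subject_ids), seed = config$seed,
         config = config,
         version = as.character(utils::packageVersion("dyadak"))),
    class = "run_report"
  )
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

# Residualize a dissimilarity matrix's dyad values on confound dyad means,
# rebuilding a symmetric matrix of residuals for Mantel testing.
residualize_dissim <- function(dm, cohort, confounds) {
  ids <- dm$subject_ids
  ut <- upper.tri(dm$d)
  vals <- dm$d[ut]
  # pair order matching d[ut] (column-major over the strict upper triangle)
  idx <- which(ut, arr.ind = TRUE)
  cm <- as.data.frame(lapply(confounds, function(nm) {
    x <- stats::setNames(cohort$covariates[[nm]], cohort$subject_ids)
    (x[ids[idx[, 1]]] + x[ids[idx[, 2]]]) / 2
  }))
  names(cm) <- confounds
  res <- residualize(vals, cm)
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  m[ut] <- res
  m <- m + t(m)
  structure(list(index_name = paste0(dm$index_name, "_resid"),
                 subject_ids = ids, d = m), class = "dissim_matrix")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Dyad-level idiosyncrasy analysis\n")
  cat(sprintf("  %d subjects, %d dyads; confounds: %s\n", x$n_subjects,
              nrow(x$dyad_table),
              if (length(x$confounds)) paste(x$confounds, collapse = ", ")
              else "none"))
  for (nm in names(x$group_fits)) {
    f <- x$group_fits[[nm]]
    hh_ll <- f$contrasts[f$contrasts$contrast == "HH-LL", ]
    cf <- x$continuous_fits[[nm]]
    cat(sprintf("  %-12s HH-LL beta = %6.3f (p = %.4g, FDR %.4g); PT slope = %6.3f (p = %.4g)\n",
                nm, hh_ll$estimate, hh_ll$p, hh_ll$p_fdr, cf$beta, cf$p))
  }
  for (nm in names(x$mantel)) {
    m <- x$mantel[[nm]]
    cat(sprintf("  Mantel %-24s r(%d) = %.3f, p = %.4g\n", nm, m$df, m$r, m$p))
  }
  invisible(x)
}

#' Write a run report to disk
#'
#' Tidy CSVs for the dyad table, contrasts and exclusions plus a JSON
#' summary carrying every estimate, p-value, seed and the config echo.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$dyad_table, file.path(dir, "dyad_table.csv"),
                   row.names = FALSE)
  contrasts <- do.call(rbind, lapply(names(report$group_fits), function(nm) {
    data.frame(index = nm, report$group_fits[[nm]]$contrasts)
  }))
  utils::write.csv(contrasts, file.path(dir, "contrasts.csv"),
                   row.names = FALSE)
  excl <- do.call(rbind, lapply(names(report$exclusions), function(nm) {
    e <- report$exclusions[[nm]]
    if (nrow(e) == 0) return(NULL)
    data.frame(index = nm, e)
  }))
  if (!is.null(excl)) {
    utils::write.csv(excl, file.path(dir, "exclusions.csv"), row.names = FALSE)
  }
  summary <- list(
    n_subjects = report$n_subjects, seed = report$seed,
    version = report$version, confounds = report$confounds,
    screening = report$screening,
    contrasts = contrasts,
    continuous = lapply(report$continuous_fits, function(f)
      f[c("beta", "SE", "t", "df", "p")]),
    mantel = lapply(report$mantel, function(m)
      m[c("r", "p", "n_perm", "alternative", "df", "n_subjects", "seed")])
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
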