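#' Median split of trait scores
#'
#' Subjects strictly above the sample median are `"high"`; scores at or below
#' the median (including ties at the median) are `"low"`.
#'
#' @param scores Named numeric vector of per-subject scores.
#' @return Factor with levels `low`, `high`, named like `scores`.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2L) stop("need at least 2 subjects")
  if (stats::sd(scores) == 0) stop("all scores equal; no median split possible")
  med <- stats::median(scores)
  factor(ifelse(scores > med, "high", "low"), levels = c("low", "high"))
}

#' Screen candidate covariates for confounding with the trait
#'
#' A covariate is flagged as a confound when it correlates with the trait
#' (Pearson test) or differs between the high and low trait groups
#' (two-sample t-test for continuous covariates, chi-square for categorical
#' ones), either test at `p < alpha`.
#'
#' @param covariates Data frame of candidate covariates (numeric or
#'   factor/character columns), one row per subject.
#' @param trait Numeric trait scores, same order as the rows.
#' @param alpha Screening significance level (default 0.05).
#' @return Data frame with one row per covariate: `name`, `p_cor`, `p_diff`,
#'   `confound`. Constant covariates are skipped with a warning.
#' @export
screen_covariates <- function(covariates, trait, alpha = 0.05) {
  stopifnot(is.data.frame(covariates), nrow(covariates) == length(trait))
  grp <- median_split(trait)
  res <- lapply(names(covariates), function(nm) {
    x <- covariates[[nm]]
    if (length(unique(x)) < 2L) {
      warning("covariate '", nm, "' is constant; skipped")
      return(data.frame(name = nm, p_cor = NA_real_, p_diff = NA_real_,
                        confound = NA))
    }
    if (is.numeric(x)) {
      p_cor <- stats::cor.test(x, trait)$p.value
      p_diff <- stats::t.test(x ~ grp)$p.value
    } else {
      p_cor <- NA_real_
      p_diff <- suppressWarnings(stats::chisq.test(table(x, grp))$p.value)
    }
    data.frame(name = nm, p_cor = p_cor, p_diff = p_diff,
               confound = isTRUE(p_cor < alpha) || isTRUE(p_diff < alpha))
  })
  do.call(rbind, res)
}

#' Build the dyad-level analysis table
#'
#' Enumerates all unordered subject pairs, labels each dyad `HH`, `HL` or
#' `LL` from the members' trait groups (a high-low pair is `HL` regardless
#' of order), records the dyad's mean trait, attaches each requested
#' dissimilarity index, and codes every confound both as a dyad-level factor
#' (from that covariate's own median split) and as the dyad mean of the raw
#' values (for continuous-trait models).
#'
#' @param trait Named numeric trait scores for the retained subjects.
#' @param dissim Named list of `dissim_matrix` objects (one per index).
#'   Dyads whose members are missing from a matrix (e.g. excluded as
#'   outliers for that index) get `NA` for that index.
#' @param covariates Optional data frame of raw covariates, rows matching
#'   `names(trait)`.
#' @param confounds Character vector of covariate names to code at dyad
#'   level (default: all columns of `covariates`).
#' @return A data frame of class `dyad_table` with columns `p1`, `p2`,
#'   `group`, `mean_trait`, one column per index, and `<name>_grp` /
#'   `<name>_mean` per confound.
#' @export
build_dyad_table <- function(trait, dissim = list(), covariates = NULL,
                             confounds = names(covariates)) {
  ids <- names(trait)
  if (is.null(ids)) stop("trait must be named by subject id")
  grp <- median_split(trait)
  pairs <- utils::combn(ids, 2)
  p1 <- pairs[1, ]; p2 <- pairs[2, ]
  g1 <- as.character(grp[p1]); g2 <- as.character(grp[p2])
  group <- ifelse(g1 == "high" & g2 == "high", "HH",
                  ifelse(g1 == "low" & g2 == "low", "LL", "HL"))
  tab <- data.frame(p1 = p1, p2 = p2,
                    group = factor(group, levels = c("LL", "HL", "HH")),
                    mean_trait = (trait[p1] + trait[p2]) / 2,
                    row.names = NULL, stringsAsFactors = FALSE)
  for (nm in names(dissim)) {
    dm <- dissim[[nm]]
    stopifnot(inherits(dm, "dissim_matrix"))
    vals <- rep(NA_real_, length(p1))
    ok <- p1 %in% dm$subject_ids & p2 %in% dm$subject_ids
    vals[ok] <- dm$d[cbind(p1[ok], p2[ok])]
    tab[[nm]] <- vals
  }
  for (nm in confounds) {
    x <- stats::setNames(covariates[[nm]], rownames(covariates))
    if (is.null(names(x)) || !all(ids %in% names(x))) {
      x <- stats::setNames(covariates[[nm]], ids)
    }
    cg <- median_split(x[ids])
    names(cg) <- ids
    c1 <- as.character(cg[p1]); c2 <- as.character(cg[p2])
    tab[[paste0(nm, "_grp")]] <- factor(
      ifelse(c1 == "high" & c2 == "high", "HH",
             ifelse(c1 == "low" & c2 == "low", "LL", "HL")),
      levels = c("LL", "HL", "HH"))
    tab[[paste0(nm, "_mean")]] <- (x[p1] + x[p2]) / 2
  }
  class(tab) <- c("dyad_table", "data.frame")
  tab
}

# Double the dyad table: each unordered dyad contributes two rows with the
# member ids swapped, enabling fully crossed participant random intercepts.
double_dyads <- function(table) {
  a <- table; a$id1 <- table$p1; a$id2 <- table$p2
  b <- table; b$id1 <- table$p2; b$id2 <- table$p1
  out <- rbind(a, b)
  out$id1 <- factor(out$id1); out$id2 <- factor(out$id2)
  out
}

# z-score that tolerates zero spread (returns centered values).
zstd <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

# Symmetric dyadic linear mixed model, fitted by profiled (RE)ML.
#
# Each unordered dyad (i, j) gets one row; the participant random effect
# a_s ~ N(0, sigma_a^2) enters additively through both members, so
#   y_ij = x_ij' beta + a_i + a_j + e_ij,   V = sigma_e^2 (I + lambda Z Z')
# with Z the dyad-by-subject incidence matrix and lambda = sigma_a^2 /
# sigma_e^2. This is the model the "double the data, crossed random
# intercepts" recipe approximates; imposing the member-role symmetry
# exactly gives every pair of dyads sharing a subject its full model
# covariance, which the split into independent role effects understates.
# All solves use the thin SVD of Z (subjects-dimensional), so fits are fast
# even for thousands of dyads.
fit_dyad_gls <- function(y, X, p1, p2, REML = TRUE) {
  subj <- sort(unique(c(p1, p2)))
  n <- length(y); p <- ncol(X)
  Z <- matrix(0, n, length(subj))
  Z[cbind(seq_len(n), match(p1, subj))] <- 1
  Z[cbind(seq_len(n), match(p2, subj))] <- 1
  sv <- svd(Z, nu = length(subj), nv = 0)
  d2 <- sv$d^2
  U <- sv$u
  profile_fit <- function(loglam) {
    lam <- exp(loglam)
    w <- lam * d2 / (1 + lam * d2)
    vinv <- function(M) M - U %*% (w * crossprod(U, M))
    XtVX <- crossprod(X, vinv(X))
    beta <- solve(XtVX, crossprod(X, vinv(y)))
    r <- drop(y - X %*% beta)
    quad <- max(sum(r * vinv(r)), 1e-300)  # keep the profile finite when y = X beta
    logdetV <- sum(log1p(lam * d2))
    if (REML) {
      s2 <- quad / (n - p)
      val <- 0.5 * (logdetV + (n - p) * log(s2) +
                      as.numeric(determinant(XtVX)$modulus))
    } else {
      s2 <- quad / n
      val <- 0.5 * (logdetV + n * log(s2))
    }
    list(val = val, beta = drop(beta), s2 = s2, XtVX = XtVX, lambda = lam)
  }
  opt <- stats::optimize(function(l) profile_fit(l)$val, c(-12, 6))
  best <- profile_fit(opt$minimum)
  at_zero <- profile_fit(-30)                  # sigma_a^2 floored at 0
  boundary <- at_zero$val <= best$val
  if (boundary) best <- at_zero
  vcov <- best$s2 * solve(best$XtVX)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  sigma_a2 <- if (boundary) 0 else best$s2 * best$lambda
  list(beta = stats::setNames(best$beta, colnames(X)), vcov = vcov,
       sigma_e2 = best$s2, sigma_a2 = sigma_a2, boundary = boundary,
       n = n, n_subjects = length(subj))
}

count_k <- function(X, k_convention) {
  if (k_convention == "focal") 1L else ncol(X) - 1L
}

# Wald t-tests of linear combinations L beta at a given df
wald_contrasts <- function(fit, L, df) {
  est <- drop(L %*% fit$beta)
  se <- sqrt(diag(L %*% fit$vcov %*% t(L)))
  tval <- est / se
  p <- 2 * stats::pt(-abs(tval), df)
  data.frame(contrast = rownames(L), estimate = est, SE = se, t = tval,
             df = df, p = p, p_fdr = fdr_adjust(p), row.names = NULL)
}

#' Dyadic mixed model comparing HH, HL and LL dyads
#'
#' Fits the symmetric dyadic linear mixed model for one dissimilarity
#' index: one row per unordered dyad, with a participant random intercept
#' that enters additively through both members, so dyads sharing a subject
#' in either position are correlated under the model. This is the exact,
#' order-symmetric form of the common "double the data with fully crossed
#' participant random intercepts" recipe; splitting each participant into
#' two independent role effects understates the shared-member covariance
#' and inflates the group tests, so the symmetry is imposed directly (see
#' the methods vignette). Estimates are identical under any per-dyad member
#' ordering by construction. Fixed effects are the dyad group
#' (`LL`/`HL`/`HH`, treatment-coded against `LL`) plus any dyad-level
#' confound group factors; the dependent variable is standardized over the
#' modeled dyads, so coefficients are on the standardized scale.
#'
#' Pairwise contrasts `HH-HL`, `HH-LL`, `HL-LL` are differences of the
#' groups' adjusted means (the fixed effects are additive, so averaging
#' over covariate levels with equal or observed weights gives the same
#' differences) and are tested with Wald t statistics at `df = N - k`,
#' where `N` is the number of unique dyads and `k` follows `k_convention`:
#' `"focal"` counts only the focal predictor (k = 1), `"all"` counts every
#' non-intercept fixed-effect column. Contrast p-values are
#' Benjamini-Hochberg adjusted within the three-contrast family.
#'
#' @param table A [build_dyad_table()] result.
#' @param dv Name of the dissimilarity column to model.
#' @param covariates Names of confounds whose `_grp` factors enter as fixed
#'   effects.
#' @param k_convention `"focal"` (default) or `"all"`.
#' @param REML Use restricted maximum likelihood (default) or plain ML.
#' @return An object of class `dyad_lme`: list with `coefficients`
#'   (standardized fixed effects), `contrasts` (estimate, SE, t, df, p,
#'   p_fdr), `n_unique`, `k`, `df`, `varcor` (participant and residual
#'   variances), `singular` (participant variance estimated at 0),
#'   `diagnostics`.
#' @export
fit_group_lme <- function(table, dv, covariates = character(0),
                          k_convention = c("focal", "all"), REML = TRUE) {
  k_convention <- match.arg(k_convention)
  cov_terms <- if (length(covariates)) paste0(covariates, "_grp") else character(0)
  need <- c("p1", "p2", "group", dv, cov_terms)
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) stop("missing columns: ", paste(missing_cols, collapse = ", "))
  tab <- table[stats::complete.cases(table[, c(dv, cov_terms), drop = FALSE]), ]
  if (nlevels(droplevels(tab$group)) < 3L) stop("all three dyad groups must be represented")
  if (stats::sd(tab[[dv]]) == 0) {
    # degenerate: a constant dv carries no group information
    contrasts <- data.frame(contrast = c("HH-HL", "HH-LL", "HL-LL"),
                            estimate = 0, SE = NA_real_, t = NA_real_,
                            df = nrow(tab) - 1L, p = NA_real_,
                            p_fdr = NA_real_)
    return(structure(
      list(coefficients = NULL, contrasts = contrasts, n_unique = nrow(tab),
           k = 1L, df = nrow(tab) - 1L, varcor = NULL, singular = TRUE,
           diagnostics = "constant dependent variable", dv = dv, fit = NULL),
      class = "dyad_lme"))
  }
  tab$.dv <- zstd(tab[[dv]])
  fm <- stats::as.formula(paste("~", paste(c("group", cov_terms),
                                           collapse = " + ")))
  X <- stats::model.matrix(fm, tab)
  fit <- fit_dyad_gls(tab$.dv, X, tab$p1, tab$p2, REML = REML)
  n_unique <- nrow(tab)
  k <- count_k(X, k_convention)
  df <- n_unique - k
  # treatment coding against LL: group means differ by the group dummies
  L <- matrix(0, 3, ncol(X), dimnames = list(c("HH-HL", "HH-LL", "HL-LL"),
                                             colnames(X)))
  L["HH-HL", "groupHH"] <- 1; L["HH-HL", "groupHL"] <- -1
  L["HH-LL", "groupHH"] <- 1
  L["HL-LL", "groupHL"] <- 1
  contrasts <- wald_contrasts(fit, L, df)
  vc <- data.frame(grp = c("participant", "residual"),
                   vcov = c(fit$sigma_a2, fit$sigma_e2))
  structure(
    list(coefficients = fit$beta, contrasts = contrasts,
         n_unique = n_unique, k = k, df = df, varcor = vc,
         singular = fit$boundary,
         diagnostics = if (fit$boundary) "participant variance estimated at zero"
                       else character(0),
         dv = dv, fit = fit),
    class = "dyad_lme"
  )
}

#' @export
print.dyad_lme <- function(x, ...) {
  cat(sprintf("Dyadic mixed model for '%s' (%d unique dyads, df = %d)\n",
              x$dv, x$n_unique, x$df))
  print(x$contrasts, digits = 3)
  if (x$singular) cat("note: singular random-effects fit\n")
  invisible(x)
}

#' Dyadic mixed model with the trait as a continuous predictor
#'
#' Same symmetric dyadic model as [fit_group_lme()], but the fixed effects
#' are the standardized dyad mean trait plus the standardized dyad means of
#' the confounds. Reports the standardized trait slope with a Wald t-test
#' at `df = N - k`.
#'
#' @inheritParams fit_group_lme
#' @param covariates Names of confounds whose `_mean` columns enter as
#'   covariates.
#' @return An object of class `dyad_lme_cont`: list with `beta`, `SE`, `t`,
#'   `df`, `p`, `coefficients`, `n_unique`, `k`, `singular`, `diagnostics`.
#' @export
fit_continuous_lme <- function(table, dv, covariates = character(0),
                               k_convention = c("focal", "all"), REML = TRUE) {
  k_convention <- match.arg(k_convention)
  cov_terms <- if (length(covariates)) paste0(covariates, "_mean") else character(0)
  need <- c("p1", "p2", "mean_trait", dv, cov_terms)
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) stop("missing columns: ", paste(missing_cols, collapse = ", "))
  tab <- table[stats::complete.cases(table[, c(dv, cov_terms), drop = FALSE]), ]
  tab$.dv <- zstd(tab[[dv]])
  X <- cbind("(Intercept)" = 1, trait = zstd(tab$mean_trait))
  for (ct in cov_terms) X <- cbind(X, zstd(tab[[ct]]))
  colnames(X) <- c("(Intercept)", "trait", cov_terms)
  fit <- fit_dyad_gls(tab$.dv, X, tab$p1, tab$p2, REML = REML)
  n_unique <- nrow(tab)
  k <- count_k(X, k_convention)
  df <- n_unique - k
  beta <- unname(fit$beta["trait"])
  se <- sqrt(fit$vcov["trait", "trait"])
  if (!is.finite(se) || se < 1e-14) se <- NA_real_  # deterministic dv
  tval <- beta / se
  structure(
    list(beta = beta, SE = se, t = tval, df = df,
         p = 2 * stats::pt(-abs(tval), df), coefficients = fit$beta,
         n_unique = n_unique, k = k, singular = fit$boundary,
         diagnostics = if (fit$boundary) "participant variance estimated at zero"
                       else character(0),
         dv = dv, fit = fit),
    class = "dyad_lme_cont"
  )
}

#' @export
print.dyad_lme_cont <- function(x, ...) {
  cat(sprintf("Continuous-trait dyadic model for '%s': beta = %.3f, SE = %.3f, t(%d) = %.2f, p = %.4g\n",
              x$dv, x$beta, x$SE, x$df, x$t, x$p))
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment of a family of p-values (wraps
#' `stats::p.adjust(method = "BH")`). Adjusted values are monotone in the
#' raw values and never smaller than them.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# all permutations of 1..n (n! rows); recursion is fine for the small n
# where exhaustive Mantel enumeration is sensible
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Mantel permutation test between two dissimilarity matrices
#'
#' Pearson correlation of the vectorized strict upper triangles, with
#' significance from jointly permuting the rows and columns of the second
#' matrix. The observed statistic is included in the null count, so the
#' Monte-Carlo p-value is `(1 + #extreme) / (1 + n_perm)` and never zero.
#' With `exact = TRUE` all `n!` subject relabelings are enumerated instead
#' (only sensible for small n; guarded at n <= 8).
#'
#' @param dm_a,dm_b `dissim_matrix` objects over the same subjects in the
#'   same order (n >= 4).
#' @param n_perm Number of random permutations (default 10000).
#' @param alternative `"greater"` (default; the directional hypothesis that
#'   the matrices are positively related), `"less"` or `"two.sided"`.
#' @param seed Optional integer seed for the permutation draw.
#' @param exact Enumerate all permutations instead of sampling.
#' @return An object of class `mantel_result`: list with `r`, `p`, `n_perm`,
#'   `alternative`, `n_subjects`, `df` (the correlation degrees of freedom
#'   `n_subjects - 2` used when reporting `r(df)`), `n_dyads` and `seed`.
#' @export
mantel_test <- function(dm_a, dm_b, n_perm = 10000,
                        alternative = c("greater", "less", "two.sided"),
                        seed = NULL, exact = FALSE) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(dm_a, "dissim_matrix"), inherits(dm_b, "dissim_matrix"))
  if (!identical(dm_a$subject_ids, dm_b$subject_ids)) {
    stop("matrices must cover the same subjects in the same order")
  }
  n <- length(dm_a$subject_ids)
  if (n < 4L) stop("need at least 4 subjects")
  ut <- upper.tri(dm_a$d)
  va <- dm_a$d[ut]
  r_obs <- stats::cor(va, dm_b$d[ut])
  extreme <- function(r_perm) {
    switch(alternative,
           greater = r_perm >= r_obs - 1e-12,
           less = r_perm <= r_obs + 1e-12,
           two.sided = abs(r_perm) >= abs(r_obs) - 1e-12)
  }
  if (exact) {
    if (n > 8L) stop("exact enumeration limited to n <= 8 subjects")
    perms <- all_permutations(n)
    r_null <- apply(perms, 1, function(pp) stats::cor(va, dm_b$d[pp, pp][ut]))
    p <- mean(extreme(r_null))
    n_perm <- nrow(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    r_null <- replicate(n_perm, {
      pp <- sample.int(n)
      stats::cor(va, dm_b$d[pp, pp][ut])
    })
    p <- (1 + sum(extreme(r_null))) / (1 + n_perm)
  }
  structure(
    list(r = r_obs, p = p, n_perm = n_perm, alternative = alternative,
         n_subjects = n, df = n - 2L, n_dyads = n * (n - 1L) / 2L,
         seed = seed, exact = exact),
    class = "mantel_result"
  )
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r(%d) = %.3f, p = %.4g (%s, %s%d permutations)\n",
              x$df, x$r, x$p, x$alternative,
              if (x$exact) "exact, " else "", x$n_perm))
  invisible(x)
}

#' Residualize dyad-level values on confound dyad means
#'
#' Ordinary least-squares residuals of the dyad values on the given confound
#' columns (with intercept); with no confounds this is centering. Residuals
#' are orthogonal to every retained confound column; collinear columns are
#' dropped by the fit with a warning.
#'
#' @param values Numeric vector of dyad-level values.
#' @param confound_means Data frame (or matrix) of confound dyad means, one
#'   row per dyad; may be `NULL`.
#' @return Numeric vector of residuals, same length as `values`.
#' @export
residualize <- function(values, confound_means = NULL) {
  if (is.null(confound_means) || NCOL(confound_means) == 0) {
    return(values - mean(values))
  }
  df <- as.data.frame(confound_means)
  if (nrow(df) != length(values)) stop("confound rows must match values")
  if (length(values) < ncol(df) + 2L) stop("too few dyads to residualize")
  fit <- stats::lm(values ~ ., data = df)
  if (any(is.na(stats::coef(fit)))) {
    warning("collinear confound column(s) dropped: ",
            paste(names(which(is.na(stats::coef(fit)))), collapse = ", "))
  }
  unname(stats::residuals(fit))
}

#' Dyad group by network interaction test
#'
#' Stacks two networks' dissimilarities of the same dyads in long format
#' (two rows per doubled dyad row, network as a factor) and fits a mixed
#' model with dyad group, network and their interaction as fixed effects and
#' crossed participant random intercepts. The interaction is tested with an
#' F-test using Satterthwaite approximate denominator degrees of freedom;
#' when that approximation fails, a likelihood-ratio chi-square comparison
#' against the no-interaction model is reported instead.
#'
#' @param table A [build_dyad_table()] result containing both dvs.
#' @param dv_a,dv_b Column names of the two networks' dissimilarity indices.
#' @param network_names Labels for the two networks (default the dv names).
#' @return List with `F`, `num_df`, `den_df`, `p`, `method`
#'   (`"satterthwaite"` or `"lrt"`) and the fitted model.
#' @export
network_interaction <- function(table, dv_a, dv_b,
                                network_names = c(dv_a, dv_b)) {
  stopifnot(all(c(dv_a, dv_b) %in% names(table)))
  tab <- table[stats::complete.cases(table[, c(dv_a, dv_b)]), ]
  long <- rbind(
    data.frame(tab[c("p1", "p2", "group")], network = network_names[1],
               value = tab[[dv_a]]),
    data.frame(tab[c("p1", "p2", "group")], network = network_names[2],
               value = tab[[dv_b]]))
  long$network <- factor(long$network, levels = network_names)
  long$value <- zstd(long$value)
  dd <- double_dyads(long)
  ans <- tryCatch({
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(value ~ group * network + (1 | id1) + (1 | id2),
                     data = dd)))
    a <- stats::anova(fit)
    row <- a["group:network", ]
    list(F = row[["F value"]], num_df = row[["NumDF"]],
         den_df = row[["DenDF"]], p = row[["Pr(>F)"]],
         method = "satterthwaite", fit = fit)
  }, error = function(e) NULL)
  if (is.null(ans) || !is.finite(ans$F)) {
    full <- suppressMessages(suppressWarnings(
      lme4::lmer(value ~ group * network + (1 | id1) + (1 | id2),
                 data = dd, REML = FALSE)))
    red <- suppressMessages(suppressWarnings(
      lme4::lmer(value ~ group + network + (1 | id1) + (1 | id2),
                 data = dd, REML = FALSE)))
    lrt <- stats::anova(red, full)
    ans <- list(F = lrt$Chisq[2] / lrt$Df[2], num_df = lrt$Df[2],
                den_df = Inf, p = lrt$`Pr(>Chisq)`[2], method = "lrt",
                fit = full)
  }
  ans
}
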