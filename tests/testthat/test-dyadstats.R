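test_that("median split sends ties to the low group and is rank-invariant", {
  s <- setNames(c(18, 19, 20, 21), letters[1:4])
  expect_identical(as.character(median_split(s)), c("low", "low", "high", "high"))
  s2 <- setNames(c(18, 19, 20), letters[1:3])   # median 19: the tie is low
  expect_identical(as.character(median_split(s2)), c("low", "low", "high"))
  expect_identical(median_split(exp(s)), median_split(s))  # monotone relabeling
  expect_error(median_split(setNames(rep(5, 4), letters[1:4])), "all scores equal")
})

test_that("covariate screening flags trait-linked variables via either arm", {
  set.seed(41)
  n <- 60
  trait <- sample(10:28, n, replace = TRUE)
  grp <- median_split(setNames(trait, seq_len(n)))
  # a covariate equal across groups on average but correlated within groups:
  # center the trait within each group so the group means match exactly
  within <- trait - ave(trait, grp)
  covs <- data.frame(self = trait,
                     within_only = within + rnorm(n, 0, 0.6),
                     noise = rnorm(n))
  scr <- screen_covariates(covs, trait)
  expect_true(scr$confound[scr$name == "self"])
  expect_true(scr$confound[scr$name == "within_only"])
  expect_gt(scr$p_diff[scr$name == "within_only"], 0.05)  # flagged via correlation arm
  expect_warning(screen_covariates(data.frame(const = rep(1, n)), trait),
                 "constant")
})

test_that("independent covariates are flagged at roughly the screening rate", {
  set.seed(42)
  flags <- vapply(1:300, function(i) {
    trait <- sample(10:28, 50, replace = TRUE)
    scr <- screen_covariates(data.frame(x = rnorm(50)), trait)
    scr$confound
  }, logical(1))
  # two tests at alpha = 0.05 with an either-arm rule: between 5% and ~10%
  expect_gt(mean(flags), 0.02)
  expect_lt(mean(flags), 0.15)
})

test_that("the dyad table enumerates unordered pairs with consistent groups", {
  set.seed(43)
  n <- 10
  trait <- setNames(sample(10:28, n, replace = TRUE), sprintf("S%02d", 1:n))
  dm <- random_dm(n, names(trait))
  covs <- data.frame(fantasy = rnorm(n), row.names = names(trait))
  tab <- build_dyad_table(trait, list(x = dm), covariates = covs,
                          confounds = "fantasy")
  expect_equal(nrow(tab), choose(n, 2))
  expect_false(any(tab$p1 == tab$p2))
  grp <- median_split(trait)
  for (r in sample(nrow(tab), 10)) {
    g <- sort(as.character(grp[c(tab$p1[r], tab$p2[r])]))
    want <- if (identical(g, c("high", "high"))) "HH"
            else if (identical(g, c("low", "low"))) "LL" else "HL"
    expect_identical(as.character(tab$group[r]), want)
    expect_equal(tab$mean_trait[r],
                 mean(trait[c(tab$p1[r], tab$p2[r])]))
    expect_equal(tab$x[r], dm$d[tab$p1[r], tab$p2[r]])
  }
  expect_true(all(c("fantasy_grp", "fantasy_mean") %in% names(tab)))
  # a subject missing from an index leaves those dyads NA
  dm_small <- subset_dissim(dm, names(trait)[-1])
  tab2 <- build_dyad_table(trait, list(x = dm_small))
  expect_equal(sum(is.na(tab2$x)), n - 1)
})

test_that("group LME estimates are invariant to dyad member ordering", {
  set.seed(44)
  n <- 14
  trait <- setNames(sample(10:28, n, replace = TRUE), sprintf("S%02d", 1:n))
  dm <- random_dm(n, names(trait))
  tab <- build_dyad_table(trait, list(x = dm))
  fit1 <- fit_group_lme(tab, "x")
  swap <- sample(nrow(tab), 40)
  tmp <- tab$p1[swap]; tab$p1[swap] <- tab$p2[swap]; tab$p2[swap] <- tmp
  fit2 <- fit_group_lme(tab, "x")
  expect_equal(fit1$contrasts$estimate, fit2$contrasts$estimate,
               tolerance = 1e-8)
  expect_equal(unname(fit1$coefficients), unname(fit2$coefficients),
               tolerance = 1e-8)
})

test_that("group LME degrees of freedom follow the N - k convention", {
  set.seed(45)
  n <- 12
  trait <- setNames(sample(10:28, n, replace = TRUE), sprintf("S%02d", 1:n))
  covs <- data.frame(fantasy = rnorm(n), row.names = names(trait))
  tab <- build_dyad_table(trait, list(x = random_dm(n, names(trait))),
                          covariates = covs, confounds = "fantasy")
  fit_focal <- fit_group_lme(tab, "x", covariates = "fantasy")
  expect_equal(fit_focal$df, choose(n, 2) - 1)
  fit_all <- fit_group_lme(tab, "x", covariates = "fantasy",
                           k_convention = "all")
  # group (2 dummies) + covariate group (2 dummies) = 4 non-intercept terms
  expect_equal(fit_all$k, 4)
  expect_equal(fit_all$df, choose(n, 2) - 4)
})

test_that("a constant dependent variable gives zero contrasts", {
  set.seed(46)
  n <- 10
  trait <- setNames(sample(10:28, n, replace = TRUE), sprintf("S%02d", 1:n))
  dm <- make_dm(matrix(0.7, n, n) - diag(0.7, n), names(trait))
  fit <- fit_group_lme(build_dyad_table(trait, list(x = dm)), "x")
  expect_equal(fit$contrasts$estimate, rep(0, 3), tolerance = 1e-10)
})

test_that("the continuous-trait model recovers a perfect standardized slope", {
  set.seed(47)
  n <- 12
  trait <- setNames(sample(10:28, n, replace = TRUE), sprintf("S%02d", 1:n))
  tab <- build_dyad_table(trait, list(x = random_dm(n, names(trait))))
  tab$x <- tab$mean_trait            # dv exactly the mean trait
  fit <- fit_continuous_lme(tab, "x")
  expect_equal(fit$beta, 1, tolerance = 1e-6)
  expect_equal(fit$df, choose(n, 2) - 1)
})

test_that("BH adjustment matches a hand-computed step-up and an independent oracle", {
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
  # direct step-up implementation as the oracle
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(m); out[o] <- pmin(adj, 1)
    out
  }
  set.seed(48)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    adj <- fdr_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))                       # adjusted >= raw
    expect_true(all(diff(adj[order(p)]) >= -1e-12))          # monotone
  }
})

test_that("mantel test handles identity, mismatch and seed reproducibility", {
  set.seed(49)
  dm <- random_dm(8)
  res <- mantel_test(dm, dm, n_perm = 500, seed = 3)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 501)  # smallest attainable with the +1 convention
  expect_equal(res$df, 6)
  res2 <- mantel_test(dm, dm, n_perm = 500, seed = 3)
  expect_identical(res$p, res2$p)
  other <- random_dm(8, ids = sprintf("T%02d", 1:8))
  expect_error(mantel_test(dm, other), "same subjects")
})

test_that("mantel agrees with vegan on the observed statistic and null behavior", {
  skip_if_not_installed("vegan")
  set.seed(50)
  a <- random_dm(12); b <- random_dm(12)
  res <- mantel_test(a, b, n_perm = 2000, seed = 11)
  veg <- vegan::mantel(as.dist(a$d), as.dist(b$d), permutations = 2000)
  expect_equal(res$r, unname(veg$statistic), tolerance = 1e-12)
  # both Monte-Carlo p-values estimate the same null quantity
  expect_lt(abs(res$p - veg$signif), 0.06)
})

test_that("exhaustive mantel enumeration matches the closed permutation set", {
  set.seed(51)
  a <- random_dm(5); b <- random_dm(5)
  ex <- mantel_test(a, b, exact = TRUE)
  expect_equal(ex$n_perm, factorial(5))
  expect_gte(ex$p, 1 / factorial(5))
  # identity permutation is counted, so p is a multiple of 1/120
  expect_equal(ex$p * 120, round(ex$p * 120), tolerance = 1e-9)
})

test_that("residualization is centering without confounds and orthogonalizes otherwise", {
  set.seed(52)
  v <- rnorm(30)
  expect_equal(residualize(v), v - mean(v))
  cm <- data.frame(a = rnorm(30), b = rnorm(30))
  v2 <- 2 + 3 * cm$a - cm$b
  expect_equal(residualize(v2, cm), rep(0, 30), tolerance = 1e-10)
  r <- residualize(v, cm)
  expect_lt(abs(sum(r * cm$a)), 1e-8)
  expect_lt(abs(sum(r * cm$b)), 1e-8)
  expect_warning(residualize(v, data.frame(a = cm$a, a2 = 2 * cm$a)),
                 "collinear")
})

test_that("the network interaction is null for identical dvs and symmetric in labels", {
  set.seed(53)
  n <- 12
  trait <- setNames(sample(10:28, n, replace = TRUE), sprintf("S%02d", 1:n))
  dm <- random_dm(n, names(trait))
  tab <- build_dyad_table(trait, list(a = dm, b = dm))
  res <- network_interaction(tab, "a", "b")
  expect_lt(res$F, 1e-8)
  dm2 <- random_dm(n, names(trait))
  tab2 <- build_dyad_table(trait, list(a = dm, b = dm2))
  r12 <- network_interaction(tab2, "a", "b")
  r21 <- network_interaction(tab2, "b", "a")
  expect_equal(r12$F, r21$F, tolerance = 1e-6)
})

test_that("the interaction detects AnnaK structure confined to one network", {
  set.seed(54)
  hits <- vapply(1:10, function(i) {
    cfg <- quick_sim(16, seed = 500 + i)
    coh <- simulate_cohort(cfg)
    d_annak <- cohort_dissim(coh, indices = "fc_profile")$matrices$fc_profile
    flat <- random_dm(16, coh$subject_ids)   # structureless control network
    tab <- build_dyad_table(coh$trait, list(mtn = d_annak, ctrl = flat))
    network_interaction(tab, "mtn", "ctrl")$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
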