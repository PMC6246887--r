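test_that("the salience slope is recovered with crossed random effects", {
  set.seed(81)
  tab <- make_beta_table(n_p = 80, n_b = 45, slope = 0.5)
  r <- fit_lmm(tab, "salience")
  expect_gt(r$estimate, 0.35)
  expect_lt(r$estimate, 0.65)
  expect_lt(r$p, 0.01)
  expect_equal(r$df_num, 1)
  expect_gt(r$df_den, 10)
  expect_false(r$singular)

  # marginal R^2 against the closed form with known variance components
  sal_var <- var(0.5 * rep_len(1:3, 45))
  r2_expected <- sal_var / (sal_var + 0.3^2 + 0.2^2 + 1)
  expect_equal(r$r2_marginal, r2_expected, tolerance = 0.3)
})

test_that("nObservers enters unbinned and finds the same signal", {
  set.seed(82)
  tab <- make_beta_table(n_p = 60, n_b = 30, slope = 0.5)
  # n_observers = 4 * salience + 2 by construction -> slope/4 on that scale
  r <- fit_lmm(tab, "nObservers")
  expect_gt(r$estimate, 0.05)
  expect_lt(r$estimate, 0.20)
  expect_lt(r$p, 0.05)
})

test_that("without random variation the fit collapses to OLS", {
  set.seed(83)
  tab <- make_beta_table(n_p = 30, n_b = 20, slope = 0.4,
                         sd_participant = 0, sd_item = 0)
  r <- suppressMessages(fit_lmm(tab, "salience"))
  sal <- c(low = 1, med = 2, high = 3)[as.character(tab$salience_bin)]
  ols <- coef(lm(tab$beta ~ sal))[["sal"]]
  expect_equal(r$estimate, ols, tolerance = 1e-4)
  expect_true(r$singular) # zero variance components are flagged, not hidden
})

test_that("aliased covariates are rejected, orthogonal ones are harmless", {
  set.seed(84)
  tab <- make_beta_table(n_p = 40, n_b = 24, slope = 0.5)
  tab$copy <- c(low = 1, med = 2, high = 3)[as.character(tab$salience_bin)]
  expect_error(fit_lmm(tab, "salience", covariates = "copy"), "alias")

  # an observation-level noise covariate orthogonal to salience leaves the
  # F statistic nearly unchanged
  tab$orth <- rnorm(nrow(tab))
  f0 <- fit_lmm(tab, "salience")
  f1 <- fit_lmm(tab, "salience", covariates = "orth")
  expect_lt(abs(f1$F - f0$F) / f0$F, 0.05)
})

test_that("a confound that truly drives the betas absorbs the salience effect", {
  set.seed(85)
  hits <- 0L
  for (rep in 1:8) {
    n_p <- 25; n_b <- 24
    sal <- rep_len(1:3, n_b)
    conf <- 0.6 * sal + rnorm(n_b, 0, 0.3) # correlated with salience
    tab <- expand.grid(participant_id = sprintf("p%02d", 1:n_p),
                       bidx = seq_len(n_b))
    tab$boundary_id <- sprintf("b%02d", tab$bidx)
    tab$salience_bin <- c("low", "med", "high")[sal[tab$bidx]]
    tab$n_observers <- 4L * sal[tab$bidx]
    tab$conf <- conf[tab$bidx]
    tab$beta <- 0.8 * conf[tab$bidx] + rnorm(nrow(tab))
    r <- fit_lmm(tab, "salience", covariates = "conf")
    if (r$p > 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 6L)
})

test_that("fits are equivariant under relabeling of participants and items", {
  set.seed(86)
  tab <- make_beta_table(n_p = 20, n_b = 15, slope = 0.3)
  r1 <- fit_lmm(tab, "salience")
  tab2 <- tab
  tab2$participant_id <- paste0("X", tab$participant_id)
  tab2$boundary_id <- paste0("Y", tab$boundary_id)
  tab2 <- tab2[sample(nrow(tab2)), ]
  r2 <- fit_lmm(tab2, "salience")
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-8)
  expect_equal(r1$F, r2$F, tolerance = 1e-6)
})

test_that("covariate models report the effect-only marginal R^2 and use SVD groups", {
  set.seed(87)
  tab <- make_beta_table(n_p = 30, n_b = 24, slope = 0.5)
  for (v in c("v1", "v2", "v3")) tab[[v]] <- rnorm(nrow(tab))
  cm <- covariate_models(tab, covariates = c("v1", "v2", "v3"),
                         effect = "salience", mode = "single",
                         svd_groups = list(vis = c("v1", "v2", "v3")))
  expect_named(cm$models, c("vis1", "vis2"))
  for (m in cm$models)
    expect_equal(m$r2_marginal, cm$effect_only$r2_marginal)
  cf <- covariate_models(tab, covariates = c("v1", "v2", "v3"),
                         effect = "salience", mode = "full")
  expect_named(cf$models, "full")
  expect_lt(cf$models$full$p, 0.05)
})

test_that("the ROI sweep applies Holm-Bonferroni sensibly", {
  set.seed(88)
  # one strong region among a few nulls
  tables <- c(list(hippocampus = make_beta_table(n_p = 40, n_b = 24,
                                                 slope = 0.5)),
              lapply(1:6, function(i) make_beta_table(n_p = 40, n_b = 24,
                                                      slope = 0)))
  names(tables)[2:7] <- paste0("null", 1:6)
  res <- suppressMessages(roi_sweep(tables, "salience"))
  expect_true(res$significant[res$region == "hippocampus"])
  # Holm decisions are monotone in raw p
  ord <- order(res$p)
  expect_true(all(diff(res$significant[ord]) <= 0))
  # m = 1 reduces to the raw test
  one <- suppressMessages(roi_sweep(tables[1], "salience"))
  expect_equal(one$p_holm, one$p)
})
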