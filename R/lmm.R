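#' Crossed random-effects model of boundary-evoked amplitudes
#'
#' Fits `beta ~ effect (+ covariates) (+ runNum) + (1|participant) +
#' (1|boundary)` by REML and reports the type-III F test for the effect of
#' interest with Satterthwaite denominator degrees of freedom, plus the
#' marginal R^2 (fixed-effect variance over total variance,
#' Nakagawa-Schielzeth). Salience enters as an ordinal score (low/med/high =
#' 1/2/3); nObservers enters as the raw observer count.
#'
#' @param table a trial-beta table (see [single_trial_betas()]), optionally
#'   joined with covariate columns; required columns `beta`,
#'   `participant_id`, `boundary_id`, and `salience_bin` or `n_observers`.
#' @param effect `"salience"` or `"nObservers"` (never both).
#' @param covariates character vector of covariate column names.
#' @param include_run add `run_id` as a categorical fixed effect.
#' @param reml fit by REML (default TRUE).
#' @return object of class `lmm_result`: `estimate`, `se`, `F`, `df_num`,
#'   `df_den`, `p`, `r2_marginal`, `singular`, `n_dropped` (rows lost to
#'   missing covariates) and the fitted `model`.
#' @export
fit_lmm <- function(table, effect = c("salience", "nObservers"),
                    covariates = character(), include_run = FALSE,
                    reml = TRUE) {
  effect <- match.arg(effect)
  df <- as.data.frame(table)
  stopifnot(all(c("beta", "participant_id", "boundary_id") %in% names(df)))
  if (effect == "salience") {
    if (!"salience_bin" %in% names(df)) stop("no 'salience_bin' column")
    df$.effect <- c(low = 1, med = 2, high = 3)[as.character(df$salience_bin)]
  } else {
    if (!"n_observers" %in% names(df)) stop("no 'n_observers' column")
    df$.effect <- as.numeric(df$n_observers)
  }
  vars <- c(".effect", covariates, if (include_run) "run_id")
  use <- stats::complete.cases(df[, c("beta", vars), drop = FALSE])
  n_dropped <- sum(!use)
  if (n_dropped > 0)
    message("dropping ", n_dropped, " row(s) with missing covariates")
  df <- df[use, , drop = FALSE]
  if (length(unique(df$participant_id)) < 2L ||
      length(unique(df$boundary_id)) < 2L)
    stop("need at least 2 participants and 2 boundaries")
  if (include_run) df$run_id <- factor(df$run_id)

  # aliasing guard: the effect must not be collinear with the covariates
  Xf <- stats::model.matrix(
    stats::reformulate(vars, intercept = TRUE), df)
  if (qr(Xf)$rank < ncol(Xf))
    stop("fixed-effect design is rank deficient; the effect of interest is ",
         "aliased with a covariate")

  fml <- stats::as.formula(paste(
    "beta ~", paste(vars, collapse = " + "),
    "+ (1 | participant_id) + (1 | boundary_id)"))
  fit <- lmerTest::lmer(fml, data = df, REML = reml)
  singular <- lme4::isSingular(fit)

  an <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
  row <- an[".effect", ]
  co <- summary(fit)$coefficients

  # marginal R^2: fixed-effect variance over fixed + random-intercept +
  # residual variance
  Xm <- stats::model.matrix(fit)
  var_fix <- stats::var(as.vector(Xm %*% lme4::fixef(fit)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_ran <- sum(vc$vcov[is.na(vc$var2) & vc$grp != "Residual"])
  var_res <- vc$vcov[vc$grp == "Residual"]
  r2m <- var_fix / (var_fix + var_ran + var_res)

  structure(list(effect = effect,
                 estimate = unname(co[".effect", "Estimate"]),
                 se = unname(co[".effect", "Std. Error"]),
                 F = row[["F value"]],
                 df_num = row[["NumDF"]], df_den = row[["DenDF"]],
                 p = row[["Pr(>F)"]],
                 r2_marginal = r2m,
                 singular = singular,
                 n_dropped = n_dropped,
                 formula = fml,
                 model = fit),
            class = "lmm_result")
}

#' @export
#' @method print lmm_result
print.lmm_result <- function(x, ...) {
  cat(sprintf(
    "<lmm_result> %s: estimate = %.4g (SE %.3g), F(%.3g, %.4g) = %.4g, p = %.3g, R2m = %.3g%s\n",
    x$effect, x$estimate, x$se, x$df_num, x$df_den, x$F, x$p, x$r2_marginal,
    if (x$singular) " [singular fit]" else ""))
  invisible(x)
}

#' Covariate-adjusted boundary-effect models
#'
#' Either refits the boundary-effect model once per covariate
#' (`mode = "single"`: `beta ~ covariate + effect + (1|participant) +
#' (1|boundary)`) or once with all covariates (`mode = "full"`). Groups of
#' highly correlated covariates (e.g. the visual, auditory and layered-
#' feature families) can first be compacted to their two leading SVD
#' components each via `svd_groups`. The reported marginal R^2 always comes
#' from the effect-only model.
#'
#' @inheritParams fit_lmm
#' @param mode `"single"` or `"full"`.
#' @param svd_groups named list of character vectors; each group's columns
#'   are replaced by two SVD component scores named `<group>1`, `<group>2`.
#' @return list with `effect_only` (the unadjusted `lmm_result`), and
#'   `models` (named list of adjusted `lmm_result`s, one per covariate for
#'   `"single"`, one `"full"` entry otherwise); each adjusted result's
#'   `r2_marginal` is replaced by the effect-only value.
#' @export
covariate_models <- function(table, covariates,
                             effect = c("salience", "nObservers"),
                             mode = c("single", "full"),
                             svd_groups = NULL, include_run = FALSE) {
  effect <- match.arg(effect)
  mode <- match.arg(mode)
  df <- as.data.frame(table)
  if (!is.null(svd_groups)) {
    for (g in names(svd_groups)) {
      cols <- svd_groups[[g]]
      sc <- svd_compact(df[, cols, drop = FALSE], k = 2)
      df[, cols] <- NULL
      df[[paste0(g, "1")]] <- sc[, 1]
      df[[paste0(g, "2")]] <- if (ncol(sc) > 1) sc[, 2] else 0
      covariates <- c(setdiff(covariates, cols), paste0(g, 1:2))
    }
  }
  # standardize continuous covariates so fixed effects share a scale
  for (cv in covariates) {
    v <- df[[cv]]
    if (is.numeric(v) && length(unique(v)) > 2L && stats::sd(v) > 0)
      df[[cv]] <- as.vector(scale(v))
  }
  effect_only <- fit_lmm(df, effect, include_run = include_run)
  fix_r2 <- function(res) { res$r2_marginal <- effect_only$r2_marginal; res }
  models <- if (mode == "single") {
    stats::setNames(lapply(covariates, function(cv)
      fix_r2(fit_lmm(df, effect, covariates = cv, include_run = include_run))),
      covariates)
  } else {
    list(full = fix_r2(fit_lmm(df, effect, covariates = covariates,
                               include_run = include_run)))
  }
  list(effect_only = effect_only, models = models)
}

#' Boundary-effect sweep over many ROIs with Holm-Bonferroni correction
#'
#' Fits the boundary-effect model in each region (bilateral homologs should
#' be averaged upstream, e.g. via [zscore_and_average()]), then applies the
#' Holm-Bonferroni step-down correction over the family of regions.
#'
#' @param tables named list of trial-beta tables, one per region.
#' @param effect `"salience"` or `"nObservers"`.
#' @param alpha family-wise error level.
#' @param ... passed to [fit_lmm()].
#' @return data frame with one row per region: `region`, `estimate`, `F`,
#'   `df_num`, `df_den`, `p`, `p_holm`, `significant`, `r2_marginal`.
#' @export
roi_sweep <- function(tables, effect = c("salience", "nObservers"),
                      alpha = 0.05, ...) {
  effect <- match.arg(effect)
  fits <- lapply(tables, fit_lmm, effect = effect, ...)
  p <- vapply(fits, `[[`, numeric(1), "p")
  p_holm <- stats::p.adjust(p, method = "holm")
  data.frame(region = names(tables),
             estimate = vapply(fits, `[[`, numeric(1), "estimate"),
             F = vapply(fits, `[[`, numeric(1), "F"),
             df_num = vapply(fits, `[[`, numeric(1), "df_num"),
             df_den = vapply(fits, `[[`, numeric(1), "df_den"),
             p = p, p_holm = p_holm,
             significant = p_holm < alpha,
             r2_marginal = vapply(fits, `[[`, numeric(1), "r2_marginal"),
             row.names = NULL)
}
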