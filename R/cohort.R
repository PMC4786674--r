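## Cohort statistics: per-larva aggregation and nested linear mixed models.
##
## Repeated trials (and, for imaging, multiple cells) within the same fish
## make observations non-independent; hypothesis tests therefore use linear
## mixed models with a random intercept per fish (and per cell nested in
## fish for imaging responses). Model fitting is delegated to
## lme4/lmerTest (REML, Satterthwaite degrees of freedom).

#' Average trial measurements within each larva
#'
#' Unweighted mean of each parameter over a fish's accepted trials. Fish
#' with zero accepted trials appear with NA so the cohort roster is
#' preserved.
#'
#' @param table Long-format data frame with columns `fish_id`, `genotype`,
#'   and one or more numeric parameter columns (e.g. `tbf`). An optional
#'   logical `accepted` column restricts the rows used.
#' @param parameters Character vector of parameter columns to average;
#'   default: every numeric column except `trial`.
#' @return Data frame with one row per fish: `fish_id`, `genotype`,
#'   per-parameter means, and `n_trials` (accepted trials used).
#' @export
summarize_per_larva <- function(table, parameters = NULL) {
  if (is.null(parameters)) {
    num <- vapply(table, is.numeric, logical(1))
    parameters <- setdiff(names(table)[num], c("trial"))
  }
  roster <- unique(table[, c("fish_id", "genotype")])
  roster <- roster[order(roster$fish_id), , drop = FALSE]
  used <- if ("accepted" %in% names(table))
    table[isTRUE_vec(table$accepted), , drop = FALSE] else table
  out <- roster
  for (p in parameters) {
    m <- tapply(used[[p]], used$fish_id, mean, na.rm = TRUE)
    out[[p]] <- as.numeric(m[out$fish_id])
    out[[p]][is.nan(out[[p]])] <- NA_real_
  }
  cnt <- tapply(rep(1, nrow(used)), used$fish_id, sum)
  out$n_trials <- as.integer(cnt[out$fish_id])
  out$n_trials[is.na(out$n_trials)] <- 0L
  rownames(out) <- NULL
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Fit a nested linear mixed model for a cohort comparison
#'
#' Fixed effects: genotype contrast(s) against the reference level and a
#' linear trial covariate (habituation across repeated trials); random
#' intercept per fish, and per cell nested within fish when `cell_col` is
#' given (imaging responses). Estimation is by REML; degrees of freedom,
#' p-values and confidence intervals use the Satterthwaite approximation.
#'
#' @param table Long-format data frame with `fish_id`, `genotype`, `trial`
#'   and the response column.
#' @param response Name of the response column (e.g. `"tbf"`).
#' @param cell_col Optional name of a cell-identifier column for imaging
#'   data (adds a nested random intercept).
#' @param trial_as_factor Code trial categorically instead of linearly.
#' @param conf_level Confidence level for intervals.
#' @return Object of class `cohort_mm`: `effects` (data frame with
#'   `term`, `estimate`, `se`, `df`, `ci_lo`, `ci_hi`, `p`), `ranef_sd`
#'   (random-effect and residual SDs), `n_fish`, `n_obs`, `singular`, and
#'   the underlying `model`.
#' @export
fit_mixed_model <- function(table, response = "tbf", cell_col = NULL,
                            trial_as_factor = FALSE, conf_level = 0.95) {
  stopifnot(response %in% names(table))
  d <- table
  d$genotype <- droplevels(factor(d$genotype))
  if (nlevels(d$genotype) < 2) stop("need at least 2 genotypes")
  if (min(table(unique(d[, c("fish_id", "genotype")])$genotype)) < 2)
    stop("need at least 2 fish per genotype")
  d$.y <- d[[response]]
  d$.trial <- if (trial_as_factor) factor(d$trial) else d$trial
  form <- if (is.null(cell_col))
    .y ~ genotype + .trial + (1 | fish_id)
  else {
    d$.cell <- d[[cell_col]]
    .y ~ genotype + .trial + (1 | fish_id / .cell)
  }
  fit <- lmerTest::lmer(form, data = d, REML = TRUE)
  singular <- lme4::isSingular(fit)
  if (singular)
    warning("singular fit: a variance component is estimated at zero")
  s <- summary(fit)$coefficients
  alpha <- 1 - conf_level
  eff <- data.frame(term = rownames(s), estimate = s[, "Estimate"],
                    se = s[, "Std. Error"], df = s[, "df"],
                    p = s[, "Pr(>|t|)"], stringsAsFactors = FALSE)
  crit <- qt(1 - alpha / 2, eff$df)
  eff$ci_lo <- eff$estimate - crit * eff$se
  eff$ci_hi <- eff$estimate + crit * eff$se
  eff <- eff[, c("term", "estimate", "se", "df", "ci_lo", "ci_hi", "p")]
  rownames(eff) <- NULL
  vc <- as.data.frame(lme4::VarCorr(fit))
  ranef_sd <- setNames(vc$sdcor, ifelse(is.na(vc$grp), "resid", vc$grp))
  structure(list(effects = eff, ranef_sd = ranef_sd,
                 n_fish = length(unique(d$fish_id)), n_obs = nrow(d),
                 singular = singular, response = response, model = fit),
            class = "cohort_mm")
}

#' @export
print.cohort_mm <- function(x, digits = 3, ...) {
  cat(sprintf("Linear mixed model for '%s' (%d obs, %d fish)\n",
              x$response, x$n_obs, x$n_fish))
  eff <- x$effects
  eff[, -1] <- lapply(eff[, -1], signif, digits)
  print(eff, row.names = FALSE)
  cat("Random-effect SDs:",
      paste(sprintf("%s=%.3g", names(x$ranef_sd), x$ranef_sd),
            collapse = ", "), "\n")
  if (x$singular) cat("Note: singular fit\n")
  invisible(x)
}

#' @export
summary.cohort_mm <- function(object, ...) summary(object$model, ...)

#' Extract fixed-effect estimates
#'
#' @param object A `cohort_mm`.
#' @param ... Unused.
#' @return Named numeric vector of fixed-effect estimates.
#' @export
coef.cohort_mm <- function(object, ...) {
  setNames(object$effects$estimate, object$effects$term)
}
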