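#' Fit the condition-comparison mixed model
#'
#' Random-intercept linear mixed model for one per-trial sway metric:
#' `response ~ stimulus * condition + (1 | subject)`, REML estimation, with
#' treatment coding against the (None, Silent) reference cell. The fixed
#' effects are therefore intercept, Noise, Easy, Hard, Noise x Easy and
#' Noise x Hard — the parameterisation under which a dual-task
#' posturography experiment's headline estimates are reported.
#'
#' @param table Per-trial metrics (e.g. from [cohort_metrics()]), with
#'   columns `subject`, `condition`, `stimulus` and the response.
#' @param response Name of the response column (e.g. `"mean_rs"`,
#'   `"alpha"`).
#' @return An object of class `condition_fit`: `model` (the `lmerMod`),
#'   `fixed_effects` (tibble: term, estimate, se, t, p), `random_intercept_sd`,
#'   `residual_sd`, `response`, `converged`. Cell means and contrasts are
#'   added by [marginal_means_and_contrasts()].
#' @examples
#' \donttest{
#' cfg <- sway_model_config(n_subjects = 4, trials_per_condition = 2,
#'                          trial_duration = 20)
#' m <- cohort_metrics(generate_cohort(cfg))
#' fit <- fit_condition_model(m, "mean_rs")
#' fit$fixed_effects
#' }
#' @export
fit_condition_model <- function(table, response) {
  need <- c("subject", "condition", "stimulus", response)
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("metrics table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(table)
  df$condition <- cond_factor(as.character(df$condition))
  df$stimulus <- stim_factor(as.character(df$stimulus))
  df$.y <- df[[response]]
  if (length(unique(df$subject)) < 2L) {
    stop("at least 2 subjects are required for a random intercept",
         call. = FALSE)
  }
  cells <- table(df$condition, df$stimulus)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop("rank-deficient design: empty cell(s) ",
         paste(rownames(cells)[empty[, 1]], colnames(cells)[empty[, 2]],
               collapse = "; "), call. = FALSE)
  }
  model <- lmerTest::lmer(.y ~ stimulus * condition + (1 | subject),
                          data = df, REML = TRUE)
  msgs <- model@optinfo$conv$lme4$messages
  converged <- is.null(msgs)
  if (!converged) {
    warning("mixed-model convergence message(s): ",
            paste(unlist(msgs), collapse = "; "), call. = FALSE)
  }
  cf <- as.data.frame(coef(summary(model)))
  vc <- as.data.frame(lme4::VarCorr(model))
  structure(list(
    model = model,
    fixed_effects = tibble::tibble(
      term = rename_terms(rownames(cf)),
      estimate = cf$Estimate, se = cf$`Std. Error`, df = cf$df,
      t = cf$`t value`, p = cf$`Pr(>|t|)`
    ),
    random_intercept_sd = vc$sdcor[vc$grp == "subject"],
    residual_sd = vc$sdcor[vc$grp == "Residual"],
    response = response,
    data = df,
    converged = converged
  ), class = "condition_fit")
}

# Map lme4 coefficient names to the package's effect vocabulary:
# intercept, noise, easy, hard, noise:easy, noise:hard.
rename_terms <- function(x) {
  x <- sub("^\\(Intercept\\)$", "intercept", x)
  x <- sub("stimulusNoise", "noise", x, fixed = TRUE)
  x <- sub("conditionEasy", "easy", x, fixed = TRUE)
  sub("conditionHard", "hard", x, fixed = TRUE)
}

#' @export
print.condition_fit <- function(x, ...) {
  cat(sprintf("<condition_fit> response %s | subject SD %.4g | residual SD %.4g\n",
              x$response, x$random_intercept_sd, x$residual_sd))
  print(x$fixed_effects)
  invisible(x)
}

#' Estimated marginal means and Tukey-adjusted pairwise contrasts
#'
#' Computes the six (condition x stimulus) estimated marginal means with
#' confidence intervals and all 15 pairwise contrasts, family-wise adjusted
#' by Tukey's studentized-range method. Denominator degrees of freedom use
#' the Kenward-Roger approximation when the pbkrtest package is available,
#' otherwise Satterthwaite; the method actually used is recorded in
#' `df_method` and never switched silently.
#'
#' @param fit A `condition_fit` from [fit_condition_model()].
#' @param df_method `"kenward-roger"` (default, falls back with a warning)
#'   or `"satterthwaite"`.
#' @return The `condition_fit` with `cell_means` (tibble: condition,
#'   stimulus, emmean, se, df, lower_cl, upper_cl), `contrasts` (tibble:
#'   contrast, estimate, se, df, t_ratio, p_value; Tukey-adjusted p) and
#'   `df_method` filled in.
#' @export
marginal_means_and_contrasts <- function(fit,
                                         df_method = c("kenward-roger",
                                                       "satterthwaite")) {
  stopifnot(inherits(fit, "condition_fit"))
  df_method <- match.arg(df_method)
  if (df_method == "kenward-roger" &&
      !requireNamespace("pbkrtest", quietly = TRUE)) {
    warning("pbkrtest unavailable; falling back to Satterthwaite df",
            call. = FALSE)
    df_method <- "satterthwaite"
  }
  emm <- emmeans::emmeans(fit$model, ~ condition * stimulus,
                          lmer.df = df_method, data = fit$data)
  cm <- as.data.frame(emm)
  ct <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                        adjust = "tukey"))
  fit$cell_means <- tibble::tibble(
    condition = cond_factor(as.character(cm$condition)),
    stimulus = stim_factor(as.character(cm$stimulus)),
    cell = paste(cm$condition, cm$stimulus),
    emmean = cm$emmean, se = cm$SE, df = cm$df,
    lower_cl = cm$lower.CL, upper_cl = cm$upper.CL
  )
  fit$contrasts <- tibble::tibble(
    contrast = clean_contrast_labels(ct$contrast),
    estimate = ct$estimate, se = ct$SE, df = ct$df,
    t_ratio = ct$t.ratio, p_value = ct$p.value
  )
  fit$df_method <- df_method
  fit
}

# emmeans labels cells "None Silent - Easy Silent"; keep that convention.
clean_contrast_labels <- function(x) gsub("[()]", "", as.character(x))

#' Extract a contrast row by its cell labels
#'
#' Convenience accessor: returns the contrast `"<cell_a> - <cell_b>"`,
#' seeking either orientation and flipping the sign (and t-ratio) when only
#' the reverse orientation is stored.
#'
#' @param fit A `condition_fit` with contrasts populated.
#' @param cell_a,cell_b Cell labels like `"None Silent"`.
#' @return A one-row tibble.
#' @export
get_contrast <- function(fit, cell_a, cell_b) {
  stopifnot(!is.null(fit$contrasts))
  lab <- paste(cell_a, "-", cell_b)
  rev_lab <- paste(cell_b, "-", cell_a)
  ct <- fit$contrasts
  if (lab %in% ct$contrast) return(ct[ct$contrast == lab, ])
  if (rev_lab %in% ct$contrast) {
    row <- ct[ct$contrast == rev_lab, ]
    row$contrast <- lab
    row$estimate <- -row$estimate
    row$t_ratio <- -row$t_ratio
    return(row)
  }
  stop("contrast not found: ", lab, call. = FALSE)
}
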