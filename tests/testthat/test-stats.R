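# Direct simulation of a metrics table from a known mixed model, bypassing
# the trial generator: fast, and isolates the model-fitting layer.
simulate_metrics_table <- function(effects, subject_sd, resid_sd, n_subjects,
                                   trials_per_cell, seed) {
  set.seed(seed)
  grid <- expand.grid(condition = c("None", "Easy", "Hard"),
                      stimulus = c("Silent", "Noise"),
                      trial = seq_len(trials_per_cell),
                      subject = sprintf("S%02d", seq_len(n_subjects)),
                      stringsAsFactors = FALSE)
  b <- stats::setNames(rnorm(n_subjects, 0, subject_sd),
                       sprintf("S%02d", seq_len(n_subjects)))
  cell <- mapply(function(cc, ss) swaydyn:::cell_effect(effects, cc, ss),
                 grid$condition, grid$stimulus)
  tibble::tibble(
    subject = grid$subject,
    condition = grid$condition,
    stimulus = grid$stimulus,
    y = cell + b[grid$subject] + rnorm(nrow(grid), 0, resid_sd)
  )
}

RS_EFFECTS <- c(intercept = 5.726, noise = -1.273, easy = 0.144, hard = 0.753,
                easy_noise = 0.831, hard_noise = 0.458)

test_that("the mixed model recovers known fixed effects from a simulated table", {
  tab <- simulate_metrics_table(RS_EFFECTS, 1.73, 1.70, 28, 5, seed = 1)
  fit <- fit_condition_model(tab, "y")
  truth <- unname(RS_EFFECTS[c("intercept", "noise", "easy", "hard",
                               "easy_noise", "hard_noise")])
  expect_identical(fit$fixed_effects$term,
                   c("intercept", "noise", "easy", "hard",
                     "noise:easy", "noise:hard"))
  expect_true(all(abs(fit$fixed_effects$estimate - truth) <
                    2 * fit$fixed_effects$se))
  expect_gt(fit$random_intercept_sd, 0.8)
  expect_lt(abs(fit$residual_sd - 1.70), 0.3)
  expect_true(fit$converged)
})

test_that("cell means, the 15-contrast family and their consistency hold", {
  tab <- simulate_metrics_table(RS_EFFECTS, 1, 1, 10, 4, seed = 2)
  fit <- marginal_means_and_contrasts(fit_condition_model(tab, "y"))
  expect_identical(nrow(fit$cell_means), 6L)
  expect_identical(nrow(fit$contrasts), 15L)
  expect_identical(fit$df_method, "kenward-roger")
  # every contrast equals the difference of its two cell means
  cm <- stats::setNames(fit$cell_means$emmean, fit$cell_means$cell)
  for (i in seq_len(15)) {
    parts <- strsplit(fit$contrasts$contrast[i], " - ", fixed = TRUE)[[1]]
    expect_equal(fit$contrasts$estimate[i], cm[[parts[1]]] - cm[[parts[2]]],
                 tolerance = 1e-8)
  }
})

test_that("contrast lookup flips orientation antisymmetrically", {
  tab <- simulate_metrics_table(RS_EFFECTS, 1, 1, 8, 3, seed = 3)
  fit <- marginal_means_and_contrasts(fit_condition_model(tab, "y"))
  ab <- get_contrast(fit, "None Silent", "None Noise")
  ba <- get_contrast(fit, "None Noise", "None Silent")
  expect_equal(ab$estimate, -ba$estimate)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("Tukey adjustment never reports smaller p than the unadjusted contrast", {
  tab <- simulate_metrics_table(RS_EFFECTS, 1, 1, 10, 3, seed = 4)
  fit <- fit_condition_model(tab, "y")
  emm <- emmeans::emmeans(fit$model, ~ condition * stimulus, data = fit$data)
  unadj <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "none"))
  adj <- marginal_means_and_contrasts(fit)$contrasts
  expect_true(all(adj$p_value >= unadj$p.value - 1e-12))
})

test_that("null-effect tables rarely produce large t statistics", {
  null_eff <- c(intercept = 5, noise = 0, easy = 0, hard = 0,
                easy_noise = 0, hard_noise = 0)
  worst_t <- vapply(1:20, function(s) {
    tab <- simulate_metrics_table(null_eff, 1, 1, 12, 4, seed = 100 + s)
    fit <- fit_condition_model(tab, "y")
    max(abs(fit$fixed_effects$t[-1]))
  }, numeric(1))
  expect_gte(mean(worst_t < 3), 0.9)
})

test_that("all 15 adjusted p-values stay above 0.05 in most null replicates", {
  null_eff <- c(intercept = 5, noise = 0, easy = 0, hard = 0,
                easy_noise = 0, hard_noise = 0)
  ok <- vapply(1:20, function(s) {
    tab <- simulate_metrics_table(null_eff, 1, 1, 12, 4, seed = 200 + s)
    fit <- marginal_means_and_contrasts(fit_condition_model(tab, "y"),
                                        df_method = "satterthwaite")
    all(fit$contrasts$p_value > 0.05)
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("duplicating every trial keeps estimates but shrinks their SEs", {
  tab <- simulate_metrics_table(RS_EFFECTS, 1, 1, 8, 3, seed = 6)
  fit1 <- fit_condition_model(tab, "y")
  fit2 <- fit_condition_model(dplyr::bind_rows(tab, tab), "y")
  expect_equal(fit2$fixed_effects$estimate, fit1$fixed_effects$estimate,
               tolerance = 1e-6)
  expect_true(all(fit2$fixed_effects$se < fit1$fixed_effects$se))
})

test_that("degenerate designs fail loudly", {
  tab <- simulate_metrics_table(RS_EFFECTS, 1, 1, 6, 3, seed = 7)
  expect_error(fit_condition_model(tab[tab$subject == "S01", ], "y"),
               "2 subjects")
  no_cell <- tab[!(tab$condition == "Hard" & tab$stimulus == "Noise"), ]
  expect_error(fit_condition_model(no_cell, "y"), "empty cell")
  expect_error(fit_condition_model(tab, "not_a_column"), "lacks column")
})
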