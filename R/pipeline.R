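#' Configuration for a full pipeline run
#'
#' @param input Either a [sway_model_config()] (synthetic cohort) or a path
#'   to a cohort directory written by [write_cohort()].
#' @param trim_seconds Startle trim window (s).
#' @param outlier_k SD multiplier for the trial-exclusion rule.
#' @param cutoff,filter_order Band-decomposition settings.
#' @param dfa_args Extra [dfa()] arguments.
#' @param df_method Degrees-of-freedom method for contrasts.
#' @param out_dir Output directory for tables, figures and the manifest.
#' @param seed Master seed (overrides the seed inside a synthetic config).
#' @param make_figures Also render box-plot figures (default `TRUE`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = sway_model_config(),
                       trim_seconds = 4, outlier_k = 2,
                       cutoff = 0.3, filter_order = 4,
                       dfa_args = list(),
                       df_method = "kenward-roger",
                       out_dir = tempfile("swaydyn_run_"),
                       seed = NULL, make_figures = TRUE) {
  if (inherits(input, "sway_model_config") && !is.null(seed)) {
    input$seed <- as.integer(seed)
  }
  structure(list(input = input, trim_seconds = trim_seconds,
                 outlier_k = outlier_k, cutoff = cutoff,
                 filter_order = filter_order, dfa_args = dfa_args,
                 df_method = df_method, out_dir = out_dir,
                 seed = seed, make_figures = make_figures),
            class = "run_config")
}

RESPONSES <- c(broadband_rs = "mean_rs", low_rs = "mean_rs_low",
               high_rs = "mean_rs_high", dfa_alpha = "alpha")

#' Run the full sway analysis pipeline
#'
#' Orchestrates simulate/ingest, startle trimming, broadband radial sway,
#' one-pass outlier exclusion on broadband trial means, band decomposition
#' and DFA on the surviving trials (one shared exclusion set for all four
#' responses), and the four condition-comparison mixed models (broadband RS,
#' low-frequency RS, high-frequency RS, DFA alpha) with estimated marginal
#' means and Tukey-adjusted contrasts. Tables, figures and a machine-readable
#' manifest are written under `config$out_dir`.
#'
#' A failing stage aborts with the stage name; outputs written before the
#' failure are left in place.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of class `pipeline_run`: `metrics` (post-
#'   exclusion per-trial table), `exclusions` (report), `fits` (named list
#'   of `condition_fit`), `out_dir`, `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  cohort <- stage("input", {
    if (inherits(config$input, "sway_model_config")) {
      generate_cohort(config$input)
    } else if (is.character(config$input)) {
      read_cohort(config$input)
    } else stop("`input` must be a sway_model_config or a directory path")
  })

  metrics <- stage("metrics", cohort_metrics(
    cohort, trim_seconds = config$trim_seconds, cutoff = config$cutoff,
    order = config$filter_order, dfa_args = config$dfa_args))

  excl <- stage("outlier_exclusion",
                remove_outlier_trials(metrics, k = config$outlier_k))
  kept <- excl$kept
  readr::write_csv(excl$report, file.path(config$out_dir, "exclusion_report.csv"))
  readr::write_csv(kept, file.path(config$out_dir, "trial_metrics.csv"))

  fits <- list()
  for (nm in names(RESPONSES)) {
    fits[[nm]] <- stage(paste0("model_", nm), {
      f <- fit_condition_model(kept, RESPONSES[[nm]])
      marginal_means_and_contrasts(f, df_method = config$df_method)
    })
    readr::write_csv(fits[[nm]]$fixed_effects,
                     file.path(config$out_dir, paste0("fixed_effects_", nm, ".csv")))
    readr::write_csv(fits[[nm]]$cell_means,
                     file.path(config$out_dir, paste0("cell_means_", nm, ".csv")))
    readr::write_csv(format_contrast_table(fits[[nm]]),
                     file.path(config$out_dir, paste0("contrasts_", nm, ".csv")))
  }

  if (isTRUE(config$make_figures)) {
    stage("figures", make_figures(kept, config$out_dir))
  }

  manifest <- list(
    package = "swaydyn",
    version = as.character(utils::packageVersion("swaydyn")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = if (inherits(config$input, "sway_model_config")) config$input$seed else config$seed,
    config_hash = config_hash(config),
    n_trials_in = nrow(metrics),
    n_trials_kept = nrow(kept),
    exclusion_rate = excl$exclusion_rate,
    df_method = fits[[1]]$df_method,
    responses = as.list(RESPONSES)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(structure(list(metrics = kept, exclusions = excl, fits = fits,
                           out_dir = config$out_dir, manifest = manifest),
                      class = "pipeline_run"))
}

# Stable digest of the run configuration (sway config serialised to YAML).
config_hash <- function(config) {
  x <- unclass(config)
  if (inherits(x$input, "sway_model_config")) x$input <- unclass(x$input)
  txt <- yaml::as.yaml(lapply(x, function(v) if (is.function(v)) "fn" else v))
  # small rolling hash; avoids a digest dependency
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Contrast table in the conventional report layout
#'
#' @param fit A `condition_fit` with contrasts populated.
#' @return A tibble with columns Contrast, Estimate, SE, T-Ratio, P-Value.
#' @export
format_contrast_table <- function(fit) {
  ct <- fit$contrasts
  tibble::tibble(Contrast = ct$contrast, Estimate = ct$estimate,
                 SE = ct$se, `T-Ratio` = ct$t_ratio, `P-Value` = ct$p_value)
}

RESPONSE_LABELS <- c(broadband_rs = "Radial sway",
                     low_rs = "Low-frequency radial sway",
                     high_rs = "High-frequency radial sway",
                     dfa_alpha = "DFA scaling exponent")

#' Box-and-whisker figures per response
#'
#' One figure per response, per condition x stimulus cell: solid line at
#' the median, solid dot at the mean, whiskers extending to the minimum and
#' maximum.
#'
#' @param metrics Per-trial metrics table (post-exclusion).
#' @param out_dir Directory for the PNG files; `NULL` returns the plots
#'   without writing.
#' @param responses Named character vector: figure name -> metrics column.
#' @return A named list of ggplot objects, invisibly when writing.
#' @export
make_figures <- function(metrics, out_dir = NULL, responses = RESPONSES) {
  empty <- dplyr::anti_join(
    tidyr::expand_grid(condition = cond_factor(COND_LEVELS),
                       stimulus = stim_factor(STIM_LEVELS)),
    metrics, by = c("condition", "stimulus"))
  if (nrow(empty)) {
    stop("no trials in cell(s): ",
         paste(empty$condition, empty$stimulus, collapse = "; "), call. = FALSE)
  }
  plots <- list()
  for (nm in names(responses)) {
    col <- responses[[nm]]
    if (!col %in% names(metrics)) stop("missing metrics column: ", col, call. = FALSE)
    p <- ggplot2::ggplot(metrics, ggplot2::aes(
      x = .data$condition, y = .data[[col]], fill = .data$stimulus)) +
      ggplot2::geom_boxplot(coef = Inf, position = ggplot2::position_dodge(0.8),
                            outlier.shape = NA) +
      ggplot2::stat_summary(fun = mean, geom = "point", shape = 16, size = 2,
                            colour = "black",
                            position = ggplot2::position_dodge(0.8)) +
      ggplot2::scale_fill_manual(values = c(Silent = "grey85", Noise = "steelblue")) +
      ggplot2::labs(x = "Cognitive condition", y = RESPONSE_LABELS[[nm]],
                    fill = "Stimulus") +
      ggplot2::theme_classic()
    plots[[nm]] <- p
    if (!is.null(out_dir)) {
      ggplot2::ggsave(file.path(out_dir, paste0("figure_", nm, ".png")), p,
                      width = 6, height = 4, dpi = 150)
    }
  }
  if (is.null(out_dir)) plots else invisible(plots)
}
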