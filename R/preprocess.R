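#' Read a CoP trial from a delimited text file
#'
#' Expects the layout written by [write_cohort()]: a header with columns
#' `time_s`, `cop_x`, `cop_y`. Metadata (subject, condition, stimulus) comes
#' from the cohort's `design.csv` via `design_row`, or from the file name
#' convention `<subject>_T<trial>.csv` when only identity is needed.
#'
#' @param path CSV file path.
#' @param design_row Optional one-row data frame with `subject`,
#'   `trial_index`, `condition`, `stimulus`.
#' @param sampling_rate Sampling rate in Hz; inferred from the median time
#'   step when `NULL`.
#' @return A validated [cop_trial()]. Missing columns, NaN/NA samples and
#'   non-monotone time raise a format error naming the offending row.
#' @export
read_cop_trial <- function(path, design_row = NULL, sampling_rate = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("time_s", "cop_x", "cop_y")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("format error in ", basename(path), ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in need) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad)) {
      stop("format error in ", basename(path), ": non-finite value in `",
           col, "` at row ", bad[1], call. = FALSE)
    }
  }
  if (is.null(sampling_rate)) {
    sampling_rate <- 1 / median(diff(df$time_s))
  }
  meta <- list(subject = NA_character_, trial_index = NA_integer_,
               condition = "None", stimulus = "Silent")
  if (!is.null(design_row)) {
    meta$subject <- as.character(design_row$subject[1])
    meta$trial_index <- as.integer(design_row$trial_index[1])
    meta$condition <- as.character(design_row$condition[1])
    meta$stimulus <- as.character(design_row$stimulus[1])
  } else {
    m <- regmatches(basename(path),
                    regexec("^(.+)_T(\\d+)\\.csv$", basename(path)))[[1]]
    if (length(m) == 3L) {
      meta$subject <- m[2]
      meta$trial_index <- as.integer(m[3])
    }
  }
  cop_trial(time = df$time_s, x = df$cop_x, y = df$cop_y,
            sampling_rate = sampling_rate, subject = meta$subject,
            condition = meta$condition, stimulus = meta$stimulus,
            trial_index = meta$trial_index)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing per-trial CSVs and `design.csv`.
#' @return A `sway_cohort`-like list with `trials` and `design` (and
#'   `config` when `config.yaml` is present).
#' @export
read_cohort <- function(dir) {
  design_path <- file.path(dir, "design.csv")
  if (!file.exists(design_path)) {
    stop("no design.csv in ", dir, call. = FALSE)
  }
  design <- readr::read_csv(design_path, show_col_types = FALSE, progress = FALSE)
  design$condition <- cond_factor(design$condition)
  design$stimulus <- stim_factor(design$stimulus)
  trials <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    nm <- sprintf("%s_T%02d", design$subject[i], design$trial_index[i])
    trials[[i]] <- read_cop_trial(file.path(dir, paste0(nm, ".csv")),
                                  design_row = design[i, ])
    names(trials)[i] <- nm
  }
  cfg_path <- file.path(dir, "config.yaml")
  config <- if (file.exists(cfg_path)) read_sway_config(cfg_path) else NULL
  structure(list(trials = trials, design = design, config = config),
            class = "sway_cohort")
}

#' Remove the initial startle window from a trial
#'
#' Drops the first `trim_seconds` of a trial (default 4 s), the window where
#' stimulus onset can startle the participant; metadata is preserved and
#' time is re-zeroed.
#'
#' @param trial A [cop_trial()].
#' @param trim_seconds Seconds to drop from the start (default 4).
#' @return The trimmed [cop_trial()]; `trim_seconds = 0` is the identity.
#' @export
trim_startle <- function(trial, trim_seconds = 4) {
  stopifnot(inherits(trial, "cop_trial"))
  if (trim_seconds < 0) stop("`trim_seconds` must be non-negative", call. = FALSE)
  if (trim_seconds == 0) return(trial)
  n_drop <- round(trim_seconds * trial$sampling_rate)
  n <- length(trial$x)
  if (n_drop >= n) {
    stop(sprintf("trial (%.3g s) is not longer than the trim window (%g s)",
                 n / trial$sampling_rate, trim_seconds), call. = FALSE)
  }
  keep <- (n_drop + 1L):n
  out <- trial
  out$time <- trial$time[keep] - trial$time[keep[1]]
  out$x <- trial$x[keep]
  out$y <- trial$y[keep]
  out
}

#' Exclude outlier trials by the +/- 2 SD rule
#'
#' Within each subject x condition cell (by default further split by
#' stimulus, since all downstream comparisons are across the six
#' condition x stimulus cells), a trial is excluded when its trial-mean RS
#' lies strictly more than `k` sample SDs from the cell mean. Statistics are
#' computed once on the full cell, including the candidate trial (one-pass
#' rule, no re-computation after removal). Cells with fewer than 3 trials
#' are skipped with a warning and nothing is excluded from them.
#'
#' @param metrics A data frame with at least `subject`, `condition`,
#'   `mean_rs`, and `stimulus` when `by_stimulus` is `TRUE`.
#' @param k SD multiplier (default 2); `k = Inf` excludes nothing.
#' @param by_stimulus Also split cells by auditory stimulus (default `TRUE`).
#' @return A list with `kept` (rows retained), `report` (every input row
#'   with `cell`, `cell_mean`, `cell_sd`, `zscore`, `excluded`), and
#'   `exclusion_rate`.
#' @examples
#' m <- tibble::tibble(subject = "S01", condition = "None", stimulus = "Silent",
#'                     trial_index = 1:10, mean_rs = c(rep(5, 9), 50))
#' remove_outlier_trials(m)$report$excluded
#' @export
remove_outlier_trials <- function(metrics, k = 2, by_stimulus = TRUE) {
  stopifnot(all(c("subject", "condition", "mean_rs") %in% names(metrics)))
  if (by_stimulus && !"stimulus" %in% names(metrics)) {
    stop("`metrics` lacks a `stimulus` column; set by_stimulus = FALSE",
         call. = FALSE)
  }
  grp <- if (by_stimulus) {
    paste(metrics$subject, metrics$condition, metrics$stimulus, sep = "|")
  } else {
    paste(metrics$subject, metrics$condition, sep = "|")
  }
  report <- metrics
  report$cell <- grp
  report$cell_mean <- stats::ave(metrics$mean_rs, grp)
  report$cell_sd <- stats::ave(metrics$mean_rs, grp,
                               FUN = function(v) rep(sd(v), length(v)))
  cell_n <- stats::ave(metrics$mean_rs, grp, FUN = length)
  small <- cell_n < 3
  if (any(small)) {
    warning("cell(s) with < 3 trials skipped by the outlier rule: ",
            paste(unique(report$cell[small]), collapse = ", "), call. = FALSE)
  }
  dev <- report$mean_rs - report$cell_mean
  report$zscore <- ifelse(report$cell_sd > 0, dev / report$cell_sd, 0)
  report$excluded <- !small & report$cell_sd > 0 & abs(dev) > k * report$cell_sd
  list(kept = metrics[!report$excluded, , drop = FALSE],
       report = report,
       exclusion_rate = mean(report$excluded))
}
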