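#' Configuration for the synthetic sway cohort generator
#'
#' Bundles every parameter of the synthetic center-of-pressure (CoP) cohort:
#' sampling, trial duration, the factorial effect structure for trial-mean
#' radial sway (RS) and for the DFA scaling exponent alpha, and the
#' between-subject / between-trial variance components.
#'
#' Effects are coded against the reference cell (condition `None`, stimulus
#' `Silent`): a named vector with elements `intercept`, `noise`, `easy`,
#' `hard`, `easy_noise`, `hard_noise`, matching a `condition * stimulus`
#' treatment parameterisation. The default RS effects place the quiet-standing
#' baseline at 5.726 (opaque "paper units", plausibly millimetres), with
#' auditory noise lowering sway and a hard working-memory task raising it; the
#' default alpha effects keep every cell inside the anti-persistent fractional
#' Brownian band (1, 1.5).
#'
#' Variance components: `subject_sd` and `trial_sd` act on the per-trial
#' target RS mean (length units); `alpha_subject_sd` and `alpha_trial_sd` act
#' on the per-trial target scaling exponent (dimensionless). Defaults are
#' calibrated so a default cohort reproduces the uncertainty structure of a
#' 28-subject, 30-trial dual-task posturography session (see the methods
#' vignette for the derivation).
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param trial_duration Trial length in seconds.
#' @param rs_effects Named effect vector for trial-mean RS (length units).
#' @param alpha_effects Named effect vector for the DFA exponent.
#' @param subject_sd SD of the per-subject RS intercept offset (length units).
#' @param trial_sd SD of the per-trial RS target noise (length units).
#' @param alpha_subject_sd SD of the per-subject alpha offset.
#' @param alpha_trial_sd SD of the per-trial alpha target noise.
#' @param amplitude_ratio Medial-lateral over anterior-posterior amplitude
#'   ratio (the two axes are generated independently; 1 = equal amplitude).
#' @param n_subjects Number of subjects in a cohort.
#' @param trials_per_condition Trials per cognitive condition per subject.
#' @param seed Master RNG seed for the cohort.
#' @return An object of class `sway_model_config` (a validated list).
#' @examples
#' cfg <- sway_model_config(n_subjects = 2)
#' cell_targets(cfg)
#' @export
sway_model_config <- function(sampling_rate = 200,
                              trial_duration = 90,
                              rs_effects = c(intercept = 5.726, noise = -1.273,
                                             easy = 0.144, hard = 0.753,
                                             easy_noise = 0.831, hard_noise = 0.458),
                              alpha_effects = c(intercept = 1.293, noise = -0.098,
                                                easy = -0.020, hard = -0.031,
                                                easy_noise = 0.063, hard_noise = 0.073),
                              subject_sd = 1.73,
                              trial_sd = 1.70,
                              alpha_subject_sd = 0.078,
                              alpha_trial_sd = 0.096,
                              amplitude_ratio = 1,
                              n_subjects = 28,
                              trials_per_condition = 10,
                              seed = 1L) {
  cfg <- structure(list(
    sampling_rate = sampling_rate, trial_duration = trial_duration,
    rs_effects = rs_effects, alpha_effects = alpha_effects,
    subject_sd = subject_sd, trial_sd = trial_sd,
    alpha_subject_sd = alpha_subject_sd, alpha_trial_sd = alpha_trial_sd,
    amplitude_ratio = amplitude_ratio,
    n_subjects = as.integer(n_subjects),
    trials_per_condition = as.integer(trials_per_condition),
    seed = as.integer(seed)
  ), class = "sway_model_config")
  validate_sway_model_config(cfg)
}

validate_sway_model_config <- function(cfg) {
  need <- c("intercept", "noise", "easy", "hard", "easy_noise", "hard_noise")
  for (f in c("rs_effects", "alpha_effects")) {
    if (!all(need %in% names(cfg[[f]]))) {
      stop(sprintf("`%s` must name the terms: %s", f, paste(need, collapse = ", ")),
           call. = FALSE)
    }
  }
  if (cfg$sampling_rate <= 0 || cfg$trial_duration <= 0) {
    stop("`sampling_rate` and `trial_duration` must be positive", call. = FALSE)
  }
  n <- cfg$sampling_rate * cfg$trial_duration
  if (abs(n - round(n)) > 1e-9) {
    stop("sampling_rate * trial_duration must be an integer sample count", call. = FALSE)
  }
  if (cfg$subject_sd < 0 || cfg$trial_sd < 0 ||
      cfg$alpha_subject_sd < 0 || cfg$alpha_trial_sd < 0) {
    stop("variance components must be non-negative", call. = FALSE)
  }
  if (cfg$amplitude_ratio <= 0) stop("`amplitude_ratio` must be positive", call. = FALSE)
  if (cfg$n_subjects < 1 || cfg$trials_per_condition < 1) {
    stop("`n_subjects` and `trials_per_condition` must be at least 1", call. = FALSE)
  }
  tg <- cell_targets(cfg)
  if (any(tg$rs_mean <= 0)) {
    stop("configuration error: implied cell-mean RS is not positive in cell(s): ",
         paste(tg$cell[tg$rs_mean <= 0], collapse = ", "), call. = FALSE)
  }
  if (any(tg$alpha <= 1 | tg$alpha >= 1.5)) {
    stop("configuration error: implied cell alpha outside the anti-persistent ",
         "range (1, 1.5) in cell(s): ",
         paste(tg$cell[tg$alpha <= 1 | tg$alpha >= 1.5], collapse = ", "),
         call. = FALSE)
  }
  cfg
}

# Treatment-coded cell value for one (condition, stimulus) cell.
cell_effect <- function(effects, condition, stimulus) {
  v <- effects[["intercept"]]
  if (stimulus == "Noise") v <- v + effects[["noise"]]
  if (condition == "Easy") {
    v <- v + effects[["easy"]]
    if (stimulus == "Noise") v <- v + effects[["easy_noise"]]
  } else if (condition == "Hard") {
    v <- v + effects[["hard"]]
    if (stimulus == "Noise") v <- v + effects[["hard_noise"]]
  }
  unname(v)
}

#' Implied cell means of a sway configuration
#'
#' Sums the treatment-coded effects into the six
#' (condition x stimulus) cell targets for trial-mean RS and DFA alpha.
#'
#' @param config A [sway_model_config()].
#' @return A tibble with columns `condition`, `stimulus`, `cell`, `rs_mean`,
#'   `alpha`.
#' @export
cell_targets <- function(config) {
  grid <- expand.grid(stimulus = STIM_LEVELS, condition = COND_LEVELS,
                      stringsAsFactors = FALSE)[, c("condition", "stimulus")]
  tibble::tibble(
    condition = cond_factor(grid$condition),
    stimulus = stim_factor(grid$stimulus),
    cell = paste(grid$condition, grid$stimulus),
    rs_mean = unname(mapply(cell_effect, grid$condition, grid$stimulus,
                            MoreArgs = list(effects = config$rs_effects))),
    alpha = unname(mapply(cell_effect, grid$condition, grid$stimulus,
                          MoreArgs = list(effects = config$alpha_effects)))
  )
}

#' Session trial design
#'
#' Builds the ordered 30-trial session layout: 10 trials per cognitive
#' condition, with the no-task trials split 4 / 2 / 4 across a beginning,
#' middle and end block around the (counterbalanced) Easy and Hard blocks,
#' and the auditory stimulus randomised under a 15-noise / 15-silent
#' constraint across the whole session.
#'
#' @param trials_per_condition Trials per cognitive condition (default 10;
#'   must be even so noise/silent split in half, and divisible so the no-task
#'   trials split 4/2/4 proportionally).
#' @param seed RNG seed controlling block order and stimulus assignment.
#' @return A tibble with columns `trial_index`, `condition`, `stimulus`,
#'   `block`.
#' @examples
#' d <- session_design(seed = 7)
#' table(d$condition, d$stimulus)
#' @export
session_design <- function(trials_per_condition = 10, seed = 1L) {
  tpc <- as.integer(trials_per_condition)
  if (tpc %% 2L != 0L) {
    stop("`trials_per_condition` must be even for a half-noise split", call. = FALSE)
  }
  local_rng(seed)
  # No-task trials bracket the task blocks: 40% / 20% / 40%.
  n_start <- round(0.4 * tpc); n_mid <- tpc - 2L * n_start
  task_order <- sample(c("Easy", "Hard"))
  condition <- c(rep("None", n_start),
                 rep(task_order[1], tpc),
                 rep("None", n_mid),
                 rep(task_order[2], tpc),
                 rep("None", n_start))
  block <- c(rep("baseline_start", n_start),
             rep(paste0("task_", tolower(task_order[1])), tpc),
             rep("baseline_mid", n_mid),
             rep(paste0("task_", tolower(task_order[2])), tpc),
             rep("baseline_end", n_start))
  n_total <- 3L * tpc
  stimulus <- rep("Silent", n_total)
  stimulus[sample.int(n_total, n_total %/% 2L)] <- "Noise"
  tibble::tibble(
    trial_index = seq_len(n_total),
    condition = cond_factor(condition),
    stimulus = stim_factor(stimulus),
    block = block
  )
}

# Derive a per-stream seed from a master seed and a counter; stays inside
# the 32-bit signed range and never returns 0.
derive_seed <- function(master, counter) {
  s <- (as.double(master) + 1000003 * as.double(counter)) %% 2147483647
  as.integer(s) + 1L
}

# Seed the RNG for the calling frame, restoring its state on exit.
local_rng <- function(seed, envir = parent.frame()) {
  withr::local_seed(as.integer(seed), .local_envir = envir)
  invisible(seed)
}
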