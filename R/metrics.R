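#' Radial sway of a CoP trial
#'
#' Per-sample Euclidean distance of the CoP from the trial-mean CoP,
#' \eqn{RS_i = \sqrt{x_i^2 + y_i^2}} after centering each axis on its trial
#' mean (set `demean = FALSE` to measure from the plate origin instead; the
#' high-frequency band is already zero-mean so either choice coincides
#' there). The trial average of RS summarises bidirectional sway
#' variability.
#'
#' @param trial A [cop_trial()].
#' @param demean Center x and y on their trial means first (default `TRUE`).
#' @return An object of class `radial_sway`: `rs` (per-sample series),
#'   `mean_rs`, `band`, `demeaned`, plus the trial's metadata.
#' @examples
#' tr <- cop_trial(time = (0:99) / 100, x = rep(3, 100), y = rep(4, 100),
#'                 sampling_rate = 100)
#' radial_sway(tr, demean = FALSE)$mean_rs  # 5
#' @export
radial_sway <- function(trial, demean = TRUE) {
  stopifnot(inherits(trial, "cop_trial"))
  if (length(trial$x) == 0L) stop("empty trial", call. = FALSE)
  x <- trial$x; y <- trial$y
  if (demean) {
    x <- x - mean(x)
    y <- y - mean(y)
  }
  rs <- sqrt(x^2 + y^2)
  structure(list(rs = rs, mean_rs = mean(rs), band = trial$band,
                 demeaned = demean, subject = trial$subject,
                 trial_index = trial$trial_index,
                 condition = trial$condition, stimulus = trial$stimulus),
            class = "radial_sway")
}

#' @export
print.radial_sway <- function(x, ...) {
  cat(sprintf("<radial_sway> %s band | mean RS %.4g | %d samples\n",
              x$band, x$mean_rs, length(x$rs)))
  invisible(x)
}

#' Decompose a CoP trial into low- and high-frequency bands
#'
#' Zero-phase (forward-backward) Butterworth filtering of the x and y
#' components at the given cutoff, separating slow, sensory-feedback-related
#' drift (low band) from fast corrective adjustments (high band). The
#' forward-backward pass squares the magnitude response, so the effective
#' attenuation is that of a filter of twice the stated order; edges are
#' handled by reflective padding of length `3 * order * rate / cutoff`
#' samples (capped at the trial length minus one).
#'
#' @param trial A broadband [cop_trial()].
#' @param cutoff Cutoff frequency in Hz (default 0.3; must be below Nyquist).
#' @param order One-pass Butterworth order (default 4).
#' @return A list with `low` and `high`, both [cop_trial()]s tagged with
#'   their band.
#' @export
decompose_bands <- function(trial, cutoff = 0.3, order = 4) {
  stopifnot(inherits(trial, "cop_trial"))
  if (cutoff >= trial$sampling_rate / 2) {
    stop("`cutoff` must be below the Nyquist frequency", call. = FALSE)
  }
  if (cutoff <= 0) stop("`cutoff` must be positive", call. = FALSE)
  w <- cutoff / (trial$sampling_rate / 2)
  lp <- signal::butter(order, w, type = "low")
  hp <- signal::butter(order, w, type = "high")
  pad <- min(ceiling(3 * order * trial$sampling_rate / cutoff),
             length(trial$x) - 1L)
  low <- trial; high <- trial
  low$x <- filtfilt_reflect(lp, trial$x, pad)
  low$y <- filtfilt_reflect(lp, trial$y, pad)
  high$x <- filtfilt_reflect(hp, trial$x, pad)
  high$y <- filtfilt_reflect(hp, trial$y, pad)
  low$band <- "low"; high$band <- "high"
  list(low = low, high = high)
}

# Zero-phase filtering with reflective edge padding: reflect `pad` samples
# about each end point, filter forward and backward, drop the padding.
filtfilt_reflect <- function(filt, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  ext <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  fwd <- signal::filter(filt, ext)
  bwd <- rev(signal::filter(filt, rev(fwd)))
  as.numeric(bwd[(pad + 1L):(pad + n)])
}

#' Detrended fluctuation analysis
#'
#' First-order DFA in the standard formulation: (1) center the series and
#' integrate it into a profile; (2) for each window size `n`, split the
#' profile into `floor(N/n)` non-overlapping windows from the start
#' (an incomplete tail window is discarded; `two_sided = TRUE` additionally
#' windows from the end and pools both passes); (3) least-squares detrend
#' each window with a polynomial of order `detrend_order`; (4) pool the
#' squared residuals into the fluctuation function
#' \eqn{F(n) = \sqrt{\langle r^2 \rangle}}; (5) the scaling exponent
#' \eqn{\alpha} is the OLS slope of \eqn{\log_{10} F} on \eqn{\log_{10} n}.
#'
#' For postural sway, \eqn{1 < \alpha < 1.5} marks anti-persistent
#' fractional Brownian motion — the semi-random-walk regime typical of
#' healthy standing.
#'
#' @param series Numeric vector (length at least 4x the largest window).
#' @param window_sizes Integer window sizes, or `NULL` for the default grid
#'   of ~16 log-spaced sizes from 10 to `length(series)/4`.
#' @param detrend_order Polynomial detrending order (default 1, linear).
#' @param n_windows Number of grid points when `window_sizes` is `NULL`.
#' @param two_sided Also window from the series tail (default `FALSE`).
#' @return An object of class `dfa_result`: `window_sizes`, `fluctuation`,
#'   `alpha`, `fit_range`, `detrend_order`.
#' @examples
#' set.seed(1)
#' dfa(rnorm(4096))$alpha      # ~0.5 (white noise)
#' dfa(cumsum(rnorm(4096)))$alpha  # ~1.5 (Brownian motion)
#' @export
dfa <- function(series, window_sizes = NULL, detrend_order = 1,
                n_windows = 16, two_sided = FALSE) {
  N <- length(series)
  if (sd(series) == 0) {
    stop("degenerate input: constant series has F(n) = 0", call. = FALSE)
  }
  if (is.null(window_sizes)) {
    if (N < 40L) stop("series too short for the default DFA grid", call. = FALSE)
    window_sizes <- unique(round(exp(seq(log(10), log(N / 4),
                                         length.out = n_windows))))
  }
  window_sizes <- sort(unique(as.integer(window_sizes)))
  if (length(window_sizes) < 8L) {
    stop("at least 8 distinct window sizes are required", call. = FALSE)
  }
  if (any(window_sizes <= detrend_order + 1L)) {
    stop("window sizes must exceed detrend_order + 1", call. = FALSE)
  }
  if (N < 4L * max(window_sizes)) {
    stop("series length must be at least 4x the largest window", call. = FALSE)
  }
  profile <- cumsum(series - mean(series))
  Fn <- vapply(window_sizes, function(n) {
    k <- N %/% n
    W <- matrix(profile[seq_len(n * k)], nrow = n)
    if (two_sided) {
      W2 <- matrix(profile[(N - n * k + 1L):N], nrow = n)
      W <- cbind(W, W2)
    }
    t <- seq_len(n)
    X <- stats::poly(t, degree = detrend_order, raw = TRUE)
    X <- cbind(1, X)
    R <- W - X %*% solve(crossprod(X), crossprod(X, W))
    sqrt(mean(R^2))
  }, numeric(1))
  fit <- lm(log10(Fn) ~ log10(window_sizes))
  structure(list(window_sizes = window_sizes, fluctuation = Fn,
                 alpha = unname(coef(fit)[2]),
                 fit_range = range(window_sizes),
                 detrend_order = detrend_order),
            class = "dfa_result")
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("<dfa_result> alpha = %.4f | %d windows in [%d, %d]\n",
              x$alpha, length(x$window_sizes), x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Per-trial sway metrics
#'
#' The full per-trial metric set used by the condition comparison: broadband
#' mean RS, mean RS of the low and high bands from [decompose_bands()], and
#' the DFA exponent of the broadband RS series. Band RS uses `demean = TRUE`
#' for the low band (which retains the trial offset) and `demean = FALSE`
#' for the already-zero-mean high band.
#'
#' @param trial A trimmed broadband [cop_trial()].
#' @param cutoff,order Band-decomposition settings (see [decompose_bands()]).
#' @param dfa_args List of extra arguments for [dfa()].
#' @return A one-row tibble: `subject`, `trial_index`, `condition`,
#'   `stimulus`, `mean_rs`, `mean_rs_low`, `mean_rs_high`, `alpha`.
#' @export
trial_metrics <- function(trial, cutoff = 0.3, order = 4, dfa_args = list()) {
  stopifnot(inherits(trial, "cop_trial"))
  rs <- radial_sway(trial, demean = TRUE)
  bands <- decompose_bands(trial, cutoff = cutoff, order = order)
  rs_low <- radial_sway(bands$low, demean = TRUE)
  rs_high <- radial_sway(bands$high, demean = FALSE)
  alpha <- do.call(dfa, c(list(series = rs$rs), dfa_args))$alpha
  tibble::tibble(
    subject = trial$subject,
    trial_index = trial$trial_index,
    condition = cond_factor(trial$condition),
    stimulus = stim_factor(trial$stimulus),
    mean_rs = rs$mean_rs,
    mean_rs_low = rs_low$mean_rs,
    mean_rs_high = rs_high$mean_rs,
    alpha = alpha
  )
}

#' Metrics table for a whole cohort
#'
#' Applies [trim_startle()] and [trial_metrics()] to every trial of a
#' cohort.
#'
#' @param cohort A `sway_cohort` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param trim_seconds Startle window to drop (default 4 s).
#' @param cutoff,order,dfa_args Passed to [trial_metrics()].
#' @return A tibble with one row per trial.
#' @export
cohort_metrics <- function(cohort, trim_seconds = 4, cutoff = 0.3, order = 4,
                           dfa_args = list()) {
  rows <- lapply(cohort$trials, function(tr) {
    trial_metrics(trim_startle(tr, trim_seconds),
                  cutoff = cutoff, order = order, dfa_args = dfa_args)
  })
  dplyr::bind_rows(rows)
}
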