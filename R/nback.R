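#' Score a modified n-back letter sequence
#'
#' Counts positional letter repetitions at the given lag: position `i`
#' matches when `letters[i] == letters[i - lag]`. Lag 1 is the Easy task
#' (repetition after a single fixation cross); lag 2 is the Hard task (one
#' random letter and two fixation crosses between the repetitions).
#' Overlapping matches count: `A A A` scores 2 at lag 1.
#'
#' @param letters Character vector of single uppercase letters, drawn from
#'   the 25-letter alphabet A-Z excluding X (X is reserved: it resembles the
#'   fixation cross).
#' @param lag 1 or 2.
#' @return Integer repetition count.
#' @examples
#' score_nback(c("A", "A", "F", "K", "R", "R", "T", "P"), lag = 1)  # 2
#' score_nback(strsplit("ARAKTRTPFP", "")[[1]], lag = 2)            # 3
#' @export
score_nback <- function(letters, lag) {
  check_lag(lag)
  check_letters(letters)
  n <- length(letters)
  if (n <= lag) return(0L)
  idx <- (lag + 1L):n
  sum(letters[idx] == letters[idx - lag])
}

NBACK_ALPHABET <- setdiff(LETTERS, "X")

check_lag <- function(lag) {
  if (!(length(lag) == 1L && lag %in% c(1L, 2L))) {
    stop("`lag` must be 1 (Easy) or 2 (Hard)", call. = FALSE)
  }
}

check_letters <- function(letters) {
  if (length(letters) == 0L) stop("`letters` must be nonempty", call. = FALSE)
  bad <- !letters %in% NBACK_ALPHABET
  if (any(bad)) {
    stop("invalid letters (alphabet is A-Z without X): ",
         paste(unique(letters[bad]), collapse = ", "), call. = FALSE)
  }
  invisible(letters)
}

#' Generate a modified n-back trial sequence
#'
#' Draws a random letter sequence over the 25-letter alphabet (A-Z without
#' X). When `target_count` is given, the sequence is constructed so that
#' [score_nback()] at `lag` returns exactly that count: match positions are
#' committed left-to-right with probability proportional to the remaining
#' quota, and non-match positions explicitly avoid the letter `lag` steps
#' back.
#'
#' The default length of 34 letters fills a 90-s trial: each letter shows for
#' 0.5 s and each of the 35 interleaved fixation crosses for 2.0 s, the trial
#' starting and ending with a cross.
#'
#' @param n_letters Sequence length (default 34).
#' @param lag 1 (Easy) or 2 (Hard).
#' @param target_count Exact repetition count to plant, or `NULL` for an
#'   unconstrained random sequence. Must be at most `n_letters - lag`.
#' @param seed RNG seed.
#' @return A list of class `nback_trial`: `letters`, `lag`, `true_count`,
#'   `reported_count` (NA until a response is attached), `letter_duration`
#'   (0.5 s), `cross_duration` (2.0 s), `n_crosses`.
#' @export
generate_nback_sequence <- function(n_letters = 34, lag, target_count = NULL,
                                    seed = 1L) {
  check_lag(lag)
  n_letters <- as.integer(n_letters)
  if (n_letters < 1L) stop("`n_letters` must be positive", call. = FALSE)
  local_rng(seed)
  if (is.null(target_count)) {
    letters_out <- sample(NBACK_ALPHABET, n_letters, replace = TRUE)
  } else {
    target_count <- as.integer(target_count)
    max_count <- n_letters - as.integer(lag)
    if (target_count < 0L || target_count > max_count) {
      stop(sprintf("`target_count` must be in [0, %d] for %d letters at lag %d",
                   max_count, n_letters, lag), call. = FALSE)
    }
    letters_out <- character(n_letters)
    head_n <- min(as.integer(lag), n_letters)
    letters_out[seq_len(head_n)] <- sample(NBACK_ALPHABET, head_n, replace = TRUE)
    remaining <- target_count
    if (n_letters > lag) {
      for (i in (lag + 1L):n_letters) {
        slots_left <- n_letters - i + 1L
        make_match <- remaining > 0 && runif(1) < remaining / slots_left
        back <- letters_out[i - lag]
        if (make_match) {
          letters_out[i] <- back
          remaining <- remaining - 1L
        } else {
          letters_out[i] <- sample(setdiff(NBACK_ALPHABET, back), 1L)
        }
      }
    }
  }
  structure(list(letters = letters_out, lag = as.integer(lag),
                 true_count = score_nback(letters_out, lag),
                 reported_count = NA_integer_,
                 letter_duration = 0.5, cross_duration = 2.0,
                 n_crosses = n_letters + 1L),
            class = "nback_trial")
}

#' @export
print.nback_trial <- function(x, ...) {
  cat(sprintf("<nback_trial> lag %d | %d letters / %d crosses | true count %d\n",
              x$lag, length(x$letters), x$n_crosses, x$true_count))
  cat(" ", paste(x$letters, collapse = " "), "\n")
  invisible(x)
}

#' Absolute error of a self-reported repetition count
#'
#' @param true_count Ground-truth repetition count (>= 0).
#' @param reported_count Self-reported count (>= 0).
#' @return `|true_count - reported_count|` as an integer.
#' @export
absolute_error <- function(true_count, reported_count) {
  if (any(true_count < 0) || any(reported_count < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  as.integer(abs(true_count - reported_count))
}

#' Simulate self-reported n-back counts
#'
#' Attaches synthetic participant responses to generated trials for
#' end-to-end runs: reported count = true count + rounded zero-mean Gaussian
#' error, truncated at 0. Real response-error distributions are not modelled
#' beyond their spread.
#'
#' @param trials A list of `nback_trial` objects.
#' @param error_sd SD of the response error, per trial (may be a vector
#'   recycled across trials; e.g. larger for the Hard condition).
#' @param seed RNG seed.
#' @return A tibble: `trial`, `lag`, `true_count`, `reported_count`,
#'   `absolute_error`.
#' @export
simulate_nback_responses <- function(trials, error_sd = 1, seed = 1L) {
  stopifnot(all(vapply(trials, inherits, logical(1), "nback_trial")))
  local_rng(seed)
  error_sd <- rep_len(error_sd, length(trials))
  true_counts <- vapply(trials, `[[`, integer(1), "true_count")
  reported <- pmax(0L, true_counts + as.integer(round(rnorm(length(trials), 0, error_sd))))
  tibble::tibble(
    trial = seq_along(trials),
    lag = vapply(trials, `[[`, integer(1), "lag"),
    true_count = true_counts,
    reported_count = reported,
    absolute_error = absolute_error(true_counts, reported)
  )
}

#' Read / write n-back sequences as plain text
#'
#' One trial per line, letters comma-separated.
#'
#' @param trials List of `nback_trial` objects (write) or lags to attach
#'   (read).
#' @param path File path.
#' @param lag Lag to attach to every read sequence.
#' @return `write_nback_sequences`: `path` invisibly; `read_nback_sequences`:
#'   a list of `nback_trial` objects.
#' @export
write_nback_sequences <- function(trials, path) {
  stopifnot(all(vapply(trials, inherits, logical(1), "nback_trial")))
  writeLines(vapply(trials, function(t) paste(t$letters, collapse = ","),
                    character(1)), path)
  invisible(path)
}

#' @rdname write_nback_sequences
#' @export
read_nback_sequences <- function(path, lag) {
  check_lag(lag)
  lines <- readLines(path)
  lapply(lines, function(l) {
    letters_in <- strsplit(l, ",", fixed = TRUE)[[1]]
    check_letters(letters_in)
    structure(list(letters = letters_in, lag = as.integer(lag),
                   true_count = score_nback(letters_in, lag),
                   reported_count = NA_integer_,
                   letter_duration = 0.5, cross_duration = 2.0,
                   n_crosses = length(letters_in) + 1L),
              class = "nback_trial")
  })
}
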