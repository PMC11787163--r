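#!/usr/bin/env Rscript
# Stage 3 — the cognitive task itself.
#
# Generates one session's worth of modified n-back sequences (10 Easy lag-1
# and 10 Hard lag-2 trials of 34 letters each), simulates self-reported
# counts with a harder-task-is-noisier response model, and scores the
# absolute error per trial. Writes the response table to results/nback/.

suppressPackageStartupMessages(library(swaydyn))

easy <- lapply(1:10, function(i) generate_nback_sequence(34, lag = 1, seed = 100 + i))
hard <- lapply(1:10, function(i) generate_nback_sequence(34, lag = 2, seed = 200 + i))
trials <- c(easy, hard)

responses <- simulate_nback_responses(trials,
                                      error_sd = rep(c(0.8, 1.6), each = 10),
                                      seed = 20260926)
out_dir <- file.path("results", "nback")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
write_nback_sequences(trials, file.path(out_dir, "sequences.txt"))
readr::write_csv(responses, file.path(out_dir, "responses.csv"))

cat("Example Easy trial:\n")
print(trials[[1]])
agg <- aggregate(absolute_error ~ lag, responses, mean)
cat(sprintf("\nMean absolute error: lag 1 = %.2f, lag 2 = %.2f\n",
            agg$absolute_error[agg$lag == 1], agg$absolute_error[agg$lag == 2]))
cat("Wrote sequences and responses under", out_dir, "\n")
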