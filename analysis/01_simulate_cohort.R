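#!/usr/bin/env Rscript
# Stage 1 — synthetic study materials.
#
# Builds the default synthetic cohort configuration (28 subjects, 30 trials
# of 90 s at 200 Hz each, condition effects at the study's reported values),
# prints the implied condition-cell targets, and writes a small on-disk demo
# of the exchange formats: a 2-subject cohort of 30-s trials (delimited CoP
# files + design table + YAML config) and one second of the white-noise
# stimulus as WAV. Full-scale cohorts are generated in memory by stage 02;
# trial files at full scale are large, so only the demo goes to disk.

suppressPackageStartupMessages(library(swaydyn))

cfg <- sway_model_config(seed = 20260926)
cat("Default cohort configuration: 28 subjects x 30 trials, 90 s @ 200 Hz\n")
cat("Implied condition-cell targets (trial-mean RS and DFA alpha):\n")
print(as.data.frame(cell_targets(cfg)), digits = 4)

demo_cfg <- sway_model_config(n_subjects = 2, trial_duration = 30,
                              seed = 20260926)
demo_dir <- file.path("scratch", "cohort_demo")
write_cohort(generate_cohort(demo_cfg), demo_dir)
cat("\nWrote demo cohort (2 subjects, 30-s trials) to", demo_dir, "\n")

wav_path <- file.path("scratch", "white_noise_1s.wav")
write_wav(generate_white_noise_audio(1, 44100, seed = 20260926), wav_path)
cat("Wrote 1 s of the auditory white-noise stimulus to", wav_path, "\n")
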