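#!/usr/bin/env Rscript
# Generate the synthetic study: one participant, both motor tasks at two
# starting arm locations, 12 directions x 5 repetitions each, from a single
# ground-truth synergy model (K = 5) at snr = 10. Datasets are written in
# the package's CSV + manifest layout together with a ground-truth sidecar
# so later stages can be checked against the generative model.

suppressPackageStartupMessages(library(emgsynergy))

seed <- 20260923L
out_root <- "results/data"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

gt <- make_ground_truth(n_muscles = 13, n_synergies = 5, seed = seed)
message("ground truth: K = 5, preferred directions ",
        paste(round(gt$preferred_dir_deg), collapse = ", "), " deg")

conditions <- expand.grid(task = c("isometric", "reaching"),
                          location = c("Distal", "Left"),
                          stringsAsFactors = FALSE)
for (i in seq_len(nrow(conditions))) {
  cnd <- conditions[i, ]
  ds <- synthesize_dataset(gt, cnd$task, cnd$location, n_reps = 5,
                           seed = seed + i)
  dir_i <- file.path(out_root, paste(cnd$task, cnd$location, sep = "_"))
  write_dataset(ds, dir_i)
  message(sprintf("wrote %-28s (%d trials)", dir_i, length(ds$trials)))
}

# ground-truth sidecar for oracle checks downstream
sidecar <- list(W_true = gt$W_true, preferred_dir_deg = gt$preferred_dir_deg,
                amplitude = gt$amplitude, tuning_offset = gt$tuning_offset,
                snr = gt$snr, seed = gt$seed)
jsonlite::write_json(sidecar, file.path(out_root, "ground_truth.json"),
                     auto_unbox = TRUE, digits = NA)
message("wrote ", file.path(out_root, "ground_truth.json"))
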