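#!/usr/bin/env Rscript
# Preprocess every simulated condition: ECG suppression, envelope
# extraction, event detection (3 x SD force rule / 10% peak-speed rule),
# 150-sample time normalization, concatenation and per-muscle variance
# normalization. Writes each condition's pooled matrix and event table.

suppressPackageStartupMessages(library(emgsynergy))

cfg <- pipeline_config()
in_root <- "results/data"
out_root <- "results/preprocessed"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

conds <- list.dirs(in_root, recursive = FALSE)
conds <- conds[basename(conds) != "ground_truth"]
for (d in conds) {
  ds <- read_dataset(d)
  t0 <- Sys.time()
  pooled <- preprocess_dataset(ds, cfg)
  id <- basename(d)
  utils::write.csv(data.frame(muscle = rownames(pooled$matrix),
                              pooled$matrix, check.names = FALSE),
                   file.path(out_root, paste0(id, "_pooled.csv")),
                   row.names = FALSE)
  ev <- do.call(rbind, lapply(seq_along(pooled$events), function(i) {
    e <- pooled$events[[i]]
    data.frame(trial = i, rule = e$rule, onset_sample = e$onset_sample,
               offset_sample = e$offset_sample)
  }))
  utils::write.csv(ev, file.path(out_root, paste0(id, "_events.csv")),
                   row.names = FALSE)
  utils::write.csv(data.frame(column = seq_along(pooled$direction_deg),
                              trial = pooled$trial_index,
                              direction_deg = pooled$direction_deg),
                   file.path(out_root, paste0(id, "_labels.csv")),
                   row.names = FALSE)
  message(sprintf("%-28s pooled %d x %d in %.1f s", id, nrow(pooled$matrix),
                  ncol(pooled$matrix),
                  as.numeric(Sys.time() - t0, units = "secs")))
}
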