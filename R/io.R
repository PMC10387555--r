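#' Write a dataset to a directory of CSV trial files plus a JSON manifest
#'
#' Each trial becomes two comma-delimited files with a header row and one row
#' per sample: `<id>_emg.csv` (`time` in seconds plus one column per muscle)
#' and `<id>_aux.csv` (`time` plus `Fx,Fy,Fz` or `speed`), stored at their
#' own sampling rates. `manifest.json` lists every trial with its metadata,
#' rates, baseline window and (if set) events.
#'
#' @param dataset An [emg_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "emg_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- vector("list", length(dataset$trials))
  for (i in seq_along(dataset$trials)) {
    tr <- dataset$trials[[i]]
    id <- sprintf("trial%03d", i)
    emg_df <- data.frame(time = (seq_len(ncol(tr$emg)) - 1) / tr$fs_emg,
                         t(tr$emg), check.names = FALSE)
    utils::write.csv(emg_df, file.path(dir, paste0(id, "_emg.csv")),
                     row.names = FALSE)
    aux <- tr$aux
    if (is.matrix(aux)) {
      aux_df <- data.frame(time = (seq_len(nrow(aux)) - 1) / tr$fs_aux, aux,
                           check.names = FALSE)
    } else {
      aux_df <- data.frame(time = (seq_along(aux) - 1) / tr$fs_aux,
                           speed = as.numeric(aux))
    }
    utils::write.csv(aux_df, file.path(dir, paste0(id, "_aux.csv")),
                     row.names = FALSE)
    entries[[i]] <- list(
      id = id,
      emg_file = paste0(id, "_emg.csv"),
      aux_file = paste0(id, "_aux.csv"),
      fs_emg = tr$fs_emg, fs_aux = tr$fs_aux,
      baseline_window = tr$baseline_window,
      events = tr$events,
      meta = unclass(tr$meta)
    )
  }
  manifest <- list(muscles = as.character(unclass(dataset$muscles)),
                   trials = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a dataset from a manifest directory
#'
#' Inverse of [write_dataset()]. Trials are returned in manifest order;
#' sampling rates and metadata come from the manifest, signal samples from
#' the CSV files. A trial file missing a manifest muscle column is a format
#' error naming the column.
#'
#' @param dir Directory containing `manifest.json` and the trial CSVs.
#' @return An [emg_dataset()].
#' @export
read_dataset <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop_emg("no manifest.json in %s", dir, class = "emg_format")
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  muscles <- muscle_set(manifest$muscles)
  if (length(manifest$trials) == 0L) {
    stop_emg("manifest lists no trials", class = "emg_format")
  }
  trials <- vector("list", length(manifest$trials))
  for (i in seq_along(manifest$trials)) {
    en <- manifest$trials[[i]]
    emg_df <- utils::read.csv(file.path(dir, en$emg_file), check.names = FALSE)
    missing <- setdiff(unclass(muscles), names(emg_df))
    if (length(missing)) {
      stop_emg("trial %s is missing muscle column(s): %s", en$id,
               paste(missing, collapse = ", "), class = "emg_format")
    }
    extra <- setdiff(names(emg_df), c("time", unclass(muscles)))
    if (length(extra)) {
      stop_emg("trial %s has muscle columns not in the manifest muscle set: %s",
               en$id, paste(extra, collapse = ", "), class = "emg_inconsistent")
    }
    if (anyNA(emg_df)) stop_emg("trial %s contains malformed rows", en$id,
                                class = "emg_format")
    emg <- t(as.matrix(emg_df[, unclass(muscles), drop = FALSE]))
    aux_df <- utils::read.csv(file.path(dir, en$aux_file), check.names = FALSE)
    if ("speed" %in% names(aux_df)) {
      aux <- as.numeric(aux_df$speed)
    } else {
      aux <- as.matrix(aux_df[, c("Fx", "Fy", "Fz"), drop = FALSE])
    }
    meta <- trial_meta(task = en$meta$task, location = en$meta$location,
                       direction_deg = en$meta$direction_deg,
                       rep = en$meta$rep, participant = en$meta$participant,
                       excluded = isTRUE(en$meta$excluded))
    events <- en$events
    if (!is.null(events)) {
      events <- list(onset_sample = as.integer(events$onset_sample),
                     offset_sample = as.integer(events$offset_sample))
    }
    trials[[i]] <- emg_trial(emg = emg, fs_emg = en$fs_emg, aux = aux,
                             fs_aux = en$fs_aux,
                             baseline_window = unlist(en$baseline_window),
                             events = events, meta = meta, muscles = muscles)
  }
  emg_dataset(trials, muscles)
}

# ---- structured result records -------------------------------------------

serialize_value <- function(x) {
  if (is.data.frame(x)) {
    list(`_df` = TRUE, columns = lapply(as.list(x), serialize_value))
  } else if (is.matrix(x)) {
    list(`_matrix` = TRUE, data = as.numeric(x), nrow = nrow(x),
         ncol = ncol(x), rownames = rownames(x), colnames = colnames(x))
  } else if (is.list(x) && !is.null(x)) {
    lapply(x, serialize_value)
  } else if (is.function(x)) {
    stop_emg("cannot serialize a function field", class = "emg_serialize")
  } else if (is.atomic(x)) {
    unclass(x) # plain vectors; S3 wrappers like muscle_set serialize as data
  } else {
    x
  }
}

deserialize_value <- function(x) {
  if (is.list(x) && isTRUE(x$`_df`)) {
    as.data.frame(lapply(x$columns, deserialize_value))
  } else if (is.list(x) && isTRUE(x$`_matrix`)) {
    m <- matrix(as.numeric(unlist(x$data)), nrow = x$nrow, ncol = x$ncol)
    if (!is.null(x$rownames)) rownames(m) <- unlist(x$rownames)
    if (!is.null(x$colnames)) colnames(m) <- unlist(x$colnames)
    m
  } else if (is.list(x)) {
    lapply(x, deserialize_value)
  } else {
    x
  }
}

#' Serialize an analysis result to a JSON record
#'
#' Writes any of the pipeline's result objects (synergy sets, VAF tables,
#' match results, tuning curves, ...) as a structured JSON record that
#' carries the object class, every field, a configuration hash and the seed
#' used (when the object records one). [read_results()] restores an equal
#' object.
#'
#' @param obj A list-based result object.
#' @param path Output file path.
#' @param config Optional `pipeline_config` whose hash is stamped into the
#'   record.
#' @return `path`, invisibly.
#' @export
write_results <- function(obj, path, config = NULL) {
  if (!is.list(obj)) stop_emg("write_results expects a list-based result object",
                              class = "emg_serialize")
  payload <- serialize_value(unclass(obj))
  rec <- list(
    class = class(obj),
    config_hash = if (is.null(config)) NULL else
      config_hash(jsonlite::toJSON(unclass(config), auto_unbox = TRUE)),
    seed = obj$seed %||% obj$null_params$seed,
    fields = payload
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a result record written by [write_results()]
#'
#' @param path Path to a JSON record.
#' @return The restored result object, with its original class.
#' @export
read_results <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE,
                             simplifyDataFrame = FALSE)
  obj <- deserialize_value(rec$fields)
  # scalars read back as length-1 vectors already match; restore integerish
  class(obj) <- unlist(rec$class)
  obj
}
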