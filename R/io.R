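# Delimited-text I/O: one TSV dialect throughout (tab separated, UTF-8,
# '.' decimal, 'NA' for missing), JSON for nested results.

.record_mandatory <- c("run", "block", "trial", "category", "state",
                       "cue_id", "rewarded_action", "reward_available",
                       "chosen_action", "missed", "reward")

#' Write a behavioral record to TSV
#' @param record a `grl_record` or compatible data.frame.
#' @param path output file.
#' @export
write_record <- function(record, path) {
  utils::write.table(as.data.frame(record), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a behavioral record from TSV
#'
#' Validates the mandatory column dictionary and basic consistency
#' (constant trial count, missed trials carrying no chosen action).
#'
#' @param path TSV written by [write_record()] (or following its column
#'   dictionary).
#' @return `grl_record` data.frame.
#' @export
read_record <- function(path) {
  rec <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, na.strings = "NA",
                           fileEncoding = "UTF-8")
  missing_cols <- setdiff(.record_mandatory, names(rec))
  if (length(missing_cols))
    stop("parse error: record file ", path, " is missing mandatory column(s) ",
         paste(missing_cols, collapse = ", "))
  if (any(duplicated(rec$trial)))
    stop("parse error: duplicated trial index in ", path)
  rec$missed <- as.logical(rec$missed)
  rec$reward_available <- as.logical(rec$reward_available)
  class(rec) <- c("grl_record", class(rec))
  rec
}

#' Serialize a session to plain text
#'
#' Writes the trial table as TSV and the block table plus configuration as
#' a JSON sidecar (`<path>.blocks.json`).
#'
#' @param session a `grl_session`; @param path trial-table TSV path.
#' @export
write_session <- function(session, path) {
  utils::write.table(session$trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  side <- paste0(path, ".blocks.json")
  jsonlite::write_json(list(config = unclass(session$config),
                            blocks = session$blocks),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a session written by [write_session()]
#' @param path trial-table TSV path (expects the `.blocks.json` sidecar).
#' @export
read_session <- function(path) {
  trials <- utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE, na.strings = "NA",
                              fileEncoding = "UTF-8")
  side <- jsonlite::read_json(paste0(path, ".blocks.json"),
                              simplifyVector = TRUE)
  cfg <- side$config
  config <- task_config(cfg$n_runs, cfg$blocks_per_run, cfg$trials_per_block,
                        cfg$variant, cfg$seed)
  trials$reward_available <- as.logical(trials$reward_available)
  structure(list(config = config, blocks = side$blocks, trials = trials),
            class = "grl_session")
}

#' Export a trial-level regressor table from a record with latent traces
#'
#' One row per within-trial event (cue, ISI, outcome; error feedback for
#' missed trials) with onsets and durations, carrying the model-derived
#' parametric modulators: preparatory-state value, chosen action value,
#' cue-locked state-value-prediction error, and outcome-locked
#' action-value-prediction error (absent on missed trials), plus RT. Value
#' regressors persist through the ISI, encoded by that event's duration.
#'
#' @param record a record with trace columns (see [replay_record()]).
#' @return data.frame event table.
#' @export
export_regressor_table <- function(record) {
  need <- c("v0", "q_left", "q_right", "delta_v", "delta_q")
  if (!all(need %in% names(record)))
    stop("traces absent: replay the record with replay_record() first")
  rows <- lapply(seq_len(nrow(record)), function(t) {
    on <- record$onset[t]
    q_chosen <- if (record$missed[t]) NA_real_ else
      if (record$chosen_action[t] == 1L) record$q_left[t] else record$q_right[t]
    if (record$missed[t]) {
      data.frame(trial = record$trial[t],
                 event = c("cue", "error_feedback"),
                 onset = c(on, on + 2), duration = c(2, 1),
                 v0 = c(record$v0[t], NA), q_chosen = NA_real_,
                 delta_v = c(record$delta_v[t], NA), delta_q = NA_real_,
                 rt = NA_real_)
    } else {
      data.frame(trial = record$trial[t],
                 event = c("cue", "isi", "outcome"),
                 onset = c(on, on + 2, on + 2 + record$isi[t]),
                 duration = c(2, record$isi[t], 1),
                 v0 = record$v0[t], q_chosen = q_chosen,
                 delta_v = record$delta_v[t],
                 delta_q = c(NA, NA, record$delta_q[t]),
                 rt = record$rt[t])
    }
  })
  do.call(rbind, rows)
}

#' Run manifest for byte-identical reruns
#'
#' Captures the configuration, seeds and output paths of a pipeline stage;
#' rerunning with the same manifest reproduces outputs because every
#' stochastic stage draws only from the named seeds.
#'
#' @param config a [task_config()] (or any serializable list).
#' @param seeds named list/vector of stage seeds.
#' @param outputs named list of output paths.
#' @param path JSON path to write.
#' @export
write_manifest <- function(config, seeds, outputs, path) {
  jsonlite::write_json(
    list(config = unclass(config), seeds = as.list(seeds),
         outputs = as.list(outputs),
         versions = list(package = as.character(utils::packageVersion("grlearn")),
                         r = R.version.string),
         checksums = lapply(outputs, function(f)
           if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
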