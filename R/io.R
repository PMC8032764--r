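## Plain-text readers/writers for the pipeline's interchange formats.

#' Write / read a concentration-response table
#'
#' CSV columns: `conc_nM`, `response`, `replicate`. If a ground-truth
#' attribute is present it is written to a JSON sidecar `<path>.truth.json`.
#'
#' @param x data.frame from [gen_conc_response()] (or same shape).
#' @param path CSV path.
#' @export
write_conc_response <- function(x, path) {
  utils::write.csv(x[, c("conc_nM", "response", "replicate")], path,
                   row.names = FALSE)
  write_truth_sidecar(attr(x, "truth"), path)
  invisible(path)
}

#' @rdname write_conc_response
#' @export
read_conc_response <- function(path) {
  x <- utils::read.csv(path)
  stopifnot(all(c("conc_nM", "response") %in% names(x)))
  x
}

#' Write / read an autoradiography cohort table
#'
#' CSV columns: `animal_id`, `treatment`, `dose_mg_kg`, `region`,
#' `signal_fmol_mg`, `plasma_ng_ml`.
#'
#' @param x cohort data.frame.
#' @param path CSV path.
#' @export
write_cohort <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  write_truth_sidecar(attr(x, "truth"), path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path)
  stopifnot(all(c("animal_id", "treatment", "region",
                  "signal_fmol_mg") %in% names(x)))
  x
}

#' Write / read framed time-activity curves
#'
#' Long CSV with columns `frame_start_s`, `frame_dur_s`, `region`,
#' `activity_kBq_ml`; scan metadata goes to a JSON sidecar.
#'
#' @param study a [gen_pet_study()] result.
#' @param path CSV path.
#' @export
write_tac <- function(study, path) {
  rows <- list()
  for (scan in names(study$scans)) {
    sc <- study$scans[[scan]]
    curves <- c(list(reference = sc$reference), sc$targets)
    for (rg in names(curves)) {
      rows[[length(rows) + 1L]] <- data.frame(
        scan = scan,
        frame_start_s = study$frames$start_s,
        frame_dur_s = study$frames$dur_s,
        region = rg,
        activity_kBq_ml = curves[[rg]])
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  jsonlite::write_json(study$meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tac
#' @export
read_tac <- function(path) {
  x <- utils::read.csv(path)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else NULL
  list(tacs = x, meta = meta)
}

#' Write / read a multichannel EEG recording as CSV
#'
#' Wide format: a `time_s` column followed by one column per channel
#' (volts); the sampling rate and labels go to a JSON sidecar.
#'
#' @param rec an [eeg_recording()].
#' @param path CSV path.
#' @export
write_eeg_csv <- function(rec, path) {
  d <- data.frame(time_s = (seq_len(ncol(rec$data)) - 1) / rec$fs_hz,
                  t(rec$data))
  names(d) <- c("time_s", rec$channels)
  utils::write.csv(d, path, row.names = FALSE)
  jsonlite::write_json(list(fs_hz = rec$fs_hz, channels = rec$channels,
                            subject = rec$subject,
                            condition = rec$condition),
                       paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_eeg_csv
#' @export
read_eeg_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  dat <- t(as.matrix(d[, meta$channels, drop = FALSE]))
  rownames(dat) <- meta$channels
  eeg_recording(dat, meta$fs_hz, meta$channels,
                subject = meta$subject, condition = meta$condition)
}

write_truth_sidecar <- function(truth, path) {
  if (is.null(truth)) return(invisible(NULL))
  truth <- unclass(truth)
  truth$frames <- NULL
  jsonlite::write_json(truth, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(NULL)
}
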