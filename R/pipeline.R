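## End-to-end orchestration: synthesize -> fit -> report, with per-stage
## sub-seeds, a run manifest, and YAML configuration. Stages communicate
## through plain-text artifacts in the run directory, so any stage can be
## re-run from saved intermediates.

pipeline_stages <- c("synth", "doseresponse", "occupancy", "pet", "eeg")

known_config_keys <- c("stages", "out_dir", "seed",
                       "mw_g_mol", "free_fraction_rat", "free_fraction_human",
                       "hill", "occupancy", "pet", "eeg")

#' Default pipeline configuration
#'
#' Conversion constants default to the study compound (molecular weight
#' 445.469 g/mol; free fraction 14% in rat, 5.5% in human); stage options
#' control the synthetic problem sizes. The default EEG block is kept small
#' (6 subjects, 4 channels, 64 s) so a demo run completes in minutes.
#'
#' @param out_dir output directory.
#' @param seed global seed; every stochastic stage derives its own recorded
#'   sub-seed from it.
#' @return named list of class `run_config`.
#' @export
default_config <- function(out_dir = tempfile("pkpd_run_"), seed = 1) {
  structure(list(
    stages = pipeline_stages,
    out_dir = out_dir,
    seed = seed,
    mw_g_mol = 445.469,
    free_fraction_rat = 0.14,
    free_fraction_human = 0.055,
    hill = list(truth = list(A = 0, B = -42, C = 8, D = 0.9),
                n_conc = 8, replicates = 8, noise_sd = 1),
    occupancy = list(n_per_group = 4, noise_sd = 18, ec50_ng_ml = 544),
    pet = list(occupancy = 0.94, noise_sd = 0.2),
    eeg = list(n_subjects = 6, channels = 4, duration_s = 64,
               effects = list(list(center_hz = 7.3, width_oct = 0.5,
                                   change = 0.19),
                              list(center_hz = 34.9, width_oct = 0.5,
                                   change = -0.19)),
               n_perm = 1000)
  ), class = "run_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config a configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Validate a configuration against the known keys, filling defaults
#' @param config a (partial) configuration list.
#' @return the completed configuration.
#' @export
validate_config <- function(config) {
  base <- default_config()
  unknown <- setdiff(names(config), known_config_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(config)) {
    if (is.list(base[[nm]]) && is.list(config[[nm]]) && nm != "stages") {
      base[[nm]][names(config[[nm]])] <- config[[nm]]
    } else {
      base[[nm]] <- config[[nm]]
    }
  }
  bad <- setdiff(base$stages, pipeline_stages)
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  class(base) <- "run_config"
  base
}

require_artifact <- function(path, producer) {
  if (!file.exists(path)) {
    stop("missing upstream artifact '", basename(path),
         "': run stage '", producer, "' first", call. = FALSE)
  }
  path
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the selected stages in dependency order. `synth` writes the four
#' synthetic input classes under `out_dir`; each fitting stage reads its
#' artifact back from disk, so stages can be re-run individually. A manifest
#' (per-stage sub-seeds, output files with MD5 checksums, headline
#' estimates) is written to `manifest.json`; any stage error aborts the run.
#'
#' @param config a config list (see [default_config()]), or a path to a
#'   YAML file.
#' @param quiet suppress per-stage log lines.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config = default_config(), quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(unclass(config))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list(), results = list())
  outputs <- character(0)
  log_stage <- function(stage, msg) {
    if (!quiet) message(sprintf("[%s] %s", stage, msg))
  }

  for (stage in intersect(pipeline_stages, config$stages)) {
    sub_seed <- derive_seed(config$seed, stage)
    log_stage(stage, sprintf("start (sub-seed %d)", sub_seed))
    res <- run_stage(stage, config, sub_seed)
    outputs <- c(outputs, res$files)
    manifest$stages[[stage]] <- list(sub_seed = sub_seed,
                                     files = basename(res$files))
    if (length(res$results)) manifest$results[[stage]] <- res$results
    log_stage(stage, "done")
  }

  manifest$outputs <- lapply(unique(outputs), function(f) {
    list(file = basename(f), md5 = unname(tools::md5sum(f)))
  })
  manifest$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

run_stage <- function(stage, config, sub_seed) {
  out <- config$out_dir
  switch(
    stage,
    synth = {
      files <- character(0)
      # concentration-response table
      h <- config$hill
      concs <- 10^seq(0, 3, length.out = h$n_conc)
      tab <- gen_conc_response(h$truth, concs, h$replicates, h$noise_sd,
                               seed = derive_seed(sub_seed, "conc"))
      files <- c(files, write_conc_response(
        tab, file.path(out, "conc_response.csv")))
      # autoradiography cohort
      oc <- config$occupancy
      cohort <- gen_occupancy_cohort(occupancy_cohort_truth(
        n_per_group = oc$n_per_group, noise_sd = oc$noise_sd,
        ec50_ng_ml = oc$ec50_ng_ml, seed = derive_seed(sub_seed, "cohort")))
      files <- c(files, write_cohort(cohort, file.path(out, "cohort.csv")))
      # PET study
      pc <- config$pet
      study <- gen_pet_study(pet_study_truth(
        occupancy = pc$occupancy, noise_sd = pc$noise_sd,
        seed = derive_seed(sub_seed, "pet")))
      files <- c(files, write_tac(study, file.path(out, "tacs.csv")))
      # EEG study
      ec <- config$eeg
      effects <- lapply(ec$effects, function(e) {
        eeg_effect(e$center_hz, e$width_oct, e$change)
      })
      truth <- eeg_study_truth(
        n_subjects = ec$n_subjects,
        channels = montage_1020()[seq_len(ec$channels)],
        duration_s = ec$duration_s, effects = effects,
        seed = derive_seed(sub_seed, "eeg"))
      eeg <- gen_eeg_study(truth)
      eeg_dir <- file.path(out, "eeg")
      dir.create(eeg_dir, showWarnings = FALSE)
      for (sub in eeg$subjects) {
        for (i in seq_along(sub$recordings)) {
          r <- sub$recordings[[i]]
          files <- c(files, write_eeg_csv(r, file.path(
            eeg_dir, sprintf("%s_%s_%02d.csv", sub$id, r$condition, i))))
        }
      }
      list(files = files, results = list())
    },
    doseresponse = {
      f <- require_artifact(file.path(out, "conc_response.csv"), "synth")
      tab <- read_conc_response(f)
      fit <- fit_hill(tab$conc_nM, tab$response, fixed = list(A = 0))
      rep_file <- file.path(out, "doseresponse_fit.json")
      jsonlite::write_json(
        list(estimates = as.list(fit$estimates), se = as.list(fit$se),
             residual_sd = fit$sigma, converged = fit$converged),
        rep_file, auto_unbox = TRUE, digits = NA, force = TRUE)
      list(files = rep_file,
           results = list(ic50_nM = unname(fit$estimates[["C"]]),
                          hill_slope = unname(fit$estimates[["D"]])))
    },
    occupancy = {
      f <- require_artifact(file.path(out, "cohort.csv"), "synth")
      cohort <- read_cohort(f)
      sb <- specific_binding(cohort, "hippocampus")
      drug <- sb$S[sb$S$treatment == "drug", ]
      occ <- percent_occupancy(drug$S, sb$vehicle_mean)
      fit <- fit_occupancy_vs_plasma(drug$plasma_ng_ml, occ)
      rep_file <- file.path(out, "occupancy_fit.json")
      jsonlite::write_json(
        list(ec50_ng_ml = fit$EC50,
             ec50_free_nM = total_to_free_nM(fit$EC50, config$mw_g_mol,
                                             config$free_fraction_rat),
             max_occupancy_pct = unname(fit$estimates[["B"]]),
             converged = fit$converged),
        rep_file, auto_unbox = TRUE, digits = NA, force = TRUE)
      list(files = rep_file,
           results = jsonlite::read_json(rep_file))
    },
    pet = {
      f <- require_artifact(file.path(out, "tacs.csv"), "synth")
      tac <- read_tac(f)
      x <- tac$tacs
      regions <- setdiff(unique(x$region), "reference")
      fits <- list()
      for (rg in regions) {
        bp <- vapply(c("baseline", "postdose"), function(scan) {
          sel <- x$scan == scan
          frames <- unique(x[sel, c("frame_start_s", "frame_dur_s")])
          names(frames) <- c("start_s", "dur_s")
          ref <- x$activity_kBq_ml[sel & x$region == "reference"]
          tgt <- x$activity_kBq_ml[sel & x$region == rg]
          srtm_fit_basis(tgt, frames, ref)$BP_ND
        }, 0)
        fits[[rg]] <- list(bp_baseline = bp[["baseline"]],
                           bp_postdose = bp[["postdose"]],
                           occupancy = occupancy_from_bp(bp[["baseline"]],
                                                         bp[["postdose"]]))
      }
      rep_file <- file.path(out, "pet_fit.json")
      jsonlite::write_json(fits, rep_file, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
      list(files = rep_file,
           results = list(occupancy_by_region = lapply(fits, `[[`,
                                                       "occupancy")))
    },
    eeg = {
      eeg_dir <- file.path(out, "eeg")
      require_artifact(eeg_dir, "synth")
      files <- list.files(eeg_dir, pattern = "\\.csv$", full.names = TRUE)
      recs <- lapply(files, read_eeg_csv)
      ids <- sort(unique(vapply(recs, `[[`, "", "subject")))
      subjects <- lapply(ids, function(id) {
        list(id = id,
             recordings = Filter(function(r) r$subject == id, recs))
      })
      study <- structure(list(subjects = subjects,
                              fs_hz = recs[[1L]]$fs_hz,
                              channels = recs[[1L]]$channels),
                         class = "eeg_study")
      ch <- eeg_change_spectra(study)
      f <- file.path(out, "eeg_change.csv")
      utils::write.csv(
        data.frame(subject = rep(ids, each = length(ch$freqs_hz)),
                   freq_hz = rep(ch$freqs_hz, length(ids)),
                   change_pct = as.vector(t(ch$change))),
        f, row.names = FALSE)
      base <- matrix(0, nrow(ch$change), ncol(ch$change))
      ct <- cluster_randomization_test(ch$change, base, ch$freqs_hz,
                                       n_perm = config$eeg$n_perm,
                                       seed = derive_seed(sub_seed, "perm"))
      sig <- ct$clusters[ct$clusters$p < 0.05, , drop = FALSE]
      rep_file <- file.path(out, "eeg_clusters.json")
      jsonlite::write_json(
        list(clusters = sig[, c("start_hz", "end_hz", "size", "sign", "p")]),
        rep_file, auto_unbox = TRUE, digits = NA, force = TRUE)
      list(files = c(f, rep_file),
           results = list(n_significant_clusters = nrow(sig)))
    },
    stop("unknown stage: ", stage, call. = FALSE)
  )
}
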