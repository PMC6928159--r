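#' Read a diffusion-weighted dataset
#'
#' Loads a 4-D NIfTI volume together with its FSL-style gradient table and
#' validates that the acquisition counts agree.
#'
#' @param dwi_path path to a 4-D NIfTI file.
#' @param bval_path,bvec_path FSL gradient table paths.
#' @param b0_threshold b-values below this (s/mm^2) count as b = 0.
#' @return list with `image` (4-D array) and `scheme`
#'   (a [gradient_scheme()]).
#' @export
read_dwi <- function(dwi_path, bval_path, bvec_path, b0_threshold = 50) {
  img <- tryCatch(RNifti::readNifti(dwi_path),
                  error = function(e) abort(sprintf("cannot read NIfTI file '%s': %s",
                                                    dwi_path, conditionMessage(e))))
  arr <- as.array(img)
  if (length(dim(arr)) != 4) {
    abort(sprintf("'%s' is not 4-D (dims: %s)", dwi_path,
                  paste(dim(arr), collapse = "x")))
  }
  scheme <- read_bval_bvec(bval_path, bvec_path, b0_threshold = b0_threshold)
  if (dim(arr)[4] != n_acquisitions(scheme)) {
    abort(sprintf("volume count mismatch: %d image volumes vs %d gradient-table entries",
                  dim(arr)[4], n_acquisitions(scheme)))
  }
  list(image = arr, scheme = scheme)
}

#' Write fitted scalar maps as NIfTI files
#'
#' @param maps a `dki_maps` object from [fit_volume()].
#' @param dir output directory (created if needed).
#' @return paths of the written files, invisibly.
#' @export
write_scalar_maps <- function(maps, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(maps$maps)) {
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(maps$maps[[nm]]), p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "fit_flags.nii.gz")
  flags <- maps$flags
  flags[is.na(flags)] <- -1L
  RNifti::writeNifti(RNifti::asNifti(flags), p)
  invisible(c(paths, p))
}

.PIPELINE_KEYS <- c("seed", "cost", "n_boot", "filter_training",
                    "call_threshold", "training_week", "behavior_week",
                    "separation_margin", "recovered_fraction", "snr")

#' Pipeline configuration
#'
#' Options steering [run_pipeline()]. Defaults mirror the study design:
#' training on distal week-4 records, SVM cost 100, 1000 bootstrap
#' resamples, outlier filtering on for both training and correlation,
#' behavioral correlation at week 12.
#'
#' `read_pipeline_config()` loads a YAML file with these keys (unknown
#' keys are rejected); `write_pipeline_config()` serializes losslessly.
#'
#' @param seed master seed for simulation and bootstrap.
#' @param cost SVM cost parameter C.
#' @param n_boot bootstrap resamples.
#' @param filter_training apply outlier rules before training.
#' @param call_threshold nerve-level mean-probability cutoff.
#' @param training_week week of the training records.
#' @param behavior_week week of the probability-behavior correlation.
#' @param separation_margin,recovered_fraction,snr forwarded to
#'   [study_config()].
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, cost = 100, n_boot = 1000,
                            filter_training = TRUE, call_threshold = 0.5,
                            training_week = 4, behavior_week = 12,
                            separation_margin = 0.10,
                            recovered_fraction = 0.5, snr = 30) {
  structure(list(seed = seed, cost = cost, n_boot = n_boot,
                 filter_training = filter_training,
                 call_threshold = call_threshold,
                 training_week = training_week,
                 behavior_week = behavior_week,
                 separation_margin = separation_margin,
                 recovered_fraction = recovered_fraction, snr = snr),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), .PIPELINE_KEYS)
  if (length(unknown) > 0) {
    abort(sprintf("unknown configuration keys: %s", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the study end to end on synthetic data: simulate the cohort
#' tables, apply the outlier filter, train the recovery model on distal
#' week-4 records, classify every slice record, convert the boundary to an
#' FA threshold, and run the cohort statistics. All tabular artifacts are
#' written under `out_dir` (CSV/JSON only, bit-reproducible for a fixed
#' config) together with a run manifest. A stage failure halts the run with
#' a stage-named error; artifacts already written are moved under
#' `failed/`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir artifact directory.
#' @return (invisibly) list with the study, model, classification and
#'   statistics objects.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages_done <- character(0)
  stage <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e) {
      failed <- file.path(out_dir, "failed")
      dir.create(failed, showWarnings = FALSE)
      writeLines(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 file.path(failed, "FAILED.txt"))
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
    stages_done <<- c(stages_done, name)
    res
  }

  study <- stage("simulate", {
    st <- simulate_study(study_config(
      separation_margin = config$separation_margin,
      recovered_fraction = config$recovered_fraction,
      snr = config$snr, seed = config$seed))
    write_study(st, out_dir)
    st
  })
  filtered <- stage("filter", {
    fl <- filter_outliers(study$slices)
    write.csv(fl$excluded, file.path(out_dir, "excluded_records.csv"),
              row.names = FALSE)
    fl
  })
  model <- stage("train", {
    m <- train_recovery_model(study$slices, cost = config$cost,
                              n_boot = config$n_boot, seed = config$seed,
                              filter_training = config$filter_training,
                              training_week = config$training_week)
    jsonlite::write_json(
      list(slope = m$boundary$slope, intercept = m$boundary$intercept,
           slope_sd = m$boundary$slope_sd, intercept_sd = m$boundary$intercept_sd,
           w = as.list(m$boundary$w), offset = m$boundary$offset,
           cost = m$boundary$cost, seed = config$seed,
           fa_threshold = m$fa$threshold, fa_threshold_sd = m$fa$sd),
      file.path(out_dir, "boundary.json"), auto_unbox = TRUE, digits = NA)
    m
  })
  classified <- stage("classify", {
    cl <- classify_study(filtered$kept, model$boundary, model$platt,
                         call_threshold = config$call_threshold)
    write.csv(cl$assessments, file.path(out_dir, "assessments.csv"),
              row.names = FALSE)
    write.csv(cl$nerves, file.path(out_dir, "nerves.csv"), row.names = FALSE)
    cl
  })
  fa <- stage("fa_threshold", model$fa)
  stats_out <- stage("stats", {
    tests <- pairwise_ttests(filtered$kept)
    corr_beh <- correlate_probability_behavior(classified$nerves, study$behavior,
                                               week = config$behavior_week)
    corr_hist <- correlate_scalars_histology(study$slices, study$histology)
    write.csv(tests, file.path(out_dir, "tests.csv"), row.names = FALSE)
    write.csv(dplyr::bind_rows(corr_beh, corr_hist),
              file.path(out_dir, "correlations.csv"), row.names = FALSE)
    list(tests = tests, behavior = corr_beh, histology = corr_hist)
  })

  jsonlite::write_json(
    list(package = "nervedki",
         version = as.character(utils::packageVersion("nervedki")),
         stages = stages_done, seed = config$seed,
         config = unclass(config)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(study = study, model = model, classification = classified,
                 fa = fa, stats = stats_out))
}
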