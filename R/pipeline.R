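#' Assemble a pipeline run configuration
#'
#' A run is driven by one configuration: either a simulation design (synthetic
#' study) or paths to profile/platemap files (real study), processing
#' parameters, the signature alpha, permutation and shuffle settings, an
#' optional clone-level split, and one master seed from which every stage
#' derives its own stream.
#'
#' @param simulation A [simulation_design()], or `NULL` when reading files.
#' @param profiles_path,platemap_path Input files (real-data route).
#' @param output_dir Directory for all stage outputs.
#' @param normalize_by `"plate"` (per-plate z-score, the convention for raw
#'   per-plate data), `"all"` (one global z-score) or `"none"`. Synthetic
#'   profiles are generated on the normalized scale already, so `"all"` is
#'   their natural setting.
#' @param corr_threshold,outlier_sd,blocklist Feature-selection parameters
#'   (see [select_features()]).
#' @param alpha Signature significance level before Bonferroni division.
#' @param n_permutations Permutations for the score null.
#' @param shuffle_reps Clone-shuffle repetitions for baseline metrics.
#' @param training_clones Clones used to fit the signature (default: all).
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(simulation = NULL, profiles_path = NULL,
                       platemap_path = NULL, output_dir = "morphsig_run",
                       normalize_by = "all", corr_threshold = 0.9,
                       outlier_sd = 15, blocklist = character(0),
                       alpha = 0.05, n_permutations = 1000,
                       shuffle_reps = 200, training_clones = NULL,
                       seed = 42) {
  has_sim <- !is.null(simulation)
  has_files <- !is.null(profiles_path)
  if (has_sim == has_files) {
    stop("supply exactly one of a simulation design or input file paths")
  }
  if (has_files && is.null(platemap_path)) {
    stop("profiles_path requires platemap_path")
  }
  structure(list(simulation = simulation, profiles_path = profiles_path,
                 platemap_path = platemap_path, output_dir = output_dir,
                 normalize_by = match.arg(normalize_by,
                                          c("all", "plate", "none")),
                 corr_threshold = corr_threshold, outlier_sd = outlier_sd,
                 blocklist = blocklist, alpha = alpha,
                 n_permutations = n_permutations,
                 shuffle_reps = shuffle_reps,
                 training_clones = training_clones, seed = seed),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; a `simulation` block
#' is passed to [simulation_design()].
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- if (!is.null(raw$simulation)) {
    do.call(simulation_design, raw$simulation)
  }
  args <- raw[setdiff(names(raw), "simulation")]
  do.call(run_config, c(list(simulation = sim), args))
}

log_stage <- function(fmt, ...) message(sprintf(paste0("[morphsig] ", fmt), ...))

#' Run the full signature-discovery pipeline
#'
#' Executes the stages in order: simulate (or ingest) profiles, process
#' (annotate, normalize, feature selection), build the signature on the
#' training clones, score every well with the permutation null, and evaluate
#' (whole-dataset and, when a training split is given, held-out clones;
#' clone-shuffled baselines). Every stage writes its artifacts before the
#' next begins; a manifest with checksums of all written files is written
#' last. All randomness derives from the config's master seed, so a rerun
#' reproduces every artifact bit for bit.
#'
#' @param config A `run_config` or path to a YAML config file.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  add_path <- function(p) paths <<- c(paths, p)

  # --- stage 1: simulate or ingest ------------------------------------------
  if (!is.null(config$simulation)) {
    sim <- simulate_profiles(config$simulation)
    profiles <- sim$profiles
    platemap <- sim$platemap
    fixture_paths <- write_fixtures(profiles, platemap, sim$truth,
                                    file.path(out, "input"))
    add_path(fixture_paths)
    log_stage("simulated %d wells x %d features", nrow(profiles),
              length(feature_cols(profiles)))
  } else {
    profiles <- read_profiles(config$profiles_path)
    platemap <- read_profiles(config$platemap_path)
    profiles <- annotate(profiles, platemap)
    log_stage("ingested %d wells x %d features", nrow(profiles),
              length(feature_cols(profiles)))
  }

  # --- stage 2: process ------------------------------------------------------
  if (config$normalize_by != "none") {
    profiles <- normalize_zscore(
      profiles,
      group_by = if (config$normalize_by == "plate") "Metadata_Plate" else NULL)
  }
  sel <- select_features(profiles, corr_threshold = config$corr_threshold,
                         outlier_sd = config$outlier_sd,
                         blocklist = config$blocklist)
  profiles <- sel$profiles
  log_stage("feature selection kept %d of %d features",
            sum(sel$report$kept), nrow(sel$report))
  p <- file.path(out, "processed_profiles.csv")
  write_profiles(profiles, p); add_path(p)
  p <- file.path(out, "selection_report.csv")
  write_profiles(sel$report, p); add_path(p)

  # --- stage 3: build signature ---------------------------------------------
  training <- profiles
  if (!is.null(config$training_clones)) {
    training <- profiles[profiles$Metadata_clone_ID %in%
                           config$training_clones, , drop = FALSE]
  }
  r1 <- fit_covariate_models(training)
  r2 <- fit_cellcount_models(training)
  signature <- build_signature(r1, r2, alpha = config$alpha)
  log_stage("signature: %d up / %d down of %d features (threshold %.3g)",
            length(signature$up_features), length(signature$down_features),
            signature$m, signature$threshold)
  if (length(signature$up_features) == 0 ||
      length(signature$down_features) == 0) {
    stop("stage build-signature: signature has an empty direction set; ",
         "no scoring is possible")
  }
  p <- file.path(out, "signature.json")
  write_signature(signature, p); add_path(p)
  p <- file.path(out, "signature_features.csv")
  write_signature_table(signature, p); add_path(p)

  # --- stage 4: score --------------------------------------------------------
  scores <- score_profiles(profiles, signature)
  null <- permutation_null(profiles, signature,
                           n_permutations = config$n_permutations,
                           seed = derive_seed(config$seed, "score"))
  predictions <- classify_clones(scores, null)
  log_stage("scored %d wells; null 95%% interval [%.3f, %.3f]",
            nrow(scores), null$ci_low, null$ci_high)
  p <- file.path(out, "well_scores.csv")
  write_profiles(scores, p); add_path(p)
  p <- file.path(out, "clone_predictions.csv")
  write_profiles(predictions, p); add_path(p)
  p <- file.path(out, "permutation_null.json")
  jsonlite::write_json(list(ci_low = null$ci_low, ci_high = null$ci_high,
                            n_permutations = null$n_permutations,
                            mean = mean(null$permuted_scores)),
                       p, auto_unbox = TRUE, digits = NA)
  add_path(p)

  # --- stage 5: evaluate -----------------------------------------------------
  eval_sets <- list(all = scores)
  if (!is.null(config$training_clones)) {
    eval_sets$training <- scores[scores$Metadata_clone_ID %in%
                                   config$training_clones, , drop = FALSE]
    eval_sets$heldout <- scores[!scores$Metadata_clone_ID %in%
                                  config$training_clones, , drop = FALSE]
  }
  reports <- lapply(names(eval_sets), function(nm) {
    rep <- evaluate_scores(eval_sets[[nm]], dataset_name = nm)
    log_stage("%s: accuracy %.3f | AP %.3f | AUROC %.3f", nm, rep$accuracy,
              rep$average_precision, rep$auroc)
    rep
  })
  names(reports) <- names(eval_sets)
  baseline <- shuffled_baseline(scores, n_reps = config$shuffle_reps,
                                seed = derive_seed(config$seed, "shuffle"))
  ks <- ks_misclassification(profiles, predictions, signature)
  p <- file.path(out, "evaluation.json")
  jsonlite::write_json(
    list(datasets = lapply(reports, function(r) {
      r$roc_points <- NULL
      unclass(r)
    }),
    shuffled = lapply(baseline[c("accuracy", "average_precision", "auroc")],
                      unclass)),
    p, auto_unbox = TRUE, digits = NA)
  add_path(p)
  p <- file.path(out, "ks_misclassification.csv")
  write_profiles(ks, p); add_path(p)

  # --- manifest --------------------------------------------------------------
  cfg_for_hash <- config
  manifest <- list(
    tool = "morphsig",
    version = as.character(utils::packageVersion("morphsig")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    config_hash = unname(tools::md5sum(
      write_lines_tmp(utils::capture.output(utils::str(cfg_for_hash))))),
    artifacts = lapply(unname(paths), function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  )
  p <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

write_lines_tmp <- function(lines) {
  tmp <- tempfile()
  writeLines(lines, tmp)
  tmp
}
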