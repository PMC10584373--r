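#' Specify a synthetic Cell Painting study design
#'
#' Describes a simulated morphological-profiling experiment: a panel of
#' drug-sensitive and drug-resistant clones plated with replicate wells
#' across batches (collection days) and incubation times, profiled on a
#' fixed number of numeric morphology features. A subset of features carries
#' a planted resistance effect (the "signal": higher or lower in resistant
#' clones); further disjoint subsets carry planted technical confounders
#' ("decoys") tied to batch, incubation time, per-well cell count, or
#' individual sensitive clones. Remaining features are pure noise, optionally
#' organised into correlated blocks driven by shared latent factors, which
#' mimics the strong redundancy of image-derived texture features.
#'
#' Features are generated directly on the normalized (z-score) scale, so all
#' effect sizes are expressed in units of the residual standard deviation.
#' Categorical confounder shifts are parameterised per step between adjacent
#' levels: a batch decoy in batch b receives
#' `effect_batch * (b - (B + 1)/2)`, so adjacent batches differ by one
#' `effect_batch` unit.
#'
#' @param n_sensitive_clones,n_resistant_clones Number of clones per class.
#' @param wells_per_clone_per_batch Replicate wells per clone, batch and
#'   incubation level. The default (4, with 3 batches and 2 incubation
#'   levels) gives 24 replicate wells per clone, in line with the 20-21
#'   technical replicates per clone typical of a multi-day Cell Painting
#'   training set.
#' @param n_batches Number of batches; each batch occupies one plate.
#' @param incubation_levels Labels of the incubation arms (default 4 h and
#'   13 h in vehicle).
#' @param n_features Total number of morphology features (default 782, the
#'   size of a post-feature-selection Cell Painting profile).
#' @param n_up_signal,n_down_signal Number of signal features higher /
#'   lower in resistant clones (defaults 14 and 31).
#' @param n_batch_decoys,n_time_decoys,n_cellcount_decoys,n_clone_decoys
#'   Number of decoy features per confounder kind.
#' @param effect_resistance Standardized mean shift of signal features
#'   between resistance classes.
#' @param effect_batch,effect_time,effect_clone Standardized per-step shifts
#'   of the decoy features. The clone-specific shift applies to a random half
#'   of the sensitive clones only, so that the affected features trigger the
#'   within-class clone-pair exclusion; its default is larger (2 SD) because a
#'   pairwise clone contrast pools far fewer wells than a class contrast and
#'   needs a stronger planted effect to be detectable at the Bonferroni cut.
#' @param cellcount_slope Slope (feature SD units per cell) applied to
#'   cell-count decoys as `slope * (count - mean count)`.
#' @param cellcount_mean,cellcount_sd Per-well cell-count distribution
#'   (Gaussian, truncated at 1, rounded).
#' @param n_corr_blocks,block_size,block_rho Number, size and within-block
#'   correlation of latent-factor blocks among the null features.
#' @param noise_sd Residual standard deviation of every feature.
#' @param plate_rows,plate_cols Plate geometry (default 8 x 12, a 96-well
#'   plate).
#' @param serpentine Assign consecutive wells along alternating row
#'   directions (snake layout), so each clone lands in many plate regions.
#' @param seed Master seed. Independent RNG streams for layout, effects and
#'   noise are derived from it.
#' @return An object of class `simulation_design` (a validated list).
#' @export
simulation_design <- function(n_sensitive_clones = 5,
                              n_resistant_clones = 5,
                              wells_per_clone_per_batch = 4,
                              n_batches = 3,
                              incubation_levels = c("4h", "13h"),
                              n_features = 782,
                              n_up_signal = 14,
                              n_down_signal = 31,
                              n_batch_decoys = 20,
                              n_time_decoys = 20,
                              n_cellcount_decoys = 20,
                              n_clone_decoys = 20,
                              effect_resistance = 1,
                              effect_batch = 1,
                              effect_time = 1,
                              effect_clone = 2,
                              cellcount_slope = 0.005,
                              cellcount_mean = 1500,
                              cellcount_sd = 200,
                              n_corr_blocks = 10,
                              block_size = 10,
                              block_rho = 0.6,
                              noise_sd = 1,
                              plate_rows = 8,
                              plate_cols = 12,
                              serpentine = TRUE,
                              seed = 42) {
  design <- list(
    n_sensitive_clones = n_sensitive_clones,
    n_resistant_clones = n_resistant_clones,
    wells_per_clone_per_batch = wells_per_clone_per_batch,
    n_batches = n_batches,
    incubation_levels = as.character(incubation_levels),
    n_features = n_features,
    n_up_signal = n_up_signal,
    n_down_signal = n_down_signal,
    n_batch_decoys = n_batch_decoys,
    n_time_decoys = n_time_decoys,
    n_cellcount_decoys = n_cellcount_decoys,
    n_clone_decoys = n_clone_decoys,
    effect_resistance = effect_resistance,
    effect_batch = effect_batch,
    effect_time = effect_time,
    effect_clone = effect_clone,
    cellcount_slope = cellcount_slope,
    cellcount_mean = cellcount_mean,
    cellcount_sd = cellcount_sd,
    n_corr_blocks = n_corr_blocks,
    block_size = block_size,
    block_rho = block_rho,
    noise_sd = noise_sd,
    plate_rows = plate_rows,
    plate_cols = plate_cols,
    serpentine = isTRUE(serpentine),
    seed = seed
  )
  class(design) <- "simulation_design"
  validate_design(design)
  design
}

validate_design <- function(design) {
  counts <- c("n_sensitive_clones", "n_resistant_clones",
              "wells_per_clone_per_batch", "n_batches", "n_features",
              "n_up_signal", "n_down_signal", "n_batch_decoys",
              "n_time_decoys", "n_cellcount_decoys", "n_clone_decoys",
              "n_corr_blocks", "block_size", "plate_rows", "plate_cols")
  for (nm in counts) stopifnot_scalar_count(design[[nm]], nm)
  stopifnot_scalar_count(design$seed, "seed")
  if (design$n_batches < 1 || design$wells_per_clone_per_batch < 1) {
    stop("need at least one batch and one well per clone per batch")
  }
  if (length(design$incubation_levels) < 1 ||
      anyDuplicated(design$incubation_levels)) {
    stop("incubation_levels must be a non-empty set of unique labels")
  }
  planted <- design$n_up_signal + design$n_down_signal +
    design$n_batch_decoys + design$n_time_decoys +
    design$n_cellcount_decoys + design$n_clone_decoys
  if (planted > design$n_features) {
    stop(sprintf(
      "planted feature sets (%d signal + decoy features) exceed n_features (%d)",
      planted, design$n_features))
  }
  if (design$block_rho < 0 || design$block_rho >= 1) {
    stop("block_rho must lie in [0, 1)")
  }
  if (!is.numeric(design$noise_sd) || design$noise_sd <= 0) {
    stop("noise_sd must be > 0")
  }
  if (design$cellcount_sd <= 0 || design$cellcount_mean <= 1) {
    stop("cell-count distribution must have mean > 1 and sd > 0")
  }
  invisible(design)
}

clone_labels <- function(design) {
  c(sprintf("WT%02d", seq_len(design$n_sensitive_clones)),
    sprintf("BZ%02d", seq_len(design$n_resistant_clones)))
}

clone_classes <- function(design) {
  stats::setNames(
    rep(c("sensitive", "resistant"),
        c(design$n_sensitive_clones, design$n_resistant_clones)),
    clone_labels(design))
}

#' Lay out a simulated experiment onto plates
#'
#' Generates one plate per batch. Within each plate, wells are filled in
#' plate-reading order (serpentine by default: row A left to right, row B
#' right to left, and so on) while cycling through clones, so consecutive
#' positions hold consecutive clones and every clone is spread across plate
#' regions. The layout fully crosses clone, batch and incubation time with
#' `wells_per_clone_per_batch` replicate wells per cell of that cross.
#' Per-well cell counts are drawn from a truncated Gaussian.
#'
#' @param design A [simulation_design()].
#' @return A data.frame plate map with one row per well: `plate_id`,
#'   `well_id`, `row`, `column`, `clone_id`, `resistance_label`, `batch`,
#'   `incubation_time`, `cell_count`.
#' @export
generate_platemap <- function(design) {
  validate_design(design)
  clones <- clone_labels(design)
  classes <- clone_classes(design)
  n_times <- length(design$incubation_levels)
  wells_per_plate <- length(clones) * n_times * design$wells_per_clone_per_batch
  capacity <- design$plate_rows * design$plate_cols
  if (wells_per_plate > capacity) {
    stop(sprintf(
      paste0("design requires %d wells per plate but the plate holds ",
             "%d (%d rows x %d columns); overflow of %d wells"),
      wells_per_plate, capacity, design$plate_rows, design$plate_cols,
      wells_per_plate - capacity))
  }

  # Deterministic fill order: replicate block, then incubation arm, then the
  # repeating clone sequence -- consecutive positions cycle through clones.
  combos <- expand.grid(clone_id = clones,
                        incubation_time = design$incubation_levels,
                        replicate = seq_len(design$wells_per_clone_per_batch),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  combos <- combos[order(combos$replicate,
                         match(combos$incubation_time,
                               design$incubation_levels)), ]

  rows <- seq_len(design$plate_rows)
  cols <- seq_len(design$plate_cols)
  pos <- expand.grid(column = cols, row = rows,
                     KEEP.OUT.ATTRS = FALSE)[, c("row", "column")]
  if (design$serpentine) {
    flip <- pos$row %% 2 == 0
    pos$column[flip] <- design$plate_cols + 1 - pos$column[flip]
  }
  pos <- pos[seq_len(wells_per_plate), ]

  maps <- lapply(seq_len(design$n_batches), function(b) {
    data.frame(
      plate_id = sprintf("plate_%02d", b),
      well_id = paste0(LETTERS[pos$row], sprintf("%02d", pos$column)),
      row = pos$row,
      column = pos$column,
      clone_id = combos$clone_id,
      resistance_label = unname(classes[combos$clone_id]),
      batch = sprintf("batch_%d", b),
      incubation_time = combos$incubation_time,
      stringsAsFactors = FALSE
    )
  })
  platemap <- do.call(rbind, maps)
  counts <- with_seed(derive_seed(design$seed, "cellcount"), {
    stats::rnorm(nrow(platemap), design$cellcount_mean, design$cellcount_sd)
  })
  platemap$cell_count <- pmax(1, round(counts))
  rownames(platemap) <- NULL
  platemap
}

feature_names <- function(n) {
  compartments <- c("Cells", "Cytoplasm", "Nuclei")
  groups <- c("Texture", "Intensity", "AreaShape", "RadialDistribution",
              "Correlation")
  sprintf("%s_%s_F%04d",
          compartments[(seq_len(n) - 1) %% 3 + 1],
          groups[(seq_len(n) - 1) %/% 3 %% 5 + 1],
          seq_len(n))
}

assign_feature_roles <- function(design) {
  feats <- feature_names(design$n_features)
  with_seed(derive_seed(design$seed, "effects"), {
    shuffled <- sample(feats)
    take <- function(n) {
      # guard n = 0: x[-integer(0)] selects nothing, not everything
      if (n == 0) return(character(0))
      out <- shuffled[seq_len(n)]
      shuffled <<- shuffled[-seq_len(n)]
      out
    }
    roles <- list(
      up_signal = take(design$n_up_signal),
      down_signal = take(design$n_down_signal),
      batch = take(design$n_batch_decoys),
      time = take(design$n_time_decoys),
      cell_count = take(design$n_cellcount_decoys),
      clone = take(design$n_clone_decoys)
    )
    # correlated blocks live among the remaining null features
    n_block_feats <- min(length(shuffled),
                         design$n_corr_blocks * design$block_size)
    block_feats <- shuffled[seq_len(n_block_feats)]
    roles$blocks <- split(block_feats,
                          ceiling(seq_along(block_feats) / design$block_size))
    sens <- sprintf("WT%02d", seq_len(design$n_sensitive_clones))
    n_shift <- floor(design$n_sensitive_clones / 2)
    roles$clone_targets <- lapply(roles$clone, function(f) {
      if (n_shift > 0) sample(sens, n_shift) else character(0)
    })
    names(roles$clone_targets) <- roles$clone
    roles
  })
}

#' Simulate well-level morphological profiles with planted structure
#'
#' Draws a profile table matching the plate map of `design`. Every feature is
#' generated as latent-block factor + independent Gaussian noise (marginal
#' standard deviation `noise_sd`), then planted effects are added: signed
#' resistance shifts on the signal features, and batch, incubation-time,
#' cell-count or clone-specific shifts on the decoy features. All plate-map
#' fields are carried as `Metadata_` columns. Output is reproducible for a
#' given design (and its seed).
#'
#' @param design A [simulation_design()].
#' @return A list with `profiles` (data.frame: metadata + features),
#'   `platemap` and `truth` (a `ground_truth` list: `up_signal`,
#'   `down_signal`, `decoys` by confounder kind, `clone_targets`,
#'   `true_labels`).
#' @export
simulate_profiles <- function(design) {
  validate_design(design)
  platemap <- generate_platemap(design)
  n <- nrow(platemap)
  feats <- feature_names(design$n_features)
  roles <- assign_feature_roles(design)

  mat <- with_seed(derive_seed(design$seed, "noise"), {
    m <- matrix(stats::rnorm(n * design$n_features, sd = design$noise_sd),
                nrow = n, dimnames = list(NULL, feats))
    rho <- design$block_rho
    if (rho > 0) {
      for (block in roles$blocks) {
        factor_vals <- stats::rnorm(n, sd = design$noise_sd)
        m[, block] <- sqrt(rho) * factor_vals +
          sqrt(1 - rho) * m[, block, drop = FALSE]
      }
    }
    m
  })

  add_shift <- function(m, feats, shift) {
    if (length(feats) > 0) m[, feats] <- m[, feats, drop = FALSE] + shift
    m
  }
  resistant <- platemap$resistance_label == "resistant"
  mat <- add_shift(mat, roles$up_signal, design$effect_resistance * resistant)
  mat <- add_shift(mat, roles$down_signal, -design$effect_resistance * resistant)

  batch_idx <- match(platemap$batch, sort(unique(platemap$batch)))
  batch_coef <- batch_idx - (design$n_batches + 1) / 2
  mat <- add_shift(mat, roles$batch, design$effect_batch * batch_coef)

  time_idx <- match(platemap$incubation_time, design$incubation_levels)
  time_coef <- time_idx - (length(design$incubation_levels) + 1) / 2
  mat <- add_shift(mat, roles$time, design$effect_time * time_coef)

  count_centered <- platemap$cell_count - mean(platemap$cell_count)
  mat <- add_shift(mat, roles$cell_count,
                   design$cellcount_slope * count_centered)

  for (f in roles$clone) {
    hit <- platemap$clone_id %in% roles$clone_targets[[f]]
    mat[, f] <- mat[, f] + design$effect_clone * hit
  }

  metadata <- data.frame(
    Metadata_Plate = platemap$plate_id,
    Metadata_Well = platemap$well_id,
    Metadata_clone_ID = platemap$clone_id,
    Metadata_resistance_label = platemap$resistance_label,
    Metadata_batch = platemap$batch,
    Metadata_time = platemap$incubation_time,
    Metadata_cell_count = platemap$cell_count,
    stringsAsFactors = FALSE
  )
  profiles <- cbind(metadata, as.data.frame(mat))

  truth <- list(
    up_signal = roles$up_signal,
    down_signal = roles$down_signal,
    decoys = list(batch = roles$batch,
                  incubation_time = roles$time,
                  cell_count = roles$cell_count,
                  clone_pairs = roles$clone),
    clone_targets = roles$clone_targets,
    true_labels = as.list(clone_classes(design))
  )
  class(truth) <- "ground_truth"

  list(profiles = profiles, platemap = platemap, truth = truth)
}

#' Write simulated profiles, plate map and ground truth to disk
#'
#' Profiles and plate map go to delimited text, the ground truth to a JSON
#' sidecar. Files round-trip losslessly through [read_profiles()] and
#' [read_ground_truth()].
#'
#' @param profiles,platemap,truth Outputs of [simulate_profiles()].
#' @param dir Output directory (created if absent).
#' @param sep Field separator for the delimited files.
#' @return Named character vector of written paths.
#' @export
write_fixtures <- function(profiles, platemap, truth, dir, sep = ",") {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  paths <- c(
    profiles = file.path(dir, "profiles.csv"),
    platemap = file.path(dir, "platemap.csv"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_profiles(profiles, paths[["profiles"]], sep = sep)
  write_profiles(platemap, paths[["platemap"]], sep = sep)
  jsonlite::write_json(unclass(truth), paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}

#' @rdname write_fixtures
#' @param path Path to a ground-truth JSON sidecar.
#' @export
read_ground_truth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth$decoys <- lapply(truth$decoys, as.character)
  truth$up_signal <- as.character(truth$up_signal)
  truth$down_signal <- as.character(truth$down_signal)
  class(truth) <- "ground_truth"
  truth
}
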