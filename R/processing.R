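#' Median-aggregate single-cell measurements to well-level profiles
#'
#' Collapses a single-cell (or any sub-well) profile table to one row per
#' well by taking the per-feature median within each (plate, well) group.
#' Metadata columns that are constant within a well are carried through;
#' conflicting metadata raises an error.
#'
#' @param cells Profile data.frame at single-cell granularity with
#'   `Metadata_Plate` and `Metadata_Well` columns.
#' @return Well-level profile data.frame, one row per well.
#' @export
aggregate_to_wells <- function(cells) {
  keys <- c("Metadata_Plate", "Metadata_Well")
  if (!all(keys %in% names(cells))) {
    stop("grouping keys Metadata_Plate and Metadata_Well are required")
  }
  feats <- feature_cols(cells)
  meta <- metadata_cols(cells)
  group <- interaction(cells[keys], drop = TRUE, lex.order = TRUE)

  meta_rows <- lapply(split(cells[meta], group), function(g) {
    n_distinct <- vapply(g, function(col) length(unique(col)), integer(1))
    bad <- names(n_distinct)[n_distinct > 1]
    if (length(bad) > 0) {
      stop("metadata not constant within well ",
           paste(unique(g$Metadata_Plate), unique(g$Metadata_Well)[1]),
           ": ", paste(bad, collapse = ", "))
    }
    g[1, , drop = FALSE]
  })
  meta_out <- do.call(rbind, meta_rows)

  feat_out <- as.data.frame(
    lapply(cells[feats],
           function(col) vapply(split(col, group), stats::median, numeric(1)))
  )
  names(feat_out) <- feats
  out <- cbind(meta_out, feat_out)
  rownames(out) <- NULL
  out
}

#' Annotate well profiles with plate-map metadata
#'
#' Left-joins a plate map onto a profile table on (plate, well). All plate-map
#' fields are added as `Metadata_`-prefixed columns; the profile row count is
#' unchanged.
#'
#' @param profiles Well-level profile data.frame with `Metadata_Plate` and
#'   `Metadata_Well`.
#' @param platemap Plate-map data.frame with `plate_id` and `well_id` plus
#'   annotation columns.
#' @return Annotated profile data.frame.
#' @export
annotate <- function(profiles, platemap) {
  keys <- c("Metadata_Plate", "Metadata_Well")
  if (!all(keys %in% names(profiles))) {
    stop("profiles must carry Metadata_Plate and Metadata_Well")
  }
  if (!all(c("plate_id", "well_id") %in% names(platemap))) {
    stop("platemap must carry plate_id and well_id")
  }
  map_key <- paste(platemap$plate_id, platemap$well_id)
  if (anyDuplicated(map_key)) {
    stop("duplicate (plate, well) keys in platemap: ",
         paste(unique(map_key[duplicated(map_key)]), collapse = ", "))
  }
  prof_key <- paste(profiles$Metadata_Plate, profiles$Metadata_Well)
  idx <- match(prof_key, map_key)
  if (anyNA(idx)) {
    stop("profile wells absent from platemap: ",
         paste(unique(prof_key[is.na(idx)]), collapse = ", "))
  }
  ann_cols <- setdiff(names(platemap), c("plate_id", "well_id"))
  ann <- platemap[idx, ann_cols, drop = FALSE]
  # platemap fields use the Metadata_ naming of the profile convention
  rename <- c(clone_id = "Metadata_clone_ID",
              resistance_label = "Metadata_resistance_label",
              batch = "Metadata_batch",
              incubation_time = "Metadata_time",
              cell_count = "Metadata_cell_count",
              row = "Metadata_row",
              column = "Metadata_column")
  names(ann) <- ifelse(names(ann) %in% names(rename),
                       rename[names(ann)],
                       paste0(METADATA_PREFIX, names(ann)))
  keep <- setdiff(names(profiles), names(ann))
  out <- cbind(profiles[keep], ann)
  meta <- metadata_cols(out)
  out <- out[c(meta, feature_cols(out))]
  rownames(out) <- NULL
  out
}

#' Z-score normalize features within groups
#'
#' Standard z-score normalization: within each group (by default each plate),
#' every feature is centred to mean 0 and scaled to sample standard deviation
#' 1 (n - 1 denominator). Features constant within a group cannot be scaled;
#' they are set to 0 there and recorded in a `constant_features` attribute
#' with a warning.
#'
#' @param profiles Profile data.frame.
#' @param group_by Metadata column defining normalization groups, or `NULL`
#'   to normalize across all wells at once.
#' @return Profile data.frame with normalized features.
#' @export
normalize_zscore <- function(profiles, group_by = "Metadata_Plate") {
  feats <- feature_cols(profiles)
  groups <- if (is.null(group_by)) {
    factor(rep("all", nrow(profiles)))
  } else {
    if (!group_by %in% names(profiles)) {
      stop("grouping column not found: ", group_by)
    }
    factor(profiles[[group_by]])
  }
  sizes <- table(groups)
  if (any(sizes < 2)) {
    stop("normalization groups of size 1 (sd undefined): ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  out <- profiles
  constant <- character(0)
  for (g in levels(groups)) {
    idx <- which(groups == g)
    block <- as.matrix(profiles[idx, feats, drop = FALSE])
    mu <- colMeans(block)
    sdev <- apply(block, 2, stats::sd)
    flat <- sdev < .Machine$double.eps^0.5
    if (any(flat)) {
      constant <- union(constant, feats[flat])
      sdev[flat] <- 1
      mu[flat] <- block[1, flat]
    }
    out[idx, feats] <- sweep(sweep(block, 2, mu, "-"), 2, sdev, "/")
  }
  if (length(constant) > 0) {
    warning("features constant within a normalization group set to 0: ",
            paste(constant, collapse = ", "))
    attr(out, "constant_features") <- constant
  }
  out
}

#' Rule-based feature selection for morphological profiles
#'
#' Applies the standard image-profiling quality filters in a fixed order:
#' (1) features with missing values, (2) low-variance features, (3) features
#' on a user-supplied blocklist, (4) one member of every feature pair with
#' absolute Pearson correlation above `corr_threshold`, (5) features with an
#' outlier beyond `outlier_sd` standard deviations of their own mean.
#' Correlation victims are chosen deterministically: the pair member with the
#' larger mean absolute correlation to all other remaining features is
#' dropped, ties broken by the lexicographically larger name.
#'
#' @param profiles Normalized profile data.frame.
#' @param corr_threshold Pearson correlation above which one pair member is
#'   removed (default 0.9).
#' @param outlier_sd Outlier cut in per-feature standard deviations
#'   (default 15).
#' @param freq_cut Low-variance rule: remove a feature when the count ratio
#'   of its second-most-frequent to most-frequent value falls below this cut
#'   (default 0.05), or when its variance is below `var_eps`.
#' @param var_eps Variance floor for the near-constant rule.
#' @param blocklist Character vector of feature names to drop outright.
#' @return A list with `profiles` (surviving features) and `report`
#'   (data.frame: `feature`, `kept`, `removal_rule`, `detail`).
#' @export
select_features <- function(profiles, corr_threshold = 0.9, outlier_sd = 15,
                            freq_cut = 0.05, var_eps = 1e-12,
                            blocklist = character(0)) {
  if (!is.numeric(corr_threshold) || corr_threshold <= 0 ||
      corr_threshold > 1) {
    stop("corr_threshold must lie in (0, 1]")
  }
  feats <- sort(feature_cols(profiles))
  mat <- feature_matrix(profiles, feats)
  report <- data.frame(feature = feats, kept = TRUE,
                       removal_rule = "none", detail = "",
                       stringsAsFactors = FALSE)
  rownames(report) <- feats
  drop <- function(fs, rule, detail) {
    fs <- fs[report[fs, "kept"]]
    report[fs, "kept"] <<- FALSE
    report[fs, "removal_rule"] <<- rule
    report[fs, "detail"] <<- detail
  }

  n_missing <- colSums(!is.finite(mat))
  drop(feats[n_missing > 0], "missing",
       as.character(n_missing[n_missing > 0]))

  alive <- feats[report$kept]
  low_var <- vapply(alive, function(f) {
    x <- mat[, f]
    if (stats::var(x) < var_eps) return(TRUE)
    counts <- sort(table(x), decreasing = TRUE)
    length(counts) < 2 || counts[2] / counts[1] < freq_cut
  }, logical(1))
  drop(alive[low_var], "low_variance", "")

  drop(intersect(feats[report$kept], blocklist), "blocklist", "")

  alive <- feats[report$kept]
  if (length(alive) >= 2) {
    cm <- abs(stats::cor(mat[, alive, drop = FALSE]))
    diag(cm) <- 0
    repeat {
      worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      if (cm[worst[1], worst[2]] <= corr_threshold) break
      pair <- sort(alive[worst])
      mean_abs <- rowMeans(cm[pair, , drop = FALSE])
      victim <- if (abs(diff(mean_abs)) > 1e-12) {
        pair[which.max(mean_abs)]
      } else {
        pair[2]  # lexicographically larger name
      }
      partner <- setdiff(pair, victim)
      drop(victim, "correlation", partner)
      keep_idx <- alive != victim
      alive <- alive[keep_idx]
      cm <- cm[keep_idx, keep_idx, drop = FALSE]
    }
  }

  alive <- feats[report$kept]
  block <- mat[, alive, drop = FALSE]
  mu <- colMeans(block)
  sdev <- apply(block, 2, stats::sd)
  max_dev <- apply(abs(sweep(block, 2, mu, "-")), 2, max)
  outlier <- sdev > 0 & max_dev > outlier_sd * sdev
  drop(alive[outlier], "outlier",
       sprintf("%.1f sd", (max_dev / sdev)[outlier]))

  kept <- report$feature[report$kept]
  out <- profiles[c(metadata_cols(profiles),
                    intersect(feature_cols(profiles), kept))]
  rownames(report) <- NULL
  list(profiles = out, report = report)
}
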