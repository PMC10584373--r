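#' Build a signed resistance signature from per-feature model results
#'
#' Applies the Bonferroni-thresholded inclusion and exclusion rules to the
#' covariate-model and cell-count-model results of `m` features. With
#' threshold `t = alpha / m`, a feature enters the signature iff
#' \itemize{
#'   \item its resistant-vs-sensitive Tukey adjusted p-value is below `t`,
#'   \item no batch pair and no incubation-time pair is significant at `t`,
#'   \item its cell-count slope p-value is at or above `t`,
#'   \item fewer than two sensitive-sensitive clone pairs differ at `t`
#'     (optionally also resistant-resistant pairs).
#' }
#' The feature's direction is the sign of its resistance coefficient
#' (resistant coded 1): positive coefficients join the up set (higher in
#' resistant clones), negative the down set. A per-feature ledger records
#' why every feature was kept or excluded.
#'
#' @param results1 Named list of covariate `feature_model`s
#'   ([fit_covariate_models()]).
#' @param results2 Named list of cell-count `feature_model`s
#'   ([fit_cellcount_models()]); must cover the same features.
#' @param alpha Family-wise significance level before Bonferroni division
#'   (default 0.05).
#' @param clone_pair_classes Classes whose within-class clone pairs count
#'   toward the clone exclusion (default only `"sensitive"`).
#' @param min_clone_pairs Number of significant within-class clone pairs at
#'   which a feature is excluded (default 2).
#' @return A `signature_definition`: `up_features`, `down_features` (ordered
#'   by ascending resistance p), `threshold`, `alpha`, `m`, and `ledger`
#'   (data.frame with `feature`, `resistance_p`, `direction`, `excluded_by`).
#' @export
build_signature <- function(results1, results2, alpha = 0.05,
                            clone_pair_classes = "sensitive",
                            min_clone_pairs = 2) {
  m <- length(results1)
  if (m == 0) stop("no model results supplied")
  feats <- vapply(results1, `[[`, character(1), "feature")
  feats2 <- vapply(results2, `[[`, character(1), "feature")
  if (!setequal(feats, feats2)) {
    stop("the two model result sets must cover the same features")
  }
  results2 <- results2[match(feats, feats2)]
  threshold <- alpha / m

  rows <- lapply(seq_len(m), function(i) {
    r1 <- results1[[i]]
    r2 <- results2[[i]]
    excluded <- character(0)

    res_tab <- r1$tukey$resistance_status
    resistance_p <- res_tab$adjusted_p[1]
    if (!(resistance_p < threshold)) excluded <- c(excluded, "not_significant")

    if (!is.null(r1$tukey$batch) &&
        any(r1$tukey$batch$adjusted_p < threshold)) {
      excluded <- c(excluded, "batch")
    }
    if (!is.null(r1$tukey$incubation_time) &&
        any(r1$tukey$incubation_time$adjusted_p < threshold)) {
      excluded <- c(excluded, "incubation_time")
    }
    if (r2$cellcount_p < threshold) excluded <- c(excluded, "cell_count")

    if (!is.null(r1$tukey$clone_id)) {
      ct <- r1$tukey$clone_id
      cls <- r1$clone_class
      within <- cls[ct$level_a] == cls[ct$level_b] &
        cls[ct$level_a] %in% clone_pair_classes
      n_sig <- sum(within & ct$adjusted_p < threshold)
      if (n_sig >= min_clone_pairs) excluded <- c(excluded, "clone_pairs")
    }

    beta <- unname(r1$betas["resistance_status"])
    direction <- sign(beta)
    if (length(excluded) == 0 && direction == 0) {
      excluded <- "zero_direction"
    }
    data.frame(feature = r1$feature,
               resistance_p = resistance_p,
               beta_resistance = beta,
               direction = direction,
               excluded_by = paste(excluded, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  ledger <- do.call(rbind, rows)
  kept <- ledger[ledger$excluded_by == "", ]
  kept <- kept[order(kept$resistance_p, kept$feature), ]

  structure(list(
    up_features = kept$feature[kept$direction > 0],
    down_features = kept$feature[kept$direction < 0],
    threshold = threshold,
    alpha = alpha,
    m = m,
    ledger = ledger
  ), class = "signature_definition")
}

#' @export
print.signature_definition <- function(x, ...) {
  cat(sprintf(
    "<signature_definition> %d up / %d down of %d features (threshold %.3g)\n",
    length(x$up_features), length(x$down_features), x$m, x$threshold))
  invisible(x)
}

#' Read and write signature definitions
#'
#' JSON layout: `{up: [...], down: [...], threshold, alpha, m, ledger:
#' [...]}`. [write_signature_table()] additionally exports a two-column
#' `feature, direction` delimited file.
#'
#' @param signature A `signature_definition`.
#' @param path Output / input path.
#' @return `path` (writers) or a `signature_definition` (reader).
#' @export
write_signature <- function(signature, path) {
  jsonlite::write_json(
    list(up = signature$up_features, down = signature$down_features,
         threshold = signature$threshold, alpha = signature$alpha,
         m = signature$m, ledger = signature$ledger),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(up_features = as.character(x$up),
                 down_features = as.character(x$down),
                 threshold = x$threshold, alpha = x$alpha, m = x$m,
                 ledger = x$ledger),
            class = "signature_definition")
}

#' @rdname write_signature
#' @export
write_signature_table <- function(signature, path) {
  tab <- data.frame(
    feature = c(signature$up_features, signature$down_features),
    direction = rep(c("up", "down"),
                    c(length(signature$up_features),
                      length(signature$down_features))),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Canonical feature spaces for cluster-enrichment comparison
#'
#' Builds the four feature spaces compared in the clustering diagnostic:
#' the full feature space, the standard feature-selection survivors, the
#' signature features, and a size-matched random draw.
#'
#' @param profiles Profile data.frame.
#' @param signature A `signature_definition`.
#' @param seed Seed for the random space.
#' @param selection Optional [select_features()] report; computed from
#'   `profiles` when absent.
#' @return Named list of feature-name vectors.
#' @export
default_feature_spaces <- function(profiles, signature, seed = 1,
                                   selection = NULL) {
  feats <- feature_cols(profiles)
  if (is.null(selection)) selection <- select_features(profiles)$report
  sig_feats <- c(signature$up_features, signature$down_features)
  random_k <- with_seed(derive_seed(seed, "random-space"),
                        sample(feats, min(length(sig_feats), length(feats))))
  list(full = feats,
       standard_selection = selection$feature[selection$kept],
       signature = sig_feats,
       random_k = random_k)
}

#' Per-cluster enrichment of resistant profiles
#'
#' For every cluster, builds the 2x2 contingency table (in-cluster vs out,
#' resistant vs sensitive) and reports the two-sided Fisher's exact p-value
#' together with a Haldane-corrected odds ratio (0.5 added to every cell, so
#' perfectly separable clusters report a large finite value instead of
#' infinity).
#'
#' @param clusters Integer cluster memberships.
#' @param is_resistant Logical vector, same length.
#' @return Data.frame: `cluster`, `n`, `n_resistant`, `odds_ratio`, `p`.
#' @export
cluster_enrichment <- function(clusters, is_resistant) {
  if (length(clusters) != length(is_resistant)) stop("length mismatch")
  ids <- sort(unique(clusters))
  rows <- lapply(ids, function(cl) {
    inside <- clusters == cl
    a <- sum(inside & is_resistant); b <- sum(inside & !is_resistant)
    cc <- sum(!inside & is_resistant); dd <- sum(!inside & !is_resistant)
    data.frame(
      cluster = cl, n = a + b, n_resistant = a,
      odds_ratio = ((a + 0.5) * (dd + 0.5)) / ((b + 0.5) * (cc + 0.5)),
      p = stats::fisher.test(matrix(c(a, b, cc, dd), 2, byrow = TRUE))$p.value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare feature spaces by cluster enrichment and silhouette width
#'
#' For every feature space and every k in `k_range`: project the space onto
#' at most `n_pcs` principal components, run k-means with `nstart` random
#' initializations (best inertia kept), test each cluster's association with
#' resistance class by a two-by-two Fisher's exact test (in-cluster vs out,
#' resistant vs sensitive; odds ratios use a Haldane 0.5 continuity
#' correction so separable clusters report a large finite value), and
#' average silhouette widths (Euclidean, in PC space).
#'
#' @param profiles Profile data.frame with `Metadata_resistance_label`.
#' @param spaces Named list of feature-name vectors
#'   (see [default_feature_spaces()]).
#' @param k_range Cluster counts to scan (default 2:14).
#' @param n_pcs Maximum number of principal components (default 30).
#' @param nstart k-means initializations (default 25).
#' @param seed Seed for the k-means initializations.
#' @return A `cluster_report` data.frame: `space`, `k`, `mean_odds_ratio`,
#'   `max_odds_ratio`, `min_fisher_p`, `mean_silhouette`.
#' @export
compare_feature_spaces <- function(profiles, spaces, k_range = 2:14,
                                   n_pcs = 30, nstart = 25, seed = 1) {
  required_model_cols(profiles, "Metadata_resistance_label")
  labels <- profiles$Metadata_resistance_label == "resistant"
  n <- nrow(profiles)
  if (max(k_range) >= n) stop("k must be smaller than the number of wells")
  if (any(vapply(spaces, length, integer(1)) == 0)) {
    stop("every feature space must be non-empty")
  }

  rows <- list()
  for (space_name in names(spaces)) {
    mat <- feature_matrix(profiles, spaces[[space_name]])
    d <- min(n_pcs, ncol(mat), n - 1)
    pcs <- stats::prcomp(mat, center = TRUE, scale. = FALSE)$x[, seq_len(d),
                                                               drop = FALSE]
    dists <- stats::dist(pcs)
    for (k in k_range) {
      km <- with_seed(derive_seed(seed, paste(space_name, k)),
                      stats::kmeans(pcs, centers = k, nstart = nstart,
                                    iter.max = 50))
      enr <- cluster_enrichment(km$cluster, labels)
      sil <- cluster::silhouette(km$cluster, dists)
      rows[[length(rows) + 1]] <- data.frame(
        space = space_name, k = k,
        mean_odds_ratio = mean(enr$odds_ratio),
        max_odds_ratio = max(enr$odds_ratio),
        min_fisher_p = min(enr$p),
        mean_silhouette = mean(sil[, "sil_width"]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cluster_report", "data.frame")
  out
}
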