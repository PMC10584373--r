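check_binary_truth <- function(truth) {
  truth <- as.logical(truth)
  if (anyNA(truth)) stop("truth labels must be binary (logical or 0/1)")
  if (length(unique(truth)) < 2) stop("both classes must be present")
  truth
}

#' Classification accuracy
#'
#' Fraction of predictions matching the truth (total correct / total
#' chances).
#'
#' @param predictions,truth Equal-length label vectors.
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(predictions, truth) {
  if (length(predictions) != length(truth)) stop("length mismatch")
  if (length(truth) == 0) stop("empty input")
  mean(predictions == truth)
}

#' Average precision of a score against binary labels
#'
#' Step-interpolated area under the precision-recall curve:
#' `AP = sum_n (R_n - R_{n-1}) * P_n` over thresholds at the distinct scores
#' in descending order (tied scores enter as one threshold group). The
#' positive class is resistant (truth = 1 / TRUE).
#'
#' @param scores Numeric scores, higher meaning more resistant.
#' @param truth Binary labels (TRUE/1 = resistant).
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(scores, truth) {
  truth <- check_binary_truth(truth)
  if (length(scores) != length(truth)) stop("length mismatch")
  thresholds <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(truth)
  recall_prev <- 0
  ap <- 0
  for (t in thresholds) {
    called <- scores >= t
    tp <- sum(called & truth)
    precision <- tp / sum(called)
    recall <- tp / n_pos
    ap <- ap + (recall - recall_prev) * precision
    recall_prev <- recall
  }
  ap
}

#' ROC curve and area under it
#'
#' Computes the ROC curve over all distinct score thresholds (plus the
#' endpoints) with AUROC by the trapezoid rule, which equals the normalized
#' Mann-Whitney U statistic (ties counted 1/2). Also reports the operating
#' point at the threshold closest to zero -- the score cut actually used to
#' call resistance.
#'
#' @inheritParams average_precision
#' @return A list: `roc_points` (data.frame `fpr`, `tpr`, `threshold`),
#'   `auroc`, `min_threshold_point`.
#' @export
roc_auroc <- function(scores, truth) {
  truth <- check_binary_truth(truth)
  if (length(scores) != length(truth)) stop("length mismatch")
  thresholds <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  tpr <- fpr <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    called <- scores >= thresholds[i]
    tpr[i] <- sum(called & truth) / n_pos
    fpr[i] <- sum(called & !truth) / n_neg
  }
  roc <- data.frame(fpr = fpr, tpr = tpr, threshold = thresholds)
  auroc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                  utils::tail(roc$tpr, -1)) / 2)
  finite <- is.finite(roc$threshold)
  min_idx <- which(finite)[which.min(abs(roc$threshold[finite]))]
  list(roc_points = roc, auroc = auroc,
       min_threshold_point = roc[min_idx, c("fpr", "tpr", "threshold")])
}

#' Evaluate well-level signature scores against clone labels
#'
#' Convenience wrapper computing accuracy (of the sign-of-score call),
#' average precision and AUROC at the well-profile level, plus clone-level
#' accuracy of the median-score rule.
#'
#' @param scores Output of [score_profiles()] carrying
#'   `Metadata_resistance_label` and `Metadata_clone_ID`.
#' @param dataset_name Label stored in the report.
#' @return An `evaluation_report` list.
#' @export
evaluate_scores <- function(scores, dataset_name = "dataset") {
  truth <- scores$Metadata_resistance_label == "resistant"
  roc <- roc_auroc(scores$total_score, truth)
  clone_med <- tapply(scores$total_score, scores$Metadata_clone_ID,
                      stats::median)
  clone_truth <- tapply(scores$Metadata_resistance_label,
                        scores$Metadata_clone_ID,
                        function(x) unique(x)[1]) == "resistant"
  structure(list(
    dataset_name = dataset_name,
    accuracy = accuracy(scores$total_score > 0, truth),
    average_precision = average_precision(scores$total_score, truth),
    auroc = roc$auroc,
    roc_points = roc$roc_points,
    min_threshold_point = roc$min_threshold_point,
    clone_accuracy = accuracy(unname(clone_med > 0), unname(clone_truth)),
    n_wells = nrow(scores)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report '%s'> accuracy %.3f | AP %.3f | AUROC %.3f (%d wells)\n",
    x$dataset_name, x$accuracy, x$average_precision, x$auroc, x$n_wells))
  invisible(x)
}

#' Clone-shuffled baseline metrics
#'
#' Permutes resistance labels at the clone level (all replicate wells of a
#' clone move together, preserving class counts) and recomputes accuracy,
#' average precision and AUROC per repetition. Shuffling whole clones rather
#' than wells respects the replicate correlation structure.
#'
#' @param scores Output of [score_profiles()].
#' @param n_reps Number of shuffles (default 200).
#' @param seed RNG seed.
#' @return A list with per-metric `mean`, 95% percentile interval and the
#'   per-repetition values.
#' @export
shuffled_baseline <- function(scores, n_reps = 200, seed = 1) {
  clones <- unique(scores$Metadata_clone_ID)
  clone_label <- tapply(scores$Metadata_resistance_label,
                        scores$Metadata_clone_ID,
                        function(x) unique(x)[1])[clones]
  if (sum(clone_label == "resistant") < 2 ||
      sum(clone_label == "sensitive") < 2) {
    stop("need at least two clones per class for a nontrivial permutation")
  }
  mets <- with_seed(derive_seed(seed, "shuffled-baseline"), {
    t(vapply(seq_len(n_reps), function(r) {
      shuffled <- stats::setNames(sample(clone_label), clones)
      truth <- shuffled[scores$Metadata_clone_ID] == "resistant"
      c(accuracy = accuracy(scores$total_score > 0, truth),
        average_precision = average_precision(scores$total_score, truth),
        auroc = roc_auroc(scores$total_score, truth)$auroc)
    }, numeric(3)))
  })
  summarise <- function(v) {
    list(mean = mean(v),
         ci = unname(stats::quantile(v, c(0.025, 0.975))))
  }
  list(accuracy = summarise(mets[, "accuracy"]),
       average_precision = summarise(mets[, "average_precision"]),
       auroc = summarise(mets[, "auroc"]),
       replicates = as.data.frame(mets),
       n_reps = n_reps, seed = seed)
}

#' Partition wells into named evaluation datasets
#'
#' Materializes disjoint profile subsets from clone/plate predicates, the
#' split logic used to separate training, validation (held-out wells of
#' training clones on the training plates), test (held-out clones) and
#' holdout (a separate plate) data. Each element of `split_spec` is a list
#' with any of `clones`, `plates`, `wells` (explicit `plate:well` keys);
#' a well must satisfy all supplied predicates to enter the subset.
#'
#' @param profiles Annotated profile data.frame.
#' @param split_spec Named list of predicate lists.
#' @return Named list of profile data.frames; overlapping predicates raise an
#'   error listing the collisions, empty subsets warn.
#' @export
dataset_splits <- function(profiles, split_spec) {
  key <- paste(profiles$Metadata_Plate, profiles$Metadata_Well, sep = ":")
  assign <- rep(NA_character_, nrow(profiles))
  out <- list()
  for (nm in names(split_spec)) {
    spec <- split_spec[[nm]]
    sel <- rep(TRUE, nrow(profiles))
    if (!is.null(spec$clones)) {
      sel <- sel & profiles$Metadata_clone_ID %in% spec$clones
    }
    if (!is.null(spec$plates)) {
      sel <- sel & profiles$Metadata_Plate %in% spec$plates
    }
    if (!is.null(spec$wells)) sel <- sel & key %in% spec$wells
    clash <- sel & !is.na(assign)
    if (any(clash)) {
      stop("wells assigned to two subsets (", nm, " and ",
           paste(unique(assign[clash]), collapse = ","), "): ",
           paste(utils::head(key[clash], 5), collapse = ", "))
    }
    assign[sel] <- nm
    if (!any(sel)) warning("empty subset: ", nm)
    out[[nm]] <- profiles[sel, , drop = FALSE]
  }
  out
}

#' Kolmogorov-Smirnov diagnostics for misclassified profiles
#'
#' For each signature feature, compares the well-level feature distribution
#' of misclassified profiles against high-confidence correctly classified
#' profiles of the same class, with a two-sample KS test -- separately for
#' sensitive and resistant clones. Comparisons with an empty group are
#' skipped with a record. P-values are reported unadjusted (they are
#' descriptive diagnostics); a Bonferroni-adjusted column is included for
#' convenience.
#'
#' @param profiles Annotated profile data.frame (well-level feature values).
#' @param predictions Output of [classify_clones()].
#' @param signature A `signature_definition`.
#' @return Data.frame: `feature`, `group_comparison`, `D`, `p`,
#'   `p_bonferroni`, `skipped`.
#' @export
ks_misclassification <- function(profiles, predictions, signature) {
  feats <- c(signature$up_features, signature$down_features)
  pred <- stats::setNames(predictions$predicted, predictions$clone_id)
  hc <- stats::setNames(predictions$high_confidence, predictions$clone_id)
  clone <- profiles$Metadata_clone_ID
  true_label <- profiles$Metadata_resistance_label
  correct <- pred[clone] == true_label

  rows <- list()
  for (cls in c("sensitive", "resistant")) {
    comparison <- paste0(cls, "_mis_vs_hc")
    mis <- which(true_label == cls & !correct)
    good <- which(true_label == cls & correct & hc[clone])
    if (length(mis) == 0 || length(good) == 0) {
      rows[[comparison]] <- data.frame(
        feature = feats, group_comparison = comparison,
        D = NA_real_, p = NA_real_, p_bonferroni = NA_real_, skipped = TRUE,
        stringsAsFactors = FALSE)
      next
    }
    res <- t(vapply(feats, function(f) {
      kt <- suppressWarnings(
        stats::ks.test(profiles[[f]][mis], profiles[[f]][good]))
      c(unname(kt$statistic), kt$p.value)
    }, numeric(2)))
    rows[[comparison]] <- data.frame(
      feature = feats, group_comparison = comparison,
      D = res[, 1], p = res[, 2],
      p_bonferroni = pmin(1, res[, 2] * length(feats)), skipped = FALSE,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
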