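#' Directional rank-based signature score (singscore) for one profile
#'
#' Ranks the signature features of a single profile (ascending, mid-ranks for
#' ties, over the `N = |up| + |down|` signature features) and converts the
#' mean rank of each direction set to a normalized score. For the up set of
#' size `n_u`, `up_score = (mean rank - rmin) / (rmax - rmin) - 0.5` with
#' `rmin = (n_u + 1)/2` and `rmax = (2N - n_u + 1)/2`; the down score is
#' computed identically on reversed ranks (`N + 1 - rank`) with `n_d`. The
#' total score is their sum and lies in `[-1, 1]`: +1 when every up feature
#' outranks every down feature, -1 for the reverse. Because only ranks enter,
#' the score is invariant to any strictly increasing transform of the profile
#' values.
#'
#' @param profile Named numeric vector (or single-row profile data.frame)
#'   mapping feature names to values.
#' @param signature A `signature_definition` (or list with `up_features` and
#'   `down_features`).
#' @return A list: `up_score`, `down_score`, `total_score`.
#' @export
singscore <- function(profile, signature) {
  if (is.data.frame(profile)) {
    if (nrow(profile) != 1) stop("profile must be a single row")
    profile <- unlist(profile[feature_cols(profile)])
  }
  up <- signature$up_features
  down <- signature$down_features
  if (length(up) == 0 || length(down) == 0) {
    stop("signature must contain both an up set and a down set")
  }
  if (anyDuplicated(c(up, down))) stop("up and down sets must be disjoint")
  absent <- setdiff(c(up, down), names(profile))
  if (length(absent) > 0) {
    stop("profile lacks signature features: ", paste(absent, collapse = ", "))
  }
  values <- profile[c(up, down)]
  if (anyNA(values)) stop("signature feature values must be non-missing")
  r <- rank(values, ties.method = "average")
  n <- length(r)
  score_set <- function(ranks, n_set) {
    rmin <- (n_set + 1) / 2
    rmax <- (2 * n - n_set + 1) / 2
    (mean(ranks) - rmin) / (rmax - rmin) - 0.5
  }
  up_score <- score_set(r[seq_along(up)], length(up))
  down_score <- score_set((n + 1 - r)[length(up) + seq_along(down)],
                          length(down))
  list(up_score = up_score, down_score = down_score,
       total_score = up_score + down_score)
}

#' Score every well profile in a table
#'
#' @param profiles Profile data.frame containing all signature features.
#' @param signature A `signature_definition`.
#' @return Data.frame with `Metadata_Plate`, `Metadata_Well`, any clone and
#'   label metadata present, and `up_score`, `down_score`, `total_score`.
#' @export
score_profiles <- function(profiles, signature) {
  feats <- c(signature$up_features, signature$down_features)
  mat <- feature_matrix(profiles, feats)
  scores <- t(apply(mat, 1, function(v) {
    s <- singscore(v, signature)
    c(s$up_score, s$down_score, s$total_score)
  }))
  meta <- intersect(c("Metadata_Plate", "Metadata_Well", "Metadata_clone_ID",
                      "Metadata_resistance_label"), names(profiles))
  out <- cbind(profiles[meta],
               data.frame(up_score = scores[, 1], down_score = scores[, 2],
                          total_score = scores[, 3]))
  rownames(out) <- NULL
  out
}

#' Permutation null distribution of signature scores
#'
#' For each profile and each of `n_permutations` permutations, the
#' value-to-feature assignment within the signature feature set is shuffled
#' and the profile rescored, yielding the distribution of scores attainable
#' by chance. The 2.5th and 97.5th percentiles of the scores pooled across
#' profiles form the 95% by-chance interval used for high-confidence calls.
#'
#' @param profiles Profile data.frame.
#' @param signature A `signature_definition`.
#' @param n_permutations Number of permutations (default 1000); fewer than
#'   100 triggers a warning (interval unstable).
#' @param seed RNG seed.
#' @return A `null_distribution` list: `permuted_scores`, `ci_low`,
#'   `ci_high`, `n_permutations`, `seed`.
#' @export
permutation_null <- function(profiles, signature, n_permutations = 1000,
                             seed = 1) {
  if (n_permutations < 100) {
    warning("fewer than 100 permutations: confidence interval is unstable")
  }
  feats <- c(signature$up_features, signature$down_features)
  mat <- feature_matrix(profiles, feats)
  n_feat <- ncol(mat)
  scores <- with_seed(derive_seed(seed, "permutation-null"), {
    out <- matrix(NA_real_, nrow = nrow(mat), ncol = n_permutations)
    for (p in seq_len(n_permutations)) {
      for (i in seq_len(nrow(mat))) {
        v <- mat[i, sample.int(n_feat)]
        names(v) <- feats
        out[i, p] <- singscore(v, signature)$total_score
      }
    }
    out
  })
  pooled <- as.vector(scores)
  ci <- stats::quantile(pooled, c(0.025, 0.975), names = FALSE)
  structure(list(permuted_scores = pooled,
                 ci_low = ci[1], ci_high = ci[2],
                 n_permutations = n_permutations, seed = seed),
            class = "null_distribution")
}

#' Classify clones from well-level signature scores
#'
#' A clone is called resistant when the median total score of its replicate
#' wells is strictly greater than zero, sensitive otherwise. The call is
#' high-confidence when the median lies outside the 95% by-chance interval
#' of the permutation null.
#'
#' @param scores Output of [score_profiles()] (must carry
#'   `Metadata_clone_ID`).
#' @param null A `null_distribution` from [permutation_null()].
#' @return Data.frame: `clone_id`, `median_score`, `predicted`,
#'   `high_confidence`, `n_wells`.
#' @export
classify_clones <- function(scores, null) {
  if (!"Metadata_clone_ID" %in% names(scores)) {
    stop("scores must carry Metadata_clone_ID")
  }
  if (anyNA(scores$Metadata_clone_ID)) stop("wells with no clone assignment")
  split_scores <- split(scores$total_score, scores$Metadata_clone_ID)
  if (any(lengths(split_scores) == 0)) stop("clone with zero wells")
  med <- vapply(split_scores, stats::median, numeric(1))
  data.frame(
    clone_id = names(med),
    median_score = unname(med),
    predicted = ifelse(med > 0, "resistant", "sensitive"),
    high_confidence = unname(med < null$ci_low | med > null$ci_high),
    n_wells = unname(lengths(split_scores)),
    stringsAsFactors = FALSE, row.names = NULL)
}
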