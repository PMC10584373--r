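# Shared fixtures, built in code.

# A small signature over named toy features.
toy_signature <- function(n_up = 2, n_down = 4) {
  structure(list(up_features = paste0("up", seq_len(n_up)),
                 down_features = paste0("dn", seq_len(n_down))),
            class = "signature_definition")
}

# A named profile vector covering a toy signature.
toy_profile <- function(signature, values) {
  stats::setNames(values,
                  c(signature$up_features, signature$down_features))
}

# A compact simulation design for fast unit tests.
small_design <- function(...) {
  args <- utils::modifyList(list(
    n_sensitive_clones = 3, n_resistant_clones = 3,
    wells_per_clone_per_batch = 3, n_batches = 2,
    n_features = 60, n_up_signal = 4, n_down_signal = 6,
    n_batch_decoys = 4, n_time_decoys = 4, n_cellcount_decoys = 4,
    n_clone_decoys = 4, n_corr_blocks = 2, block_size = 5,
    seed = 123), list(...))
  do.call(simulation_design, args)
}

# Hand-built 12-well annotated profile table: 2 sensitive + 2 resistant
# clones, 2 batches, 2 incubation arms, varying cell counts.
hand_profiles <- function(feature_values) {
  data.frame(
    Metadata_Plate = rep(c("p1", "p2"), each = 6),
    Metadata_Well = sprintf("A%02d", 1:12),
    Metadata_clone_ID = rep(c("s1", "s2", "r1", "r2"), 3),
    Metadata_resistance_label = rep(c("sensitive", "sensitive",
                                      "resistant", "resistant"), 3),
    Metadata_batch = rep(c("b1", "b2"), each = 6),
    Metadata_time = c("t1", "t1", "t1", "t1", "t2", "t2",
                      "t2", "t2", "t1", "t2", "t1", "t2"),
    Metadata_cell_count = c(900, 1100, 1000, 1250, 950, 1020,
                            1080, 990, 1130, 1010, 940, 1200),
    F1 = feature_values,
    stringsAsFactors = FALSE)
}

# Independent upper-tail studentized-range probability by direct double
# integration (oracle for the Tukey-Kramer adjusted p).
ptukey_numint <- function(q, k, df) {
  inner <- function(si) {
    f <- function(z) k * stats::dnorm(z) *
      (stats::pnorm(z) - stats::pnorm(z - q * si))^(k - 1)
    stats::integrate(f, -8, 8, rel.tol = 1e-10)$value
  }
  fs <- function(s) 2 * df^(df / 2) / gamma(df / 2) / 2^(df / 2) *
    s^(df - 1) * exp(-df * s^2 / 2)
  g <- function(s) fs(s) * vapply(s, inner, numeric(1))
  1 - stats::integrate(g, 0, 5, rel.tol = 1e-10)$value
}

# Pair-counting AUROC oracle: ties count one half.
auroc_paircount <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Brute-force average precision over explicit threshold sweeps.
ap_bruteforce <- function(scores, truth) {
  cuts <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  total <- 0
  for (cut in cuts) {
    tp <- 0; fp <- 0
    for (i in seq_along(scores)) {
      if (scores[i] >= cut) {
        if (truth[i]) tp <- tp + 1 else fp <- fp + 1
      }
    }
    precision <- tp / (tp + fp)
    recall <- tp / sum(truth)
    total <- total + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  total
}

# Brute-force two-sample KS statistic: max ECDF gap over pooled points.
ks_d_bruteforce <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(vapply(pts, function(t) {
    abs(mean(x <= t) - mean(y <= t))
  }, numeric(1)))
}
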