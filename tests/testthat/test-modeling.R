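test_that("identical groups give zero difference and p = 1", {
  x <- rep(c(1, 2, 3), 2)
  g <- rep(c("a", "b"), each = 3)
  out <- tukey_hsd(x, g)
  expect_equal(out$mean_diff, 0)
  expect_equal(out$adjusted_p, 1)
})

test_that("well-separated groups are detected, overlapping ones are not", {
  set.seed(42)
  x <- c(rnorm(10, 0, 0.1), rnorm(10, 0, 0.1), rnorm(10, 10, 0.1))
  g <- rep(c("g1", "g2", "g3"), each = 10)
  out <- tukey_hsd(x, g)
  key <- paste(out$level_a, out$level_b)
  p <- setNames(out$adjusted_p, key)
  expect_lt(p[["g1 g3"]], 1e-6)
  expect_lt(p[["g2 g3"]], 1e-6)
  expect_gt(p[["g1 g2"]], 0.05)
})

test_that("adjusted p matches an independent studentized-range evaluation", {
  # fixed 3 x 8 table
  set.seed(7)
  x <- c(rnorm(8, 0), rnorm(8, 0.8), rnorm(8, 1.6))
  g <- rep(c("a", "b", "c"), each = 8)
  mine <- tukey_hsd(x, g)

  ref <- TukeyHSD(aov(x ~ g))$g  # base stats reference implementation
  ref_p <- ref[paste0(mine$level_b, "-", mine$level_a), "p adj"]
  expect_equal(mine$adjusted_p, unname(ref_p), tolerance = 1e-8)

  # direct numerical integration of the studentized range distribution
  means <- tapply(x, g, mean)
  msw <- sum((x - means[g])^2) / (length(x) - 3)
  for (i in seq_len(nrow(mine))) {
    diff <- mine$mean_diff[i]
    q <- abs(diff) / sqrt(msw / 2 * (1 / 8 + 1 / 8))
    expect_equal(mine$adjusted_p[i], ptukey_numint(q, 3, 21),
                 tolerance = 1e-6)
  }
})

test_that("unequal group sizes use the Tukey-Kramer standard error", {
  set.seed(11)
  x <- c(rnorm(5, 0), rnorm(12, 1), rnorm(8, 2))
  g <- rep(c("a", "b", "c"), c(5, 12, 8))
  mine <- tukey_hsd(x, g)
  ref <- TukeyHSD(aov(x ~ g))$g
  ref_p <- ref[paste0(mine$level_b, "-", mine$level_a), "p adj"]
  expect_equal(mine$adjusted_p, unname(ref_p), tolerance = 1e-8)
})

test_that("Tukey adjustment is never anti-conservative", {
  set.seed(33)
  for (rep in 1:20) {
    k <- sample(3:5, 1)
    n <- sample(4:8, k, replace = TRUE)
    x <- rnorm(sum(n), mean = rep(runif(k, 0, 2), n))
    g <- rep(letters[1:k], n)
    out <- tukey_hsd(x, g)
    means <- tapply(x, g, mean)
    msw <- sum((x - means[g])^2) / (sum(n) - k)
    for (i in seq_len(nrow(out))) {
      na <- n[match(out$level_a[i], letters[1:k])]
      nb <- n[match(out$level_b[i], letters[1:k])]
      t_stat <- abs(out$mean_diff[i]) / sqrt(msw * (1 / na + 1 / nb))
      p_unadj <- 2 * pt(-t_stat, df = sum(n) - k)
      expect_gte(out$adjusted_p[i], p_unadj - 1e-12)
    }
  }
})

test_that("groups with fewer than two observations are rejected", {
  expect_error(tukey_hsd(c(1, 2, 3), c("a", "a", "b")), ">= 2 observations")
  expect_error(tukey_hsd(c(1, 2), c("a", "a")), "at least 2 groups")
})

test_that("noiseless resistance effect is recovered exactly", {
  prof <- hand_profiles(rep(0, 12))
  prof$F1 <- 1 + 2 * (prof$Metadata_resistance_label == "resistant")
  fit <- fit_model_one(prof, "F1")
  expect_equal(unname(fit$betas["resistance_status"]), 2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
})

test_that("covariate-model betas equal the normal-equation solution", {
  set.seed(3)
  prof <- hand_profiles(rnorm(12))
  fit <- fit_model_one(prof, "F1")
  X <- morphsig:::covariate_design_matrix(prof)
  beta_ref <- solve(t(X) %*% X, t(X) %*% prof$F1)[, 1]
  expect_equal(fit$betas, beta_ref, tolerance = 1e-10)
  expect_equal(sum(fit$residuals), 0, tolerance = 1e-8)
})

test_that("cell-count slope and its p-value behave as OLS theory predicts", {
  set.seed(5)
  n <- 100
  prof <- data.frame(
    Metadata_Plate = "p1", Metadata_Well = sprintf("A%03d", 1:n),
    Metadata_clone_ID = rep(c("s1", "r1"), n / 2),
    Metadata_resistance_label = rep(c("sensitive", "resistant"), n / 2),
    Metadata_batch = "b1", Metadata_time = "t1",
    Metadata_cell_count = rnorm(n, 10, 1))
  prof$F1 <- 0.5 * prof$Metadata_cell_count + rnorm(n, sd = 0.01)
  fit <- fit_model_two(prof, "F1")
  expect_true(fit$betas["cell_count"] > 0.45 && fit$betas["cell_count"] < 0.55)
  expect_lt(fit$cellcount_p, 1e-6)

  prof$F1 <- 2 + 3 * prof$Metadata_cell_count  # zero noise
  expect_equal(fit_model_two(prof, "F1")$r_squared, 1, tolerance = 1e-10)

  prof$Metadata_cell_count <- 7
  expect_error(fit_model_two(prof, "F1"), "varying")
})

test_that("model results are invariant to covariate level labels", {
  set.seed(9)
  sim <- simulate_profiles(small_design(seed = 44))
  prof <- sim$profiles
  f <- feature_cols(prof)[1]
  fit_a <- fit_model_one(prof, f)
  # rename batches so their lexicographic order flips
  prof2 <- prof
  prof2$Metadata_batch <- ifelse(prof$Metadata_batch == "batch_1",
                                 "z_run", "a_run")
  fit_b <- fit_model_one(prof2, f)
  expect_equal(fit_a$tukey$resistance_status$adjusted_p,
               fit_b$tukey$resistance_status$adjusted_p, tolerance = 1e-10)
  expect_equal(fit_a$r_squared, fit_b$r_squared, tolerance = 1e-10)
  expect_equal(unname(fit_a$betas["resistance_status"]),
               unname(fit_b$betas["resistance_status"]), tolerance = 1e-10)
  expect_equal(sort(abs(fit_a$tukey$batch$mean_diff)),
               sort(abs(fit_b$tukey$batch$mean_diff)), tolerance = 1e-10)
})

test_that("a feature differing in two sensitive clones is excluded", {
  d <- small_design(n_sensitive_clones = 5, n_resistant_clones = 5,
                    wells_per_clone_per_batch = 4,
                    effect_resistance = 0, effect_batch = 0, effect_time = 0,
                    effect_clone = 0, cellcount_slope = 0, n_corr_blocks = 0,
                    n_features = 30, n_up_signal = 0, n_down_signal = 0,
                    n_batch_decoys = 0, n_time_decoys = 0,
                    n_cellcount_decoys = 0, n_clone_decoys = 0, seed = 55)
  sim <- simulate_profiles(d)
  prof <- sim$profiles
  f <- feature_cols(prof)[1]
  shifted <- prof$Metadata_clone_ID %in% c("WT01", "WT02")
  prof[[f]] <- prof[[f]] + 5 * shifted
  r1 <- fit_covariate_models(prof)
  r2 <- fit_cellcount_models(prof)
  sig <- build_signature(r1, r2)
  row <- sig$ledger[sig$ledger$feature == f, ]
  expect_match(row$excluded_by, "clone_pairs")
})

test_that("signature membership is monotone in alpha", {
  sim <- simulate_profiles(small_design(effect_resistance = 1.2, seed = 66))
  r1 <- fit_covariate_models(sim$profiles)
  r2 <- fit_cellcount_models(sim$profiles)
  wide <- build_signature(r1, r2, alpha = 0.05)
  narrow <- build_signature(r1, r2, alpha = 0.005)
  expect_true(all(narrow$up_features %in% wide$up_features))
  expect_true(all(narrow$down_features %in% wide$down_features))
  # ledger covers every feature exactly once
  expect_setequal(wide$ledger$feature,
                  vapply(r1, `[[`, character(1), "feature"))
  expect_equal(anyDuplicated(wide$ledger$feature), 0)
  in_sig <- wide$ledger$feature %in% c(wide$up_features, wide$down_features)
  expect_equal(in_sig, wide$ledger$excluded_by == "")
})

test_that("signature directions follow the resistance coefficient", {
  sim <- simulate_profiles(small_design(effect_resistance = 3, seed = 77))
  r1 <- fit_covariate_models(sim$profiles)
  r2 <- fit_cellcount_models(sim$profiles)
  sig <- build_signature(r1, r2)
  expect_setequal(sig$up_features, sim$truth$up_signal)
  expect_setequal(sig$down_features, sim$truth$down_signal)
})

test_that("signature JSON and table exports round-trip", {
  sim <- simulate_profiles(small_design(effect_resistance = 3, seed = 78))
  sig <- build_signature(fit_covariate_models(sim$profiles),
                         fit_cellcount_models(sim$profiles))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "sig.json")
  write_signature(sig, p)
  sig2 <- read_signature(p)
  expect_equal(sig2$up_features, sig$up_features)
  expect_equal(sig2$down_features, sig$down_features)
  expect_equal(sig2$threshold, sig$threshold)
})
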