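test_that("platemap fully crosses clone, batch, time and replicates", {
  d <- simulation_design(n_sensitive_clones = 1, n_resistant_clones = 1,
                         wells_per_clone_per_batch = 3, n_batches = 1,
                         incubation_levels = "4h", n_features = 10,
                         n_up_signal = 1, n_down_signal = 1,
                         n_batch_decoys = 0, n_time_decoys = 0,
                         n_cellcount_decoys = 0, n_clone_decoys = 0,
                         n_corr_blocks = 0, seed = 1)
  pm <- generate_platemap(d)
  expect_equal(nrow(pm), 6)
  expect_equal(as.integer(table(pm$clone_id)), c(3L, 3L))
  expect_false(anyDuplicated(paste(pm$plate_id, pm$well_id)) > 0)

  d2 <- small_design()
  pm2 <- generate_platemap(d2)
  cross <- table(pm2$clone_id, pm2$batch, pm2$incubation_time)
  expect_true(all(cross == d2$wells_per_clone_per_batch))
  # every clone maps to exactly one resistance label
  expect_true(all(tapply(pm2$resistance_label, pm2$clone_id,
                         function(x) length(unique(x))) == 1))
})

test_that("serpentine layout alternates row direction", {
  d <- simulation_design(n_sensitive_clones = 2, n_resistant_clones = 2,
                         wells_per_clone_per_batch = 3, n_batches = 1,
                         incubation_levels = "4h", plate_rows = 2,
                         plate_cols = 6, n_features = 10,
                         n_up_signal = 1, n_down_signal = 1,
                         n_batch_decoys = 0, n_time_decoys = 0,
                         n_cellcount_decoys = 0, n_clone_decoys = 0,
                         n_corr_blocks = 0, seed = 1)
  pm <- generate_platemap(d)
  row_a <- pm$column[pm$row == 1]
  row_b <- pm$column[pm$row == 2]
  expect_equal(row_a, sort(row_a))                 # left to right
  expect_equal(row_b, sort(row_b, decreasing = TRUE))  # right to left
})

test_that("layout assigns consecutive clones to consecutive wells", {
  d <- small_design()
  pm <- generate_platemap(d)
  first_six <- pm$clone_id[1:6]
  expect_equal(length(unique(first_six)), 6)
})

test_that("designs exceeding plate capacity raise a capacity error", {
  expect_error(
    generate_platemap(small_design(wells_per_clone_per_batch = 10)),
    "overflow")
})

test_that("same design and seed reproduce identical outputs", {
  d <- small_design(seed = 99)
  s1 <- simulate_profiles(d)
  s2 <- simulate_profiles(d)
  expect_identical(s1$profiles, s2$profiles)
  expect_identical(s1$platemap, s2$platemap)
  expect_identical(s1$truth, s2$truth)
})

test_that("planted sets are disjoint and within the feature universe", {
  tr <- simulate_profiles(small_design())$truth
  sets <- c(list(tr$up_signal, tr$down_signal), unname(tr$decoys))
  all_names <- unlist(sets)
  expect_equal(anyDuplicated(all_names), 0)
  expect_true(all(all_names %in%
                    feature_cols(simulate_profiles(small_design())$profiles)))
})

test_that("null design produces no class differences beyond noise", {
  d <- small_design(effect_resistance = 0, effect_batch = 0,
                    effect_time = 0, effect_clone = 0, cellcount_slope = 0,
                    wells_per_clone_per_batch = 6, seed = 5)
  sim <- simulate_profiles(d)
  prof <- sim$profiles
  res <- prof$Metadata_resistance_label == "resistant"
  n_per_class <- min(sum(res), sum(!res))
  bound <- 4 * d$noise_sd / sqrt(n_per_class)
  diffs <- vapply(feature_cols(prof), function(f) {
    mean(prof[[f]][res]) - mean(prof[[f]][!res])
  }, numeric(1))
  expect_true(all(abs(diffs) < bound))
})

test_that("noiseless limit recovers the planted resistance shift exactly", {
  d <- small_design(noise_sd = 1e-9, effect_resistance = 1,
                    effect_batch = 0, effect_time = 0, effect_clone = 0,
                    cellcount_slope = 0, n_corr_blocks = 0, seed = 2)
  sim <- simulate_profiles(d)
  prof <- sim$profiles
  res <- prof$Metadata_resistance_label == "resistant"
  up <- sim$truth$up_signal[1]
  dn <- sim$truth$down_signal[1]
  expect_equal(mean(prof[[up]][res]) - mean(prof[[up]][!res]), 1,
               tolerance = 1e-6)
  expect_equal(mean(prof[[dn]][res]) - mean(prof[[dn]][!res]), -1,
               tolerance = 1e-6)
})

test_that("latent-factor blocks induce the specified correlation", {
  d <- small_design(n_sensitive_clones = 4, n_resistant_clones = 4,
                    wells_per_clone_per_batch = 5, n_batches = 3,
                    n_features = 40, n_up_signal = 0, n_down_signal = 0,
                    n_batch_decoys = 0, n_time_decoys = 0,
                    n_cellcount_decoys = 0, n_clone_decoys = 0,
                    n_corr_blocks = 1, block_size = 10, block_rho = 0.95,
                    seed = 31)
  sim <- simulate_profiles(d)
  expect_gte(nrow(sim$profiles), 200)
  # the block features are the ones with high mutual correlation
  cm <- cor(feature_matrix(sim$profiles))
  diag(cm) <- 0
  linked <- colnames(cm)[colSums(cm > 0.8) > 0]
  expect_equal(length(linked), 10)
  expect_true(all(cm[linked, linked][upper.tri(diag(10))] > 0.8))
})

test_that("planted resistance effects are recoverable by a t statistic", {
  # effect 2 SD, >= 20 wells per class: nearly every signal feature should
  # show |t| > 5
  hits <- 0; total <- 0
  for (seed in 1:3) {
    d <- small_design(effect_resistance = 2, wells_per_clone_per_batch = 4,
                      seed = seed)
    sim <- simulate_profiles(d)
    prof <- sim$profiles
    res <- prof$Metadata_resistance_label == "resistant"
    for (f in c(sim$truth$up_signal, sim$truth$down_signal)) {
      t_stat <- abs(t.test(prof[[f]][res], prof[[f]][!res])$statistic)
      hits <- hits + (t_stat > 5)
      total <- total + 1
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("batch decoys carry a detectable between-batch signal", {
  d <- small_design(n_batches = 3, seed = 17)
  sim <- simulate_profiles(d)
  prof <- sim$profiles
  batch <- factor(prof$Metadata_batch)
  crit <- qf(0.99, df1 = nlevels(batch) - 1,
             df2 = nrow(prof) - nlevels(batch))
  f_stats <- vapply(sim$truth$decoys$batch, function(f) {
    summary(aov(prof[[f]] ~ batch))[[1]]$`F value`[1]
  }, numeric(1))
  expect_true(all(f_stats > crit))
})

test_that("fixtures round-trip through the readers", {
  d <- small_design(seed = 8)
  sim <- simulate_profiles(d)
  dir <- withr::local_tempdir()
  paths <- write_fixtures(sim$profiles, sim$platemap, sim$truth, dir)
  prof2 <- read_profiles(paths[["profiles"]])
  expect_equal(dim(prof2), dim(sim$profiles))
  expect_equal(feature_matrix(prof2), feature_matrix(sim$profiles),
               tolerance = 1e-12)
  truth2 <- read_ground_truth(paths[["truth"]])
  expect_setequal(truth2$up_signal, sim$truth$up_signal)
  expect_setequal(truth2$down_signal, sim$truth$down_signal)
  expect_setequal(truth2$decoys$batch, sim$truth$decoys$batch)

  # degenerate: empty table writes header only
  empty <- sim$profiles[0, ]
  p <- file.path(dir, "empty.csv")
  write_profiles(empty, p)
  expect_equal(length(readLines(p)), 1)
})

test_that("invalid designs are rejected", {
  expect_error(small_design(n_features = 5), "exceed")
  expect_error(small_design(block_rho = 1), "block_rho")
  expect_error(small_design(noise_sd = 0), "noise_sd")
})
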