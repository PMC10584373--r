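#' Tukey-Kramer honestly-significant-difference test
#'
#' All pairwise group-mean comparisons with family-wise error control from
#' the studentized-range distribution, in the unequal-group-size
#' (Tukey-Kramer) form: for groups i, j the statistic is
#' `q = |mean_i - mean_j| / sqrt(MSW * (1/n_i + 1/n_j) / 2)` with `MSW` the
#' pooled within-group mean square on `N - k` degrees of freedom, and the
#' adjusted p-value is the upper tail of the studentized range with k means.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (coerced to factor).
#' @return Data.frame with one row per unordered level pair: `level_a`,
#'   `level_b` (sorted level order), `mean_diff` (`level_b - level_a`),
#'   `adjusted_p`.
#' @export
tukey_hsd <- function(values, groups) {
  groups <- factor(as.character(groups))
  if (length(values) != length(groups)) stop("length mismatch")
  k <- nlevels(groups)
  if (k < 2) stop("need at least 2 groups")
  n_i <- tabulate(groups)
  if (any(n_i < 2)) {
    stop("every group needs >= 2 observations; offending: ",
         paste(levels(groups)[n_i < 2], collapse = ", "))
  }
  lev <- sort(levels(groups))
  groups <- factor(groups, levels = lev)
  n_i <- tabulate(groups)
  means <- tapply(values, groups, mean)
  ssw <- sum((values - means[groups])^2)
  df <- length(values) - k
  msw <- ssw / df

  pairs <- utils::combn(lev, 2)
  mean_diff <- means[pairs[2, ]] - means[pairs[1, ]]
  se <- sqrt(msw / 2 * (1 / n_i[match(pairs[1, ], lev)] +
                          1 / n_i[match(pairs[2, ], lev)]))
  q <- abs(mean_diff) / se
  p <- ifelse(se > 0,
              stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE),
              ifelse(mean_diff == 0, 1, 0))
  data.frame(level_a = pairs[1, ], level_b = pairs[2, ],
             mean_diff = unname(mean_diff), adjusted_p = unname(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Vectorized Tukey-Kramer across the columns of a feature matrix. Returns a
# list of data.frames keyed by "a|b" pair, each with per-feature diff and p.
tukey_hsd_matrix <- function(Y, groups) {
  groups <- factor(as.character(groups))
  lev <- sort(levels(groups))
  groups <- factor(groups, levels = lev)
  k <- length(lev)
  n_i <- tabulate(groups)
  if (k < 2 || any(n_i < 2)) stop("need >= 2 groups with >= 2 observations")
  sums <- rowsum(Y, groups)
  means <- sums / n_i
  ssw <- colSums(Y^2) - colSums(means^2 * n_i)
  df <- nrow(Y) - k
  msw <- pmax(ssw / df, 0)
  pairs <- utils::combn(seq_len(k), 2)
  out <- vector("list", ncol(pairs))
  for (idx in seq_len(ncol(pairs))) {
    i <- pairs[1, idx]; j <- pairs[2, idx]
    diff <- means[j, ] - means[i, ]
    se <- sqrt(msw / 2 * (1 / n_i[i] + 1 / n_i[j]))
    q <- abs(diff) / se
    p <- ifelse(se > 0,
                stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE),
                ifelse(diff == 0, 1, 0))
    out[[idx]] <- data.frame(level_a = lev[i], level_b = lev[j],
                             feature = colnames(Y), mean_diff = unname(diff),
                             adjusted_p = unname(p),
                             stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}

required_model_cols <- function(profiles, cols) {
  missing <- setdiff(cols, names(profiles))
  if (length(missing) > 0) {
    stop("profiles lack required metadata columns: ",
         paste(missing, collapse = ", "))
  }
}

# Design matrix for the covariate model: intercept, resistance indicator
# (resistant = 1), treatment-coded batch and incubation time (reference =
# lexicographically first level), and clone ID deviation-coded within each
# resistance class. Clones are perfectly nested in resistance status, so
# plain dummy coding of both would be rank-deficient; the within-class
# sum-to-zero coding keeps the resistance main effect identifiable while
# still absorbing clone-to-clone variation.
covariate_design_matrix <- function(profiles) {
  required_model_cols(profiles, c("Metadata_resistance_label",
                                  "Metadata_batch", "Metadata_time",
                                  "Metadata_clone_ID"))
  n <- nrow(profiles)
  resistant <- as.numeric(profiles$Metadata_resistance_label == "resistant")
  X <- cbind(intercept = rep(1, n), resistance_status = resistant)

  dummy_block <- function(values, prefix) {
    lev <- sort(unique(as.character(values)))
    if (length(lev) < 2) return(NULL)
    cols <- sapply(lev[-1], function(l) as.numeric(values == l))
    colnames(cols) <- paste0(prefix, lev[-1])
    cols
  }
  X <- cbind(X, dummy_block(profiles$Metadata_batch, "batch_"))
  X <- cbind(X, dummy_block(profiles$Metadata_time, "time_"))

  for (cls in sort(unique(profiles$Metadata_resistance_label))) {
    in_cls <- profiles$Metadata_resistance_label == cls
    clones <- sort(unique(profiles$Metadata_clone_ID[in_cls]))
    if (length(clones) < 2) next
    ref <- clones[length(clones)]
    for (cl in clones[-length(clones)]) {
      col <- numeric(n)
      col[profiles$Metadata_clone_ID == cl] <- 1
      col[profiles$Metadata_clone_ID == ref] <- -1
      X <- cbind(X, col)
      colnames(X)[ncol(X)] <- paste0("clone_", cl)
    }
  }
  if (qr(X)$rank < ncol(X)) stop("rank-deficient covariate design matrix")
  X
}

cellcount_design_matrix <- function(profiles) {
  required_model_cols(profiles, c("Metadata_resistance_label",
                                  "Metadata_cell_count"))
  counts <- profiles$Metadata_cell_count
  if (!is.numeric(counts) || stats::var(counts) == 0) {
    stop("cell_count must be numeric and varying")
  }
  cbind(intercept = 1,
        resistance_status =
          as.numeric(profiles$Metadata_resistance_label == "resistant"),
        cell_count = counts)
}

ols_fit_matrix <- function(X, Y) {
  if (nrow(X) - ncol(X) < 1) stop("no residual degrees of freedom")
  fit <- stats::lm.fit(X, Y)
  coefs <- fit$coefficients
  if (is.null(dim(coefs))) coefs <- matrix(coefs, ncol = 1,
                                           dimnames = list(names(coefs), NULL))
  res <- fit$residuals
  if (is.null(dim(res))) res <- matrix(res, ncol = 1)
  tss <- colSums(sweep(Y, 2, colMeans(Y), "-")^2)
  rss <- colSums(res^2)
  r2 <- ifelse(tss > 0, 1 - rss / tss, 0)
  list(coefficients = coefs, residuals = res, r_squared = r2,
       df_residual = nrow(X) - ncol(X), rss = rss)
}

# Residuals of all features after removing batch and incubation-time effects
# (used for the clone-level post-hoc comparisons).
batch_time_residuals <- function(profiles, Y) {
  n <- nrow(profiles)
  X <- cbind(intercept = rep(1, n))
  bt <- function(values, prefix) {
    lev <- sort(unique(as.character(values)))
    if (length(lev) < 2) return(NULL)
    cols <- sapply(lev[-1], function(l) as.numeric(values == l))
    colnames(cols) <- paste0(prefix, lev[-1])
    cols
  }
  X <- cbind(X, bt(profiles$Metadata_batch, "batch_"))
  X <- cbind(X, bt(profiles$Metadata_time, "time_"))
  stats::lm.fit(X, Y)$residuals
}

#' Fit the per-feature covariate model with post-hoc screening
#'
#' Ordinary least squares of one morphology feature on resistance status,
#' batch, incubation time and clone ID
#' (`Y = b0 + b_res X_res + b_batch X_batch + b_time X_time + b_clone X_clone + e`),
#' followed by Tukey-Kramer post-hoc comparisons for each categorical
#' covariate. Resistance, batch and time comparisons are one-way tests on
#' the feature values; clone comparisons are one-way tests on the residuals
#' after removing batch and time effects, because clones are nested in
#' resistance class (see [covariate_design_matrix()]).
#'
#' @param profiles Annotated, normalized profile data.frame.
#' @param feature Feature column name.
#' @return A `feature_model` list: `feature`, `betas`, `r_squared`,
#'   `residuals`, `tukey` (named list of comparison data.frames per
#'   covariate), `clone_class` (clone to class map).
#' @export
fit_model_one <- function(profiles, feature) {
  fit_covariate_models(profiles, feature)[[1]]
}

#' Fit the covariate model for many features at once
#'
#' Vectorized counterpart of [fit_model_one()] sharing one design-matrix
#' factorization across features.
#'
#' @param profiles Annotated, normalized profile data.frame.
#' @param features Feature names (default: all feature columns).
#' @return Named list of `feature_model` objects.
#' @export
fit_covariate_models <- function(profiles, features = NULL) {
  if (is.null(features)) features <- feature_cols(profiles)
  Y <- feature_matrix(profiles, features)
  X <- covariate_design_matrix(profiles)
  fit <- ols_fit_matrix(X, Y)

  tk <- list(
    resistance_status = tukey_hsd_matrix(Y, profiles$Metadata_resistance_label)
  )
  if (length(unique(profiles$Metadata_batch)) > 1) {
    tk$batch <- tukey_hsd_matrix(Y, profiles$Metadata_batch)
  }
  if (length(unique(profiles$Metadata_time)) > 1) {
    tk$incubation_time <- tukey_hsd_matrix(Y, profiles$Metadata_time)
  }
  if (length(unique(profiles$Metadata_clone_ID)) > 1) {
    res_bt <- batch_time_residuals(profiles, Y)
    if (is.null(dim(res_bt))) res_bt <- matrix(res_bt, ncol = 1)
    colnames(res_bt) <- colnames(Y)
    tk$clone_id <- tukey_hsd_matrix(res_bt, profiles$Metadata_clone_ID)
  }

  clone_class <- tapply(as.character(profiles$Metadata_resistance_label),
                        profiles$Metadata_clone_ID,
                        function(x) unique(x)[1])

  tk_split <- lapply(tk, function(tab) {
    tab$feature <- factor(tab$feature, levels = features)
    split(tab[c("level_a", "level_b", "mean_diff", "adjusted_p")],
          tab$feature)
  })
  out <- lapply(seq_along(features), function(i) {
    f <- features[i]
    tukey <- lapply(tk_split, function(s) {
      sub <- s[[f]]
      rownames(sub) <- NULL
      sub
    })
    structure(list(feature = f,
                   betas = fit$coefficients[, i],
                   r_squared = unname(fit$r_squared[i]),
                   residuals = unname(fit$residuals[, i]),
                   tukey = tukey,
                   clone_class = clone_class,
                   model = "covariate"),
              class = "feature_model")
  })
  names(out) <- features
  out
}

#' Fit the per-feature cell-count model
#'
#' OLS of one feature on resistance status and per-well cell count
#' (`Y = b0 + b_res X_res + b_count X_count + e`), used to screen features
#' that track well confluence rather than resistance. `cellcount_p` is the
#' two-sided t-test p-value of the cell-count slope.
#'
#' @inheritParams fit_model_one
#' @return A `feature_model` list with `betas`, `r_squared`, `residuals`,
#'   `cellcount_p`.
#' @export
fit_model_two <- function(profiles, feature) {
  fit_cellcount_models(profiles, feature)[[1]]
}

#' @rdname fit_model_two
#' @param features Feature names (default: all feature columns).
#' @export
fit_cellcount_models <- function(profiles, features = NULL) {
  if (is.null(features)) features <- feature_cols(profiles)
  Y <- feature_matrix(profiles, features)
  X <- cellcount_design_matrix(profiles)
  fit <- ols_fit_matrix(X, Y)
  xtx_inv <- chol2inv(chol(crossprod(X)))
  sigma2 <- fit$rss / fit$df_residual
  se <- sqrt(sigma2 * xtx_inv[3, 3])
  tval <- fit$coefficients["cell_count", ] / se
  pval <- 2 * stats::pt(-abs(tval), df = fit$df_residual)

  out <- lapply(seq_along(features), function(i) {
    structure(list(feature = features[i],
                   betas = fit$coefficients[, i],
                   r_squared = unname(fit$r_squared[i]),
                   residuals = unname(fit$residuals[, i]),
                   cellcount_p = unname(pval[i]),
                   model = "cellcount"),
              class = "feature_model")
  })
  names(out) <- features
  out
}

#' @export
print.feature_model <- function(x, ...) {
  cat(sprintf("<feature_model '%s' (%s)> R^2 = %.3f\n",
              x$feature, x$model, x$r_squared))
  print(round(x$betas, 4))
  invisible(x)
}
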