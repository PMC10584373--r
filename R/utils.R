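#' @keywords internal
"_PACKAGE"

METADATA_PREFIX <- "Metadata_"

#' Metadata and feature column helpers
#'
#' Well-level profile tables carry per-well annotations in columns prefixed
#' `Metadata_` and numeric morphology features in all remaining columns.
#' These helpers split a profile table by that convention.
#'
#' @param profiles A profile data.frame.
#' @return Character vector of column names.
#' @export
metadata_cols <- function(profiles) {
  grep(paste0("^", METADATA_PREFIX), names(profiles), value = TRUE)
}

#' @rdname metadata_cols
#' @export
feature_cols <- function(profiles) {
  setdiff(names(profiles), metadata_cols(profiles))
}

#' Extract the feature block of a profile table as a numeric matrix
#'
#' @param profiles A profile data.frame.
#' @param features Optional subset of feature columns to extract.
#' @return Numeric matrix, wells in rows, features in columns.
#' @export
feature_matrix <- function(profiles, features = NULL) {
  if (is.null(features)) features <- feature_cols(profiles)
  missing <- setdiff(features, names(profiles))
  if (length(missing) > 0) {
    stop("features absent from profile table: ",
         paste(missing, collapse = ", "))
  }
  as.matrix(profiles[, features, drop = FALSE])
}

# Derive a child RNG seed from a master seed and a stream label, so that
# logically distinct sources of randomness (layout, effects, noise, ...)
# do not reshuffle each other when one design field changes. Kept < 2^31.
derive_seed <- function(seed, stream) {
  salt <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.double(seed) * 48271 + salt) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stopifnot_scalar_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
      x != round(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min))
  }
}

#' Read and write delimited profile tables
#'
#' Profile tables and plate maps are exchanged as delimited text (comma by
#' default) with `Metadata_`-prefixed annotation columns.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return A data.frame.
#' @export
read_profiles <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  df
}

#' @rdname read_profiles
#' @param x Data.frame to write.
#' @export
write_profiles <- function(x, path, sep = ",") {
  utils::write.table(x, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
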