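#' Read a breakthrough-curve table from delimited text
#'
#' Reads a CSV/TSV file holding fixed-bed breakthrough observations with four
#' predictors -- initial concentration `c0` (mg/L), bed height `h0` (cm), flow
#' velocity `u`, run time `t` (min) -- and the dimensionless outlet ratio
#' `ratio` = C/C0. Column names in the file are resolved through `column_map`,
#' so the supplementary table of a study can be used after a one-off rename or
#' by pointing the map at its headers.
#'
#' Validation enforces the physical constraints of a breakthrough experiment:
#' `c0`, `h0`, `u` strictly positive, `t >= 0`, and `ratio` in \[0, 1.05\]
#' (small experimental overshoot above 1 is tolerated; larger values are
#' rejected as data errors).
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping the canonical names
#'   `c0, h0, u, t, ratio` to the column names used in the file.
#' @param sep Field separator; `""` (default) lets [utils::read.table()]
#'   treat any whitespace, `","` forces CSV.
#' @return A `data.frame` with columns `c0, h0, u, t, ratio`, rows in file
#'   order.
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' write.csv(data.frame(c0 = 24, h0 = 7, u = 160, t = c(0, 30, 60),
#'                      ratio = c(0.01, 0.4, 0.9)), tmp, row.names = FALSE)
#' read_breakthrough(tmp)
#' @export
read_breakthrough <- function(path,
                              column_map = c(c0 = "c0", h0 = "h0", u = "u",
                                             t = "t", ratio = "ratio"),
                              sep = ",") {
  required <- c("c0", "h0", "u", "t", "ratio")
  if (!all(required %in% names(column_map)))
    stop("column_map must name all of: ", paste(required, collapse = ", "))
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty dataset: ", path)
  missing_cols <- setdiff(unname(column_map[required]), names(raw))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  out <- raw[, unname(column_map[required])]
  names(out) <- required
  for (col in required) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(v) & !is.na(out[[col]]) | is.na(out[[col]]))
    if (length(bad))
      stop("unparsable or missing numeric value in column '", col,
           "', row ", bad[1L])
    out[[col]] <- v
  }
  validate_breakthrough(out)
  message(sprintf("read %d breakthrough records from %s", nrow(out), path))
  out
}

#' @noRd
validate_breakthrough <- function(data) {
  stopifnot(is.data.frame(data))
  required <- c("c0", "h0", "u", "t", "ratio")
  if (!all(required %in% names(data)))
    stop("breakthrough data must have columns ",
         paste(required, collapse = ", "))
  for (col in c("c0", "h0", "u")) {
    bad <- which(data[[col]] <= 0)
    if (length(bad))
      stop("non-positive ", col, " at row ", bad[1L])
  }
  bad_t <- which(data$t < 0)
  if (length(bad_t)) stop("negative run time at row ", bad_t[1L])
  bad_r <- which(data$ratio < 0 | data$ratio > 1.05)
  if (length(bad_r))
    stop("ratio outside [0, 1.05] at row ", bad_r[1L],
         " (value ", data$ratio[bad_r[1L]], ")")
  invisible(data)
}

#' Fit a min-max normalizer mapping each feature to \[-1, 1\]
#'
#' Records column-wise minima and maxima so that each feature `D` can be
#' mapped to `D_N = 2 (D - D_min) / (D_max - D_min) - 1`. Fitting on the
#' training partition only (the default in [btlssvm()]) avoids information
#' leakage from the test set.
#'
#' @param data A data.frame of numeric columns.
#' @param columns Character vector of columns to include (default: all).
#' @return An object of class `minmax_spec`: a list with numeric vectors
#'   `min` and `max`, one entry per feature.
#' @seealso [normalize_data()], [denormalize_data()]
#' @export
fit_normalizer <- function(data, columns = names(data)) {
  stopifnot(is.data.frame(data), nrow(data) >= 1L)
  mins <- vapply(data[columns], min, numeric(1))
  maxs <- vapply(data[columns], max, numeric(1))
  flat <- which(maxs <= mins)
  if (length(flat))
    stop("constant column(s), zero range: ",
         paste(columns[flat], collapse = ", "))
  structure(list(min = mins, max = maxs), class = "minmax_spec")
}

#' @export
print.minmax_spec <- function(x, ...) {
  cat("min-max normalizer to [-1, 1]\n")
  print(data.frame(min = x$min, max = x$max))
  invisible(x)
}

#' Apply a fitted min-max map
#'
#' Maps each stored feature affinely so the fitted minimum goes to -1 and the
#' fitted maximum to +1. Values outside the fitted range map outside
#' \[-1, 1\] without clipping; a warning flags the extrapolation.
#'
#' @param spec A `minmax_spec` from [fit_normalizer()].
#' @param data Data.frame containing (at least) the fitted columns, in
#'   original units.
#' @param warn_extrapolation Warn when any value falls outside the fitted
#'   range (default TRUE).
#' @return Data.frame of the fitted columns on the \[-1, 1\] scale.
#' @export
normalize_data <- function(spec, data, warn_extrapolation = TRUE) {
  stopifnot(inherits(spec, "minmax_spec"))
  cols <- names(spec$min)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    stop("data lacks fitted column(s): ", paste(missing_cols, collapse = ", "))
  out <- data[cols]
  for (col in cols) {
    rng <- spec$max[[col]] - spec$min[[col]]
    out[[col]] <- 2 * (data[[col]] - spec$min[[col]]) / rng - 1
  }
  if (warn_extrapolation && any(unlist(out) < -1 - 1e-12 | unlist(out) > 1 + 1e-12))
    warning("values outside the fitted range map outside [-1, 1] (extrapolation)")
  out
}

#' Invert a fitted min-max map
#'
#' @inheritParams normalize_data
#' @param data Data.frame of fitted columns on the \[-1, 1\] scale.
#' @return Data.frame in original units; `normalize_data()` then
#'   `denormalize_data()` is the identity to within 1e-12 relative tolerance.
#' @export
denormalize_data <- function(spec, data) {
  stopifnot(inherits(spec, "minmax_spec"))
  cols <- names(spec$min)
  out <- data[cols]
  for (col in cols) {
    rng <- spec$max[[col]] - spec$min[[col]]
    out[[col]] <- (data[[col]] + 1) / 2 * rng + spec$min[[col]]
  }
  out
}

#' Split breakthrough data into training and test partitions
#'
#' Draws a uniformly random partition without replacement, of sizes
#' `round(N * train_fraction)` and the remainder. The seed is mandatory so
#' every partition is reproducible. A `"sequential"` mode (first rows train)
#' is available for sensitivity checks.
#'
#' @param data Data.frame with at least 4 rows.
#' @param train_fraction Fraction of rows assigned to training, in (0, 1).
#'   Default 0.75, the conventional 75/25 split.
#' @param seed Integer seed for the draw (default 42).
#' @param method `"random"` (default) or `"sequential"`.
#' @return List with elements `train`, `test` (data.frames) and `train_idx`
#'   (integer row indices of the training partition).
#' @export
split_breakthrough <- function(data, train_fraction = 0.75, seed = 42L,
                               method = c("random", "sequential")) {
  method <- match.arg(method)
  n <- nrow(data)
  stopifnot(n >= 4L, train_fraction > 0, train_fraction < 1)
  n_train <- round(n * train_fraction)
  if (n_train < 1L || n_train >= n)
    stop("train_fraction ", train_fraction, " leaves an empty partition for n = ", n)
  if (method == "random") {
    train_idx <- with_seed(seed, sort(sample.int(n, n_train)))
  } else {
    train_idx <- seq_len(n_train)
  }
  list(train = data[train_idx, , drop = FALSE],
       test = data[-train_idx, , drop = FALSE],
       train_idx = train_idx)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state, so
#' seeded internals never perturb the user's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
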