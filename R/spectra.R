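#' Body-fluid label vocabulary
#'
#' The five body-fluid classes handled by the discrimination schemes, in
#' canonical order. Interferent (non-body-fluid) samples carry labels of the
#' form `"non_bf:<name>"` and are never valid training classes.
#'
#' @return Character vector of the five fluid labels.
#' @export
fluid_labels <- function() {
  c("blood", "saliva", "semen", "urine", "sweat")
}

#' Standard ATR FT-IR wavenumber grid
#'
#' Uniform wavenumber axis from 600 to 3700 cm-1 at 4 cm-1 spacing
#' (776 points), the instrument range and resolution the package assumes by
#' default.
#'
#' @param from,to Range limits in cm-1.
#' @param by Spacing in cm-1.
#' @return Numeric vector of wavenumbers.
#' @export
default_grid <- function(from = 600, to = 3700, by = 4) {
  seq(from, to, by = by)
}

.validate_grid <- function(grid) {
  if (length(grid) < 2L || anyNA(grid) || any(!is.finite(grid))) {
    stop("grid error: wavenumber grid must be finite with length >= 2",
         call. = FALSE)
  }
  d <- diff(grid)
  if (any(d <= 0)) {
    stop("grid error: wavenumbers must be strictly increasing", call. = FALSE)
  }
  if (max(abs(d - d[1])) > 1e-9 * abs(d[1])) {
    stop("grid error: wavenumber spacing is not uniform", call. = FALSE)
  }
  invisible(grid)
}

.grid_spacing <- function(grid) grid[2] - grid[1]

.valid_fluid <- function(fluid) {
  fluid %in% fluid_labels() | startsWith(fluid, "non_bf:")
}

#' Construct a spectra set
#'
#' Bundles a matrix of spectra sharing one wavenumber grid with per-spectrum
#' metadata. Rows of `X` are spectra; columns follow `grid`.
#'
#' @param X Numeric matrix, `n` spectra by `length(grid)` wavenumbers.
#' @param grid Wavenumber grid (strictly increasing, uniform spacing).
#' @param meta Data frame with columns `sample_id`, `fluid`, `donor_id`,
#'   `age_days`, one row per spectrum. `fluid` must be one of
#'   [fluid_labels()] or `"non_bf:<name>"`.
#' @param mode `"transmittance"` or `"absorbance"`. Transmittance values must
#'   be strictly positive.
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(X, grid = default_grid(), meta,
                        mode = c("absorbance", "transmittance")) {
  mode <- match.arg(mode)
  .validate_grid(grid)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) != length(grid)) {
    stop("dimension error: ncol(X) must equal length(grid)", call. = FALSE)
  }
  if (nrow(X) > 0 && any(!is.finite(X))) {
    stop("data error: spectra contain non-finite values", call. = FALSE)
  }
  if (mode == "transmittance" && nrow(X) > 0 && any(X <= 0)) {
    stop("data error: transmittance values must be strictly positive",
         call. = FALSE)
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  req <- c("sample_id", "fluid", "donor_id", "age_days")
  if (!all(req %in% names(meta))) {
    stop("metadata error: meta needs columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (nrow(meta) != nrow(X)) {
    stop("metadata error: one metadata row per spectrum required",
         call. = FALSE)
  }
  if (nrow(meta) > 0) {
    if (!all(.valid_fluid(meta$fluid))) {
      stop("metadata error: unknown fluid label(s): ",
           paste(unique(meta$fluid[!.valid_fluid(meta$fluid)]), collapse = ", "),
           call. = FALSE)
    }
    if (any(!nzchar(meta$donor_id))) {
      stop("metadata error: donor_id must be non-empty", call. = FALSE)
    }
    if (any(meta$age_days < 0)) {
      stop("metadata error: age_days must be non-negative", call. = FALSE)
    }
  }
  rownames(X) <- meta$sample_id
  structure(list(grid = as.numeric(grid), X = X,
                 meta = meta[req], mode = mode),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("spectra_set: %d spectra x %d wavenumbers (%g-%g cm-1, %s)\n",
              nrow(x$X), length(x$grid), min(x$grid), max(x$grid), x$mode))
  if (nrow(x$meta) > 0) {
    tab <- table(x$meta$fluid)
    cat("  fluids:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
        "\n")
    ages <- sort(unique(x$meta$age_days))
    cat("  ages (days):", paste(ages, collapse = " "), "\n")
  }
  invisible(x)
}

#' Subset a spectra set by row
#'
#' @param s A [spectra_set()].
#' @param i Row index (logical, integer or sample-id character).
#' @return A `spectra_set` with the selected spectra.
#' @export
subset_spectra <- function(s, i) {
  if (is.character(i)) i <- match(i, s$meta$sample_id)
  spectra_set(s$X[i, , drop = FALSE], s$grid,
              s$meta[i, , drop = FALSE], s$mode)
}

#' Combine spectra sets sharing a grid and mode
#'
#' @param ... `spectra_set` objects on identical grids and in the same mode.
#' @return The row-bound `spectra_set`.
#' @export
bind_spectra <- function(...) {
  sets <- list(...)
  g <- sets[[1]]$grid
  for (s in sets) {
    if (!isTRUE(all.equal(s$grid, g)) || s$mode != sets[[1]]$mode) {
      stop("grid error: spectra sets differ in grid or mode", call. = FALSE)
    }
  }
  spectra_set(do.call(rbind, lapply(sets, `[[`, "X")), g,
              do.call(rbind, lapply(sets, `[[`, "meta")), sets[[1]]$mode)
}

#' Read spectra from CSV
#'
#' Two plain-text layouts are supported. `csv_wide`: first column
#' `wavenumber`, one column per sample id; `csv_long`: columns
#' `sample_id,wavenumber,intensity`. Metadata (`sample_id,fluid,donor_id,
#' age_days`) comes from a sidecar CSV, by default `<path>` with its
#' extension replaced by `_meta.csv`.
#'
#' @param path Spectra CSV file.
#' @param format `"csv_wide"` or `"csv_long"`.
#' @param meta_path Metadata CSV; defaults to the sidecar convention.
#' @param mode Intensity mode of the stored spectra.
#' @return A [spectra_set()]. Rows keep the file order.
#' @export
read_spectra <- function(path, format = c("csv_wide", "csv_long"),
                         meta_path = NULL,
                         mode = c("absorbance", "transmittance")) {
  format <- match.arg(format)
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("I/O error: no such file: ", path, call. = FALSE)
  if (is.null(meta_path)) meta_path <- sub("\\.csv$", "_meta.csv", path)
  if (!file.exists(meta_path)) {
    stop("metadata error: sidecar metadata file not found: ", meta_path,
         call. = FALSE)
  }
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE,
                          colClasses = c(sample_id = "character",
                                         donor_id = "character"))
  if (format == "csv_wide") {
    d <- utils::read.csv(path, check.names = FALSE)
    if (names(d)[1] != "wavenumber") {
      stop("data error: first column of a wide CSV must be 'wavenumber'",
           call. = FALSE)
    }
    grid <- as.numeric(d[[1]])
    X <- t(as.matrix(d[-1]))
    ids <- colnames(d)[-1]
  } else {
    d <- utils::read.csv(path, colClasses = c(sample_id = "character"))
    ids <- unique(d$sample_id)
    grid <- sort(unique(d$wavenumber))
    X <- matrix(NA_real_, length(ids), length(grid),
                dimnames = list(ids, NULL))
    X[cbind(match(d$sample_id, ids), match(d$wavenumber, grid))] <- d$intensity
  }
  if (anyNA(X)) stop("data error: missing/NaN intensities", call. = FALSE)
  if (anyDuplicated(grid)) {
    stop("grid error: duplicated wavenumber rows", call. = FALSE)
  }
  mi <- match(ids, meta$sample_id)
  if (anyNA(mi)) {
    stop("metadata error: samples missing from metadata: ",
         paste(ids[is.na(mi)], collapse = ", "), call. = FALSE)
  }
  spectra_set(X, grid, meta[mi, , drop = FALSE], mode)
}

#' Write spectra to CSV
#'
#' Writes the spectra file plus the metadata sidecar (`*_meta.csv`). Numeric
#' values are serialized with 17 significant digits so a read/write round
#' trip is bit-identical.
#'
#' @param s A [spectra_set()].
#' @param path Output CSV path.
#' @param format `"csv_wide"` or `"csv_long"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(s, path, format = c("csv_wide", "csv_long")) {
  format <- match.arg(format)
  meta_path <- sub("\\.csv$", "_meta.csv", path)
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  if (format == "csv_wide") {
    d <- data.frame(wavenumber = fmt(s$grid), check.names = FALSE)
    for (i in seq_len(nrow(s$X))) d[[s$meta$sample_id[i]]] <- fmt(s$X[i, ])
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  } else {
    n <- nrow(s$X); p <- length(s$grid)
    d <- data.frame(sample_id = rep(s$meta$sample_id, each = p),
                    wavenumber = fmt(rep(s$grid, times = n)),
                    intensity = fmt(as.vector(t(s$X))))
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(s$meta, meta_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert transmittance spectra to absorbance
#'
#' Applies the Beer-Lambert transform A = log10(1/T) elementwise.
#'
#' @param s A [spectra_set()] in transmittance mode with all T > 0.
#' @return The set in absorbance mode.
#' @export
to_absorbance <- function(s) {
  if (s$mode != "transmittance") {
    stop("mode error: spectra are already in absorbance mode", call. = FALSE)
  }
  if (any(s$X <= 0)) {
    stop("domain error: transmittance must be strictly positive",
         call. = FALSE)
  }
  spectra_set(log10(1 / s$X), s$grid, s$meta, "absorbance")
}

#' Normalize each spectrum by its total area
#'
#' Divides every spectrum by its integrated absorbance, computed as
#' (sum of intensities) x (grid spacing) -- a rectangle rule, proportional
#' to the plain sum on a uniform grid. After normalization each spectrum has
#' unit area. Negative absorbance values are tolerated; only the total area
#' must be positive.
#'
#' @param s A [spectra_set()] in absorbance mode.
#' @return The area-normalized set.
#' @export
normalize_total_area <- function(s) {
  if (s$mode != "absorbance") {
    stop("mode error: area normalization requires absorbance spectra",
         call. = FALSE)
  }
  spectra_set(area_normalize_matrix(s$X, s$grid), s$grid, s$meta,
              "absorbance")
}

#' Area-normalize a bare absorbance matrix
#'
#' Matrix form of [normalize_total_area()] for workflows (bulk Monte-Carlo
#' draws) that carry no metadata.
#'
#' @param X n x p absorbance matrix.
#' @param grid Wavenumber grid matching the columns.
#' @return Matrix with every row scaled to unit total area.
#' @export
area_normalize_matrix <- function(X, grid = default_grid()) {
  area <- rowSums(X) * .grid_spacing(grid)
  if (any(area <= 0)) {
    stop("normalization error: non-positive total area", call. = FALSE)
  }
  X / area
}

#' Standard preprocessing pipeline
#'
#' Absorbance conversion (when needed) followed by total-area normalization:
#' the preprocessing applied to every spectrum before modeling.
#'
#' @param s A [spectra_set()].
#' @return Preprocessed `spectra_set` (absorbance, unit area).
#' @export
preprocess_spectra <- function(s) {
  if (s$mode == "transmittance") s <- to_absorbance(s)
  normalize_total_area(s)
}

#' Mean-center a matrix by column
#'
#' @param X Numeric matrix with at least one row.
#' @return List with `Xc` (centered matrix) and `mean` (column means, kept
#'   for projecting new samples).
#' @export
mean_center <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 1L) stop("dimension error: empty matrix", call. = FALSE)
  m <- colMeans(X)
  list(Xc = sweep(X, 2L, m, "-"), mean = m)
}

#' Per-class mean and standard-deviation spectra
#'
#' @param s A [spectra_set()].
#' @param fluid Fluid label to summarize.
#' @return List with `mean` and `sd` spectra (sd uses the n-1 denominator
#'   and is the zero vector when only one spectrum matches).
#' @export
summarize_class <- function(s, fluid) {
  i <- which(s$meta$fluid == fluid)
  if (length(i) == 0L) {
    stop("selection error: no spectra with fluid '", fluid, "'", call. = FALSE)
  }
  Xs <- s$X[i, , drop = FALSE]
  sdv <- if (nrow(Xs) > 1L) apply(Xs, 2L, stats::sd) else numeric(ncol(Xs)) * 0
  list(mean = colMeans(Xs), sd = sdv)
}

#' Difference spectrum (aged minus fresh)
#'
#' @param aged_mean,fresh_mean Spectra on the same grid.
#' @return Elementwise difference `aged_mean - fresh_mean`.
#' @export
difference_spectrum <- function(aged_mean, fresh_mean) {
  if (length(aged_mean) != length(fresh_mean)) {
    stop("grid error: spectra have different lengths", call. = FALSE)
  }
  aged_mean - fresh_mean
}

#' Linear re-gridding of spectra
#'
#' Explicit linear interpolation onto a new uniform grid. Never applied
#' implicitly: sets on mismatched grids are rejected by the modeling
#' functions and must be re-gridded deliberately.
#'
#' @param s A [spectra_set()].
#' @param new_grid Target grid, contained in the range of the current grid.
#' @return The interpolated `spectra_set`.
#' @export
regrid_spectra <- function(s, new_grid) {
  .validate_grid(new_grid)
  if (min(new_grid) < min(s$grid) || max(new_grid) > max(s$grid)) {
    stop("grid error: new grid extends beyond the data range", call. = FALSE)
  }
  Xn <- t(apply(s$X, 1L, function(r) {
    stats::approx(s$grid, r, xout = new_grid)$y
  }))
  if (nrow(s$X) == 1L) Xn <- matrix(Xn, nrow = 1L)
  spectra_set(Xn, new_grid, s$meta, s$mode)
}

#' Principal component analysis of mean-centered spectra
#'
#' Thin wrapper around [stats::prcomp()] on already mean-centered,
#' unscaled data.
#'
#' @param Xc Mean-centered matrix (n x p).
#' @param n_components Number of components, at most `min(n - 1, p)`.
#' @return List with `scores` (n x k), `loadings` (p x k, orthonormal) and
#'   `explained_variance` (k-vector, non-increasing).
#' @export
pca_spectra <- function(Xc, n_components) {
  Xc <- as.matrix(Xc)
  kmax <- min(nrow(Xc) - 1L, ncol(Xc))
  if (n_components > kmax) {
    stop("dimension error: n_components exceeds min(n-1, p)", call. = FALSE)
  }
  pc <- stats::prcomp(Xc, center = FALSE, scale. = FALSE)
  k <- seq_len(n_components)
  list(scores = pc$x[, k, drop = FALSE],
       loadings = pc$rotation[, k, drop = FALSE],
       explained_variance = pc$sdev[k]^2)
}
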