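# Piecewise-linear interpolation with linear extrapolation beyond the data
# range (stats::approx only extends constantly). Exact for affine inputs,
# which is what makes a plane-valued plate self-normalise to 1 everywhere.
lin_interp <- function(x, y, xout) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) == 0L) return(rep(NA_real_, length(xout)))
  if (length(x) == 1L) return(rep(y, length(xout)))
  o <- order(x)
  x <- x[o]; y <- y[o]
  out <- stats::approx(x, y, xout, rule = 2, ties = mean)$y
  n <- length(x)
  lo <- xout < x[1]
  if (any(lo)) {
    s <- (y[2] - y[1]) / (x[2] - x[1])
    out[lo] <- y[1] + s * (xout[lo] - x[1])
  }
  hi <- xout > x[n]
  if (any(hi)) {
    s <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    out[hi] <- y[n] + s * (xout[hi] - x[n])
  }
  out
}

#' Build a reference surface from grid-colony measurements
#'
#' Interpolates the measurements of the reference-grid (control) colonies to
#' every plate position, giving the locally expected colony value against
#' which test colonies are compared. Interpolation is separable
#' piecewise-linear: values are first interpolated along columns within each
#' grid row, then along rows for every column, with linear extension beyond
#' the outermost grid positions. This reproduces any affine trend exactly and
#' matches the lattice structure of the standard grid layouts. Grid colonies
#' that are missing or non-positive are excluded and flagged; positions whose
#' interpolated expectation is non-positive are flagged as normalisation
#' artefacts.
#'
#' Before interpolation the grid values are denoised by a local plane fit:
#' each grid value is replaced by the value, at its own position, of a
#' least-squares plane fitted through the grid colonies within
#' `smooth_window` grid-node steps in each direction. This suppresses the
#' propagation of single-colony noise into whole plate regions (which would
#' spatially correlate corrected values) while reproducing any affine trend
#' exactly, so a plate lying on a plane still self-normalises to 1
#' everywhere. Set `smooth_window = 0` to interpolate the raw grid values.
#'
#' @param plate_values numeric matrix (n_rows x n_cols) of raw colony values
#' @param layout a `plate_layout` with at least 3 usable grid positions
#'   spanning at least 2 distinct rows and 2 distinct columns
#' @param smooth_window radius, in grid-node steps, of the plane-fit
#'   denoising neighbourhood (default 1, i.e. up to 3 x 3 grid nodes)
#' @return object of class `reference_surface`: list with `expected`
#'   (numeric matrix), `n_grid_used`, `flags` (character vector) and
#'   `artefact` (logical matrix marking positions with expectation <= 0)
#' @export
build_reference_surface <- function(plate_values, layout, smooth_window = 1) {
  stopifnot(is.matrix(plate_values))
  if (any(dim(plate_values) != c(layout$n_rows, layout$n_cols)))
    stop("plate_values dimensions do not match layout")
  nr <- layout$n_rows; nc <- layout$n_cols
  flags <- character(0)

  gpos <- which(layout$is_grid, arr.ind = TRUE)
  gval <- plate_values[layout$is_grid]
  usable <- is.finite(gval) & gval > 0
  if (any(!usable)) {
    bad <- gpos[!usable, , drop = FALSE]
    flags <- c(flags, sprintf("missing grid colony at (%d,%d)",
                              bad[, 1] - 1L, bad[, 2] - 1L))
  }
  gpos <- gpos[usable, , drop = FALSE]
  gval <- gval[usable]
  if (length(gval) < 3L || length(unique(gpos[, 1])) < 2L ||
      length(unique(gpos[, 2])) < 2L)
    stop("degenerate grid: fewer than 3 usable, non-collinear grid colonies")

  if (smooth_window > 0)
    gval <- smooth_grid_values(gpos, gval, smooth_window)

  # stage 1: interpolate along columns within each grid row
  grid_rows <- sort(unique(gpos[, 1]))
  row_profiles <- matrix(NA_real_, length(grid_rows), nc)
  for (i in seq_along(grid_rows)) {
    sel <- gpos[, 1] == grid_rows[i]
    row_profiles[i, ] <- lin_interp(gpos[sel, 2], gval[sel], seq_len(nc))
  }
  keep <- rowSums(is.finite(row_profiles)) > 0L
  grid_rows <- grid_rows[keep]
  row_profiles <- row_profiles[keep, , drop = FALSE]
  if (length(grid_rows) < 2L)
    stop("degenerate grid: grid colonies span fewer than 2 rows")

  # stage 2: interpolate across grid rows for every column
  expected <- matrix(NA_real_, nr, nc)
  for (j in seq_len(nc))
    expected[, j] <- lin_interp(grid_rows, row_profiles[, j], seq_len(nr))

  artefact <- is.finite(expected) & expected <= 0
  if (any(artefact)) {
    bad <- which(artefact, arr.ind = TRUE)
    flags <- c(flags, sprintf("artefact: non-positive expectation at (%d,%d)",
                              bad[, 1] - 1L, bad[, 2] - 1L))
  }
  structure(list(expected = expected, n_grid_used = length(gval),
                 flags = flags, artefact = artefact),
            class = "reference_surface")
}

# order-1 Savitzky-Golay denoising on the grid lattice: refit each grid
# value from a least-squares plane through its grid-node neighbourhood.
# Exact for affine surfaces (including at borders); neighbourhoods that
# cannot support a plane fit leave the value unchanged.
smooth_grid_values <- function(gpos, gval, window) {
  ur <- sort(unique(gpos[, 1])); uc <- sort(unique(gpos[, 2]))
  ri <- match(gpos[, 1], ur); ci <- match(gpos[, 2], uc)
  out <- gval
  for (k in seq_along(gval)) {
    sel <- abs(ri - ri[k]) <= window & abs(ci - ci[k]) <= window
    if (sum(sel) < 3) next
    X <- cbind(1, gpos[sel, 1], gpos[sel, 2])
    if (qr(X)$rank < 3) next
    fit <- stats::lm.fit(X, gval[sel])
    out[k] <- sum(fit$coefficients * c(1, gpos[k, 1], gpos[k, 2]))
  }
  out
}

#' @export
print.reference_surface <- function(x, ...) {
  cat(sprintf("reference_surface: %d x %d, %d grid colonies used, %d flags\n",
              nrow(x$expected), ncol(x$expected), x$n_grid_used,
              length(x$flags)))
  invisible(x)
}

#' Reference-grid normalisation
#'
#' Divides each colony value by the locally expected value interpolated from
#' the reference-grid colonies, so that corrected fitness 1 means "grows like
#' the grid strain here". Positions flagged as artefacts (non-positive
#' expectation) and positions whose strain is "empty" become missing.
#'
#' @param plate_values numeric matrix of raw values
#' @param layout a `plate_layout`
#' @param surface optional precomputed `reference_surface`
#' @param smooth_window grid-denoising radius passed to
#'   [build_reference_surface()]
#' @return numeric matrix of corrected values, with the surface attached as
#'   attribute `surface`
#' @export
grid_normalise <- function(plate_values, layout, surface = NULL,
                           smooth_window = 1) {
  if (is.null(surface))
    surface <- build_reference_surface(plate_values, layout, smooth_window)
  corrected <- plate_values / surface$expected
  corrected[surface$artefact] <- NA_real_
  corrected[layout$strain == "empty"] <- NA_real_
  attr(corrected, "surface") <- surface
  corrected
}

#' Row/column median normalisation
#'
#' Divides every value by the median of its row, then divides the result by
#' the (recomputed) median of its column. Under the assumption that most
#' strains in every row and column are phenotypically neutral, this removes
#' additive-free multiplicative row/column plate effects and centres neutral
#' strains at 1. Missing values are ignored when computing medians and stay
#' missing.
#'
#' @param plate_values numeric matrix
#' @return numeric matrix of corrected values
#' @export
rowcol_median_normalise <- function(plate_values) {
  stopifnot(is.matrix(plate_values))
  rmed <- apply(plate_values, 1, stats::median, na.rm = TRUE)
  zero <- which(is.finite(rmed) & rmed == 0)
  if (length(zero))
    stop("zero row median at row ", zero[1] - 1L)
  out <- plate_values / rmed             # recycles down columns
  cmed <- apply(out, 2, stats::median, na.rm = TRUE)
  zero <- which(is.finite(cmed) & cmed == 0)
  if (length(zero))
    stop("zero column median at column ", zero[1] - 1L)
  sweep(out, 2, cmed, "/")
}

#' Read an experimental design table
#'
#' One row per plate with required columns `plate_id` and `data_path`,
#' optional `layout_path`, `condition`, `control` and `batch`; any other
#' columns are carried through to the aggregated experiment table.
#'
#' @param path CSV file
#' @return data.frame
#' @export
read_edt <- function(path) {
  edt <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  req <- c("plate_id", "data_path")
  miss <- setdiff(req, names(edt))
  if (length(miss))
    stop("experimental design table lacks required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(edt$plate_id))
    stop("plate_id values must be unique")
  edt
}

# read one plate's colony data CSV (long: row, col, <value_column>, ...)
# into a value matrix plus optional circularity matrix
read_plate_data <- function(path, value_column, layout = NULL) {
  if (!file.exists(path)) stop("data file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("row", "col") %in% names(d)))
    stop("plate data file must have 'row' and 'col' columns: ", path)
  if (!value_column %in% names(d))
    stop("value column '", value_column, "' not found in ", path)
  nr <- if (!is.null(layout)) layout$n_rows else max(d$row) + 1L
  nc <- if (!is.null(layout)) layout$n_cols else max(d$col) + 1L
  if (any(d$row < 0 | d$row >= nr | d$col < 0 | d$col >= nc))
    stop("plate data positions exceed layout dimensions (", nr, " x ", nc,
         ") in ", path)
  idx <- cbind(d$row + 1L, d$col + 1L)
  values <- matrix(NA_real_, nr, nc)
  values[idx] <- d[[value_column]]
  circ <- NULL
  if ("circularity" %in% names(d)) {
    circ <- matrix(NA_real_, nr, nc)
    circ[idx] <- d$circularity
  }
  list(values = values, circularity = circ)
}

#' Aggregate a multi-plate experiment into one long table
#'
#' Loads every plate listed in an experimental design table, applies the
#' requested per-plate normalisation and concatenates the results into a
#' single long table with one row per colony. When both normalisations are
#' requested, grid normalisation is performed before row/column median
#' normalisation. Zero raw values are treated as missing before
#' normalisation and flagged.
#'
#' @param edt data.frame (see [read_edt()]) or path to the EDT CSV
#' @param method "grid", "rowcol", "grid+rowcol" or "none"
#' @param value_column name of the value column in the plate data files
#' @param layout default `plate_layout` used for plates without a
#'   `layout_path`
#' @param qc_dir optional directory for per-plate QC heatmaps (raw vs
#'   corrected, and the reference surface when grid normalisation is used)
#' @return data.frame with columns plate_id, row, col, strain, is_grid,
#'   condition, batch, raw_value, reference_value, corrected_value,
#'   normalisation_method, qc_flags, circularity (when present in the data),
#'   plus any extra EDT metadata columns
#' @export
aggregate_experiment <- function(edt,
                                 method = c("grid", "rowcol", "grid+rowcol",
                                            "none"),
                                 value_column = "value",
                                 layout = NULL,
                                 qc_dir = NULL) {
  method <- match.arg(method)
  if (is.character(edt) && length(edt) == 1L) edt <- read_edt(edt)
  if (!is.null(qc_dir) && !dir.exists(qc_dir))
    dir.create(qc_dir, recursive = TRUE)

  extra_cols <- setdiff(names(edt),
                        c("plate_id", "data_path", "layout_path"))
  out <- vector("list", nrow(edt))
  for (i in seq_len(nrow(edt))) {
    pid <- edt$plate_id[i]
    lay <- layout
    if ("layout_path" %in% names(edt) && nzchar(edt$layout_path[i] %||% ""))
      lay <- read_layout(edt$layout_path[i])
    if (is.null(lay))
      stop("no layout available for plate ", pid)
    pd <- tryCatch(read_plate_data(edt$data_path[i], value_column, lay),
                   error = function(e)
                     stop("plate ", pid, ": ", conditionMessage(e)))
    raw <- pd$values
    nr <- lay$n_rows; nc <- lay$n_cols

    qc <- matrix("", nr, nc)
    zero <- is.finite(raw) & raw == 0
    if (any(zero)) {
      raw[zero] <- NA_real_
      qc[zero] <- "zero raw value"
    }

    surface <- NULL
    if (method %in% c("grid", "grid+rowcol")) {
      corrected <- grid_normalise(raw, lay)
      surface <- attr(corrected, "surface")
      if (any(surface$artefact))
        qc[surface$artefact] <- paste_flag(qc[surface$artefact],
                                           "normalisation artefact")
      if (method == "grid+rowcol")
        corrected <- rowcol_median_normalise(corrected)
    } else if (method == "rowcol") {
      corrected <- rowcol_median_normalise(raw)
    } else {
      corrected <- raw
    }
    empty <- lay$strain == "empty"
    if (any(empty)) {
      corrected[empty] <- NA_real_
      qc[empty] <- paste_flag(qc[empty], "empty position")
    }
    newly_missing <- !is.finite(corrected) & is.finite(pd$values) &
      !nzchar(qc)
    if (any(newly_missing))
      qc[newly_missing] <- "lost in normalisation"

    reference <- pd$values / corrected
    reference[!is.finite(reference)] <- NA_real_

    tab <- data.frame(
      plate_id = pid,
      row = rep(0:(nr - 1), times = nc),
      col = rep(0:(nc - 1), each = nr),
      strain = as.vector(lay$strain),
      is_grid = as.vector(lay$is_grid),
      raw_value = as.vector(pd$values),
      reference_value = as.vector(reference),
      corrected_value = as.vector(corrected),
      normalisation_method = method,
      qc_flags = as.vector(qc),
      stringsAsFactors = FALSE
    )
    if (!is.null(pd$circularity))
      tab$circularity <- as.vector(pd$circularity)
    for (cc in extra_cols) tab[[cc]] <- edt[[cc]][i]
    out[[i]] <- tab

    if (!is.null(qc_dir))
      plot_plate_qc(qc_dir, pid, pd$values, corrected, surface)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

paste_flag <- function(existing, flag)
  ifelse(nzchar(existing), paste(existing, flag, sep = "; "), flag)

plot_plate_qc <- function(qc_dir, plate_id, raw, corrected, surface) {
  f <- file.path(qc_dir, paste0(plate_id, "_qc.png"))
  grDevices::png(f, width = 1200, height = 400)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 3), mar = c(2, 2, 3, 1))
  plate_heat(raw, "raw")
  plate_heat(corrected, "corrected")
  if (!is.null(surface)) plate_heat(surface$expected, "reference surface")
  invisible(f)
}

# heatmap in plate orientation: row 0 on top, col 0 on the left
plate_heat <- function(m, main) {
  z <- t(m[rev(seq_len(nrow(m))), , drop = FALSE])
  graphics::image(seq_len(nrow(z)), seq_len(ncol(z)), z, main = main,
                  xlab = "", ylab = "", axes = FALSE,
                  col = grDevices::hcl.colors(64, "viridis"))
  graphics::box()
}
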