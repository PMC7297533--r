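#' Standard plate formats
#'
#' Colony-array screens use 96 (8 x 12), 384 (16 x 24) or 1536 (32 x 48)
#' positions. Row 0 is at the top of the plate image, column 0 at the left;
#' all grid indices in this package are 0-based.
#'
#' @param format one of 96, 384, 1536
#' @return integer vector c(n_rows, n_cols)
#' @export
plate_dims <- function(format) {
  format <- as.integer(format)
  dims <- switch(as.character(format),
    "96"   = c(8L, 12L),
    "384"  = c(16L, 24L),
    "1536" = c(32L, 48L),
    stop("unknown plate format: ", format, " (expected 96, 384 or 1536)")
  )
  dims
}

#' Create a plate layout
#'
#' A layout maps each (row, col) position to a strain ID and marks
#' reference-grid (control) positions. The `topleft96` scheme places a
#' 96-position control grid: in 384 format the grid strain occupies the
#' top-left position of every 2 x 2 block (one colony in every fourth
#' position); in 1536 format the 96 grid positions are spread as evenly as
#' 8 x 12 positions allow in a 32 x 48 array, with grid colonies present in
#' all four border rows/columns so that no test colony needs extrapolation
#' far beyond the grid hull.
#'
#' @param format plate format (96, 384 or 1536)
#' @param grid_scheme "topleft96", "none" or "custom"
#' @param strains optional character vector of strain IDs, recycled over
#'   non-grid positions in row-major order; defaults to "strain_0001", ...
#' @param grid_strain strain ID used at grid positions
#' @param custom_grid optional logical matrix (n_rows x n_cols) of grid flags,
#'   required when `grid_scheme = "custom"`
#' @return object of class `plate_layout`: list with `n_rows`, `n_cols`,
#'   `strain` (character matrix) and `is_grid` (logical matrix)
#' @export
make_layout <- function(format = 384,
                        grid_scheme = c("topleft96", "none", "custom"),
                        strains = NULL,
                        grid_strain = "grid",
                        custom_grid = NULL) {
  grid_scheme <- match.arg(grid_scheme)
  d <- plate_dims(format)
  nr <- d[1]; nc <- d[2]
  is_grid <- matrix(FALSE, nr, nc)

  if (grid_scheme == "topleft96") {
    if (format == 384) {
      is_grid[seq(1, nr, by = 2), seq(1, nc, by = 2)] <- TRUE
    } else if (format == 1536) {
      gr <- round(seq(0, nr - 1, length.out = 8)) + 1
      gc <- round(seq(0, nc - 1, length.out = 12)) + 1
      is_grid[gr, gc] <- TRUE
    } else {
      stop("grid_scheme 'topleft96' requires 384 or 1536 format")
    }
  } else if (grid_scheme == "custom") {
    if (is.null(custom_grid))
      stop("grid_scheme 'custom' requires a `custom_grid` logical matrix")
    if (!is.logical(custom_grid) || any(dim(custom_grid) != c(nr, nc)))
      stop("custom_grid must be a ", nr, " x ", nc, " logical matrix")
    is_grid <- custom_grid
  }

  strain <- matrix(NA_character_, nr, nc)
  strain[is_grid] <- grid_strain
  n_test <- sum(!is_grid)
  if (is.null(strains))
    strains <- sprintf("strain_%04d", seq_len(n_test))
  # fill non-grid positions row-major, recycling the strain vector
  idx <- which(t(!is_grid))            # row-major order over positions
  fill <- rep_len(strains, n_test)
  tm <- t(strain)
  tm[idx] <- fill
  strain <- t(tm)

  structure(list(n_rows = nr, n_cols = nc, strain = strain, is_grid = is_grid),
            class = "plate_layout")
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("plate_layout: %d x %d (%d positions), %d grid, %d strains\n",
              x$n_rows, x$n_cols, x$n_rows * x$n_cols, sum(x$is_grid),
              length(setdiff(unique(as.vector(x$strain)), c("grid", "empty")))))
  invisible(x)
}

#' Read a plate layout from CSV
#'
#' The strain file is an n_rows x n_cols CSV matrix of strain IDs (no
#' header). Grid flags come from an optional parallel CSV matrix of 0/1
#' values; when absent, positions whose strain ID equals `grid_strain`
#' are taken as grid.
#'
#' @param strain_file CSV matrix of strain IDs
#' @param grid_file optional CSV matrix of 0/1 grid flags
#' @param grid_strain strain ID identifying grid positions when `grid_file`
#'   is not given
#' @return a `plate_layout`
#' @export
read_layout <- function(strain_file, grid_file = NULL, grid_strain = "grid") {
  strain <- as.matrix(utils::read.csv(strain_file, header = FALSE,
                                      colClasses = "character"))
  dimnames(strain) <- NULL
  if (!is.null(grid_file)) {
    g <- as.matrix(utils::read.csv(grid_file, header = FALSE))
    if (any(dim(g) != dim(strain)))
      stop("grid flag matrix dimensions do not match strain matrix")
    is_grid <- matrix(as.logical(g), nrow(strain), ncol(strain))
  } else {
    is_grid <- strain == grid_strain
  }
  structure(list(n_rows = nrow(strain), n_cols = ncol(strain),
                 strain = strain, is_grid = is_grid),
            class = "plate_layout")
}

#' Write a plate layout to CSV
#'
#' @param layout a `plate_layout`
#' @param strain_file path for the strain-ID matrix CSV
#' @param grid_file optional path for the 0/1 grid-flag matrix CSV
#' @return invisibly, the layout
#' @export
write_layout <- function(layout, strain_file, grid_file = NULL) {
  utils::write.table(layout$strain, strain_file, sep = ",", row.names = FALSE,
                     col.names = FALSE, qmethod = "double")
  if (!is.null(grid_file))
    utils::write.table(layout$is_grid * 1L, grid_file, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  invisible(layout)
}
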