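# Images follow EBImage conventions throughout: the first array dimension is
# x (width, plate columns), the second y (height, plate rows), intensities in
# [0, 1]. Grid positions are 0-based with row 0 at the image top.

#' Load a plate image
#'
#' Reads a JPEG/PNG/TIFF plate scan, clamps intensities to \[0,1\] and drops
#' any alpha channel.
#'
#' @param path image file
#' @return an [EBImage::Image], Grayscale or Color, with attribute
#'   `source_path`
#' @export
read_plate_image <- function(path) {
  img <- EBImage::readImage(path)
  if (length(dim(img)) == 3 && dim(img)[3] > 3)
    img <- img[, , 1:3]
  img[img < 0] <- 0; img[img > 1] <- 1
  attr(img, "source_path") <- path
  img
}

parse_grid <- function(grid) {
  if (is.character(grid)) {
    parts <- as.integer(strsplit(grid, "[x,]")[[1]])
    if (length(parts) != 2 || any(is.na(parts)))
      stop("grid must be 'RxC', e.g. '32x48'")
    grid <- parts
  }
  grid <- as.integer(grid)
  stopifnot(length(grid) == 2, all(grid >= 1))
  grid
}

as_grey_matrix <- function(image) {
  a <- if (inherits(image, "Image")) EBImage::imageData(image) else image
  if (length(dim(a)) == 3) stop("expected a greyscale image")
  a
}

# fit evenly spaced lattice coordinates along one axis: node centres at
# origin + i * pitch, i = 0..n-1. Starts from the geometric prior (the image
# spans the array) and refines origin/pitch by least squares on the
# assigned object centroids.
fit_lattice_axis <- function(pos, n, extent) {
  p <- extent / n
  o <- p / 2
  if (n == 1) return(list(origin = mean(pos), pitch = extent))
  for (iter in 1:3) {
    i <- pmin(pmax(round((pos - o) / p), 0), n - 1)
    if (length(unique(i)) >= 2) {
      fit <- stats::lm.fit(cbind(1, i), pos)
      o2 <- fit$coefficients[1]; p2 <- fit$coefficients[2]
      if (!is.finite(p2) || p2 <= 0)
        stop("geometry error: fitted lattice pitch is non-positive")
      o <- o2; p <- p2
    } else {
      o <- mean(pos) - i[1] * p
    }
  }
  list(origin = o, pitch = p)
}

#' Segment a plate image into grid-assigned colonies
#'
#' Colonies are detected by adaptive mean thresholding over square blocks
#' (block size defaulting to about 1.25 x the lattice pitch), cleaned by
#' morphological opening and hole filling, and labelled. An evenly spaced
#' n_rows x n_cols lattice is then fitted to the object centroids by least
#' squares and each object is assigned to its nearest lattice node; objects
#' farther than half the lattice pitch from every node are discarded, and
#' when several objects compete for one node the largest wins. Images may be
#' downscaled before processing for speed; the returned mask is in
#' original-image resolution.
#'
#' @param image greyscale [EBImage::Image] or matrix in \[0,1\]
#' @param grid c(n_rows, n_cols) or "RxC" string
#' @param scale downscaling factor in (0, 1] applied before processing
#' @param local_block odd block size (pixels, after scaling) for the
#'   adaptive threshold; default about 1.25 x the expected pitch
#' @param offset adaptive-threshold offset above the local mean
#' @param invert "auto" inverts the image when colonies are darker than
#'   the background (transmission scans vary); "yes"/"no" force it
#' @return object of class `segmentation_mask`: list with `labels` (integer
#'   matrix, 0 = background), `position_map` (data.frame label, row, col),
#'   `pitch` and `origin` (c(y, x), original-image pixels)
#' @export
segment_plate <- function(image, grid, scale = 1, local_block = NULL,
                          offset = 0.02, invert = c("auto", "yes", "no")) {
  invert <- match.arg(invert)
  grid <- parse_grid(grid)
  nr <- grid[1]; nc <- grid[2]
  a <- as_grey_matrix(image)
  if (nrow(a) < 64 || ncol(a) < 64)
    stop("image must be at least 64 x 64 pixels")
  stopifnot(scale > 0, scale <= 1)
  w0 <- nrow(a); h0 <- ncol(a)

  small <- if (scale < 1)
    EBImage::imageData(EBImage::resize(EBImage::Image(a),
                                       w = max(64, round(w0 * scale))))
  else a
  w <- nrow(small); h <- ncol(small)

  do_invert <- switch(invert,
    yes = TRUE, no = FALSE,
    auto = mean(small) < stats::median(small))
  if (do_invert) small <- 1 - small

  pitch_prior <- min(h / nr, w / nc)
  if (is.null(local_block)) {
    local_block <- max(3, round(1.25 * pitch_prior))
    if (local_block %% 2 == 0) local_block <- local_block + 1
  }
  if (local_block < 3 || local_block %% 2 == 0)
    stop("local_block must be odd and at least 3")
  half <- max(1, (local_block - 1) / 2)

  bw <- EBImage::thresh(EBImage::Image(small), w = half, h = half,
                        offset = offset)
  bw <- EBImage::opening(bw, EBImage::makeBrush(3, "disc"))
  bw <- EBImage::fillHull(bw)
  lab <- EBImage::bwlabel(bw)
  nobj <- max(lab)
  if (nobj == 0) stop("no objects detected in image")

  mom <- EBImage::computeFeatures.moment(lab)
  shp <- EBImage::computeFeatures.shape(lab)
  cx <- mom[, "m.cx"]; cy <- mom[, "m.cy"]
  area <- shp[, "s.area"]

  fx <- fit_lattice_axis(cx, nc, w)
  fy <- fit_lattice_axis(cy, nr, h)

  ci <- pmin(pmax(round((cx - fx$origin) / fx$pitch), 0), nc - 1)
  ri <- pmin(pmax(round((cy - fy$origin) / fy$pitch), 0), nr - 1)
  dx <- abs(cx - (fx$origin + ci * fx$pitch))
  dy <- abs(cy - (fy$origin + ri * fy$pitch))
  ok <- dx <= fx$pitch / 2 & dy <= fy$pitch / 2

  node <- ri * nc + ci
  keep <- rep(FALSE, nobj)
  for (nd in unique(node[ok])) {
    cand <- which(ok & node == nd)
    if (length(cand) > 1) {
      warning("multiple objects at grid position (", nd %/% nc, ",",
              nd %% nc, "); keeping the largest")
      cand <- cand[which.max(area[cand])]
    }
    keep[cand] <- TRUE
  }
  sel <- which(keep)
  if (length(sel) == 0) stop("no objects could be assigned to the lattice")

  # relabel kept objects 1..k in (row, col) order
  ord <- sel[order(node[sel])]
  lut <- integer(nobj + 1L)           # old label -> new label (index+1)
  lut[ord + 1L] <- seq_along(ord)
  labm <- EBImage::imageData(lab)
  newlab <- matrix(lut[labm + 1L], nrow(labm), ncol(labm))

  if (scale < 1) {
    up <- EBImage::resize(EBImage::Image(newlab), w = w0, h = h0,
                          filter = "none")
    newlab <- round(EBImage::imageData(up))
  }
  sf <- c(h0 / h, w0 / w)             # (y, x) back-scaling

  structure(list(
    labels = newlab,
    position_map = data.frame(label = seq_along(ord),
                              row = node[ord] %/% nc,
                              col = node[ord] %% nc),
    pitch = c(fy$pitch * sf[1], fx$pitch * sf[2]),
    origin = c(fy$origin * sf[1], fx$origin * sf[2]),
    inverted = do_invert
  ), class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("segmentation_mask: %d colonies, pitch (%.1f, %.1f) px\n",
              nrow(x$position_map), x$pitch[1], x$pitch[2]))
  invisible(x)
}

#' Median background intensity outside colonies
#'
#' @param image greyscale image or matrix aligned with the mask
#' @param mask a `segmentation_mask`
#' @return median intensity of non-colony pixels
#' @export
estimate_background <- function(image, mask) {
  a <- as_grey_matrix(image)
  bgpix <- a[mask$labels == 0]
  if (length(bgpix) == 0)
    stop("no background: mask covers the entire image")
  stats::median(bgpix)
}

# corrected chain-code perimeter (Kulpa weights) from an 8-connected
# object contour; unbiased for smooth shapes, unlike raw pixel counts
contour_perimeter <- function(coords) {
  n <- nrow(coords)
  if (n < 2) return(0)
  d <- coords[c(2:n, 1), , drop = FALSE] - coords
  steps <- sqrt(rowSums(d^2))
  sum(ifelse(steps > 1.2, 1.340, 0.948) * (steps > 0))
}

# per-position measurements for all grid positions given a mask; intensity
# is measured on the same polarity the mask was detected in (bright
# colonies), so auto-inverted transmission scans quantify identically
measure_colonies <- function(image, mask, grid, redness_image = NULL) {
  grid <- parse_grid(grid)
  a <- as_grey_matrix(image)
  if (isTRUE(mask$inverted)) a <- 1 - a
  lab <- mask$labels
  nlab <- nrow(mask$position_map)
  bg <- estimate_background(a, mask)

  idx <- which(lab > 0L)
  labs <- lab[idx]
  w <- nrow(a)
  xs <- ((idx - 1L) %% w) + 1L
  ys <- ((idx - 1L) %/% w) + 1L
  area <- tabulate(labs, nbins = nlab)
  sum_by_label <- function(x) {
    o <- rowsum(as.numeric(x), labs)
    out <- numeric(nlab)
    out[as.integer(rownames(o))] <- o
    out
  }
  psum <- sum_by_label(a[idx])
  cxs <- sum_by_label(xs) / pmax(1, area)
  cys <- sum_by_label(ys) / pmax(1, area)

  per <- numeric(nlab)
  oc <- EBImage::ocontour(EBImage::Image(lab))
  for (k in seq_len(nlab))
    per[k] <- if (k <= length(oc) && !is.null(oc[[k]]))
      contour_perimeter(oc[[k]]) else 0

  red <- NULL
  if (!is.null(redness_image)) {
    stopifnot(length(dim(redness_image)) == 3)
    rr <- redness_image[, , 1]; gg <- redness_image[, , 2]
    bb <- redness_image[, , 3]
    tot <- rr[idx] + gg[idx] + bb[idx]
    pr <- ifelse(tot > 0, rr[idx] / tot, NA_real_)
    red <- sum_by_label(ifelse(is.na(pr), 0, pr)) /
      pmax(1, sum_by_label(!is.na(pr)))
    red <- pmin(pmax(red, 0), 1)
  }

  nr <- grid[1]; nc <- grid[2]
  rec <- data.frame(
    row = rep(0:(nr - 1), each = nc),
    col = rep(0:(nc - 1), times = nr),
    area = 0, intensity = 0, circularity = NA_real_, perimeter = 0,
    centroid_x = NA_real_, centroid_y = NA_real_, found = FALSE
  )
  if (!is.null(red)) rec$redness <- NA_real_

  pm <- mask$position_map
  at <- pm$row * nc + pm$col + 1L
  rec$found[at] <- TRUE
  rec$area[at] <- area
  rec$intensity[at] <- pmax(0, psum - area * bg)
  rec$perimeter[at] <- per
  rec$circularity[at] <- ifelse(per > 0,
                                pmin(4 * pi * area / per^2, 1.2), NA_real_)
  rec$centroid_x[at] <- cxs - 0.5
  rec$centroid_y[at] <- cys - 0.5
  if (!is.null(red)) rec$redness[at] <- red
  attr(rec, "background") <- bg
  rec
}

#' Batch colony-size quantification
#'
#' Analyses each greyscale transmission image independently: segments the
#' colony array, measures area, perimeter, circularity, centroid and the
#' background-subtracted intensity sum per grid position, and (optionally)
#' writes one CSV and one QC overlay image per input.
#'
#' @param images list of greyscale images (or file paths)
#' @param grid c(n_rows, n_cols) or "RxC"
#' @param scale downscaling factor for segmentation
#' @param out_dir optional output directory for CSVs and QC overlays
#' @param ... further arguments to [segment_plate()]
#' @return named list (one element per image) of lists with `source_path`
#'   and `records` (data.frame, one row per grid position)
#' @export
quantify_batch <- function(images, grid, scale = 1, out_dir = NULL, ...) {
  if (!is.list(images)) images <- list(images)
  imgs <- lapply(images, function(im)
    if (is.character(im)) read_plate_image(im) else im)
  for (im in imgs)
    if (length(dim(im)) == 3)
      stop("batch mode requires greyscale transmission images")
  dims <- vapply(imgs, function(im) dim(im)[1:2], integer(2))
  if (ncol(dims) > 1 && any(dims != dims[, 1]))
    stop("dimension error: mixed image sizes within one batch call")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  out <- vector("list", length(imgs))
  for (i in seq_along(imgs)) {
    src <- attr(imgs[[i]], "source_path") %||% sprintf("image_%03d", i)
    mask <- segment_plate(imgs[[i]], grid, scale = scale, ...)
    rec <- measure_colonies(imgs[[i]], mask, grid)
    if (!is.null(out_dir)) {
      base <- tools::file_path_sans_ext(basename(src))
      utils::write.csv(rec, file.path(out_dir, paste0(base, ".csv")),
                       row.names = FALSE)
      write_qc_overlay(file.path(out_dir, paste0(base, "_qc.png")),
                       imgs[[i]], mask, rec)
    }
    out[[i]] <- list(source_path = src, records = rec)
  }
  names(out) <- vapply(out, `[[`, "", "source_path")
  out
}

#' Colony redness (viability) quantification
#'
#' For RGB reflective scans of phloxine B-stained plates. Colonies are
#' detected on a contrast-enhanced, background-subtracted detection channel
#' by the same local-thresholding pipeline as batch mode; the redness score
#' of a colony is the mean over its footprint of the per-pixel chromaticity
#' R / (R + G + B), an exposure-invariant measure of red colour share
#' (1/3 for grey pixels). All geometry fields are populated as in batch
#' mode.
#'
#' @param image RGB image (or file path)
#' @param grid c(n_rows, n_cols) or "RxC"
#' @param scale downscaling factor for segmentation
#' @param out_dir optional output directory for the CSV and QC overlay
#' @param ... further arguments to [segment_plate()]
#' @return data.frame of per-position records including `redness`
#' @export
quantify_redness <- function(image, grid, scale = 1, out_dir = NULL, ...) {
  if (is.character(image)) image <- read_plate_image(image)
  if (length(dim(image)) != 3 || dim(image)[3] != 3)
    stop("mode error: redness mode requires an RGB image")
  a <- if (inherits(image, "Image")) EBImage::imageData(image) else image
  det <- (a[, , 1] + a[, , 2] + a[, , 3]) / 3
  rng <- range(det)
  if (diff(rng) > 0) det <- (det - rng[1]) / diff(rng)  # contrast enhancement
  mask <- segment_plate(det, grid, scale = scale, ...)
  rec <- measure_colonies(det, mask, grid, redness_image = a)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    src <- attr(image, "source_path") %||% "redness"
    base <- tools::file_path_sans_ext(basename(src))
    utils::write.csv(rec, file.path(out_dir, paste0(base, ".csv")),
                     row.names = FALSE)
    write_qc_overlay(file.path(out_dir, paste0(base, "_qc.png")),
                     det, mask, rec, scores = round(rec$redness, 3))
  }
  rec
}

#' Timecourse quantification of an image series
#'
#' Colony positions are determined in the last image of the series only,
#' and that fixed mask is applied to every earlier image, extracting the
#' background-subtracted sum of pixel intensities per position (background
#' re-estimated per image as the off-colony median, so uniform exposure
#' shifts cancel). The result has one growth curve per found position.
#'
#' @param image_series ordered list of greyscale images (or paths), at
#'   least 2, identical dimensions
#' @param grid c(n_rows, n_cols) or "RxC"
#' @param timestamps optional numeric vector of acquisition times (hours),
#'   strictly increasing; defaults to 0, 1, 2, ...
#' @param scale downscaling factor for segmentation of the final image
#' @param ... further arguments to [segment_plate()]
#' @return data.frame: `timepoint` plus one column per found position,
#'   named "R-C" (0-based row-col)
#' @export
quantify_timecourse <- function(image_series, grid, timestamps = NULL,
                                scale = 1, ...) {
  stopifnot(is.list(image_series), length(image_series) >= 2)
  imgs <- lapply(image_series, function(im)
    if (is.character(im)) read_plate_image(im) else im)
  dims <- vapply(imgs, function(im) dim(im)[1:2], integer(2))
  if (any(dims != dims[, 1]))
    stop("dimension error: images in a series must have identical sizes")
  n <- length(imgs)
  if (is.null(timestamps)) timestamps <- as.numeric(seq_len(n) - 1)
  if (length(timestamps) != n || any(diff(timestamps) <= 0))
    stop("timestamps must match the series length and strictly increase")

  mask <- tryCatch(segment_plate(imgs[[n]], grid, scale = scale, ...),
                   error = function(e)
                     stop("no mask: final image yields no colonies (",
                          conditionMessage(e), ")"))
  grid <- parse_grid(grid)
  lab <- mask$labels
  idx <- which(lab > 0L)
  labs <- lab[idx]
  nlab <- nrow(mask$position_map)
  area <- tabulate(labs, nbins = nlab)

  vals <- matrix(0, n, nlab)
  for (i in seq_len(n)) {
    a <- as_grey_matrix(imgs[[i]])
    if (isTRUE(mask$inverted)) a <- 1 - a
    bg <- stats::median(a[lab == 0])
    vals[i, ] <- pmax(0, as.vector(rowsum(a[idx], labs)) - area * bg)
  }
  out <- data.frame(timepoint = timestamps)
  nm <- sprintf("%d-%d", mask$position_map$row, mask$position_map$col)
  for (k in seq_len(nlab)) out[[nm[k]]] <- vals[, k]
  attr(out, "mask") <- mask
  out
}

write_qc_overlay <- function(path, image, mask, records, scores = NULL) {
  a <- if (inherits(image, "Image")) EBImage::imageData(image) else image
  w <- dim(a)[1]; h <- dim(a)[2]
  rast <- if (length(dim(a)) == 3) aperm(a, c(2, 1, 3)) else t(a)
  grDevices::png(path, width = w, height = h)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, w), ylim = c(h, 0), xaxs = "i",
                        yaxs = "i", asp = 1)
  graphics::rasterImage(rast, 0, h, w, 0)
  found <- records[records$found, ]
  r_eq <- sqrt(found$area / pi)
  graphics::symbols(found$centroid_x, found$centroid_y, circles = r_eq,
                    inches = FALSE, add = TRUE, fg = "red")
  if (!is.null(scores))
    graphics::text(found$centroid_x, found$centroid_y - r_eq - 2,
                   scores[records$found], col = "red", cex = 0.5)
  invisible(path)
}
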