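#' Simulation configuration for synthetic screen data
#'
#' Bundles the parameters controlling all synthetic-data generators: plate
#' format, the amplitude of a smooth multiplicative spatial gradient,
#' multiplicative observation noise (CV-parameterised lognormal), per-strain
#' relative fitness effects, per-strain dead-cell fractions (drive colony
#' redness under a phloxine B-like stain), logistic growth parameters and the
#' imaging sampling schedule.
#'
#' Defaults emulate a standard knock-out screen plate: 5\% multiplicative
#' noise, a gradient with peak-to-trough amplitude 0.4, logistic growth with
#' carrying capacity 100 and rates around 0.5/h, imaged every 20 min for
#' 48 h.
#'
#' @param format plate format (96, 384 or 1536)
#' @param gradient_amplitude peak-to-trough amplitude of the multiplicative
#'   spatial surface (0 = flat)
#' @param noise_cv coefficient of variation of the lognormal observation
#'   noise
#' @param strain_effects named numeric vector mapping strain ID to relative
#'   fitness (1 = neutral); strains absent from the map are an error, except
#'   that a NULL map means "all strains neutral"
#' @param dead_fraction named numeric vector mapping strain ID to the
#'   fraction of dead cells in \[0,1\]; unnamed strains default to 0.05
#' @param seed integer seed; identical configs give identical outputs
#' @param image_colony_radius rendered radius (pixels) of a colony at the
#'   base value
#' @param image_pitch lattice pitch in pixels for rendered plate images
#' @param base_value raw colony value of a neutral strain with no gradient
#' @param growth list with K (carrying capacity), r_mean/r_sd (growth-rate
#'   distribution, per hour) and t0_mean/t0_sd (inflection-time
#'   distribution, hours)
#' @param sampling list with interval and duration in hours
#' @param condition_effects optional named list: condition -> named numeric
#'   vector of per-strain fitness multipliers applied in that condition
#' @return object of class `sim_config`
#' @export
sim_config <- function(format = 384,
                       gradient_amplitude = 0.4,
                       noise_cv = 0.05,
                       strain_effects = NULL,
                       dead_fraction = NULL,
                       seed = 1L,
                       image_colony_radius = 8,
                       image_pitch = 24,
                       base_value = 40,
                       growth = list(K = 100, r_mean = 0.5, r_sd = 0.1,
                                     t0_mean = 12, t0_sd = 1),
                       sampling = list(interval = 1 / 3, duration = 48),
                       condition_effects = NULL) {
  stopifnot(gradient_amplitude >= 0, noise_cv >= 0)
  if (!is.null(dead_fraction) &&
      any(dead_fraction < 0 | dead_fraction > 1))
    stop("dead_fraction values must lie in [0, 1]")
  if (!is.null(growth$K) && growth$K <= 0)
    stop("carrying capacity K must be positive")
  structure(list(format = format,
                 gradient_amplitude = gradient_amplitude,
                 noise_cv = noise_cv,
                 strain_effects = strain_effects,
                 dead_fraction = dead_fraction,
                 seed = as.integer(seed),
                 image_colony_radius = image_colony_radius,
                 image_pitch = image_pitch,
                 base_value = base_value,
                 growth = growth,
                 sampling = sampling,
                 condition_effects = condition_effects),
            class = "sim_config")
}

#' Random strain-effect map for a simulated screen
#'
#' Draws lognormal relative fitness effects (median 1) for a set of strains,
#' emulating the spread of fitness across a strain library.
#'
#' @param n number of strains
#' @param sdlog log-scale standard deviation of the effects (0.1 gives a
#'   realistic ~10\% fitness spread)
#' @param seed integer seed
#' @param prefix strain-ID prefix
#' @return named numeric vector suitable for [sim_config()]'s
#'   `strain_effects`
#' @export
random_strain_effects <- function(n, sdlog = 0.1, seed = 1,
                                  prefix = "strain") {
  set.seed(seed)
  stats::setNames(stats::rlnorm(n, 0, sdlog),
                  sprintf("%s_%04d", prefix, seq_len(n)))
}

# smooth separable cosine surface with requested peak-to-trough amplitude,
# centred on 1 (multiplicative)
gradient_surface <- function(n_rows, n_cols, amplitude) {
  rr <- if (n_rows > 1) cos(pi * (0:(n_rows - 1)) / (n_rows - 1)) else 1
  cc <- if (n_cols > 1) cos(pi * (0:(n_cols - 1)) / (n_cols - 1)) else 1
  1 + (amplitude / 2) * outer(rr, cc)
}

# lognormal multiplier with unit mean and given CV
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

strain_effect_matrix <- function(config, layout, condition = NULL) {
  eff <- matrix(1, layout$n_rows, layout$n_cols)
  se <- config$strain_effects
  if (!is.null(se)) {
    known <- c(names(se), "grid", "empty")
    unknown <- setdiff(unique(as.vector(layout$strain)), known)
    if (length(unknown))
      stop("strain(s) in layout without a configured effect: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    hit <- layout$strain %in% names(se)
    eff[hit] <- se[layout$strain[hit]]
  }
  if (!is.null(condition) && !is.null(config$condition_effects[[condition]])) {
    ce <- config$condition_effects[[condition]]
    hit <- layout$strain %in% names(ce)
    eff[hit] <- eff[hit] * ce[layout$strain[hit]]
  }
  eff
}

#' Simulate an endpoint fitness plate
#'
#' Each position's value is base x strain effect x spatial gradient x
#' lognormal noise. Positions with strain "empty" are missing.
#'
#' @param config a `sim_config`
#' @param layout a `plate_layout` matching the config's format
#' @param seed seed for this plate (defaults to the config seed)
#' @param condition optional condition name; applies the config's
#'   condition-specific effect multipliers
#' @return list with `values` (matrix) and `truth` (data.frame of row, col,
#'   strain, effect and the noise-free expected value)
#' @export
simulate_fitness_plate <- function(config, layout, seed = config$seed,
                                   condition = NULL) {
  d <- plate_dims(config$format)
  if (any(d != c(layout$n_rows, layout$n_cols)))
    stop("layout dimensions do not match config format")
  set.seed(seed)
  eff <- strain_effect_matrix(config, layout, condition)
  grad <- gradient_surface(layout$n_rows, layout$n_cols,
                           config$gradient_amplitude)
  expected <- config$base_value * eff * grad
  noise <- matrix(rlnorm_cv(length(expected), config$noise_cv),
                  layout$n_rows, layout$n_cols)
  values <- expected * noise
  empty <- layout$strain == "empty"
  values[empty] <- NA_real_
  truth <- data.frame(
    row = rep(0:(layout$n_rows - 1), times = layout$n_cols),
    col = rep(0:(layout$n_cols - 1), each = layout$n_rows),
    strain = as.vector(layout$strain),
    effect = as.vector(eff),
    expected = as.vector(expected),
    stringsAsFactors = FALSE
  )
  list(values = values, truth = truth)
}

#' Render a synthetic plate image
#'
#' Draws anti-aliased disks on an evenly spaced lattice, with radius
#' proportional to the square root of the supplied size (so rendered area is
#' proportional to size). In grey mode, colonies are bright on a dark
#' background, emulating transmission scanning. In rgb mode each colony's
#' colour mixes a pale colony colour with a red stain colour in proportion
#' to its strain's dead-cell fraction, emulating phloxine B staining on a
#' reflective scan.
#'
#' @param config a `sim_config`
#' @param layout a `plate_layout` (used for dead fractions in rgb mode);
#'   may be NULL in grey mode
#' @param sizes numeric matrix of colony sizes (same dims as the lattice);
#'   0 or NA renders no colony
#' @param mode "grey" or "rgb"
#' @param axis_ratio ellipse axis ratio (>1 elongates colonies along the
#'   row axis, lowering their circularity; used to exercise shape filters)
#' @return an [EBImage::Image] in \[0,1\], Grayscale or Color
#' @export
simulate_plate_image <- function(config, layout = NULL, sizes,
                                 mode = c("grey", "rgb"), axis_ratio = 1) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(sizes))
  nr <- nrow(sizes); nc <- ncol(sizes)
  if (!is.null(layout) && any(c(nr, nc) != c(layout$n_rows, layout$n_cols)))
    stop("sizes dimensions do not match layout")
  pitch <- config$image_pitch
  w <- nc * pitch; h <- nr * pitch

  dead <- matrix(0.05, nr, nc)
  if (!is.null(layout) && !is.null(config$dead_fraction)) {
    hit <- layout$strain %in% names(config$dead_fraction)
    dead[hit] <- config$dead_fraction[layout$strain[hit]]
  }

  bg_grey <- 0.15; fg_grey <- 0.85
  bg_rgb <- c(0.95, 0.95, 0.95)
  colony_rgb <- c(0.85, 0.78, 0.70)
  stain_rgb <- c(0.80, 0.10, 0.12)

  # coverage accumulates one plane (x = width, y = height; EBImage order)
  cov <- matrix(0, w, h)
  col_r <- matrix(0, w, h); col_g <- matrix(0, w, h); col_b <- matrix(0, w, h)

  for (r in seq_len(nr)) for (cl in seq_len(nc)) {
    s <- sizes[r, cl]
    if (!is.finite(s) || s <= 0) next
    rad <- config$image_colony_radius * sqrt(s / config$base_value)
    if (rad <= 0) next
    cx <- (cl - 0.5) * pitch; cy <- (r - 0.5) * pitch
    rx <- rad * sqrt(axis_ratio); ry <- rad / sqrt(axis_ratio)
    x0 <- max(1, floor(cx - rx - 2)); x1 <- min(w, ceiling(cx + rx + 2))
    y0 <- max(1, floor(cy - ry - 2)); y1 <- min(h, ceiling(cy + ry + 2))
    xs <- x0:x1; ys <- y0:y1
    # signed distance to the ellipse boundary, in units of the minor radius
    dx <- (xs - 0.5 - cx) / rx
    dy <- (ys - 0.5 - cy) / ry
    dmat <- sqrt(outer(dx^2, dy^2, "+"))
    a <- pmin(pmax(ry * (1 - dmat) + 0.5, 0), 1)   # anti-aliased coverage
    cov[xs, ys] <- pmax(cov[xs, ys], a)
    if (mode == "rgb") {
      ccol <- (1 - dead[r, cl]) * colony_rgb + dead[r, cl] * stain_rgb
      col_r[xs, ys] <- ifelse(a > 0, ccol[1], col_r[xs, ys])
      col_g[xs, ys] <- ifelse(a > 0, ccol[2], col_g[xs, ys])
      col_b[xs, ys] <- ifelse(a > 0, ccol[3], col_b[xs, ys])
    }
  }

  if (mode == "grey") {
    px <- bg_grey + cov * (fg_grey - bg_grey)
    EBImage::Image(px, colormode = "Grayscale")
  } else {
    px <- array(0, dim = c(w, h, 3))
    px[, , 1] <- bg_rgb[1] * (1 - cov) + col_r * cov
    px[, , 2] <- bg_rgb[2] * (1 - cov) + col_g * cov
    px[, , 3] <- bg_rgb[3] * (1 - cov) + col_b * cov
    EBImage::Image(px, colormode = "Color")
  }
}

#' Simulate a panel of logistic growth curves
#'
#' One curve per plate position: y(t) = K / (1 + exp(-r (t - t0))) with the
#' growth rate r drawn per position and, like the carrying capacity K,
#' scaled by the strain effect and the spatial gradient (less fit strains
#' both grow slower and plateau at smaller colonies, as colony-size proxies
#' do); every observation carries multiplicative lognormal noise.
#'
#' @param config a `sim_config`
#' @param layout a `plate_layout`
#' @param seed seed (defaults to the config seed)
#' @return list with `table` (data.frame: `timepoint` plus one "R-C" column
#'   per position) and `truth` (data.frame with each position's true maximum
#'   slope rK/4)
#' @export
simulate_growth_panel <- function(config, layout, seed = config$seed) {
  if (config$sampling$interval <= 0) stop("sampling interval must be > 0")
  if (config$growth$K <= 0) stop("carrying capacity K must be positive")
  set.seed(seed)
  tt <- seq(0, config$sampling$duration, by = config$sampling$interval)
  eff <- strain_effect_matrix(config, layout)
  grad <- gradient_surface(layout$n_rows, layout$n_cols,
                           config$gradient_amplitude)
  K <- config$growth$K
  nr <- layout$n_rows; nc <- layout$n_cols
  n <- nr * nc
  r0 <- matrix(stats::rnorm(n, config$growth$r_mean, config$growth$r_sd),
               nr, nc)
  r0[r0 < 0.05] <- 0.05
  r <- r0 * eff * grad
  Kmat <- K * eff * grad
  t0 <- matrix(stats::rnorm(n, config$growth$t0_mean, config$growth$t0_sd),
               nr, nc)

  cols <- vector("list", n)
  nms <- character(n)
  truth <- data.frame(row = integer(n), col = integer(n),
                      strain = character(n), max_slope_true = numeric(n),
                      stringsAsFactors = FALSE)
  k <- 0L
  for (cl in seq_len(nc)) for (rw in seq_len(nr)) {
    k <- k + 1L
    y <- Kmat[rw, cl] / (1 + exp(-r[rw, cl] * (tt - t0[rw, cl])))
    y <- y * rlnorm_cv(length(tt), config$noise_cv)
    cols[[k]] <- y
    nms[k] <- sprintf("%d-%d", rw - 1L, cl - 1L)
    truth$row[k] <- rw - 1L; truth$col[k] <- cl - 1L
    truth$strain[k] <- layout$strain[rw, cl]
    truth$max_slope_true[k] <- r[rw, cl] * Kmat[rw, cl] / 4
  }
  tab <- data.frame(timepoint = tt)
  for (k in seq_len(n)) tab[[nms[k]]] <- cols[[k]]
  list(table = tab, truth = truth)
}

#' Simulate a complete multi-plate experiment on disk
#'
#' Writes per-plate colony data CSVs (row, col, value, circularity), the
#' layout CSVs and an experimental design table referencing them, with
#' `n_plates` replicate plates per condition. Condition-specific strain
#' effects from the config are applied on top of the baseline effects. The
#' output is directly consumable by [aggregate_experiment()],
#' [plate_quality_filter()] and [test_condition_effects()].
#'
#' @param config a `sim_config`
#' @param n_plates replicate plates per condition
#' @param conditions character vector of condition names; the first is the
#'   control condition
#' @param out_dir output directory (created if absent)
#' @return the EDT as a data.frame (invisibly written to `edt.csv`), with
#'   the per-plate truth tables attached as attribute `truth`
#' @export
simulate_experiment <- function(config, n_plates, conditions, out_dir) {
  stopifnot(n_plates >= 1, length(conditions) >= 1)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  layout <- make_layout(config$format, "topleft96",
                        strains = names(config$strain_effects))
  strain_file <- file.path(out_dir, "layout_strains.csv")
  grid_file <- file.path(out_dir, "layout_grid.csv")
  write_layout(layout, strain_file, grid_file)

  rows <- list(); truths <- list()
  k <- 0L
  for (ci in seq_along(conditions)) for (p in seq_len(n_plates)) {
    k <- k + 1L
    pid <- sprintf("%s_rep%d", conditions[ci], p)
    sim <- simulate_fitness_plate(config, layout,
                                  seed = (config$seed + 997L * k) %% .Machine$integer.max,
                                  condition = conditions[ci])
    dat <- data.frame(
      row = rep(0:(layout$n_rows - 1), times = layout$n_cols),
      col = rep(0:(layout$n_cols - 1), each = layout$n_rows),
      value = as.vector(sim$values),
      circularity = 1
    )
    dpath <- file.path(out_dir, paste0(pid, ".csv"))
    utils::write.csv(dat, dpath, row.names = FALSE)
    rows[[k]] <- data.frame(plate_id = pid, data_path = dpath,
                            layout_path = strain_file,
                            condition = conditions[ci],
                            control = ci == 1L, batch = p,
                            stringsAsFactors = FALSE)
    sim$truth$plate_id <- pid
    sim$truth$condition <- conditions[ci]
    truths[[k]] <- sim$truth
  }
  edt <- do.call(rbind, rows)
  # layout flags live in a separate matrix file; record it for the reader
  utils::write.csv(edt, file.path(out_dir, "edt.csv"), row.names = FALSE)
  attr(edt, "truth") <- do.call(rbind, truths)
  attr(edt, "grid_file") <- grid_file
  edt
}
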