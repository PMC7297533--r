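# Independent brute-force oracle for row/column median normalisation:
# scalar double loops, no vectorised sweeps shared with the implementation.
brute_rowcol_normalise <- function(m) {
  out <- m
  for (r in seq_len(nrow(m))) {
    med <- median(m[r, ], na.rm = TRUE)
    for (cl in seq_len(ncol(m))) out[r, cl] <- m[r, cl] / med
  }
  res <- out
  for (cl in seq_len(ncol(out))) {
    med <- median(out[, cl], na.rm = TRUE)
    for (r in seq_len(nrow(out))) res[r, cl] <- out[r, cl] / med
  }
  res
}

# Hard-edged disk drawing on an (width x height [x 3]) array, EBImage
# orientation; independent of the package's anti-aliased renderer.
draw_disk <- function(px, cx, cy, radius, value) {
  w <- dim(px)[1]; h <- dim(px)[2]
  xs <- pmax(1, floor(cx - radius - 1)):pmin(w, ceiling(cx + radius + 1))
  ys <- pmax(1, floor(cy - radius - 1)):pmin(h, ceiling(cy + radius + 1))
  for (x in xs) for (y in ys) {
    if ((x - cx)^2 + (y - cy)^2 <= radius^2) {
      if (length(dim(px)) == 3) px[x, y, ] <- value else px[x, y] <- value
    }
  }
  px
}

# independent connected-components count: global threshold + bwlabel,
# bypassing the package's adaptive-threshold/lattice pipeline
count_components <- function(img, thr = 0.5) {
  a <- if (inherits(img, "Image")) EBImage::imageData(img) else img
  max(EBImage::bwlabel(a > thr))
}

# independent smooth-gradient surface (cosine bump, peak-to-trough amp)
gradient_surface_for_test <- function(nr, nc, amp) {
  1 + (amp / 2) * outer(cos(pi * (0:(nr - 1)) / (nr - 1)),
                        cos(pi * (0:(nc - 1)) / (nc - 1)))
}

# two-condition replicate table for testing the statistics module
make_replicate_table <- function(values_by_strain_cond) {
  rows <- list()
  for (s in names(values_by_strain_cond))
    for (cond in names(values_by_strain_cond[[s]])) {
      v <- values_by_strain_cond[[s]][[cond]]
      rows[[paste(s, cond)]] <- data.frame(
        strain = s, condition = cond, is_grid = FALSE,
        corrected_value = v)
    }
  do.call(rbind, rows)
}

# spiked two-condition screen: n_null + n_spiked strains, n replicates per
# condition; spiked strains shifted by `shift_sd` standard deviations in
# the treated condition
simulate_spiked_screen <- function(n_null = 200, n_spiked = 10, n = 6,
                                   shift_sd = 3, sd = 0.1) {
  strains <- c(sprintf("null_%03d", seq_len(n_null)),
               sprintf("spike_%02d", seq_len(n_spiked)))
  spiked <- grepl("^spike", strains)
  ctrl <- data.frame(strain = rep(strains, each = n), condition = "control",
                     is_grid = FALSE,
                     corrected_value = rnorm(length(strains) * n, 1, sd))
  trt <- data.frame(strain = rep(strains, each = n), condition = "treated",
                    is_grid = FALSE,
                    corrected_value = rnorm(length(strains) * n, 1, sd) +
                      rep(ifelse(spiked, shift_sd * sd, 0), each = n))
  list(table = rbind(ctrl, trt), spiked = strains[spiked])
}
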