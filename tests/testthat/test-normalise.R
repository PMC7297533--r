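plane_384 <- function() outer(2 * (0:15), rep(1, 24)) + 40

test_that("reference surface reproduces constants and planes exactly", {
  lay <- make_layout(384, "topleft96")
  flat <- matrix(50, 16, 24)
  surf <- build_reference_surface(flat, lay)
  expect_equal(surf$expected, matrix(50, 16, 24))
  expect_equal(surf$n_grid_used, 96)
  expect_length(surf$flags, 0)

  plane <- plane_384()
  surf2 <- build_reference_surface(plane, lay)
  expect_lt(max(abs(surf2$expected - plane)), 1e-6)
})

test_that("missing grid colonies are excluded and flagged", {
  lay <- make_layout(384, "topleft96")
  vals <- matrix(50, 16, 24)
  vals[1, 1] <- 0                       # grid position (0,0) failed to grow
  surf <- build_reference_surface(vals, lay)
  expect_equal(surf$n_grid_used, 95)
  expect_true(any(grepl("missing grid colony at \\(0,0\\)", surf$flags)))
  expect_equal(surf$expected, matrix(50, 16, 24))
})

test_that("degenerate grids are rejected", {
  lay <- make_layout(384, "topleft96")
  vals <- matrix(NA_real_, 16, 24)
  vals[1, c(1, 3)] <- 50                # 2 usable grid colonies, collinear
  expect_error(build_reference_surface(vals, lay), "degenerate grid")
})

test_that("grid normalisation is exact self-normalisation on a plane", {
  lay <- make_layout(384, "topleft96")
  corr <- grid_normalise(plane_384(), lay)
  expect_equal(as.vector(corr), rep(1, 384), tolerance = 1e-12)
})

test_that("a colony at twice its local expectation scores 2.0", {
  lay <- make_layout(384, "topleft96")
  vals <- matrix(50, 16, 24)
  vals[2, 2] <- 100                     # non-grid position
  corr <- grid_normalise(vals, lay)
  expect_equal(corr[2, 2], 2.0)
})

test_that("grid normalisation is invariant under global scaling", {
  lay <- make_layout(384, "topleft96")
  set.seed(42)
  vals <- matrix(rlnorm(384, log(40), 0.1), 16, 24)
  expect_equal(grid_normalise(7.3 * vals, lay), grid_normalise(vals, lay),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a multiplicative gradient shared by grid and tests cancels", {
  eff <- random_strain_effects(1440, sdlog = 0.1, seed = 9)
  lay <- make_layout(1536, "topleft96", strains = names(eff))
  cfg <- sim_config(format = 1536, gradient_amplitude = 0.4,
                    noise_cv = 0.05, strain_effects = eff, seed = 11)
  sim <- simulate_fitness_plate(cfg, lay)
  corr <- grid_normalise(sim$values, lay)
  rows <- row(corr)
  resid <- corr / matrix(sim$truth$effect, 32, 48)  # strain effect removed
  expect_lt(abs(cor(as.vector(resid), as.vector(rows))), 0.05)
})

test_that("row/column medians match hand computation on a 2x2 plate", {
  m <- matrix(c(2, 6, 4, 12), 2, 2)    # rows (2,4) and (6,12)
  out <- rowcol_median_normalise(m)
  expect_equal(out, matrix(1, 2, 2))
  expect_equal(rowcol_median_normalise(matrix(7, 4, 6)), matrix(1, 4, 6))
})

test_that("row/column median normalisation matches the brute-force oracle", {
  set.seed(100)
  for (i in 1:20) {
    m <- matrix(rlnorm(16 * 24, log(40), 0.3), 16, 24)
    expect_equal(rowcol_median_normalise(m), brute_rowcol_normalise(m),
                 tolerance = 1e-12)
  }
})

test_that("pure multiplicative row/column effects are removed in one pass", {
  # rank-1 plates (value = row effect x column effect) normalise to a fixed
  # point: a second pass changes nothing
  set.seed(7)
  m <- outer(rlnorm(8, 0, 0.3), rlnorm(12, 0, 0.3))
  once <- rowcol_median_normalise(m)
  expect_equal(once, matrix(1, 8, 12), tolerance = 1e-12)
  expect_equal(rowcol_median_normalise(once), once, tolerance = 1e-12)
  # on general plates repeated application contracts towards a fixed point
  m2 <- matrix(rlnorm(96, 0, 0.2), 8, 12)
  a <- rowcol_median_normalise(m2)
  b <- rowcol_median_normalise(a)
  c3 <- rowcol_median_normalise(b)
  expect_lt(max(abs(c3 - b)), max(abs(b - a)))
})

test_that("median normalisation preserves minority strain effects", {
  set.seed(21)
  nr <- 16; nc <- 24
  effect <- matrix(1, nr, nc)
  hit <- sample(nr * nc, round(0.1 * nr * nc))
  effect[hit] <- 0.5
  gradient <- outer(seq(0.8, 1.2, length.out = nr), rep(1, nc))
  m <- 40 * effect * gradient * matrix(rlnorm(nr * nc, 0, 0.02), nr, nc)
  out <- rowcol_median_normalise(m)
  expect_equal(median(out[-hit]), 1, tolerance = 0.05)
  expect_equal(median(out[hit]), 0.5, tolerance = 0.05)
})

test_that("zero medians are reported with their index", {
  expect_error(rowcol_median_normalise(rbind(c(0, 0), c(1, 1))), "row 0")
  expect_error(rowcol_median_normalise(cbind(c(0, 0), c(1, 1))), "column 0")
})

test_that("missing values never decrease through normalisation and are flagged", {
  eff <- random_strain_effects(288, seed = 3)
  cfg <- sim_config(format = 384, strain_effects = eff, seed = 3)
  dir <- tempfile(); lay <- make_layout(384, "topleft96")
  edt <- simulate_experiment(cfg, 1, "ctrl", dir)
  # poke holes into the data file
  d <- read.csv(edt$data_path[1])
  d$value[c(5, 50)] <- NA
  d$value[100] <- 0
  write.csv(d, edt$data_path[1], row.names = FALSE)
  tab <- aggregate_experiment(edt, "grid+rowcol")
  expect_gte(sum(!is.finite(tab$corrected_value)), 3)
  new_missing <- !is.finite(tab$corrected_value) & is.finite(tab$raw_value)
  expect_true(all(nzchar(tab$qc_flags[new_missing])))
})

test_that("aggregation without normalisation returns raw values verbatim", {
  eff <- random_strain_effects(288, seed = 5)
  cfg <- sim_config(format = 384, strain_effects = eff, seed = 5)
  dir <- tempfile()
  edt <- simulate_experiment(cfg, 3, "ctrl", dir)
  tab <- aggregate_experiment(edt, "none")
  expect_equal(nrow(tab), 3 * 384)
  expect_equal(tab$corrected_value, tab$raw_value)
  expect_true(all(tab$normalisation_method == "none"))
  # determinism: loading the same EDT twice gives identical tables
  expect_identical(tab, aggregate_experiment(edt, "none"))
})

test_that("parameter recovery: simulated fitness levels are recovered within 5%", {
  levels <- c(0.5, 0.8, 1.0, 1.2)
  eff <- setNames(rep(levels, each = 1), paste0("f", levels))
  # 32 replicate positions per fitness level, scattered over a 384 plate
  strains <- rep(names(eff), length.out = 288)
  cfg <- sim_config(format = 384, strain_effects = eff, seed = 17,
                    gradient_amplitude = 0.4, noise_cv = 0.05)
  lay <- make_layout(384, "topleft96", strains = strains)
  sim <- simulate_fitness_plate(cfg, lay)
  corr <- grid_normalise(sim$values, lay)
  for (s in names(eff)) {
    est <- mean(corr[lay$strain == s])
    expect_equal(est, eff[[s]], tolerance = 0.05)
  }
})
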