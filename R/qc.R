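#' Coefficient of variation of control colonies
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#' Computed over replicate control (grid) colonies it measures the precision
#' of a plate's readout.
#'
#' @param values numeric vector of control measurements; NAs are dropped
#' @return the CV as a dimensionless fraction
#' @export
compute_cv <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("CV needs at least 2 non-missing values")
  m <- mean(values)
  if (m == 0) stop("CV undefined: mean is 0")
  stats::sd(values) / m
}

#' Fraction of unexplained variance
#'
#' Ratio of the sample variance of the control colonies to the sample
#' variance of the entire dataset. Low values mean technical noise is small
#' relative to the biological signal.
#'
#' @param controls numeric vector of control measurements
#' @param all_values numeric vector of all measurements
#' @return the FUV as a dimensionless fraction
#' @export
compute_fuv <- function(controls, all_values) {
  controls <- controls[is.finite(controls)]
  all_values <- all_values[is.finite(all_values)]
  if (length(controls) < 2 || length(all_values) < 2)
    stop("FUV needs at least 2 non-missing values in each set")
  v_all <- stats::var(all_values)
  if (v_all == 0) stop("FUV undefined: variance of the full dataset is 0")
  stats::var(controls) / v_all
}

#' Neighbour-sum spatial bias
#'
#' For every interior plate position whose value and all 8 neighbours are
#' non-missing, pairs the colony value with the sum of its 8 neighbours and
#' reports the Pearson correlation. A positive correlation indicates
#' regional plate effects (spatial bias); a negative one would indicate
#' competition artefacts. Border positions are excluded rather than
#' renormalised so the statistic is comparable across plates.
#'
#' @param plate_values numeric matrix, at least 3 x 3
#' @return list with `correlation` and `pairs` (data.frame: row, col,
#'   value, neighbour_sum; 0-based positions)
#' @export
neighbour_bias <- function(plate_values) {
  stopifnot(is.matrix(plate_values))
  nr <- nrow(plate_values); nc <- ncol(plate_values)
  if (nr < 3 || nc < 3)
    stop("insufficient data: plate must be at least 3 x 3")
  rows <- integer(0); cols <- integer(0); val <- numeric(0); nsum <- numeric(0)
  for (r in 2:(nr - 1)) for (cl in 2:(nc - 1)) {
    block <- plate_values[(r - 1):(r + 1), (cl - 1):(cl + 1)]
    if (any(!is.finite(block))) next
    rows <- c(rows, r - 1L); cols <- c(cols, cl - 1L)
    val <- c(val, block[2, 2])
    nsum <- c(nsum, sum(block) - block[2, 2])
  }
  if (length(val) < 3)
    stop("insufficient data: no complete interior positions")
  list(correlation = stats::cor(val, nsum),
       pairs = data.frame(row = rows, col = cols, value = val,
                          neighbour_sum = nsum))
}

#' Pearson correlation matrix across timepoints
#'
#' Given one strain-averaged value vector per timepoint, returns the
#' symmetric matrix of pairwise Pearson correlations. Timepoints whose
#' vector is constant yield missing correlations and are reported in the
#' `flagged` attribute; diagonal entries are 1.
#'
#' @param per_timepoint_values list of equal-length numeric vectors, or a
#'   matrix with one column per timepoint
#' @return correlation matrix with attribute `flagged` (indices of constant
#'   timepoints)
#' @export
timepoint_correlation_matrix <- function(per_timepoint_values) {
  m <- if (is.list(per_timepoint_values))
    do.call(cbind, per_timepoint_values) else as.matrix(per_timepoint_values)
  if (ncol(m) < 2) stop("at least 2 timepoints are required")
  flagged <- which(apply(m, 2, function(v) stats::var(v, na.rm = TRUE) == 0))
  cm <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  if (length(flagged)) {
    cm[flagged, ] <- NA_real_
    cm[, flagged] <- NA_real_
  }
  diag(cm) <- 1
  attr(cm, "flagged") <- flagged
  cm
}

#' Per-plate quality statistics
#'
#' CV and FUV of the corrected values of each plate, with controls defined
#' as grid colonies, plus the pass/fail call at the given cutoffs.
#'
#' @param table an experiment table (see [aggregate_experiment()])
#' @param cv_max maximum allowed control CV
#' @param fuv_max maximum allowed FUV
#' @param value_col column holding the values to assess
#' @return data.frame: plate_id, cv, fuv, n_controls, n_total, pass
#' @export
plate_qc_stats <- function(table, cv_max = 0.2, fuv_max = 1,
                           value_col = "corrected_value") {
  stopifnot(all(c("plate_id", "is_grid", value_col) %in% names(table)))
  plates <- unique(table$plate_id)
  out <- lapply(plates, function(pid) {
    sub <- table[table$plate_id == pid, ]
    ctrl <- sub[[value_col]][sub$is_grid]
    allv <- sub[[value_col]]
    cv <- tryCatch(compute_cv(ctrl), error = function(e) NA_real_)
    fuv <- tryCatch(compute_fuv(ctrl, allv), error = function(e) NA_real_)
    data.frame(plate_id = pid, cv = cv, fuv = fuv,
               n_controls = sum(is.finite(ctrl)),
               n_total = sum(is.finite(allv)),
               pass = isTRUE(cv <= cv_max) && isTRUE(fuv <= fuv_max))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Quality filtering of an experiment table
#'
#' Colony-level: values of 0-sized colonies and colonies whose circularity
#' is below `circ_min` are set missing (with a qc flag). Plate-level:
#' plates whose control CV exceeds `cv_max` or whose FUV exceeds `fuv_max`
#' are removed entirely. Surviving numeric values are never altered.
#'
#' @param table an experiment table carrying `circularity` and `is_grid`
#' @param cv_max plate-level control-CV cutoff (default 0.2)
#' @param fuv_max plate-level FUV cutoff (default 1)
#' @param circ_min colony-level circularity cutoff (default 0.85); set to
#'   NULL to skip the circularity filter
#' @return the filtered table, with attributes `dropped_plates` (character
#'   vector) and `plate_qc` (the [plate_qc_stats()] table)
#' @export
plate_quality_filter <- function(table, cv_max = 0.2, fuv_max = 1,
                                 circ_min = 0.85) {
  stopifnot(is.data.frame(table))
  if (!is.null(circ_min) && !"circularity" %in% names(table))
    stop("schema error: circularity column required for the shape filter")

  bad <- is.finite(table$raw_value) & table$raw_value == 0
  if (!is.null(circ_min))
    bad <- bad | (is.finite(table$circularity) & table$circularity < circ_min)
  bad <- bad & is.finite(table$corrected_value)
  if (any(bad)) {
    table$corrected_value[bad] <- NA_real_
    table$qc_flags[bad] <- paste_flag(table$qc_flags[bad],
                                      "failed colony quality filter")
  }

  qc <- plate_qc_stats(table, cv_max, fuv_max)
  dropped <- qc$plate_id[!qc$pass]
  if (length(dropped)) {
    message("removing ", length(dropped), " plate(s) failing CV/FUV cutoffs: ",
            paste(dropped, collapse = ", "))
    table <- table[!table$plate_id %in% dropped, ]
  }
  rownames(table) <- NULL
  attr(table, "dropped_plates") <- dropped
  attr(table, "plate_qc") <- qc
  table
}
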