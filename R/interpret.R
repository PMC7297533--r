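#' Replicate summary statistics
#'
#' Per group (any combination of grouping columns): replicate count, mean,
#' median, sample SD, CV and number of missing values of the corrected
#' fitness.
#'
#' @param table an experiment table
#' @param group_by character vector of grouping column names (e.g.
#'   c("strain", "condition"))
#' @param value_col value column to summarise
#' @return data.frame with one row per group
#' @export
summarise_replicates <- function(table, group_by = c("strain", "condition"),
                                 value_col = "corrected_value") {
  if (length(group_by) == 0) stop("schema error: empty grouping column set")
  miss <- setdiff(c(group_by, value_col), names(table))
  if (length(miss))
    stop("schema error: column(s) not in table: ", paste(miss, collapse = ", "))
  key <- interaction(table[group_by], drop = TRUE, lex.order = TRUE)
  parts <- split(seq_len(nrow(table)), key)
  out <- lapply(parts, function(idx) {
    v <- table[[value_col]][idx]
    ok <- v[is.finite(v)]
    s <- data.frame(table[idx[1], group_by, drop = FALSE],
                    n = length(ok),
                    mean = if (length(ok)) mean(ok) else NA_real_,
                    median = if (length(ok)) stats::median(ok) else NA_real_,
                    sd = if (length(ok) > 1) stats::sd(ok) else NA_real_,
                    n_missing = sum(!is.finite(v)))
    s$cv <- if (length(ok) > 1 && s$mean != 0) s$sd / s$mean else NA_real_
    s
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Vectorised two-sample t-tests from group summaries; returns two-sided
# p-values. "student" pools the variances (exact size under equal
# variances, which matters at triplicate-scale n); "welch" uses the
# Satterthwaite approximation. Degenerate cases: both groups constant and
# equal -> p 1; both constant but different -> p NA (the test is
# undefined, as stats::t.test would error).
tstat_p <- function(m1, v1, n1, m2, v2, n2, flavour = "student") {
  if (flavour == "welch") {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    vp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- vp * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  }
  p <- 2 * stats::pt(-abs(m1 - m2) / sqrt(se2), df)
  degen <- is.finite(v1) & is.finite(v2) & v1 == 0 & v2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, NA_real_)
  p
}

#' Differential fitness testing
#'
#' Tests for condition-specific fitness effects on the corrected values of
#' an experiment table. Two testing axes are available:
#'
#' * `across_conditions` (recommended for condition screens): for every
#'   (strain, condition != control) pair, the strain's replicate values in
#'   the condition are compared with the same strain's values in the
#'   control condition.
#' * `within_condition`: every strain is compared against the reference
#'   population of all other non-grid strains in the same condition.
#'
#' The default test is the pooled-variance two-sample t-test, whose size is
#' exact under the null at the triplicate-scale replicate numbers typical
#' of colony screens; Welch's unequal-variance test and a Wilcoxon
#' rank-sum alternative are available. The effect size is the ratio of
#' medians (condition / control), matching how relative fitness is
#' reported elsewhere in the package (1 = no effect). P-values are
#' adjusted with Benjamini-Hochberg across all contrasts of the call
#' (optionally per condition). Grid colonies are excluded by default —
#' they define the reference and are not hypotheses.
#'
#' @param table an experiment table
#' @param control_condition name of the control condition (required for
#'   `across_conditions`)
#' @param axis "across_conditions" or "within_condition"
#' @param value_col value column to test
#' @param test "student", "welch" or "wilcoxon"
#' @param include_grid keep grid-strain rows as test hypotheses
#' @param adjust_per_condition apply BH within each condition instead of
#'   across the whole call
#' @return data.frame with one row per contrast: strain, condition,
#'   control_condition, n_cond, n_ctrl, effect_ratio, mean_cond, mean_ctrl,
#'   p_value, p_adj, test_name, reason ("" for valid contrasts; skipped
#'   contrasts carry missing p-values and the reason)
#' @export
test_condition_effects <- function(table, control_condition = NULL,
                                   axis = c("across_conditions",
                                            "within_condition"),
                                   value_col = "corrected_value",
                                   test = c("student", "welch", "wilcoxon"),
                                   include_grid = FALSE,
                                   adjust_per_condition = FALSE) {
  axis <- match.arg(axis)
  test <- match.arg(test)
  stopifnot(all(c("strain", "condition", value_col) %in% names(table)))
  if (!include_grid && "is_grid" %in% names(table))
    table <- table[!table$is_grid, ]
  table <- table[is.finite(table[[value_col]]), ]

  conditions <- sort(unique(table$condition))
  if (axis == "across_conditions") {
    if (is.null(control_condition))
      stop("configuration error: control_condition is required")
    if (!control_condition %in% conditions)
      stop("configuration error: control condition '", control_condition,
           "' absent from table")
  }
  test_name <- switch(test, student = "Student t-test",
                      welch = "Welch t-test", wilcoxon = "Wilcoxon rank-sum")

  v <- table[[value_col]]
  key <- paste(table$strain, table$condition, sep = "\r")
  grp <- split(v, key)
  stat <- data.frame(key = names(grp),
                     n = lengths(grp),
                     mean = vapply(grp, mean, 0),
                     var = vapply(grp, stats::var, 0),
                     median = vapply(grp, stats::median, 0),
                     stringsAsFactors = FALSE)
  rownames(stat) <- stat$key

  if (axis == "across_conditions") {
    ks <- strsplit(stat$key, "\r", fixed = TRUE)
    strain <- vapply(ks, `[`, "", 1)
    cond <- vapply(ks, `[`, "", 2)
    sel <- cond != control_condition
    res <- data.frame(strain = strain[sel], condition = cond[sel],
                      control_condition = control_condition,
                      stringsAsFactors = FALSE)
    a <- stat[paste(res$strain, res$condition, sep = "\r"), ]
    b <- stat[paste(res$strain, control_condition, sep = "\r"), ]
  } else {
    # each strain against the pooled other strains of the same condition
    ks <- strsplit(stat$key, "\r", fixed = TRUE)
    strain <- vapply(ks, `[`, "", 1)
    cond <- vapply(ks, `[`, "", 2)
    res <- data.frame(strain = strain, condition = cond,
                      control_condition = "population",
                      stringsAsFactors = FALSE)
    a <- stat
    b <- do.call(rbind, lapply(seq_len(nrow(res)), function(i) {
      ref <- v[table$condition == res$condition[i] &
                 table$strain != res$strain[i]]
      data.frame(n = length(ref),
                 mean = if (length(ref)) mean(ref) else NA_real_,
                 var = if (length(ref) > 1) stats::var(ref) else NA_real_,
                 median = if (length(ref)) stats::median(ref) else NA_real_)
    }))
  }

  res$n_cond <- a$n
  res$n_ctrl <- ifelse(is.na(b$n), 0L, b$n)
  res$effect_ratio <- ifelse(is.finite(b$median) & b$median != 0,
                             a$median / b$median, NA_real_)
  res$mean_cond <- a$mean
  res$mean_ctrl <- b$mean
  valid <- res$n_cond >= 2 & res$n_ctrl >= 2
  res$p_value <- NA_real_
  if (test == "wilcoxon") {
    for (i in which(valid)) {
      x <- grp[[paste(res$strain[i], res$condition[i], sep = "\r")]]
      y <- if (axis == "across_conditions")
        grp[[paste(res$strain[i], control_condition, sep = "\r")]]
      else v[table$condition == res$condition[i] &
               table$strain != res$strain[i]]
      res$p_value[i] <- suppressWarnings(
        stats::wilcox.test(x, y, exact = FALSE)$p.value)
    }
  } else {
    res$p_value[valid] <- tstat_p(a$mean[valid], a$var[valid], a$n[valid],
                                  b$mean[valid], b$var[valid], b$n[valid],
                                  flavour = test)
  }
  res$test_name <- test_name
  res$reason <- ifelse(!valid, "fewer than 2 replicates",
                       ifelse(is.na(res$p_value),
                              "test undefined (constant data)", ""))

  res <- res[order(res$strain, res$condition), ]
  if (adjust_per_condition) {
    res$p_adj <- NA_real_
    for (cond in unique(res$condition)) {
      s <- res$condition == cond
      res$p_adj[s] <- adjust_pvalues(res$p_value[s])
    }
  } else {
    res$p_adj <- adjust_pvalues(res$p_value)
  }
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a validated wrapper around
#' [stats::p.adjust()]. Missing p-values stay missing and do not count
#' towards the number of tests.
#'
#' @param p numeric vector of p-values in \[0,1\]
#' @param method only "BH"
#' @return adjusted p-values, capped at 1
#' @export
adjust_pvalues <- function(p, method = "BH") {
  method <- match.arg(method)
  if (any(is.finite(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
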