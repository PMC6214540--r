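#' Intra-individual percent change
#'
#' (M1 - M0) / M0 x 100, vectorised. Cohort-level change is reported as
#' the mean of per-subject percent changes (not the ratio of the cohort
#' means), the convention used throughout this package.
#'
#' @param m0_value baseline value(s), strictly positive.
#' @param m1_value follow-up value(s).
#' @return Percent change(s).
#' @export
percent_change <- function(m0_value, m1_value) {
  if (any(m0_value <= 0)) stop("m0_value must be positive")
  (m1_value - m0_value) / m0_value * 100
}

#' Shapiro-Wilk normality gate
#'
#' Tests a vector (typically per-subject percent changes) for normality;
#' the downstream one-sample test is chosen by this gate at alpha = 0.05.
#' A constant vector is flagged degenerate and treated as non-normal.
#'
#' @param values numeric vector, n >= 3.
#' @param alpha gate level (default 0.05).
#' @return List with `W`, `p`, `is_normal`, `degenerate`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  if (length(values) < 3) stop("normality test needs n >= 3")
  if (stats::sd(values) == 0)
    return(list(W = NA_real_, p = NA_real_, is_normal = FALSE,
                degenerate = TRUE))
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value,
       is_normal = sw$p.value >= alpha, degenerate = FALSE)
}

#' Significance stars
#'
#' `""` for p >= 0.05, `"*"` for p < 0.05, `"**"` for p < 0.01,
#' `"***"` for p < 0.001.
#'
#' @param p p-value(s).
#' @return Character vector of star strings.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) return(NA_character_)
    if (pp < 0.001) "***" else if (pp < 0.01) "**" else if (pp < 0.05) "*" else ""
  }, character(1))
}

#' Normality-gated one-sample test of percent changes against zero
#'
#' If the normality gate passes, a two-sided one-sample t-test against a
#' 0 % mean; otherwise a two-sided one-sample Wilcoxon signed-rank test
#' against a 0 % median (zeros dropped, the standard signed-rank
#' convention; exact p for n <= 25 without ties, normal approximation
#' otherwise). A 95 % t-based confidence interval of the mean percent
#' change is always reported (it is what error bars on mean changes show).
#'
#' @param values per-subject percent changes, n >= 3.
#' @param gate_result output of [normality_gate()]; computed from
#'   `values` if missing.
#' @return List with `n`, `mean`, `ci95` (length 2), `normality_p`,
#'   `test_used` (`"t"` or `"wilcoxon"`), `statistic`, `p_value`,
#'   `stars`, `flag`.
#' @export
one_sample_change_test <- function(values, gate_result = NULL) {
  n <- length(values)
  if (n < 3) stop("need n >= 3")
  if (is.null(gate_result)) gate_result <- normality_gate(values)
  m <- mean(values)
  se <- stats::sd(values) / sqrt(n)
  ci <- m + c(-1, 1) * stats::qt(0.975, n - 1) * se
  if (all(values == 0)) {
    return(list(n = n, mean = 0, ci95 = c(0, 0),
                normality_p = gate_result$p, test_used = "wilcoxon",
                statistic = NA_real_, p_value = 1, stars = "", flag = TRUE))
  }
  if (gate_result$is_normal) {
    tt <- stats::t.test(values, mu = 0)
    res <- list(test_used = "t", statistic = unname(tt$statistic),
                p_value = tt$p.value)
  } else {
    nz <- values[values != 0]
    exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
    wt <- suppressWarnings(stats::wilcox.test(nz, mu = 0, exact = exact,
                                              correct = !exact))
    res <- list(test_used = "wilcoxon", statistic = unname(wt$statistic),
                p_value = wt$p.value)
  }
  c(list(n = n, mean = m, ci95 = ci, normality_p = gate_result$p),
    res, list(stars = significance_stars(res$p_value), flag = FALSE))
}

#' Count subjects by direction of change
#'
#' Counts subjects whose value increased, decreased or stayed the same
#' between timepoints, with equality judged after rounding both values to
#' a stated precision (matching how values are stored in report tables).
#'
#' @param m0_values,m1_values paired per-subject values.
#' @param digits rounding precision for the equality test (default 1).
#' @return List with `n_plus`, `n_minus`, `n_zero`.
#' @export
sign_count <- function(m0_values, m1_values, digits = 1) {
  if (length(m0_values) != length(m1_values))
    stop("m0 and m1 vectors must be paired (equal length)")
  a <- round(m0_values, digits); b <- round(m1_values, digits)
  list(n_plus = sum(b > a), n_minus = sum(b < a), n_zero = sum(b == a))
}

cohort_parameters <- function() {
  c(bmi_kg_m2 = "BMI [kg/m2]", v_vat_l = "V_VAT-T [L]",
    t1_vat_ms = "T1_VAT [ms]", t1_sat_ms = "T1_SAT [ms]",
    ff_vat_pct = "FF_VAT [%]", ff_sat_pct = "FF_SAT [%]")
}

#' Full cohort change report
#'
#' For each parameter present in the cohort: M0/M1 mean and SD, mean
#' per-subject percent change with 95 % CI, Shapiro-Wilk gated one-sample
#' test of the percent changes against zero, significance stars, and the
#' direction counts.
#'
#' @param records long-format data.frame with columns `subject_id`,
#'   `timepoint` (`"M0"`/`"M1"`) and one column per parameter (see
#'   [make_cohort()] for the canonical names).
#' @param parameters parameter columns to report; default all canonical
#'   ones found in `records`.
#' @return Object of class `cohort_summary`: a data.frame with one row
#'   per parameter.
#' @export
cohort_summary <- function(records, parameters = NULL) {
  stopifnot(is.data.frame(records),
            all(c("subject_id", "timepoint") %in% names(records)))
  if (is.null(parameters))
    parameters <- intersect(names(cohort_parameters()), names(records))
  if (length(parameters) == 0) stop("no known parameter columns in records")
  m0 <- records[records$timepoint == "M0", ]
  m1 <- records[records$timepoint == "M1", ]
  common <- intersect(m0$subject_id, m1$subject_id)
  if (length(common) < 3) stop("need at least 3 complete paired subjects")
  m0 <- m0[match(common, m0$subject_id), ]
  m1 <- m1[match(common, m1$subject_id), ]

  rows <- lapply(parameters, function(p) {
    if (!p %in% names(records)) {
      warning("parameter column missing: ", p)
      return(NULL)
    }
    v0 <- m0[[p]]; v1 <- m1[[p]]
    keep <- !is.na(v0) & !is.na(v1)
    v0 <- v0[keep]; v1 <- v1[keep]
    pc <- percent_change(v0, v1)
    gate <- normality_gate(pc)
    tst <- one_sample_change_test(pc, gate)
    sc <- sign_count(v0, v1)
    data.frame(parameter = p, n = length(pc),
               mean_m0 = mean(v0), sd_m0 = stats::sd(v0),
               mean_m1 = mean(v1), sd_m1 = stats::sd(v1),
               mean_pct_change = tst$mean,
               ci95_lo = tst$ci95[1], ci95_hi = tst$ci95[2],
               normality_p = gate$p, test_used = tst$test_used,
               p_value = tst$p_value, stars = tst$stars,
               n_plus = sc$n_plus, n_minus = sc$n_minus,
               n_zero = sc$n_zero, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  labs <- cohort_parameters()
  cat(sprintf("Paired cohort change report (n = %d)\n\n", x$n[1]))
  cat(sprintf("%-12s %15s %15s %18s %9s %8s\n",
              "parameter", "M0 (mean+/-SD)", "M1 (mean+/-SD)",
              "change % [95% CI]", "test", "p"))
  for (i in seq_len(nrow(x))) {
    lab <- if (x$parameter[i] %in% names(labs)) labs[[x$parameter[i]]] else x$parameter[i]
    cat(sprintf("%-12s %7.2f+/-%-6.2f %7.2f+/-%-6.2f %+6.1f [%+5.1f,%+5.1f] %9s %8.3g %s\n",
                lab, x$mean_m0[i], x$sd_m0[i], x$mean_m1[i], x$sd_m1[i],
                x$mean_pct_change[i], x$ci95_lo[i], x$ci95_hi[i],
                x$test_used[i], x$p_value[i], x$stars[i]))
  }
  invisible(x)
}
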