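#' Welch's t-test from group summaries
#'
#' Two-sample unequal-variance t-test computed directly from each group's
#' mean, SD and n, as needed when comparing a small carrier group against a
#' large cohort for which only summary statistics are published. With the
#' background n in the hundreds of thousands the Welch degrees of freedom
#' approach `n1 - 1` and the p-value is driven almost entirely by the small
#' group's summary.
#'
#' @param mean1,sd1,n1 Summary of group 1 (`n1 >= 2`, `sd1 >= 0`).
#' @param mean2,sd2,n2 Summary of group 2.
#' @return List with `t`, `df` (Welch-Satterthwaite) and `p_two_sided`.
#' @examples
#' welch_t_summary(163.6, 20.8, 9, 144.2, 24.1, 450984)$p_two_sided  # ~0.023
#' @export
welch_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be non-negative")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  if (v1 + v2 == 0) {
    if (mean1 == mean2) return(list(t = 0, df = n1 + n2 - 2, p_two_sided = 1))
    warning("both SDs are zero with different means: t is infinite")
    return(list(t = sign(mean1 - mean2) * Inf, df = NA_real_, p_two_sided = 0))
  }
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p_two_sided = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson's chi-square with 1 degree of freedom; the Yates continuity
#' correction is off by default and exposed as a flag.
#'
#' @param table A [contingency_table()].
#' @param correct Apply the continuity correction (default `FALSE`).
#' @return List with `statistic`, `df` and `p`.
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  stopifnot(inherits(table, "contingency_table"))
  mat <- matrix(c(table$a, table$b, table$c, table$d), 2L, byrow = TRUE)
  expected <- outer(rowSums(mat), colSums(mat)) / sum(mat)
  if (any(expected <= 0))
    stop("zero expected count: chi-square statistic undefined")
  ht <- suppressWarnings(stats::chisq.test(mat, correct = correct))
  list(statistic = unname(ht$statistic), df = 1L, p = unname(ht$p.value))
}

#' CKD-EPI 2009 estimated glomerular filtration rate
#'
#' The 2009 CKD Epidemiology Collaboration creatinine equation:
#' `eGFR = 141 * min(Scr/k, 1)^alpha * max(Scr/k, 1)^-1.209 * 0.993^age
#'  * 1.018 [female] * 1.159 [black]`, with `k = 0.7` (female) / `0.9`
#' (male) and `alpha = -0.329` (female) / `-0.411` (male). The ethnicity
#' coefficient of the published 2009 equation is retained for fidelity and is
#' controlled by the `black` flag.
#'
#' @param creatinine_mg_dl Serum creatinine, mg/dL (> 0). Vectorized.
#' @param age Age in years (> 0).
#' @param sex `"female"` or `"male"` (also accepts `"F"`/`"M"`).
#' @param black Logical, ethnicity coefficient of the published equation.
#' @return eGFR in mL/min/1.73 m^2.
#' @examples
#' ckd_epi_2009(0.7, 50, "female")  # ~101
#' @export
ckd_epi_2009 <- function(creatinine_mg_dl, age, sex, black = FALSE) {
  if (any(creatinine_mg_dl <= 0)) stop("creatinine must be positive")
  if (any(age <= 0)) stop("age must be positive")
  sex <- tolower(substr(as.character(sex), 1L, 1L))
  if (!all(sex %in% c("f", "m"))) stop("sex must be 'female' or 'male'")
  female <- sex == "f"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  r <- creatinine_mg_dl / kappa
  141 * pmin(r, 1)^alpha * pmax(r, 1)^(-1.209) * 0.993^age *
    ifelse(female, 1.018, 1) * ifelse(black, 1.159, 1)
}

#' KDIGO CKD staging from eGFR and albuminuria
#'
#' G stages by eGFR (mL/min/1.73 m^2): G1 >= 90, G2 60-89, G3a 45-59,
#' G3b 30-44, G4 15-29, G5 < 15. A stages by albumin:creatinine ratio
#' (mg/mmol): A1 < 3, A2 3-30, A3 > 30. The CKD flag is `TRUE` when
#' eGFR < 60 or albuminuria reaches A2; the KDIGO chronicity (> 3 months)
#' criterion is the caller's responsibility.
#'
#' @param egfr eGFR values (>= 0). Vectorized.
#' @param acr_mg_per_mmol Albumin:creatinine ratio, mg/mmol; `NA` allowed.
#' @return Data frame with `g_stage`, `a_stage` and `ckd`.
#' @export
ckd_stage <- function(egfr, acr_mg_per_mmol = NA_real_) {
  if (any(egfr < 0, na.rm = TRUE)) stop("eGFR must be non-negative")
  acr <- rep_len(acr_mg_per_mmol, length(egfr))
  g <- cut(egfr, breaks = c(-Inf, 15, 30, 45, 60, 90, Inf), right = FALSE,
           labels = c("G5", "G4", "G3b", "G3a", "G2", "G1"))
  a <- ifelse(is.na(acr), NA_character_,
              ifelse(acr < 3, "A1", ifelse(acr <= 30, "A2", "A3")))
  ckd <- egfr < 60 | (!is.na(a) & a %in% c("A2", "A3"))
  data.frame(g_stage = as.character(g), a_stage = as.character(a),
             ckd = ckd, stringsAsFactors = FALSE)
}

#' Kaplan-Meier renal survival curve
#'
#' Product-limit estimator of renal survival (time to renal replacement
#' therapy, with censoring for those who never reach it), via
#' [survival::survfit()]. The median is the first time at which the survival
#' function drops to 0.5 or below, `NA` if it never does.
#'
#' @param time Positive times (age in years at event or censoring).
#' @param event Logical/0-1 event indicator.
#' @return An object of class `km_curve`: list with step-function `time`,
#'   `surv`, `n_risk`, `n_event`, `median` and the underlying `survfit`
#'   object in `fit`.
#' @export
km_curve <- function(time, event) {
  if (length(time) == 0L) stop("need at least one record")
  if (any(time <= 0)) stop("times must be positive")
  event <- as.integer(as.logical(event))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  med <- fit$time[fit$surv <= 0.5][1]
  structure(
    list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
         n_event = fit$n.event, median = unname(med), fit = fit),
    class = "km_curve"
  )
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", sum(x$n_event), "events over",
      length(x$time), "distinct times; median =",
      if (is.na(x$median)) "not reached" else x$median, "\n")
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  plot(x$fit, xlab = "age (years)", ylab = "renal survival", ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected log-rank test with hypergeometric
#' variance at each distinct event time, via [survival::survdiff()];
#' p-value from chi-square with 1 df.
#'
#' @param time Positive times.
#' @param event Logical/0-1 event indicator (at least one event required).
#' @param group Two-level grouping factor (e.g. sex).
#' @return List with `statistic`, `df` and `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) stop("exactly two groups required")
  event <- as.integer(as.logical(event))
  if (sum(event) == 0L) stop("no events: log-rank test undefined")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(statistic = unname(sd$chisq), df = 1L,
       p = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE))
}
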