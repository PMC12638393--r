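#' Postoperative headache-relief classification
#'
#' A patient is classified as relieved when the pain visual-analogue-scale
#' (VAS, 0-10) score dropped by strictly more than two points after surgery
#' AND quality of life improved. A reduction of exactly two points does not
#' qualify.
#'
#' @param vas_pre,vas_post pain VAS scores in [0, 10] (vectorised).
#' @param qol_improved logical: quality of life improved.
#' @return Logical vector.
#' @export
classify_relief <- function(vas_pre, vas_post, qol_improved) {
  if (any(vas_pre < 0 | vas_pre > 10 | vas_post < 0 | vas_post > 10))
    stop("VAS scores must lie in [0, 10]")
  (vas_pre - vas_post) > 2 & as.logical(qol_improved)
}

#' Chicago Chiari Outcome Scale improvement flag
#'
#' The CCOS totals four domains scored 1-4 (range 4-16); totals of 13-16
#' are read as postoperative improvement.
#'
#' @param ccos_total integer total score in [4, 16] (vectorised).
#' @return Logical vector.
#' @export
ccos_improved <- function(ccos_total) {
  if (any(ccos_total < 4 | ccos_total > 16))
    stop("CCOS total must lie in [4, 16]")
  ccos_total >= 13 & ccos_total <= 16
}

#' Improvement rate
#'
#' Percentage of improved patients, rounded to one decimal as reported
#' clinically.
#'
#' @param improved logical vector, one element per patient (non-empty).
#' @return Percentage in [0, 100], one decimal.
#' @export
improvement_rate <- function(improved) {
  if (length(improved) == 0L) stop("no patients")
  round(100 * sum(as.logical(improved)) / length(improved), 1)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS distance of the empirical CDF against a normal reference.
#' By default the reference uses the sample mean and SD (plug-in); the
#' classic asymptotic Kolmogorov p-value is then conservative (it is exact
#' only for a fully prespecified reference), which is the usual caveat when
#' the KS test is used as a normality gate.
#'
#' @param x numeric sample, n >= 5, not constant.
#' @param mean,sd reference normal parameters; default plug-in estimates.
#' @return List with `statistic` (D), `p_value`, `n`.
#' @export
ks_normality <- function(x, mean = NULL, sd = NULL) {
  n <- length(x)
  if (n < 5L) stop("need at least 5 observations")
  if (stats::sd(x) == 0) stop("constant sample")
  if (is.null(mean)) mean <- base::mean(x)
  if (is.null(sd)) sd <- stats::sd(x)
  xs <- sort(x)
  f <- stats::pnorm(xs, mean, sd)
  d_plus <- max(seq_len(n) / n - f)
  d_minus <- max(f - (seq_len(n) - 1L) / n)
  d <- max(d_plus, d_minus)
  # asymptotic Kolmogorov tail with Stephens' small-sample scaling
  lambda <- (sqrt(n) + 0.12 + 0.11 / sqrt(n)) * d
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  list(statistic = d, p_value = min(max(p, 0), 1), n = n)
}

#' Group summary statistics
#'
#' @param n group size (>= 2); `mean`, `sd` in the variable's units
#'   (uL per cardiac cycle for stroke volumes).
#' @param mean,sd summary values; `sd >= 0`.
#' @return Object of class `summary_stats`.
#' @export
summary_stats <- function(n, mean, sd) {
  if (n < 2L) stop("n must be >= 2")
  if (sd < 0) stop("sd must be >= 0")
  structure(list(n = as.integer(n), mean = mean, sd = sd),
            class = "summary_stats")
}

group_comparison <- function(variable, n1, n2, mean1, sd1, mean2, sd2,
                             test, statistic, df, p_value, alpha = 0.05,
                             note = NULL) {
  structure(list(variable = variable, n1 = n1, n2 = n2,
                 mean1 = mean1, sd1 = sd1, mean2 = mean2, sd2 = sd2,
                 test = test, statistic = statistic, df = df,
                 p_value = p_value, significant = p_value <= alpha,
                 alpha = alpha, note = note),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %.4g +/- %.4g (n=%d) vs %.4g +/- %.4g (n=%d)  [%s] p = %.3g%s\n",
              x$variable, x$mean1, x$sd1, x$n1, x$mean2, x$sd2, x$n2,
              x$test, x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}

#' Two-sample t test from summary statistics
#'
#' Computes the two-sided two-sample t test directly from group means, SDs
#' and sizes — the form needed to re-test published summary tables. The
#' `welch` variant (unequal variances, Welch-Satterthwaite df) is the
#' default because it is the variant that reproduces the published
#' significance pattern for the stroke-volume table; the pooled-variance
#' `student` form is available for comparison and its use is recorded in
#' the result's `test` field.
#'
#' @param a,b [summary_stats()] for the two groups (or lists with fields
#'   `n`, `mean`, `sd`).
#' @param variant `"welch"` (default) or `"student"`.
#' @param variable label carried into the result.
#' @param alpha significance level (default 0.05).
#' @return A `group_comparison`.
#' @export
t_test_summary <- function(a, b, variant = c("welch", "student"),
                           variable = "sv", alpha = 0.05) {
  variant <- match.arg(variant)
  if (a$n < 2L || b$n < 2L) stop("each group needs n >= 2")
  if (a$sd == 0 && b$sd == 0 && a$mean == b$mean) {
    return(group_comparison(variable, a$n, b$n, a$mean, a$sd, b$mean, b$sd,
                            test = paste0("t_", variant), statistic = 0,
                            df = a$n + b$n - 2, p_value = 1, alpha = alpha))
  }
  if (variant == "welch") {
    se2_1 <- a$sd^2 / a$n; se2_2 <- b$sd^2 / b$n
    se <- sqrt(se2_1 + se2_2)
    t <- (a$mean - b$mean) / se
    df <- (se2_1 + se2_2)^2 /
      (se2_1^2 / (a$n - 1) + se2_2^2 / (b$n - 1))
  } else {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  }
  p <- 2 * stats::pt(-abs(t), df)
  group_comparison(variable, a$n, b$n, a$mean, a$sd, b$mean, b$sd,
                   test = paste0("t_", variant), statistic = t, df = df,
                   p_value = p, alpha = alpha)
}

#' Two-sample t test from raw samples
#'
#' Identical by construction to [t_test_summary()] applied to the samples'
#' own summary statistics.
#'
#' @param x,y numeric samples, n >= 2 each.
#' @inheritParams t_test_summary
#' @return A `group_comparison`.
#' @export
t_test_samples <- function(x, y, variant = c("welch", "student"),
                           variable = "sv", alpha = 0.05) {
  variant <- match.arg(variant)
  t_test_summary(summary_stats(length(x), mean(x), stats::sd(x)),
                 summary_stats(length(y), mean(y), stats::sd(y)),
                 variant = variant, variable = variable, alpha = alpha)
}

#' Two-sample Mann-Whitney test
#'
#' U is the number of (x, y) pairs with x > y (ties count 1/2). For small
#' samples (n1 + n2 <= `exact_max`) without ties the two-sided p-value is
#' exact, from the combinatorial null distribution of U; otherwise the
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param x,y numeric samples, n >= 2 each.
#' @param variable label carried into the result.
#' @param exact_max largest n1 + n2 for which the exact distribution is
#'   used (no ties); default 12.
#' @param alpha significance level.
#' @return A `group_comparison` with `statistic = U` and `df = NA`.
#' @export
mann_whitney <- function(x, y, variable = "sv", exact_max = 12L,
                         alpha = 0.05) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("each group needs n >= 2")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # pairs x > y, ties 1/2
  ties <- any(duplicated(c(x, y)))
  if (!ties && n1 + n2 <= exact_max) {
    # exact null CDF of U (Wilcoxon rank-sum count distribution)
    p_lo <- stats::pwilcox(u, n1, n2)
    p_hi <- 1 - stats::pwilcox(u - 1, n1, n2)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "mann_whitney_exact"
  } else {
    nn <- n1 + n2
    tab <- table(r)
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - sum(tab^3 - tab) / (nn * (nn - 1)))
    mu <- n1 * n2 / 2
    z <- u - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
    p <- 2 * stats::pnorm(-abs(z))
    method <- "mann_whitney_normal"
  }
  group_comparison(variable, n1, n2, mean(x), stats::sd(x),
                   mean(y), stats::sd(y), test = method, statistic = u,
                   df = NA_real_, p_value = p, alpha = alpha)
}

#' Group comparison across a cohort table
#'
#' Reproduces the study's statistical pipeline on a per-patient table: for
#' each of the five stroke-volume sites, each group is first checked for
#' normality (KS); if both groups pass at `normality_alpha` the configured
#' t test is applied, otherwise the Mann-Whitney test. The Evans index and
#' the aqueductal area are always compared with the Mann-Whitney test (the
#' study treated them as non-normal throughout). Results are starred at
#' `p <= alpha`; no multiple-testing correction is applied by default,
#' matching the source analysis, but Holm adjustment can be switched on.
#'
#' @param table cohort data frame (see [generate_cohort()] /
#'   [read_cohort()]).
#' @param t_variant `"welch"` or `"student"`, passed to the t test.
#' @param alpha significance level (default 0.05).
#' @param normality_alpha level for the KS normality gate.
#' @param holm apply Holm correction across the stroke-volume sites?
#' @param variables which columns to compare; defaults to the five
#'   `sv_*` sites plus `evans_index` and `aqueduct_area_mm2` when present.
#' @return Data frame, one row per variable: group summary statistics,
#'   test used, statistic, df, `p_value`, `significant`. Attribute
#'   `"comparisons"` holds the underlying `group_comparison` objects and
#'   `"meta"` the configuration used.
#' @export
compare_cohort <- function(table, t_variant = c("welch", "student"),
                           alpha = 0.05, normality_alpha = 0.05,
                           holm = FALSE, variables = NULL) {
  t_variant <- match.arg(t_variant)
  g1 <- table[table$group == "relieved", , drop = FALSE]
  g2 <- table[table$group == "not_relieved", , drop = FALSE]
  if (nrow(g1) < 2L || nrow(g2) < 2L)
    stop("each outcome group needs at least 2 patients")
  sv_vars <- paste0("sv_", csf_sites())
  morpho_vars <- intersect(c("evans_index", "aqueduct_area_mm2"),
                           names(table))
  if (is.null(variables)) variables <- c(sv_vars, morpho_vars)
  comps <- list()
  for (v in variables) {
    x <- g1[[v]]; y <- g2[[v]]
    if (v %in% morpho_vars) {
      cmp <- mann_whitney(x, y, variable = v, alpha = alpha)
      cmp$note <- "rank test by design (non-normal morphometrics)"
    } else {
      normal <- tryCatch(
        ks_normality(x)$p_value > normality_alpha &&
          ks_normality(y)$p_value > normality_alpha,
        error = function(e) FALSE)
      cmp <- if (normal)
        t_test_samples(x, y, variant = t_variant, variable = v,
                       alpha = alpha)
      else mann_whitney(x, y, variable = v, alpha = alpha)
      if (!normal) cmp$note <- "KS normality rejected; rank test used"
    }
    comps[[v]] <- cmp
  }
  out <- do.call(rbind, lapply(comps, function(cmp)
    data.frame(variable = cmp$variable, n1 = cmp$n1, n2 = cmp$n2,
               mean1 = cmp$mean1, sd1 = cmp$sd1,
               mean2 = cmp$mean2, sd2 = cmp$sd2,
               test = cmp$test, statistic = cmp$statistic, df = cmp$df,
               p_value = cmp$p_value, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  if (holm) {
    idx <- out$variable %in% sv_vars
    out$p_adjusted <- out$p_value
    out$p_adjusted[idx] <- stats::p.adjust(out$p_value[idx],
                                           method = "holm")
    out$significant <- out$p_adjusted <= alpha
  } else {
    out$significant <- out$p_value <= alpha
  }
  attr(out, "comparisons") <- comps
  attr(out, "meta") <- list(t_variant = t_variant, alpha = alpha,
                            normality_alpha = normality_alpha, holm = holm,
                            note = paste("default t variant is welch:",
                                         "the variant consistent with the",
                                         "published significance pattern"))
  out
}

#' Default stroke-volume exclusivity rules
#'
#' Dichotomisation cut-offs observed in the study's scatter of per-patient
#' values: aqueductal SV above 100 uL/CC seen only in relieved patients,
#' below 18 uL/CC only in non-relieved; C2-C3 SV below 300 uL/CC only in
#' relieved, above 800 uL/CC only in non-relieved.
#'
#' @return Data frame with columns `variable`, `direction` (`">"`/`"<"`),
#'   `cutoff`, `exclusive_to`.
#' @export
default_threshold_rules <- function() {
  data.frame(variable = c("sv_aqu", "sv_aqu", "sv_c2c3", "sv_c2c3"),
             direction = c(">", "<", "<", ">"),
             cutoff = c(100, 18, 300, 800),
             exclusive_to = c("relieved", "not_relieved",
                              "relieved", "not_relieved"),
             stringsAsFactors = FALSE)
}

#' Threshold-exclusivity report
#'
#' For each rule, counts how many patients in each outcome group fall in
#' the rule's region and flags whether the region is occupied exclusively
#' by the expected group in this table (vacuously true when nobody
#' qualifies).
#'
#' @param table cohort data frame.
#' @param rules rule table as in [default_threshold_rules()]; an empty
#'   rule set yields an empty report.
#' @return Data frame: rule columns plus `n_relieved`, `n_not_relieved`,
#'   `holds`.
#' @export
threshold_exclusivity <- function(table, rules = default_threshold_rules()) {
  if (nrow(rules) == 0L)
    return(data.frame(variable = character(), direction = character(),
                      cutoff = numeric(), exclusive_to = character(),
                      n_relieved = integer(), n_not_relieved = integer(),
                      holds = logical(), stringsAsFactors = FALSE))
  res <- rules
  res$n_relieved <- NA_integer_
  res$n_not_relieved <- NA_integer_
  res$holds <- NA
  for (i in seq_len(nrow(rules))) {
    v <- table[[rules$variable[i]]]
    if (is.null(v)) stop("cohort table lacks column ", rules$variable[i])
    hit <- if (rules$direction[i] == ">") v > rules$cutoff[i]
           else v < rules$cutoff[i]
    nr <- sum(hit & table$group == "relieved")
    nn <- sum(hit & table$group == "not_relieved")
    res$n_relieved[i] <- nr
    res$n_not_relieved[i] <- nn
    res$holds[i] <- if (rules$exclusive_to[i] == "relieved") nn == 0L
                    else nr == 0L
  }
  res
}
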