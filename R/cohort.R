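#' Published group summary statistics for the five stroke-volume sites
#'
#' Preoperative mean and SD of CSF stroke volume (uL per cardiac cycle) at
#' each craniospinal site, for patients with (n = 12) and without (n = 29)
#' postoperative headache relief, as reported by the source study's summary
#' table.
#'
#' @return Data frame with columns `site`, `group`, `mean_ul`, `sd_ul`, `n`.
#' @export
published_sv_summaries <- function() {
  data.frame(
    site = rep(csf_sites(), each = 2L),
    group = rep(c("relieved", "not_relieved"), times = 5L),
    mean_ul = c(65, 32, 334, 410, 436, 504, 248, 157, 485, 613),
    sd_ul   = c(45, 24, 262, 172, 301, 225, 155, 109, 163, 166),
    n       = rep(c(12L, 29L), times = 5L),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic two-group patient cohort
#'
#' Per-patient stroke volumes are drawn site-wise from normal distributions
#' truncated at 0 uL (the published SDs are comparable to the means, so an
#' untruncated normal would produce negative volumes), one distribution per
#' site and outcome group. Morphometrics (Evans index, narrowest aqueductal
#' area) are drawn from a single distribution shared by both groups,
#' mirroring the study's finding that they do not discriminate outcome.
#'
#' @param n_relieved,n_not_relieved group sizes (each >= 2).
#' @param params data frame in the format of [published_sv_summaries()]
#'   (columns `site`, `group`, `mean_ul`, `sd_ul`).
#' @param morpho list with fields `evans_mean`, `evans_sd`,
#'   `aqueduct_area_mean_mm2`, `aqueduct_area_sd_mm2` (shared by groups).
#' @param seed integer RNG seed; the generated table is fully determined
#'   by it.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_relieved = 12L, n_not_relieved = 29L,
                        params = published_sv_summaries(),
                        morpho = list(evans_mean = 0.27, evans_sd = 0.03,
                                      aqueduct_area_mean_mm2 = 2.6,
                                      aqueduct_area_sd_mm2 = 0.9),
                        seed = 1L) {
  stopifnot(n_relieved >= 2L, n_not_relieved >= 2L)
  stopifnot(all(c("site", "group", "mean_ul", "sd_ul") %in% names(params)))
  if (any(params$sd_ul < 0)) stop("sd_ul must be >= 0")
  structure(list(n_relieved = as.integer(n_relieved),
                 n_not_relieved = as.integer(n_not_relieved),
                 params = params, morpho = morpho, seed = seed),
            class = "cohort_spec")
}

# Normal draws truncated below at `lower` by rejection (exact for the
# truncated-normal law; sd = 0 returns the mean).
rnorm_trunc <- function(n, mean, sd, lower = 0) {
  if (sd == 0) return(rep(max(mean, lower), n))
  out <- stats::rnorm(n, mean, sd)
  bad <- out < lower
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out < lower
  }
  out
}

#' Generate a synthetic patient cohort table
#'
#' @param spec a [cohort_spec()].
#' @return Data frame with one row per patient: `patient_id`, `group`
#'   (`relieved` / `not_relieved`), `sv_aqu`, `sv_ppc`, `sv_fm`,
#'   `sv_nevrax`, `sv_c2c3` (uL per cardiac cycle), `evans_index`,
#'   `aqueduct_area_mm2`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  groups <- c(rep("relieved", spec$n_relieved),
              rep("not_relieved", spec$n_not_relieved))
  n <- length(groups)
  out <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                    group = groups, stringsAsFactors = FALSE)
  for (s in csf_sites()) {
    sv <- numeric(n)
    for (g in c("relieved", "not_relieved")) {
      row <- spec$params[spec$params$site == s & spec$params$group == g, ]
      if (nrow(row) != 1L) stop("params must hold one row per site x group")
      idx <- groups == g
      sv[idx] <- rnorm_trunc(sum(idx), row$mean_ul, row$sd_ul, lower = 0)
    }
    out[[paste0("sv_", s)]] <- sv
  }
  m <- spec$morpho
  out$evans_index <- pmin(rnorm_trunc(n, m$evans_mean, m$evans_sd,
                                      lower = 0.05), 0.95)
  out$aqueduct_area_mm2 <- rnorm_trunc(n, m$aqueduct_area_mean_mm2,
                                       m$aqueduct_area_sd_mm2, lower = 0.3)
  out
}

#' Write / read a cohort table as CSV
#'
#' @param cohort data frame from [generate_cohort()].
#' @param path CSV path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @return `read_cohort`: the cohort data frame.
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "group", paste0("sv_", csf_sites()))
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("cohort table lacks columns: ", paste(missing, collapse = ", "))
  tab
}
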