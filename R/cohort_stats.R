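#' Diagnosis frequency table for a proband cohort
#'
#' Expresses per-diagnosis proband counts as percentages of their diagnosis
#' group (LPD or MPD) and computes the male/female ratio per group, both
#' half-up to one decimal as in the published cohort tables.
#'
#' @param counts data frame with columns `abbrev`, `n`, `m`, `f`
#'   (total, male, female proband counts per diagnosis).
#' @param map a [diagnosis_map()]-shaped data frame assigning each `abbrev`
#'   to a group.
#' @return list with `per_diagnosis` (abbrev, group, n, m, f, pct) and
#'   `per_group` (group, n, m, f, mf_ratio) data frames.  Percentages are of
#'   the group total; diagnoses with zero counts get `NA` percent.
#' @export
frequency_table <- function(counts, map = diagnosis_map()) {
  stopifnot(all(c("abbrev", "n", "m", "f") %in% names(counts)))
  grp <- map$group[match(counts$abbrev, map$abbrev)]
  if (anyNA(grp)) {
    mbd_error("mbdfam_malformed",
              paste("diagnoses not in map:",
                    paste(counts$abbrev[is.na(grp)], collapse = ", ")))
  }
  per_diag <- data.frame(abbrev = counts$abbrev, group = grp,
                         n = counts$n, m = counts$m, f = counts$f,
                         stringsAsFactors = FALSE)
  gt <- tapply(per_diag$n, per_diag$group, sum)
  per_diag$pct <- ifelse(per_diag$n > 0,
                         round_half_up(100 * per_diag$n / gt[per_diag$group], 1),
                         NA_real_)
  groups <- sort(unique(per_diag$group))
  per_group <- data.frame(
    group = groups,
    n = as.integer(tapply(per_diag$n, per_diag$group, sum)[groups]),
    m = as.integer(tapply(per_diag$m, per_diag$group, sum)[groups]),
    f = as.integer(tapply(per_diag$f, per_diag$group, sum)[groups]),
    stringsAsFactors = FALSE
  )
  per_group$mf_ratio <- ifelse(per_group$f > 0,
                               round_half_up(per_group$m / per_group$f, 1),
                               NA_real_)
  list(per_diagnosis = per_diag, per_group = per_group)
}

#' Hodgkin and united-NHL lymphoma shares
#'
#' Two summary shares used when comparing familial cohorts with registry
#' data: Hodgkin's lymphoma as a percentage of all malignant lymphomas
#' (ICD-10 C81-C85) and the united non-Hodgkin lymphomas (C82-C85) as a
#' percentage of all lymphoproliferative disorders.
#'
#' @inheritParams frequency_table
#' @return list with `hl_of_lymphomas` and `nhl_of_lpd` (percent, half-up to
#'   one decimal) plus the underlying `hl`, `nhl` and `lpd_total` counts.
#' @export
lymphoma_shares <- function(counts, map = diagnosis_map()) {
  stopifnot(all(c("abbrev", "n") %in% names(counts)))
  code <- map$icd10[match(counts$abbrev, map$abbrev)]
  grp <- map$group[match(counts$abbrev, map$abbrev)]
  is_hl <- !is.na(code) & substr(code, 1, 3) == "C81"
  is_nhl <- !is.na(code) & substr(code, 1, 3) %in% c("C82", "C83", "C84", "C85")
  hl <- sum(counts$n[is_hl])
  nhl <- sum(counts$n[is_nhl])
  lpd <- sum(counts$n[!is.na(grp) & grp == "LPD"])
  list(
    hl = hl, nhl = nhl, lpd_total = lpd,
    hl_of_lymphomas = if (hl + nhl > 0) round_half_up(100 * hl / (hl + nhl), 1)
                      else NA_real_,
    nhl_of_lpd = if (lpd > 0) round_half_up(100 * nhl / lpd, 1) else NA_real_
  )
}

#' Compare familial diagnosis counts against registry proportions
#'
#' For each diagnosis, the familial count is tested against the expected
#' count under the registry reference mix (a one-sample, two-cell chi-squared
#' goodness of fit of the diagnosis versus the rest of the cohort).  Verdicts
#' report enrichment or depletion at the 0.05 and 0.01 levels.
#'
#' @param familial data frame with columns `abbrev`, `n` (familial counts of
#'   one diagnosis group).
#' @param registry data frame with columns `abbrev`, `pct` (reference
#'   percentages for the same diagnoses, e.g. from [registry_reference()]).
#' @return data frame with `abbrev`, `obs`, `exp`, `chisq`, `p`, `verdict`
#'   (`"enrichment"`, `"depletion"`, `"none"`) and `level` (0, 1 or 2 for
#'   n.s., p < 0.05, p < 0.01).
#' @export
anticipation_compare <- function(familial, registry) {
  stopifnot(all(c("abbrev", "n") %in% names(familial)),
            all(c("abbrev", "pct") %in% names(registry)))
  n_total <- sum(familial$n)
  if (n_total <= 0) mbd_error("mbdfam_malformed", "familial cohort is empty")
  p_ref <- registry$pct[match(familial$abbrev, registry$abbrev)] / 100
  out <- data.frame(abbrev = familial$abbrev, obs = familial$n,
                    exp = n_total * p_ref, stringsAsFactors = FALSE)
  chisq <- p <- rep(NA_real_, nrow(out))
  ok <- !is.na(p_ref) & p_ref > 0 & p_ref < 1
  chisq[ok] <- (out$obs[ok] - out$exp[ok])^2 / out$exp[ok] +
    (out$obs[ok] - out$exp[ok])^2 / (n_total - out$exp[ok])
  p[ok] <- pchisq(chisq[ok], df = 1, lower.tail = FALSE)
  out$chisq <- chisq
  out$p <- p
  out$verdict <- ifelse(is.na(p) | p >= 0.05, "none",
                        ifelse(out$obs > out$exp, "enrichment", "depletion"))
  out$level <- ifelse(is.na(p) | p >= 0.05, 0L, ifelse(p >= 0.01, 1L, 2L))
  out
}

#' Compare onset-age distributions between two cohorts
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) comparison of age at onset,
#' exact when sample sizes permit and no ties are present.
#'
#' @param ages_a,ages_b numeric vectors of onset ages.
#' @return list with `median_a`, `median_b`, `statistic` (W), `p`.
#' @export
onset_compare <- function(ages_a, ages_b) {
  if (!length(ages_a) || !length(ages_b)) {
    mbd_error("mbdfam_malformed", "both onset-age samples must be non-empty")
  }
  wt <- suppressWarnings(wilcox.test(ages_a, ages_b, alternative = "two.sided"))
  list(median_a = median(ages_a), median_b = median(ages_b),
       statistic = unname(wt$statistic), p = wt$p.value)
}
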