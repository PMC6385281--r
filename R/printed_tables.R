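#' Diagnosis grouping map
#'
#' Maps ICD-10 codes for malignant blood disorders to a readable label, the
#' conventional abbreviation and the diagnosis group: LPD (lymphoproliferative
#' disorders), MPD (myeloproliferative disorders) or OTHER.
#'
#' @param path optional path to a custom map (tab-separated with columns
#'   `icd10`, `label`, `abbrev`, `group`); the default is the map shipped
#'   with the package.
#' @return data frame with columns `icd10`, `label`, `abbrev`, `group`.
#' @export
diagnosis_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "diagnosis_groups.tsv",
                                package = "mbdfam", mustWork = TRUE)
  map <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("icd10", "label", "abbrev", "group")
  if (!all(needed %in% names(map))) {
    mbd_error("mbdfam_malformed",
              paste("diagnosis map must have columns:", paste(needed, collapse = ", ")))
  }
  if (anyDuplicated(map$icd10)) {
    mbd_error("mbdfam_duplicate_id", "diagnosis map has duplicated ICD-10 codes")
  }
  if (!all(map$group %in% c("LPD", "MPD", "OTHER"))) {
    mbd_error("mbdfam_malformed", "diagnosis groups must be LPD, MPD or OTHER")
  }
  map
}

#' Reference cohort count table
#'
#' Per-diagnosis proband counts for the two study cohorts — the single large
#' inbred island family ("faroe" columns) and the Norwegian/Danish families
#' with unrelated parents ("nd" columns) — together with the published
#' percentage columns and the national cancer-registry reference percentages.
#' Percent cells are as printed (one decimal, half-up); `registry_pct` keeps
#' the `"<1"` entries verbatim.
#'
#' @return data frame, one row per diagnosis.
#' @export
cohort_counts <- function() {
  read.delim(system.file("extdata", "cohort_counts.tsv",
                         package = "mbdfam", mustWork = TRUE),
             stringsAsFactors = FALSE,
             colClasses = c(registry_pct = "character"))
}

#' Reference four-group table
#'
#' The published affected-relative distribution for the inbred island cohort:
#' per row, an AR diagnosis group counted for probands of one diagnosis, the
#' four AR/Pc mean ratios, observed AR counts total (male, female) in the
#' four proband-sex by parental-line groups (Psm-PA, Psm-MA, Psf-PA, Psf-MA),
#' the printed expected triplet, and the printed signed chi-squared scores
#' (`NA` for the small-sample rows that were not scored).  `ratio_anomaly`
#' and `exp_anomaly` flag the one row whose printed ratios and expected male
#' count are internally inconsistent with the rest of the table.
#'
#' @return data frame, one row per proband/AR group pair.
#' @export
four_group_printed <- function() {
  read.delim(system.file("extdata", "four_group_printed.tsv",
                         package = "mbdfam", mustWork = TRUE),
             stringsAsFactors = FALSE)
}

#' Registry reference percentages
#'
#' The national cancer-registry diagnosis mix used as the fixed reference in
#' [anticipation_compare()].  `"<1"` entries are returned as `lt1 = TRUE`
#' with `pct` set to the configurable stand-in value.
#'
#' @param lt1_value numeric stand-in for the `"<1"` registry cells.
#' @return data frame with columns `abbrev`, `group`, `pct`, `lt1`.
#' @export
registry_reference <- function(lt1_value = 0.5) {
  cc <- cohort_counts()
  lt1 <- !is.na(cc$registry_pct) & cc$registry_pct == "<1"
  pct <- suppressWarnings(as.numeric(cc$registry_pct))
  pct[lt1] <- lt1_value
  out <- data.frame(abbrev = cc$abbrev, group = cc$group, pct = pct, lt1 = lt1,
                    stringsAsFactors = FALSE)
  out[!is.na(out$pct), , drop = FALSE]
}
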