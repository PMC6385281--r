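#' Pedigree objects
#'
#' A pedigree is stored as a data frame with one row per individual and
#' columns `family`, `id`, `father`, `mother` (`NA` for founders), `sex`
#' (`"male"`/`"female"`), `affected` (`"affected"`/`"unaffected"`/`"unknown"`),
#' `diagnosis` (ICD-10 code or `NA`), `birth_year` and `onset_year`.
#' `as_pedigree()` validates the kinship structure: ids must be unique,
#' fathers male, mothers female, all referenced parents present, and the
#' child-to-parent links must form a directed acyclic graph.
#'
#' @param x a data frame with at least `family`, `id`, `father`, `mother`,
#'   `sex` and `affected` columns.
#' @return An object of class `pedigree` (a validated data frame).
#' @export
as_pedigree <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  required <- c("family", "id", "father", "mother", "sex", "affected")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    mbd_error("mbdfam_malformed",
              paste("missing pedigree columns:", paste(missing_cols, collapse = ", ")))
  }
  for (col in c("diagnosis", "birth_year", "onset_year")) {
    if (is.null(x[[col]])) x[[col]] <- NA
  }
  x$id     <- as.character(x$id)
  x$family <- as.character(x$family)
  x$father <- as.character(x$father)
  x$mother <- as.character(x$mother)
  x$father[x$father %in% c("0", "")] <- NA_character_
  x$mother[x$mother %in% c("0", "")] <- NA_character_

  if (anyDuplicated(x$id)) {
    mbd_error("mbdfam_duplicate_id",
              paste("duplicate individual id:",
                    paste(unique(x$id[duplicated(x$id)]), collapse = ", ")))
  }
  if (!all(x$sex %in% c("male", "female"))) {
    mbd_error("mbdfam_malformed", "sex must be 'male' or 'female'")
  }
  if (!all(x$affected %in% c("affected", "unaffected", "unknown"))) {
    mbd_error("mbdfam_malformed",
              "affected must be 'affected', 'unaffected' or 'unknown'")
  }

  for (side in c("father", "mother")) {
    ref <- x[[side]]
    bad <- !is.na(ref) & !(ref %in% x$id)
    if (any(bad)) {
      mbd_error("mbdfam_unknown_parent",
                paste0("unknown ", side, " id: ",
                       paste(unique(ref[bad]), collapse = ", ")))
    }
  }
  sex_of <- setNames(x$sex, x$id)
  bad_f <- !is.na(x$father) & sex_of[x$father] != "male"
  if (any(bad_f)) {
    mbd_error("mbdfam_sex_mismatch",
              paste("father is not male for individual(s):",
                    paste(x$id[bad_f], collapse = ", ")))
  }
  bad_m <- !is.na(x$mother) & sex_of[x$mother] != "female"
  if (any(bad_m)) {
    mbd_error("mbdfam_sex_mismatch",
              paste("mother is not female for individual(s):",
                    paste(x$id[bad_m], collapse = ", ")))
  }

  # Kahn's algorithm over child->parent links: everyone must be reachable
  # from the founders, otherwise the parent links contain a cycle.
  idx <- seq_len(nrow(x))
  names(idx) <- x$id
  fa <- ifelse(is.na(x$father), NA_integer_, idx[x$father])
  mo <- ifelse(is.na(x$mother), NA_integer_, idx[x$mother])
  unresolved <- (!is.na(fa)) + (!is.na(mo))
  kids <- vector("list", nrow(x))
  for (i in idx) {
    if (!is.na(fa[i])) kids[[fa[i]]] <- c(kids[[fa[i]]], i)
    if (!is.na(mo[i])) kids[[mo[i]]] <- c(kids[[mo[i]]], i)
  }
  queue <- integer(nrow(x))
  nq <- 0L
  for (v in which(unresolved == 0L)) { nq <- nq + 1L; queue[nq] <- v }
  head_i <- 1L
  seen <- 0L
  while (head_i <= nq) {
    v <- queue[head_i]; head_i <- head_i + 1L
    seen <- seen + 1L
    for (k in kids[[v]]) {
      unresolved[k] <- unresolved[k] - 1L
      if (unresolved[k] == 0L) { nq <- nq + 1L; queue[nq] <- k }
    }
  }
  if (seen < nrow(x)) {
    mbd_error("mbdfam_cycle",
              paste("pedigree parent links contain a cycle involving:",
                    paste(x$id[unresolved > 0L], collapse = ", ")))
  }

  rownames(x) <- NULL
  class(x) <- c("pedigree", "data.frame")
  x
}

#' Read a pedigree from PED and phenotype files
#'
#' The PED dialect is the classic 6-column LINKAGE layout, tab-separated and
#' headerless: family id, individual id, father id, mother id, sex
#' (1 = male, 2 = female) and phenotype (1 = unaffected, 2 = affected,
#' 0 = unknown).  Founder parents are coded `0`.  The optional companion
#' phenotype table is a tab-separated file with header
#' `iid  icd10  birth_year  onset_year`; individuals without a phenotype row
#' keep `NA` diagnosis and years.
#'
#' @param ped_path path to the PED file.
#' @param phenotype_path optional path to the phenotype table.
#' @return a [as_pedigree()] validated `pedigree`.
#' @export
read_pedigree <- function(ped_path, phenotype_path = NULL) {
  if (!file.exists(ped_path)) {
    mbd_error("mbdfam_io", paste("PED file not found:", ped_path))
  }
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6L)) {
    mbd_error("mbdfam_malformed",
              paste0("malformed PED line (expected 6 tab-separated fields): line ",
                     which(nf != 6L)[1]))
  }
  m <- do.call(rbind, fields)
  sex_code <- m[, 5]
  aff_code <- m[, 6]
  if (!all(sex_code %in% c("1", "2"))) {
    mbd_error("mbdfam_malformed",
              paste0("invalid sex code on line ",
                     which(!sex_code %in% c("1", "2"))[1], " (expected 1 or 2)"))
  }
  if (!all(aff_code %in% c("0", "1", "2"))) {
    mbd_error("mbdfam_malformed",
              paste0("invalid phenotype code on line ",
                     which(!aff_code %in% c("0", "1", "2"))[1],
                     " (expected 0, 1 or 2)"))
  }
  ped <- data.frame(
    family = m[, 1], id = m[, 2], father = m[, 3], mother = m[, 4],
    sex = c("1" = "male", "2" = "female")[sex_code],
    affected = c("0" = "unknown", "1" = "unaffected", "2" = "affected")[aff_code],
    diagnosis = NA_character_, birth_year = NA_integer_, onset_year = NA_integer_,
    stringsAsFactors = FALSE
  )
  if (!is.null(phenotype_path)) {
    if (!file.exists(phenotype_path)) {
      mbd_error("mbdfam_io", paste("phenotype file not found:", phenotype_path))
    }
    phe <- read.delim(phenotype_path, stringsAsFactors = FALSE,
                      colClasses = c(iid = "character"))
    needed <- c("iid", "icd10", "birth_year", "onset_year")
    if (!all(needed %in% names(phe))) {
      mbd_error("mbdfam_malformed",
                paste("phenotype table must have columns:",
                      paste(needed, collapse = ", ")))
    }
    hit <- match(ped$id, phe$iid)
    ped$diagnosis  <- ifelse(is.na(hit), NA_character_, as.character(phe$icd10[hit]))
    ped$diagnosis[!is.na(ped$diagnosis) & ped$diagnosis == ""] <- NA_character_
    ped$birth_year <- as.integer(phe$birth_year[hit])
    ped$onset_year <- as.integer(phe$onset_year[hit])
  }
  as_pedigree(ped)
}

#' Write a pedigree to PED and phenotype files
#'
#' Inverse of [read_pedigree()]; `read_pedigree(write_pedigree(p))`
#' round-trips to an identical pedigree.
#'
#' @param ped a `pedigree`.
#' @param ped_path output path for the PED file.
#' @param phenotype_path optional output path for the phenotype table.
#' @return `ped`, invisibly.
#' @export
write_pedigree <- function(ped, ped_path, phenotype_path = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  out <- data.frame(
    ped$family, ped$id,
    ifelse(is.na(ped$father), "0", ped$father),
    ifelse(is.na(ped$mother), "0", ped$mother),
    c(male = "1", female = "2")[ped$sex],
    c(unknown = "0", unaffected = "1", affected = "2")[ped$affected]
  )
  write.table(out, ped_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (!is.null(phenotype_path)) {
    phe <- data.frame(iid = ped$id, icd10 = ped$diagnosis,
                      birth_year = ped$birth_year, onset_year = ped$onset_year)
    write.table(phe, phenotype_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
  }
  invisible(ped)
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree: %d individuals in %d famil%s (%d affected)\n",
              nrow(x), length(unique(x$family)),
              if (length(unique(x$family)) == 1L) "y" else "ies",
              sum(x$affected == "affected")))
  NextMethod()
}

# parent/child adjacency index reused by the traversal code
ped_index <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  fa <- unname(ifelse(is.na(ped$father), NA_integer_, idx[ped$father]))
  mo <- unname(ifelse(is.na(ped$mother), NA_integer_, idx[ped$mother]))
  kids <- rep(list(integer()), n)
  for (i in idx) {
    if (!is.na(fa[i])) kids[[fa[i]]] <- c(kids[[fa[i]]], i)
    if (!is.na(mo[i])) kids[[mo[i]]] <- c(kids[[mo[i]]], i)
  }
  kids <- lapply(kids, function(k) k[order(ped$id[k])])
  list(idx = idx, father = fa, mother = mo, children = kids,
       unaffected = ped$affected != "affected")
}
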