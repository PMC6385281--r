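#' @section Affected-relative enumeration:
#' The closeness of a relative is the number of *unaffected* individuals
#' strictly between proband and relative on a kinship path (affected
#' intermediates do not count against the limit).  Minimal closeness per
#' parental line is computed by an apex decomposition: a dynamic programme
#' over the pedigree DAG gives, for every individual, the minimal
#' unaffected-interior cost to each ancestor; a connecting path is an
#' ascent from the proband to a shared apex followed by a descent to the
#' relative, so the per-line minimum is the minimum over apexes of
#' up-cost + apex charge + down-cost.  Any up-down walk that revisits a
#' vertex other than the proband collapses, at no extra cost and with the
#' same first step, to a simple path; walks revisiting the proband cost at
#' least as much as the direct descent, and ties between the descent route
#' and an ancestral route are resolved toward the descent.  The minima are
#' therefore exactly the simple-path minima under the stated tie rules.
#' @name segregation
NULL

# minimal unaffected-interior cost from each individual up to each ancestor;
# Inf when not an ancestor, endpoints never charged
ancestor_cost_matrix <- function(ped, ix = ped_index(ped)) {
  n <- nrow(ped)
  unaff <- as.numeric(ix$unaffected)
  anc <- matrix(Inf, n, n)
  # topological order, parents before children
  unresolved <- (!is.na(ix$father)) + (!is.na(ix$mother))
  topo <- integer(n)
  nt <- 0L
  for (v in which(unresolved == 0L)) { nt <- nt + 1L; topo[nt] <- v }
  head_i <- 1L
  while (head_i <= nt) {
    v <- topo[head_i]; head_i <- head_i + 1L
    for (k in ix$children[[v]]) {
      unresolved[k] <- unresolved[k] - 1L
      if (unresolved[k] == 0L) { nt <- nt + 1L; topo[nt] <- k }
    }
  }
  topo <- topo[seq_len(nt)]
  for (i in topo) {
    row <- rep(Inf, n)
    for (p in c(ix$father[i], ix$mother[i])) {
      if (!is.na(p)) {
        via <- anc[p, ] + unaff[p]
        via[p] <- 0
        row <- pmin(row, via)
      }
    }
    anc[i, ] <- row
  }
  anc
}

# per-line minimal costs from one proband to every affected individual
proband_line_costs <- function(a, ix, anc, aff_idx, unaff) {
  n <- ncol(anc)
  sub <- anc[aff_idx, , drop = FALSE]
  line_cost <- function(parent) {
    if (is.na(parent)) return(rep(Inf, length(aff_idx)))
    up <- anc[parent, ] + unaff[parent]
    up[parent] <- 0
    w <- up + unaff                       # charge the apex as an interior
    cols <- which(is.finite(w))
    best <- up[aff_idx]                   # apex = the relative itself
    for (v in cols) best <- pmin(best, sub[, v] + w[v])
    best
  }
  list(PA = line_cost(ix$father[a]),
       MA = line_cost(ix$mother[a]),
       DE = sub[, a])
}

#' Enumerate affected-relative links for probands
#'
#' For every proband (by default every affected individual), finds all other
#' affected individuals connected by a kinship path with at most
#' `max_intermediates` unaffected individuals strictly between them, and
#' attaches each to the parental line of its closest qualifying path:
#' `PA` (first step through the father), `MA` (through the mother),
#' `ambiguous` (equally close through both, e.g. full siblings) or
#' `descendant` (closest connection is direct descent).  Each relative
#' appears at most once per proband.
#'
#' @param ped a `pedigree`.
#' @param probands character vector of proband ids; default all affected.
#' @param max_intermediates maximum number of unaffected intermediates.
#' @param include_descendants count affected descendants (and relatives whose
#'   only connection is through descent) as relatives.
#' @return data frame with columns `proband`, `relative`, `line`,
#'   `intermediates`, `relative_sex`, `parent_offspring`, `cost_pa`,
#'   `cost_ma`, `cost_de` (per-line closeness, `NA` when unconnected).
#' @export
affected_links <- function(ped, probands = NULL, max_intermediates = 5,
                           include_descendants = TRUE) {
  stopifnot(inherits(ped, "pedigree"))
  ix <- ped_index(ped)
  aff_ids <- ped$id[ped$affected == "affected"]
  probands <- sort(probands %||% aff_ids)
  bad <- setdiff(probands, aff_ids)
  if (length(bad)) {
    mbd_error("mbdfam_not_affected",
              paste("probands must be affected:", paste(bad, collapse = ", ")))
  }
  anc <- ancestor_cost_matrix(ped, ix)
  aff_idx <- which(ped$affected == "affected")
  unaff <- as.numeric(ix$unaffected)
  out <- vector("list", length(probands))
  for (k in seq_along(probands)) {
    a <- ix$idx[[probands[k]]]
    costs <- proband_line_costs(a, ix, anc, aff_idx, unaff)
    best <- pmin(costs$PA, costs$MA, costs$DE)
    self <- aff_idx == a
    keep <- which(!self & is.finite(best) & best <= max_intermediates)
    if (!length(keep)) next
    pa <- costs$PA[keep]; ma <- costs$MA[keep]; de <- costs$DE[keep]
    b <- best[keep]
    line <- ifelse(de <= pmin(pa, ma), "descendant",
                   ifelse(pa == b & ma == b, "ambiguous",
                          ifelse(pa == b, "PA", "MA")))
    if (!include_descendants) {
      drop <- line == "descendant"
      keep <- keep[!drop]; pa <- pa[!drop]; ma <- ma[!drop]
      de <- de[!drop]; b <- b[!drop]; line <- line[!drop]
      if (!length(keep)) next
    }
    rel <- ped$id[aff_idx[keep]]
    out[[k]] <- data.frame(
      proband = probands[k], relative = rel, line = line,
      intermediates = as.integer(b),
      relative_sex = ped$sex[aff_idx[keep]],
      parent_offspring =
        rel %in% c(ped$father[a], ped$mother[a]) |
        ped$father[aff_idx[keep]] %in% probands[k] |
        ped$mother[aff_idx[keep]] %in% probands[k],
      cost_pa = ifelse(is.finite(pa), pa, NA_real_),
      cost_ma = ifelse(is.finite(ma), ma, NA_real_),
      cost_de = ifelse(is.finite(de), de, NA_real_),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(proband = character(), relative = character(),
                      line = character(), intermediates = integer(),
                      relative_sex = character(), parent_offspring = logical(),
                      cost_pa = numeric(), cost_ma = numeric(),
                      cost_de = numeric(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Enumerate affected relatives of a single proband
#'
#' Convenience wrapper around [affected_links()] for one proband.
#'
#' @inheritParams affected_links
#' @param proband a single affected individual id.
#' @return the [affected_links()] data frame restricted to `proband`.
#' @export
enumerate_ar <- function(ped, proband, max_intermediates = 5,
                         include_descendants = TRUE) {
  affected_links(ped, probands = proband,
                 max_intermediates = max_intermediates,
                 include_descendants = include_descendants)
}

#' Classify the parental-line affiliation of a proband
#'
#' @param links the [affected_links()] rows of one proband.
#' @return one of `"PA+MA"` (unambiguous links in both lines), `"PA"`,
#'   `"MA"`, `"PA=MA"` (ancestral links present but all of ambiguous line)
#'   or `"none-visible"` (no link in the ancestral direction).
#' @export
classify_affiliation <- function(links) {
  if (length(unique(links$proband)) > 1L) {
    mbd_error("mbdfam_malformed", "links must belong to a single proband")
  }
  has_pa <- any(links$line == "PA")
  has_ma <- any(links$line == "MA")
  if (has_pa && has_ma) return("PA+MA")
  if (has_pa) return("PA")
  if (has_ma) return("MA")
  if (any(links$line == "ambiguous")) return("PA=MA")
  "none-visible"
}

#' Build proband records from a link table
#'
#' @param ped a `pedigree`.
#' @param links an [affected_links()] table.
#' @return data frame with one row per proband: `proband`, `sex`,
#'   `diagnosis`, `n_links`, `affiliation`.
#' @export
proband_records <- function(ped, links) {
  probands <- sort(unique(links$proband))
  aff <- vapply(probands, function(p)
    classify_affiliation(links[links$proband == p, , drop = FALSE]), "")
  data.frame(
    proband = probands,
    sex = ped$sex[match(probands, ped$id)],
    diagnosis = ped$diagnosis[match(probands, ped$id)],
    n_links = as.integer(table(factor(links$proband, levels = probands))),
    affiliation = aff,
    stringsAsFactors = FALSE
  )
}

# deterministic alternating assignment: PA, MA, PA, ... over sorted keys
alternate_lines <- function(keys) {
  ord <- order(keys)
  out <- character(length(keys))
  out[ord] <- rep(c("PA", "MA"), length.out = length(keys))
  out
}

#' Standardize probands to monoparental lines
#'
#' Converts crude probands (Pc) into standard probands (Ps), each counting a
#' single parental line.  Probands with unambiguous links in both lines
#' yield two Ps (one per line); single-line probands yield one.  Probands of
#' entirely mixed affiliation are placed on the line bringing the majority
#' of their relatives closest (summed closeness as tiebreak, then a
#' deterministic alternation).  Probands with no ancestral-direction link
#' are shared equally between the lines, alternating over sorted proband ids
#' with any odd remainder going to the patrilineal side.  For two-line
#' probands, links of ambiguous line are alternated over sorted relative ids
#' (each relative still counts once per proband) and descendant links follow
#' the proband's own vertical line: patrilineal below a male proband,
#' matrilineal below a female one.
#'
#' @param records a [proband_records()] data frame.
#' @param links the matching [affected_links()] table.
#' @return list with `ps` (data frame: `ps_id`, `proband`, `sex`, `line`,
#'   `tie_broken`) and `links` (the input links with a `ps_id` column
#'   assigning each link to one Ps).
#' @export
standardize <- function(records, links) {
  records <- records[order(records$proband), , drop = FALSE]
  ps <- list()
  links$ps_id <- rep(NA_character_, nrow(links))
  none_ids <- records$proband[records$affiliation == "none-visible"]
  none_line <- setNames(alternate_lines(none_ids), none_ids)
  for (i in seq_len(nrow(records))) {
    p <- records$proband[i]
    sex <- records$sex[i]
    grp <- records$affiliation[i]
    li <- which(links$proband == p)
    if (grp == "PA+MA") {
      id_pa <- paste0(p, ":PA"); id_ma <- paste0(p, ":MA")
      ps[[length(ps) + 1L]] <- data.frame(ps_id = id_pa, proband = p, sex = sex,
                                          line = "PA", tie_broken = FALSE)
      ps[[length(ps) + 1L]] <- data.frame(ps_id = id_ma, proband = p, sex = sex,
                                          line = "MA", tie_broken = FALSE)
      lin <- links$line[li]
      links$ps_id[li[lin == "PA"]] <- id_pa
      links$ps_id[li[lin == "MA"]] <- id_ma
      # a proband's descendants continue the proband's own vertical line:
      # patrilineal below a male proband, matrilineal below a female one
      de <- li[lin == "descendant"]
      if (length(de)) links$ps_id[de] <- if (sex == "male") id_pa else id_ma
      rest <- li[lin == "ambiguous"]
      if (length(rest)) {
        side <- alternate_lines(links$relative[rest])
        links$ps_id[rest] <- ifelse(side == "PA", id_pa, id_ma)
      }
    } else {
      tie <- FALSE
      if (grp %in% c("PA", "MA")) {
        line <- grp
      } else if (grp == "PA=MA") {
        # majority of relatives by strictly closer line, then summed
        # closeness, then deterministic alternation with the none-visible set
        cp <- links$cost_pa[li]; cm <- links$cost_ma[li]
        n_pa <- sum(!is.na(cp) & (is.na(cm) | cp < cm))
        n_ma <- sum(!is.na(cm) & (is.na(cp) | cm < cp))
        if (n_pa != n_ma) {
          line <- if (n_pa > n_ma) "PA" else "MA"
        } else {
          s_pa <- sum(cp, na.rm = TRUE); s_ma <- sum(cm, na.rm = TRUE)
          if (s_pa != s_ma) {
            line <- if (s_pa < s_ma) "PA" else "MA"
            tie <- TRUE
          } else {
            rank <- match(p, sort(records$proband[records$affiliation == "PA=MA"]))
            line <- if (rank %% 2L == 1L) "PA" else "MA"
            tie <- TRUE
          }
        }
      } else {  # none-visible
        line <- none_line[[p]]
        tie <- FALSE
      }
      id <- paste0(p, ":", line)
      ps[[length(ps) + 1L]] <- data.frame(ps_id = id, proband = p, sex = sex,
                                          line = line, tie_broken = tie)
      links$ps_id[li] <- id
    }
  }
  ps <- if (length(ps)) do.call(rbind, ps) else
    data.frame(ps_id = character(), proband = character(), sex = character(),
               line = character(), tie_broken = logical())
  rownames(ps) <- NULL
  list(ps = ps, links = links)
}

#' Observed four-group table from standardized probands
#'
#' Tallies affected-relative links into the four proband-sex by
#' parental-line groups and scores them with [score_four_group()].
#'
#' @param ps,links the two components returned by [standardize()].
#' @param yates passed to [score_four_group()].
#' @return a [score_four_group()] object.
#' @export
four_group_table <- function(ps, links, yates = FALSE) {
  links <- links[!is.na(links$ps_id), , drop = FALSE]
  line <- ps$line[match(links$ps_id, ps$ps_id)]
  sex <- ps$sex[match(links$ps_id, ps$ps_id)]
  grp <- factor(paste0("Ps", substr(sex, 1, 1), "-", line),
                levels = ps_group_levels)
  male <- links$relative_sex == "male"
  obs <- cbind(
    total = as.integer(table(grp)),
    male = as.integer(table(grp[male])),
    female = as.integer(table(grp[!male]))
  )
  rownames(obs) <- ps_group_levels
  score_four_group(obs, yates = yates)
}

#' Full segregation analysis of a pedigree cohort
#'
#' Runs the whole proband pipeline: affected-relative enumeration, parental
#' affiliation, proband standardization, the scored four-group table with
#' its pattern classification, and the parent-offspring pair census.
#'
#' @inheritParams affected_links
#' @param yates passed to the chi-squared scoring.
#' @return object of class `segregation_analysis`: list with `links`,
#'   `records`, `ps`, `table` (a `four_group_table`), `pattern`, `census`.
#' @export
analyze_segregation <- function(ped, probands = NULL, max_intermediates = 5,
                                include_descendants = TRUE, yates = FALSE) {
  links <- affected_links(ped, probands = probands,
                          max_intermediates = max_intermediates,
                          include_descendants = include_descendants)
  if (!nrow(links)) {
    out <- list(links = links, records = proband_records(ped, links),
                ps = NULL, table = NULL, pattern = NA_character_,
                census = pair_census(links))
    class(out) <- "segregation_analysis"
    return(out)
  }
  records <- proband_records(ped, links)
  std <- standardize(records, links)
  tab <- four_group_table(std$ps, std$links, yates = yates)
  map <- diagnosis_map()
  links2 <- std$links
  links2$group <- map$group[match(ped$diagnosis[match(links2$proband, ped$id)],
                                  map$icd10)]
  links2$group[is.na(links2$group)] <- "all"
  out <- list(links = std$links, records = records, ps = std$ps, table = tab,
              pattern = tab$pattern, census = pair_census(links2))
  class(out) <- "segregation_analysis"
  out
}

#' @export
print.segregation_analysis <- function(x, ...) {
  cat(sprintf("Segregation analysis: %d probands, %d links, %d Ps\n",
              if (is.null(x$records)) 0L else nrow(x$records),
              nrow(x$links), if (is.null(x$ps)) 0L else nrow(x$ps)))
  if (!is.null(x$table)) print(x$table)
  invisible(x)
}
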