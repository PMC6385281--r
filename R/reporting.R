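#' Write a run manifest
#'
#' Every pipeline output directory gets a `manifest.json` recording the
#' command, seed, configuration hash, input file digests and package
#' version, so that identical manifests imply identical outputs.
#'
#' @param out_dir output directory.
#' @param command character command name.
#' @param seed integer seed (or `NA`).
#' @param config list serialized into the manifest hash.
#' @param inputs named character vector of input file paths to digest.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(out_dir, command, seed = NA_integer_,
                           config = list(), inputs = character()) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               null = "null")
  tmp <- tempfile()
  writeLines(as.character(cfg_json), tmp)
  manifest <- list(
    command = command,
    seed = seed,
    config_hash = unname(tools::md5sum(tmp)),
    inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    tool = paste0("mbdfam ", as.character(utils::packageVersion("mbdfam"))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Simulate a cohort and write its files
#'
#' @param config a [sim_config()] or a named list / YAML-free config file
#'   path (tab-separated `key value` pairs) of overrides to [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param seed optional seed overriding the config's.
#' @return the [simulate_cohort()] result, invisibly; writes
#'   `pedigree.ped`, `phenotype.tsv`, `truth.tsv` and `manifest.json`.
#' @export
run_simulate <- function(config = sim_config(), out_dir, seed = NULL) {
  if (is.character(config)) config <- read_sim_config(config)
  if (is.list(config) && !inherits(config, "sim_config")) {
    bad <- setdiff(names(config), names(formals(sim_config)))
    if (length(bad)) {
      mbd_error("mbdfam_config",
                paste("unknown config key(s):", paste(bad, collapse = ", ")))
    }
    config <- do.call(sim_config, config)
  }
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_cohort(config)
  write_pedigree(sim$ped, file.path(out_dir, "pedigree.ped"),
                 file.path(out_dir, "phenotype.tsv"))
  write.table(sim$truth, file.path(out_dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- unclass(sim$config)
  cfg$diagnosis_probs <- as.list(cfg$diagnosis_probs)
  write_manifest(out_dir, "simulate", seed = sim$config$seed, config = cfg)
  invisible(sim)
}

read_sim_config <- function(path) {
  if (!file.exists(path)) {
    mbd_error("mbdfam_io", paste("config file not found:", path))
  }
  kv <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("key", "value"))
  vals <- lapply(seq_len(nrow(kv)), function(i) {
    v <- utils::type.convert(kv$value[i], as.is = TRUE)
    v
  })
  setNames(vals, kv$key)
}

#' Analyze a pedigree cohort and write reports
#'
#' Runs [analyze_segregation()], the cohort frequency table, the pair
#' census and the covariation screen, writing tab-separated reports and a
#' JSON pattern classification.
#'
#' @param ped_path,phenotype_path input files for [read_pedigree()].
#' @param map_path optional custom [diagnosis_map()] file.
#' @param out_dir output directory.
#' @param max_intermediates,include_descendants passed to
#'   [analyze_segregation()].
#' @return the `segregation_analysis` object, invisibly.
#' @export
run_analyze <- function(ped_path, phenotype_path = NULL, map_path = NULL,
                        out_dir, max_intermediates = 5,
                        include_descendants = TRUE) {
  ped <- read_pedigree(ped_path, phenotype_path)
  map <- diagnosis_map(map_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seg <- analyze_segregation(ped, max_intermediates = max_intermediates,
                             include_descendants = include_descendants)
  write.table(seg$links, file.path(out_dir, "links.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(seg$ps)) {
    write.table(seg$ps, file.path(out_dir, "ps.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  write.table(seg$census, file.path(out_dir, "pair_census.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # cohort frequency table over the affected individuals
  aff <- ped[ped$affected == "affected", , drop = FALSE]
  abbrev <- map$abbrev[match(aff$diagnosis, map$icd10)]
  counts <- data.frame(table(abbrev, aff$sex))
  freq <- NULL
  if (nrow(aff) && !all(is.na(abbrev))) {
    tab <- table(factor(abbrev), factor(aff$sex, levels = c("male", "female")))
    counts <- data.frame(abbrev = rownames(tab),
                         n = as.integer(rowSums(tab)),
                         m = as.integer(tab[, "male"]),
                         f = as.integer(tab[, "female"]),
                         stringsAsFactors = FALSE)
    freq <- frequency_table(counts, map)
    write.table(freq$per_diagnosis, file.path(out_dir, "frequency.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # covariation screen over proband/relative diagnosis pairs
  cov <- NULL
  if (nrow(seg$links)) {
    links <- seg$links
    links$pc_diag <- ped$diagnosis[match(links$proband, ped$id)]
    links$ar_diag <- ped$diagnosis[match(links$relative, ped$id)]
    links <- links[!is.na(links$pc_diag) & !is.na(links$ar_diag), , drop = FALSE]
    if (nrow(links)) {
      pc_counts <- as.data.frame(table(diag = aff$diagnosis),
                                 stringsAsFactors = FALSE)
      names(pc_counts) <- c("diag", "n")
      cov <- covariation_table(links, pc_counts)
      write.table(cov, file.path(out_dir, "covariation.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }

  report <- list(
    n_individuals = nrow(ped),
    n_probands = if (is.null(seg$records)) 0L else nrow(seg$records),
    n_links = nrow(seg$links),
    pattern = seg$pattern,
    scores = if (!is.null(seg$table)) as.data.frame(seg$table$scores),
    obs = if (!is.null(seg$table)) as.data.frame(seg$table$obs),
    exp = if (!is.null(seg$table)) as.list(seg$table$exp)
  )
  jsonlite::write_json(report, file.path(out_dir, "pattern.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(out_dir, "analyze",
                 config = list(max_intermediates = max_intermediates,
                               include_descendants = include_descendants),
                 inputs = c(ped = ped_path,
                            phenotype = phenotype_path %||% character(),
                            map = map_path %||% character()))
  invisible(seg)
}

#' Birth-order report for a pedigree
#'
#' @param ped a `pedigree` (or PED file path).
#' @param phenotype_path companion phenotype table when `ped` is a path.
#' @param affected_ids optional stratum passed to
#'   [sibships_from_pedigree()].
#' @param out_dir optional output directory for a one-row TSV report.
#' @return list with the [haldane_smith()] result and the
#'   [wilcoxon_control()] result.
#' @export
run_birth_order <- function(ped, phenotype_path = NULL, affected_ids = NULL,
                            out_dir = NULL) {
  if (is.character(ped)) ped <- read_pedigree(ped, phenotype_path)
  sibs <- sibships_from_pedigree(ped, affected_ids = affected_ids)
  hs <- haldane_smith(sibs)
  wc <- tryCatch(wilcoxon_control(sibs), mbdfam_error = function(e) NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    row <- data.frame(A = hs$A, E = hs$expectation, Var = hs$variance,
                      z = hs$z, p = hs$p, ci_lo = hs$ci95[1],
                      ci_hi = hs$ci95[2], n_informative = hs$n_informative,
                      wilcoxon_p = if (is.null(wc)) NA_real_ else wc$p)
    write.table(row, file.path(out_dir, "birth_order.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(haldane_smith = hs, wilcoxon = wc)
}
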