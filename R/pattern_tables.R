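#' Mean affected relatives per proband, by sex
#'
#' The four AR/Pc ratios of the familial-aggregation table: mean number of
#' male and female affected relatives per male and per female proband,
#' reported half-up to one decimal.
#'
#' @param ar_males,ar_females total affected-relative counts by sex.
#' @param pc_males,pc_females proband counts by sex.
#' @return data frame with one row and columns `mm` (AR-male/Pc-male), `fm`
#'   (AR-female/Pc-male), `mf`, `ff`, plus `undefined_m`/`undefined_f` flags
#'   set when a proband sex has zero members (those ratios are `NA`).
#' @export
ar_pc_ratios <- function(ar_males, ar_females, pc_males, pc_females) {
  stopifnot(pc_males >= 0, pc_females >= 0, ar_males >= 0, ar_females >= 0)
  div <- function(a, b) if (b > 0) round_half_up(a / b, 1) else NA_real_
  data.frame(
    mm = div(ar_males, pc_males), fm = div(ar_females, pc_males),
    mf = div(ar_males, pc_females), ff = div(ar_females, pc_females),
    undefined_m = pc_males == 0, undefined_f = pc_females == 0
  )
}

#' Expected affected-relative counts under the equal-distribution null
#'
#' The null hypothesis distributes the observed affected relatives equally
#' over the four proband-sex by parental-line groups: each group expects one
#' fourth of the grand total.  Two forms are returned: the exact quarters and
#' the display triplet used in the published table, where the total and male
#' quarters are rounded half-up and the female value is the complement (so
#' the triplet stays additive).
#'
#' @param grand_total total number of affected relatives.
#' @param male_total number of male affected relatives.
#' @return list with `exact` and `display`, each `c(total =, male =, female =)`.
#' @export
expected_counts <- function(grand_total, male_total) {
  if (grand_total < 0 || male_total < 0) {
    mbd_error("mbdfam_malformed", "counts must be non-negative")
  }
  stopifnot(male_total <= grand_total)
  exact <- c(total = grand_total / 4, male = male_total / 4,
             female = (grand_total - male_total) / 4)
  dt <- round_half_up(grand_total / 4)
  dm <- round_half_up(male_total / 4)
  display <- c(total = dt, male = dm, female = dt - dm)
  list(exact = exact, display = display)
}

#' Score one observed-versus-expected cell
#'
#' Chi-squared goodness of fit of a single observed count against its
#' expected value, `(O - E)^2 / E` on 1 df, converted to the signed
#' significance score used in the four-group table: 0 when p > 0.05,
#' otherwise 1, 2 or 3 for p below 0.05, 0.01 and 0.001, with the sign of
#' `O - E`.
#'
#' @param obs observed count.
#' @param exp expected count (> 0); by convention the rounded display value.
#' @param yates apply Yates' continuity correction (default off).
#' @return list with `score`, `chisq` and `p`.
#' @export
score_cell <- function(obs, exp, yates = FALSE) {
  if (!is.finite(exp) || exp <= 0) {
    mbd_error("mbdfam_malformed", "expected value must be positive")
  }
  dev <- abs(obs - exp)
  if (yates) dev <- max(0, dev - 0.5)
  chisq <- dev^2 / exp
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  score <- if (p >= 0.05) 0L else if (p >= 0.01) 1L else if (p >= 0.001) 2L else 3L
  list(score = as.integer(sign(obs - exp)) * score, chisq = chisq, p = p)
}

ps_group_levels <- c("Psm-PA", "Psm-MA", "Psf-PA", "Psf-MA")

#' Score a four-group observed table
#'
#' Applies [expected_counts()] and [score_cell()] to a complete
#' observed-count table over the four proband-sex by parental-line groups.
#'
#' @param obs a 4 x 3 matrix (or data frame) of observed counts, rows
#'   `Psm-PA`, `Psm-MA`, `Psf-PA`, `Psf-MA`, columns `total`, `male`,
#'   `female`.
#' @param yates passed to [score_cell()].
#' @return object of class `four_group_table`: list with `obs`, `exp`
#'   (display), `exp_exact`, `scores` (signed integers, same shape as `obs`),
#'   `p` (matrix of p-values) and `pattern` from [classify_pattern()].
#' @export
score_four_group <- function(obs, yates = FALSE) {
  obs <- as.matrix(obs)
  if (!all(dim(obs) == c(4L, 3L))) {
    mbd_error("mbdfam_malformed", "obs must be 4 groups x (total, male, female)")
  }
  rownames(obs) <- ps_group_levels
  colnames(obs) <- c("total", "male", "female")
  if (any(obs[, "male"] + obs[, "female"] != obs[, "total"])) {
    mbd_error("mbdfam_malformed", "male + female must equal total in each group")
  }
  ec <- expected_counts(sum(obs[, "total"]), sum(obs[, "male"]))
  scores <- p <- chisq <- matrix(NA_real_, 4, 3,
                                 dimnames = dimnames(obs))
  for (g in 1:4) {
    for (col in colnames(obs)) {
      e <- ec$display[[col]]
      if (e > 0) {
        sc <- score_cell(obs[g, col], e, yates = yates)
      } else {
        # a zero expected display count carries no information
        sc <- list(score = 0L, chisq = 0, p = 1)
      }
      scores[g, col] <- sc$score; p[g, col] <- sc$p; chisq[g, col] <- sc$chisq
    }
  }
  out <- list(obs = obs, exp = ec$display, exp_exact = ec$exact,
              scores = scores, p = p, chisq = chisq)
  out$pattern <- classify_pattern(scores)
  class(out) <- "four_group_table"
  out
}

#' @export
print.four_group_table <- function(x, ...) {
  cat("Four-group affected-relative table (pattern:", x$pattern, ")\n")
  disp <- cbind(as.data.frame(x$obs),
                exp = paste0(x$exp[["total"]], " (", x$exp[["male"]], ", ",
                             x$exp[["female"]], ")"),
                score = apply(x$scores, 1, function(s)
                  sprintf("%d (%d, %d)", s[1], s[2], s[3])))
  print(disp, ...)
  invisible(x)
}

#' Classify the pattern of distribution of affected relatives
#'
#' Three canonical patterns of the signed score matrix are recognised.
#' PD1: excess male relatives for male probands and deficit for female
#' probands in the patrilineal line only, with both matrilineal male scores
#' null.  PD2: the same male excess/deficit in both parental lines.
#' PD3: no score anywhere differs from the null.  Everything else is
#' `"other"`.
#'
#' @param scores a 4 x 3 signed score matrix, rows `Psm-PA`, `Psm-MA`,
#'   `Psf-PA`, `Psf-MA`, columns `total`, `male`, `female` (as produced by
#'   [score_four_group()], which calls this automatically).
#' @return one of `"PD1"`, `"PD2"`, `"PD3"`, `"other"`.
#' @export
classify_pattern <- function(scores) {
  scores <- as.matrix(scores)
  if (!all(dim(scores) == c(4L, 3L)) || anyNA(scores)) {
    mbd_error("mbdfam_malformed", "scores must be a complete 4 x 3 matrix")
  }
  rownames(scores) <- ps_group_levels
  m <- scores[, 2]  # male column drives PD1/PD2
  if (all(scores == 0)) return("PD3")
  if (m[["Psm-PA"]] > 0 && m[["Psf-PA"]] < 0 &&
      m[["Psm-MA"]] == 0 && m[["Psf-MA"]] == 0) return("PD1")
  if (m[["Psm-PA"]] > 0 && m[["Psf-PA"]] < 0 &&
      m[["Psm-MA"]] > 0 && m[["Psf-MA"]] < 0) return("PD2")
  "other"
}

#' Census of parent-offspring versus oblique affected pairs
#'
#' Counts, per diagnosis group, how many proband/affected-relative links are
#' direct parent-offspring pairs and how many are other vertical ("oblique")
#' connections such as proband-uncle or proband-aunt.
#'
#' @param links a data frame of affected-relative links with at least a
#'   logical `parent_offspring` column; an optional `group` column splits the
#'   census by diagnosis group.
#' @return data frame with columns `group`, `n_pairs`, `parent_offspring`,
#'   `oblique`, `oblique_pct` (half-up, one decimal; `NA` when empty).
#' @export
pair_census <- function(links) {
  if (is.null(links$group)) links$group <- rep("all", nrow(links))
  groups <- sort(unique(as.character(links$group)))
  if (!length(groups)) groups <- "all"
  rows <- lapply(groups, function(g) {
    sub <- links[links$group == g, , drop = FALSE]
    n <- nrow(sub)
    po <- sum(sub$parent_offspring)
    data.frame(group = g, n_pairs = n, parent_offspring = po,
               oblique = n - po,
               oblique_pct = if (n > 0) round_half_up(100 * (n - po) / n, 1)
                             else NA_real_)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(group = character(), n_pairs = integer(),
                      parent_offspring = integer(), oblique = integer(),
                      oblique_pct = numeric())
  }
  out
}

#' Score a four-group table across pedigree replicates
#'
#' For simulated multi-pedigree cohorts the chi-squared count test of
#' [score_cell()] is anti-conservative: links are clustered within lineages
#' and pedigrees, so cell counts are overdispersed relative to the
#' independent-draw null.  This scorer treats each pedigree as the unit of
#' replication: per pedigree and per column (total, male, female) it takes
#' the share of links falling in each proband-sex by parental-line group
#' and tests the mean share against the null quarter with a one-sample
#' t-test, converting p-values to the same signed score levels.
#'
#' @param obs_list list of 4 x 3 observed-count matrices, one per pedigree
#'   (rows `Psm-PA`, `Psm-MA`, `Psf-PA`, `Psf-MA`; columns `total`, `male`,
#'   `female`).
#' @param min_links pedigrees contribute to a column only when they carry
#'   at least this many links of that column's class.
#' @return object of class `four_group_table` with the pooled `obs`, the
#'   pooled display `exp`, replicate-based `scores` and `p`, the number of
#'   contributing replicates `n_rep`, and the resulting `pattern`.
#' @export
score_four_group_replicates <- function(obs_list, min_links = 3L) {
  stopifnot(length(obs_list) >= 2L)
  obs <- Reduce(`+`, obs_list)
  rownames(obs) <- ps_group_levels
  colnames(obs) <- c("total", "male", "female")
  scores <- p <- matrix(NA_real_, 4, 3, dimnames = dimnames(obs))
  n_rep <- setNames(integer(3), colnames(obs))
  for (col in colnames(obs)) {
    shares <- vapply(obs_list, function(m) {
      tot <- sum(m[, col])
      if (tot >= min_links) m[, col] / tot else rep(NA_real_, 4)
    }, numeric(4))
    w_all <- vapply(obs_list, function(m) sum(m[, col]), 0)
    for (g in 1:4) {
      x <- shares[g, ]
      keep <- !is.na(x)
      x <- x[keep]; w <- w_all[keep]
      n_rep[[col]] <- length(x)
      if (length(x) < 3L || stats::sd(x) == 0) {
        scores[g, col] <- 0L; p[g, col] <- 1
        next
      }
      # links-weighted mean share with a cluster-robust (sandwich) variance:
      # pedigrees are the clusters, so the empirical between-pedigree
      # dispersion replaces the independent-draw variance
      xb <- sum(w * x) / sum(w)
      se <- sqrt(sum(w^2 * (x - xb)^2) / sum(w)^2)
      tt <- (xb - 0.25) / se
      pv <- 2 * stats::pt(-abs(tt), df = length(x) - 1L)
      lev <- if (pv >= 0.05) 0L else if (pv >= 0.01) 1L else if (pv >= 0.001) 2L else 3L
      scores[g, col] <- sign(xb - 0.25) * lev
      p[g, col] <- pv
    }
  }
  ec <- expected_counts(sum(obs[, "total"]), sum(obs[, "male"]))
  out <- list(obs = obs, exp = ec$display, exp_exact = ec$exact,
              scores = scores, p = p, n_rep = n_rep)
  out$pattern <- classify_pattern(scores)
  class(out) <- "four_group_table"
  out
}
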