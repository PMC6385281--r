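#' Sibship constructor
#'
#' A sibship records the birth ranks (1 = first-born) of its affected
#' members.  Sibships where nobody or everybody is affected, or of size one,
#' carry no birth-order information and are excluded from the test sum.
#'
#' @param size number of sibs.
#' @param affected_ranks integer vector of birth ranks of the affected sibs.
#' @param id optional identifier.
#' @return object of class `sibship`.
#' @export
sibship <- function(size, affected_ranks, id = NA_character_) {
  size <- as.integer(size)
  affected_ranks <- as.integer(sort(affected_ranks))
  if (size < 1L || length(affected_ranks) > size ||
      anyDuplicated(affected_ranks) ||
      (length(affected_ranks) && (min(affected_ranks) < 1L ||
                                  max(affected_ranks) > size))) {
    mbd_error("mbdfam_malformed", "invalid sibship: ranks must be distinct in 1..size")
  }
  structure(list(id = id, size = size, affected_ranks = affected_ranks,
                 m = length(affected_ranks)),
            class = "sibship")
}

sibship_informative <- function(sib) sib$size >= 2L && sib$m >= 1L && sib$m < sib$size

#' Extract sibships from a pedigree
#'
#' Groups individuals by their (father, mother) couple; birth order within a
#' sibship follows `birth_year` (ties broken by id, never inferred from equal
#' years alone).
#'
#' @param ped a `pedigree`.
#' @param affected_ids optional character vector: treat exactly these
#'   individuals as affected (used e.g. to restrict the test to a stratum of
#'   standardized probands); default is the pedigree's affection status.
#' @return list of [sibship()] objects.
#' @export
sibships_from_pedigree <- function(ped, affected_ids = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  has_parents <- !is.na(ped$father) & !is.na(ped$mother)
  kids <- ped[has_parents, , drop = FALSE]
  if (!nrow(kids)) return(list())
  key <- paste(kids$father, kids$mother, sep = "\r")
  aff <- if (is.null(affected_ids)) kids$affected == "affected"
         else kids$id %in% affected_ids
  out <- lapply(split(seq_len(nrow(kids)), key), function(rows) {
    by <- kids$birth_year[rows]
    ord <- order(by, kids$id[rows], na.last = TRUE)
    rows <- rows[ord]
    sibship(length(rows), which(aff[rows]),
            id = paste(kids$father[rows[1]], kids$mother[rows[1]], sep = "x"))
  })
  unname(out[order(vapply(out, `[[`, "", "id"))])
}

#' Haldane-Smith birth-order test
#'
#' Tests whether affected sibs occupy random birth ranks within their
#' sibships.  The statistic is `A`, the sum of birth ranks of affected sibs
#' over informative sibships (those with at least one affected and one
#' unaffected sib).  Under the null each of the `choose(s, m)` rank subsets
#' is equally likely, giving `E[A] = sum m(s+1)/2` and
#' `Var[A] = sum m(s-m)(s+1)/12`; the test reports the normal deviate, a
#' two-sided p and the 95% confidence band of `A` under the null.
#'
#' @param sibs list of [sibship()] objects.
#' @return object of class `birth_order_result`: list with `A`, `expectation`,
#'   `variance`, `z`, `p`, `ci95` (the null band `E +/- 1.96 sd`) and
#'   `n_informative`.
#' @export
haldane_smith <- function(sibs) {
  sibs <- sibs[vapply(sibs, sibship_informative, TRUE)]
  if (!length(sibs)) {
    mbd_error("mbdfam_no_informative", "no informative sibship (need 1 <= m < s, s >= 2)")
  }
  s <- vapply(sibs, `[[`, 0L, "size")
  m <- vapply(sibs, `[[`, 0L, "m")
  A <- sum(vapply(sibs, function(x) sum(x$affected_ranks), 0))
  expectation <- sum(m * (s + 1) / 2)
  variance <- sum(m * (s - m) * (s + 1) / 12)
  z <- (A - expectation) / sqrt(variance)
  structure(list(A = A, expectation = expectation, variance = variance,
                 z = z, p = 2 * pnorm(-abs(z)),
                 ci95 = expectation + c(-1, 1) * 1.96 * sqrt(variance),
                 n_informative = length(sibs)),
            class = "birth_order_result")
}

#' @export
print.birth_order_result <- function(x, ...) {
  cat(sprintf(paste0("Haldane-Smith birth-order test: A = %g, E = %g, ",
                     "Var = %g\n  z = %.3f, p = %.4g, null CI95 [%.1f, %.1f], ",
                     "%d informative sibships\n"),
              x$A, x$expectation, x$variance, x$z, x$p,
              x$ci95[1], x$ci95[2], x$n_informative))
  invisible(x)
}

# exact null distribution of the rank sum within one sibship
sibship_rank_sum_dist <- function(s, m) {
  subsets <- utils::combn(s, m)
  sums <- colSums(matrix(subsets, nrow = m))
  tab <- table(sums)
  support <- as.integer(names(tab))
  data.frame(A = support, prob = as.numeric(tab) / sum(tab))
}

#' Exact tail probabilities for the Haldane-Smith statistic
#'
#' Full enumeration of the equally likely rank assignments across the
#' informative sibships (computed as the convolution of the per-sibship rank
#' sum distributions, which is exact because sibships are independent).
#'
#' @param sibs list of [sibship()] objects.
#' @param budget maximum number of rank assignments
#'   (`prod(choose(s_i, m_i))`) allowed before giving up.
#' @return list with `A` (observed), `p_ge` = P(A >= observed),
#'   `p_le` = P(A <= observed), and `dist` (the exact null distribution).
#' @export
haldane_smith_exact <- function(sibs, budget = 1e7) {
  sibs <- sibs[vapply(sibs, sibship_informative, TRUE)]
  if (!length(sibs)) {
    mbd_error("mbdfam_no_informative", "no informative sibship")
  }
  n_assign <- prod(vapply(sibs, function(x) choose(x$size, x$m), 0))
  if (n_assign > budget) {
    mbd_error("mbdfam_budget", sprintf("enumeration budget exceeded (%g > %g)",
                                       n_assign, budget))
  }
  obs <- sum(vapply(sibs, function(x) sum(x$affected_ranks), 0))
  # convolve per-sibship distributions on an integer grid
  dist <- data.frame(A = 0L, prob = 1)
  for (sib in sibs) {
    d <- sibship_rank_sum_dist(sib$size, sib$m)
    grid <- outer(dist$A, d$A, `+`)
    pr <- outer(dist$prob, d$prob)
    agg <- tapply(as.vector(pr), as.vector(grid), sum)
    dist <- data.frame(A = as.integer(names(agg)), prob = as.numeric(agg))
  }
  list(A = obs,
       p_ge = sum(dist$prob[dist$A >= obs]),
       p_le = sum(dist$prob[dist$A <= obs]),
       dist = dist)
}

#' Wilcoxon signed-rank control for the birth-order effect
#'
#' Each affected sib's birth rank is centred on the median rank of its
#' sibship (`(s + 1) / 2`, the midpoint of all healthy and affected sibs);
#' the centred values are tested against zero with the Wilcoxon signed-rank
#' test.  Positive values mean affected sibs born late.
#'
#' @param sibs list of [sibship()] objects; sibships of size one are
#'   excluded.
#' @return list with `statistic` (V), `p`, `centered` (the centred ranks).
#' @export
wilcoxon_control <- function(sibs) {
  sibs <- sibs[vapply(sibs, function(x) x$size >= 2L && x$m >= 1L, TRUE)]
  centered <- unlist(lapply(sibs, function(x)
    x$affected_ranks - (x$size + 1) / 2))
  if (!length(centered) || all(centered == 0)) {
    mbd_error("mbdfam_no_informative", "all centred ranks are zero")
  }
  wt <- suppressWarnings(wilcox.test(centered, mu = 0,
                                     alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p = wt$p.value, centered = centered)
}
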