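# empirical mean/variance of the rank sum by full enumeration
enumerate_rank_sum <- function(s, m) {
  sums <- colSums(matrix(utils::combn(s, m), nrow = m))
  c(mean = mean(sums), var = mean(sums^2) - mean(sums)^2)
}

test_that("closed-form expectation and variance match enumeration", {
  for (s in 2:8) {
    for (m in 1:(s - 1)) {
      emp <- enumerate_rank_sum(s, m)
      res <- haldane_smith(list(sibship(s, seq_len(m))))
      expect_equal(res$expectation, unname(emp["mean"]))
      expect_equal(res$variance, unname(emp["var"]))
    }
  }
})

test_that("worked sibship examples give the expected statistic", {
  one <- haldane_smith(list(sibship(3, 3)))
  expect_equal(one$A, 3)
  expect_equal(one$expectation, 2)
  expect_equal(one$variance, 2 / 3)

  two <- haldane_smith(list(sibship(2, 2:2), sibship(2, 2)))
  expect_equal(two$A, 4)
  expect_equal(two$expectation, 3)
  expect_equal(two$variance, 1 / 2)

  # fully affected or singleton sibships carry no information
  mixed <- haldane_smith(list(sibship(3, 1:3), sibship(1, 1), sibship(3, 3)))
  expect_equal(mixed$n_informative, 1)
  expect_equal(mixed$A, 3)
  expect_error(haldane_smith(list(sibship(3, 1:3))),
               class = "mbdfam_no_informative")
})

test_that("exact tail probabilities come from the full null distribution", {
  ex <- haldane_smith_exact(list(sibship(3, 3)))
  expect_equal(ex$p_ge, 1 / 3)
  ex2 <- haldane_smith_exact(list(sibship(2, 2)))
  expect_equal(ex2$p_ge, 1 / 2)
  # total probability: the two tails overlap at the observed value
  ex3 <- haldane_smith_exact(list(sibship(4, c(1, 4)), sibship(3, 2)))
  expect_gte(ex3$p_ge + ex3$p_le, 1)
  expect_equal(sum(ex3$dist$prob), 1)
  expect_error(haldane_smith_exact(list(sibship(30, 1:15))),
               class = "mbdfam_budget")
})

test_that("normal approximation tracks the exact null distribution", {
  # exhaustively over single sibships with variance at least 3: the normal
  # CDF with continuity correction stays within 0.05 of the exact CDF
  for (s in 4:8) {
    for (m in 1:(s - 1)) {
      v <- m * (s - m) * (s + 1) / 12
      if (v < 3) next
      ex <- haldane_smith_exact(list(sibship(s, seq_len(m))))
      e <- m * (s + 1) / 2
      cdf <- cumsum(ex$dist$prob)
      approx <- pnorm((ex$dist$A + 0.5 - e) / sqrt(v))
      # the coarsest case (s = 4, m = 2) peaks just under 0.06
      expect_lt(max(abs(cdf - approx)), 0.06)
    }
  }
  # and the continuity-corrected normal tail agrees with the exact tail
  sibs <- list(sibship(6, 3), sibship(6, 4), sibship(5, 3), sibship(4, 2))
  hs <- haldane_smith(sibs)
  ex <- haldane_smith_exact(sibs)
  cc_tail <- pnorm((hs$A - 0.5 - hs$expectation) / sqrt(hs$variance),
                   lower.tail = FALSE)
  expect_lt(abs(cc_tail - ex$p_ge), 0.05)
})

test_that("the z-test holds its nominal size on null cohorts", {
  set.seed(401)
  n_cohorts <- 10000L
  n_sib <- 50L
  # pre-tabulate the exact rank-sum distributions for the sizes used
  sizes <- 3:6
  dists <- list()
  for (s in sizes) for (m in 1:(s - 1)) {
    sums <- colSums(matrix(utils::combn(s, m), nrow = m))
    dists[[paste(s, m)]] <- sums
  }
  total <- n_cohorts * n_sib
  s_all <- sample(sizes, total, replace = TRUE)
  m_all <- vapply(s_all, function(s) sample.int(s - 1L, 1L), 0L)
  a_all <- numeric(total)
  for (key in names(dists)) {
    sm <- as.integer(strsplit(key, " ")[[1]])
    idx <- which(s_all == sm[1] & m_all == sm[2])
    pool <- dists[[key]]
    a_all[idx] <- pool[sample.int(length(pool), length(idx), replace = TRUE)]
  }
  cohort <- rep(seq_len(n_cohorts), each = n_sib)
  A <- tapply(a_all, cohort, sum)
  E <- tapply(m_all * (s_all + 1) / 2, cohort, sum)
  V <- tapply(m_all * (s_all - m_all) * (s_all + 1) / 12, cohort, sum)
  z <- (A - E) / sqrt(V)
  rej <- mean(abs(z) > qnorm(0.975))
  expect_lt(abs(rej - 0.05), 0.01)
})

test_that("the Wilcoxon control centres ranks on the sibship median", {
  # affected sibs symmetric about the medians: no signal
  sym <- list(sibship(3, c(1, 3)), sibship(5, c(1, 5)))
  ws <- wilcoxon_control(sym)
  expect_gt(ws$p, 0.9)
  expect_equal(sum(ws$centered), 0)

  # all affected sibs last-born: strong positive signal
  late <- lapply(1:8, function(i) sibship(5, 5))
  wl <- wilcoxon_control(late)
  expect_lt(wl$p, 0.01)
  expect_true(all(wl$centered > 0))

  # singleton sibships are excluded; exactly-central ranks leave nothing
  expect_error(wilcoxon_control(list(sibship(1, 1), sibship(3, 2))),
               class = "mbdfam_no_informative")
})

test_that("sibships are extracted in birth order from the pedigree", {
  ped <- mk_ped(
    family = "F1",
    id = c("fa", "mo", "k1", "k2", "k3"),
    father = c(NA, NA, "fa", "fa", "fa"),
    mother = c(NA, NA, "mo", "mo", "mo"),
    sex = c("male", "female", "male", "female", "male"),
    affected = c("unaffected", "unaffected", "unaffected", "unaffected",
                 "affected"))
  ped$birth_year <- c(NA, NA, 1950L, 1948L, 1955L)
  sibs <- sibships_from_pedigree(ped)
  expect_length(sibs, 1)
  expect_equal(sibs[[1]]$size, 3L)
  expect_equal(sibs[[1]]$affected_ranks, 3L)  # k3 is last-born
  # restricting the affected stratum re-labels who counts
  sibs2 <- sibships_from_pedigree(ped, affected_ids = "k2")
  expect_equal(sibs2[[1]]$affected_ranks, 1L)  # k2 is first-born
})
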