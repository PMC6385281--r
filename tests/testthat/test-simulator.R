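small_cfg <- function(seed = 1, ...) {
  args <- list(seed = seed, founder_couples = 8L, carrier_founders = 3L,
               max_couples = 30L, generations = 5L)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(sim_config, args)
}

test_that("allele transmission and imprinting rules are respected", {
  set.seed(1)
  # non-carrier parents never transmit
  expect_false(transmit_allele(FALSE, "male", "maternal")$inherited)
  # a maternally transmitted copy is silenced under maternal imprinting
  hits <- replicate(200, {
    t <- transmit_allele(TRUE, "female", "maternal")
    c(t$inherited, t$expressed)
  })
  expect_true(any(hits[1, ]))
  expect_false(any(hits[2, ]))
  # and expressed when the father transmits
  pats <- replicate(200, {
    t <- transmit_allele(TRUE, "male", "maternal")
    c(t$inherited, t$expressed)
  })
  expect_true(all(pats[2, ] == pats[1, ]))
  # mode none expresses nothing
  expect_false(transmit_allele(TRUE, "male", "none")$expressed)
})

test_that("microchimerism updates follow birth order", {
  m <- mother_state(0)
  b1 <- update_microchimerism(m, fetus_carrier = TRUE, fetus_sex = "male",
                              birth_index = 1)
  expect_equal(b1$child_letters, 0L)       # pre-birth load
  expect_equal(b1$mother$acquired, 1L)
  b2 <- update_microchimerism(b1$mother, FALSE, "female", 2)
  expect_equal(b2$child_letters, 1L)       # later sib inherits more
  expect_equal(b2$mother$acquired, 1L)     # non-carrier daughter: no mark
  expect_error(update_microchimerism(b2$mother, TRUE, "male", 5),
               class = "mbdfam_birth_order")
  # the cap limits what can be transmitted
  deep <- mother_state(9)
  b3 <- update_microchimerism(deep, FALSE, "male", 1, letters_cap = 7)
  expect_equal(b3$child_letters, 7L)
})

test_that("manifestation needs expression and threshold load", {
  expect_true(manifest(TRUE, 2, theta = 2)$affected)
  expect_false(manifest(TRUE, 1, theta = 2)$affected)   # silent bystander
  expect_false(manifest(FALSE, 5, theta = 2)$affected)  # unexpressed carrier
  early <- manifest(TRUE, 7, onset_base = 75, slope = 4, onset_min = 15)
  late <- manifest(TRUE, 2, onset_base = 75, slope = 4, onset_min = 15)
  expect_lt(early$onset_age, late$onset_age)  # anticipation
})

test_that("simulation is reproducible and respects the null mode", {
  a <- simulate_cohort(small_cfg(3))
  b <- simulate_cohort(small_cfg(3))
  expect_identical(a$ped, b$ped)
  expect_identical(a$truth, b$truth)

  null <- simulate_cohort(small_cfg(3, imprinting_mode = "none"))
  expect_equal(sum(null$ped$affected == "affected"), 0)
  expect_true(attr(null, "extinct"))
})

test_that("carrier transmission frequency is one half", {
  trans <- 0L; carried <- 0L
  for (s in 1:16) {
    sim <- simulate_cohort(small_cfg(s, founder_couples = 20L,
                                     carrier_founders = 20L,
                                     max_couples = 110L, generations = 6L,
                                     immigrant_carrier_prob = 0.45))
    tr <- sim$truth
    ped <- sim$ped
    fa_c <- tr$carrier[match(ped$father, tr$id)]
    mo_c <- tr$carrier[match(ped$mother, tr$id)]
    one <- !is.na(fa_c) & !is.na(mo_c) & xor(fa_c, mo_c)
    trans <- trans + sum(one)
    carried <- carried + sum(tr$carrier[one])
  }
  expect_gt(trans, 10000)
  p <- carried / trans
  ci <- 2.58 * sqrt(0.25 / trans)
  expect_lt(abs(p - 0.5), ci)
})

test_that("affection routes respect the imprinting mode structurally", {
  for (s in 1:4) {
    # pure maternal imprinting, no escape, no background:
    # every affected individual's allele is paternally transmitted
    sim <- simulate_cohort(small_cfg(s, imprint_escape = 0, sporadic_rate = 0))
    tr <- sim$truth[sim$truth$affected, ]
    expect_true(all(tr$allele_pat))
    # converse under paternal imprinting
    simp <- simulate_cohort(small_cfg(s, imprinting_mode = "paternal",
                                      imprint_escape = 0, sporadic_rate = 0))
    trp <- simp$truth[simp$truth$affected, ]
    expect_true(all(trp$allele_mat))
  }
})

test_that("letters at birth never decrease along a sibship", {
  sim <- simulate_cohort(small_cfg(5))
  ped <- sim$ped
  tr <- sim$truth
  key <- paste(ped$father, ped$mother)
  for (k in unique(key[!is.na(ped$father)])) {
    sibs <- which(key == k & !is.na(ped$father))
    ord <- order(ped$birth_year[sibs], ped$id[sibs])
    expect_true(all(diff(tr$letters[sibs][ord]) >= 0))
  }
})

test_that("nuclear-families mode yields unrelated parents", {
  sim <- simulate_cohort(small_cfg(2, inbreeding_mode = "nuclear-families",
                                   founder_couples = 25L, generations = 3L))
  ped <- sim$ped
  expect_gt(length(unique(ped$family)), 20)
  # spouses never share a pedigree ancestor: every mother or father of a
  # child is either a founder or married to a founder
  kids <- ped[!is.na(ped$father), ]
  fa_founder <- is.na(ped$father[match(kids$father, ped$id)])
  mo_founder <- is.na(ped$father[match(kids$mother, ped$id)])
  expect_true(all(fa_founder | mo_founder))
})

test_that("simulated phenotype files round-trip through the PED reader", {
  sim <- simulate_cohort(small_cfg(4))
  dir <- tempfile()
  run_simulate(sim$config, out_dir = dir)
  expect_true(file.exists(file.path(dir, "pedigree.ped")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_pedigree(file.path(dir, "pedigree.ped"),
                        file.path(dir, "phenotype.tsv"))
  expect_equal(nrow(back), nrow(sim$ped))
  expect_equal(sum(back$affected == "affected"),
               sum(sim$ped$affected == "affected"))
  expect_equal(back$diagnosis, sim$ped$diagnosis)
})
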