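test_that("affected relatives are enumerated with the intermediates rule", {
  ped <- three_gen_ped()
  links <- enumerate_ar(ped, "pr")
  expect_setequal(links$relative, c("un", "sib"))
  un <- links[links$relative == "un", ]
  expect_equal(un$line, "PA")
  expect_equal(un$intermediates, 2L)  # healthy father and grandparent
  sib <- links[links$relative == "sib", ]
  expect_equal(sib$line, "ambiguous")  # equally close via both parents
  expect_equal(sib$intermediates, 1L)

  expect_error(enumerate_ar(ped, "fa"), class = "mbdfam_not_affected")
})

test_that("relatives beyond five healthy intermediates are excluded", {
  # chain: proband - 6 healthy ancestors - affected top ancestor
  n <- 8
  ids <- c("pr", paste0("h", 1:6), "top")
  ped <- mk_ped(
    family = "F1", id = ids,
    father = c("h1", paste0("h", 2:6), "top", NA),
    mother = rep(NA_character_, n),
    sex = "male",
    affected = c("affected", rep("unaffected", 6), "affected")
  )
  expect_equal(nrow(enumerate_ar(ped, "pr", max_intermediates = 5)), 0)
  expect_equal(nrow(enumerate_ar(ped, "pr", max_intermediates = 6)), 1)
  # an affected individual on the chain does not count against the budget
  ped2 <- ped
  ped2$affected[ped2$id == "h3"] <- "affected"
  l2 <- enumerate_ar(ped2, "pr", max_intermediates = 5)
  expect_setequal(l2$relative, c("h3", "top"))
  expect_equal(l2$intermediates[l2$relative == "top"], 5L)
})

test_that("affiliation classification follows the four groups", {
  pa_links <- data.frame(proband = "p", relative = c("r1", "r2"),
                         line = c("PA", "PA"))
  expect_equal(classify_affiliation(pa_links), "PA")
  both <- data.frame(proband = "p", relative = c("r1", "r2"),
                     line = c("PA", "MA"))
  expect_equal(classify_affiliation(both), "PA+MA")
  amb <- data.frame(proband = "p", relative = c("r1", "r2"),
                    line = c("ambiguous", "ambiguous"))
  expect_equal(classify_affiliation(amb), "PA=MA")
  none <- data.frame(proband = character(0), relative = character(0),
                     line = character(0))
  expect_equal(classify_affiliation(none), "none-visible")
  desc <- data.frame(proband = "p", relative = "kid", line = "descendant")
  expect_equal(classify_affiliation(desc), "none-visible")
})

test_that("standardization conserves counts and splits the none-visible set", {
  # 22 probands with no visible ancestral link -> 11 on each line
  recs <- data.frame(
    proband = sprintf("p%02d", 1:22), sex = "male",
    diagnosis = NA_character_, n_links = 0L,
    affiliation = "none-visible", stringsAsFactors = FALSE)
  links <- data.frame(proband = character(), relative = character(),
                      line = character(), cost_pa = numeric(),
                      cost_ma = numeric(), stringsAsFactors = FALSE)
  std <- standardize(recs, links)
  expect_equal(nrow(std$ps), 22)
  expect_equal(sum(std$ps$line == "PA"), 11)
  expect_equal(sum(std$ps$line == "MA"), 11)
  # odd remainder goes to the patrilineal side
  std3 <- standardize(recs[1:3, ], links)
  expect_equal(sum(std3$ps$line == "PA"), 2)

  # a two-line proband yields two standard probands
  recs2 <- data.frame(proband = "q", sex = "female", diagnosis = NA,
                      n_links = 2L, affiliation = "PA+MA")
  links2 <- data.frame(proband = "q", relative = c("r1", "r2"),
                       line = c("PA", "MA"), cost_pa = c(1, NA),
                       cost_ma = c(NA, 0), stringsAsFactors = FALSE)
  std2 <- standardize(recs2, links2)
  expect_equal(nrow(std2$ps), 2)
  expect_setequal(std2$ps$line, c("PA", "MA"))
  expect_equal(std2$links$ps_id[std2$links$relative == "r1"], "q:PA")
  expect_equal(std2$links$ps_id[std2$links$relative == "r2"], "q:MA")
})

test_that("mixed-affiliation probands go to the closer majority line", {
  recs <- data.frame(proband = "m", sex = "male", diagnosis = NA,
                     n_links = 3L, affiliation = "PA=MA")
  # three relatives, all strictly closer through the mother
  links <- data.frame(proband = "m", relative = c("r1", "r2", "r3"),
                      line = "ambiguous",
                      cost_pa = c(3, 2, 4), cost_ma = c(1, 1, 2),
                      stringsAsFactors = FALSE)
  std <- standardize(recs, links)
  expect_equal(std$ps$line, "MA")
  expect_false(std$ps$tie_broken)
})

test_that("count conservation holds across affiliation groups", {
  for (seed in c(2, 9, 17)) {
    sim <- simulate_cohort(sim_config(seed = seed, founder_couples = 6L,
                                      carrier_founders = 3L,
                                      max_couples = 25L, generations = 5L))
    if (sum(sim$ped$affected == "affected") < 5) next
    seg <- analyze_segregation(sim$ped)
    tab <- table(seg$records$affiliation)
    n <- function(k) if (k %in% names(tab)) tab[[k]] else 0L
    expect_equal(nrow(seg$ps),
                 2L * n("PA+MA") + n("PA") + n("MA") + n("PA=MA") +
                   n("none-visible"))
    # each relative appears at most once per proband
    expect_false(any(duplicated(seg$links[, c("proband", "relative")])))
  }
})

test_that("link enumeration matches the brute-force oracle", {
  for (seed in 1:20) {
    ped <- random_pedigree(seed + 100, sample(12:40, 1))
    aff <- ped$id[ped$affected == "affected"]
    if (length(aff) < 2) next
    links <- affected_links(ped)
    for (p in head(sort(aff), 4)) {
      got <- links[links$proband == p, c("relative", "line", "intermediates")]
      got <- got[order(got$relative), , drop = FALSE]
      want <- oracle_links(ped, p)
      expect_equal(got$relative, want$relative, info = paste(seed, p))
      expect_equal(got$line, want$line, info = paste(seed, p))
      expect_equal(got$intermediates, want$intermediates, info = paste(seed, p))
    }
  }
})

test_that("analysis output is deterministic for a fixed pedigree", {
  ped <- random_pedigree(7, 30)
  a <- analyze_segregation(ped)
  b <- analyze_segregation(ped)
  expect_identical(a$links, b$links)
  expect_identical(a$ps, b$ps)
  expect_identical(a$table$scores, b$table$scores)
})
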