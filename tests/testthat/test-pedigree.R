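test_that("a minimal trio parses and round-trips through PED files", {
  ped_file <- tempfile(fileext = ".ped")
  phe_file <- tempfile(fileext = ".tsv")
  writeLines(c("F1\tfa\t0\t0\t1\t1",
               "F1\tmo\t0\t0\t2\t1",
               "F1\tch\tfa\tmo\t1\t2"), ped_file)
  writeLines(c("iid\ticd10\tbirth_year\tonset_year",
               "ch\tC91.1\t1950\t2001"), phe_file)
  ped <- read_pedigree(ped_file, phe_file)
  expect_s3_class(ped, "pedigree")
  expect_equal(nrow(ped), 3)
  ch <- ped[ped$id == "ch", ]
  expect_equal(ch$father, "fa")
  expect_equal(ch$mother, "mo")
  expect_equal(ch$affected, "affected")
  expect_equal(ch$diagnosis, "C91.1")
  expect_equal(ch$onset_year, 2001L)

  out_ped <- tempfile(fileext = ".ped")
  out_phe <- tempfile(fileext = ".tsv")
  write_pedigree(ped, out_ped, out_phe)
  back <- read_pedigree(out_ped, out_phe)
  expect_identical(as.data.frame(back), as.data.frame(ped))
})

test_that("validation failures raise distinct named conditions", {
  base <- data.frame(
    family = "F1", id = c("a", "b", "c"),
    father = c(NA, NA, "a"), mother = c(NA, NA, "b"),
    sex = c("male", "female", "male"),
    affected = "unaffected", stringsAsFactors = FALSE)

  cyc <- base
  cyc$father[1] <- "c"  # a's father is its own grandchild
  expect_error(as_pedigree(cyc), class = "mbdfam_cycle")

  sx <- base
  sx$sex[1] <- "female"  # father coded female
  expect_error(as_pedigree(sx), class = "mbdfam_sex_mismatch")

  dup <- base
  dup$id[2] <- "a"
  expect_error(as_pedigree(dup), class = "mbdfam_duplicate_id")

  orphan <- base
  orphan$father[3] <- "zz"
  expect_error(as_pedigree(orphan), class = "mbdfam_unknown_parent")

  bad_file <- tempfile()
  writeLines("F1\tonly\tthree", bad_file)
  expect_error(read_pedigree(bad_file), class = "mbdfam_malformed")
  writeLines("F1\tx\t0\t0\t5\t1", bad_file)
  expect_error(read_pedigree(bad_file), class = "mbdfam_malformed")
})

test_that("connecting paths find the classic relationships", {
  ped <- three_gen_ped()

  to_gf <- connecting_paths(ped, "pr", "gf", 5)
  expect_length(to_gf, 1)
  expect_equal(to_gf[[1]]$ids, c("pr", "fa", "gf"))
  expect_equal(relationship_label(to_gf[[1]]), "grandparent-line")

  sibs <- connecting_paths(ped, "pr", "sib", 5)
  expect_length(sibs, 2)  # via father and via mother
  expect_setequal(vapply(sibs, function(p) p$ids[2], ""), c("fa", "mo"))
  expect_true(all(vapply(sibs, relationship_label, "") == "sibling"))

  uncle <- connecting_paths(ped, "pr", "un", 5)
  expect_true(all(vapply(uncle, relationship_label, "") == "uncle-aunt"))

  expect_equal(relationship_label(connecting_paths(ped, "pr", "fa", 3)[[1]]),
               "parent-offspring")

  # unrelated founders are unconnected
  expect_length(connecting_paths(ped, "gf", "mo", 6), 0)

  expect_error(connecting_paths(ped, "pr", "pr", 5), class = "mbdfam_malformed")
})

test_that("interior count is path length minus one", {
  ped <- random_pedigree(5, 25)
  ids <- ped$id
  for (k in 1:10) {
    ab <- sample(ids, 2)
    for (p in connecting_paths(ped, ab[1], ab[2], 8)) {
      expect_equal(length(p$ids) - 2, length(p$ids) - 1 - 1)
      expect_equal(p$up + p$down, length(p$ids) - 1)
    }
  }
})

test_that("connecting_paths agrees with brute-force enumeration", {
  for (seed in 1:25) {
    ped <- random_pedigree(seed, sample(10:40, 1))
    ids <- ped$id
    for (k in 1:4) {
      ab <- sample(ids, 2)
      got <- connecting_paths(ped, ab[1], ab[2], 7)
      want <- oracle_paths(ped, ab[1], ab[2], 7)
      key <- function(p) paste(p$ids, collapse = ">")
      expect_setequal(vapply(got, key, ""), vapply(want, key, ""))
      if (length(got)) {
        gk <- vapply(got, key, "")
        wk <- vapply(want, key, "")
        expect_equal(vapply(got, `[[`, 0L, "up")[order(gk)],
                     vapply(want, function(p) as.integer(p$up), 0L)[order(wk)])
      }
    }
  }
})

test_that("the diagnosis map covers the hematologic ICD-10 range", {
  map <- diagnosis_map()
  expect_true(all(c("C81", "C91.1", "C90", "C92.1", "D45", "D47.1") %in% map$icd10))
  expect_true(all(map$group %in% c("LPD", "MPD", "OTHER")))
  expect_false(anyDuplicated(map$icd10) > 0)
  expect_equal(map$group[map$icd10 == "C91.1"], "LPD")
  expect_equal(map$group[map$icd10 == "D45"], "MPD")
})
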