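test_that("pedigree construction validates, normalizes, and orders", {
  ped <- pedigree(data.frame(id = c("C", "A", "B"),
                             sire = c("A", "0", ""),
                             dam = c("B", "0", "0")))
  expect_s3_class(ped, "pedigree")
  expect_equal(nrow(ped), 3)
  expect_gt(which(ped$animal_id == "C"), max(which(ped$animal_id %in% c("A", "B"))))

  # referenced-but-unlisted parent is auto-added as a founder
  ped2 <- pedigree(data.frame(id = c("A", "B", "C"),
                              sire = c("0", "0", "D"),
                              dam = c("0", "0", "A")))
  expect_equal(nrow(ped2), 4)
  d <- ped2[ped2$animal_id == "D"]
  expect_true(is.na(d$sire_id) && is.na(d$dam_id) && is.na(d$birth_year))
  expect_equal(d$sex, "male")

  expect_error(pedigree(data.frame(id = c("A", "B"), sire = c("B", "A"),
                                   dam = c("0", "0"))),
               "cycle")
  expect_error(pedigree(data.frame(id = c("A", "A"), sire = c("0", "0"),
                                   dam = c("0", "0"))),
               "duplicate")
})

test_that("load_pedigree reads delimited text with configurable columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal,father,mother,sx,yob",
               "A,0,,1,2000", "B,0,0,2,2001", "C,A,B,2,2005"), f)
  ped <- load_pedigree(f, columns = c(id = "animal", sire = "father",
                                      dam = "mother", sex = "sx",
                                      birth_year = "yob"))
  expect_equal(nrow(ped), 3)
  expect_equal(ped[animal_id == "C"]$sire_id, "A")
  expect_equal(ped[animal_id == "A"]$sex, "male")
  expect_error(load_pedigree(f, columns = c(id = "nope", sire = "father",
                                            dam = "mother")),
               "lacks required column")
})

test_that("compute_fped matches classical closed forms", {
  # offspring of full sibs from unrelated non-inbred founders: F = 0.25
  ped <- pedigree(data.frame(id = c("A", "B", "S1", "S2", "X"),
                             sire = c("0", "0", "A", "A", "S1"),
                             dam = c("0", "0", "B", "B", "S2")))
  f <- compute_fped(ped)
  expect_equal(unname(f["X"]), 0.25)
  expect_equal(unname(f[c("A", "B", "S1", "S2")]), rep(0, 4))

  # offspring of paternal half sibs: F = 0.125
  ped2 <- pedigree(data.frame(id = c("A", "B", "C", "H1", "H2", "X"),
                              sire = c("0", "0", "0", "A", "A", "H1"),
                              dam = c("0", "0", "0", "B", "C", "H2")))
  expect_equal(unname(compute_fped(ped2)["X"]), 0.125)
})

test_that("compute_fped equals the recursive-kinship oracle on random pedigrees", {
  for (seed in 1:10) {
    set.seed(seed)
    ped <- random_pedigree(sample(20:50, 1))
    expect_equal(compute_fped(ped), oracle_fped(ped), tolerance = 1e-12)
  }
})

test_that("F_ped is 0 with at most one known parent; founders unaffected by padding", {
  ped <- pedigree(data.frame(id = c("A", "B", "X", "Y"),
                             sire = c("0", "0", "A", "A"),
                             dam = c("0", "0", "0", "B")))
  f <- compute_fped(ped)
  expect_equal(unname(f["X"]), 0)

  # adding unrelated founders changes no existing F_ped or CGE
  set.seed(42)
  ped1 <- random_pedigree(30)
  extra <- data.frame(id = sprintf("Z%02d", 1:5), sire = "0", dam = "0",
                      sex = "female", birth_year = 1990)
  base <- data.frame(id = ped1$animal_id,
                     sire = ifelse(is.na(ped1$sire_id), "0", ped1$sire_id),
                     dam = ifelse(is.na(ped1$dam_id), "0", ped1$dam_id),
                     sex = ped1$sex, birth_year = ped1$birth_year)
  ped2 <- pedigree(rbind(base, extra))
  f1 <- compute_fped(ped1); f2 <- compute_fped(ped2)
  c1 <- compute_cge(ped1); c2 <- compute_cge(ped2)
  expect_equal(f1, f2[names(f1)])
  expect_equal(c1, c2[names(c1)])
})

test_that("compute_cge follows the path-sum definition and is monotone", {
  ped <- pedigree(data.frame(
    id = c("GS", "GD", "GS2", "GD2", "S", "D", "X", "P"),
    sire = c("0", "0", "0", "0", "GS", "GS2", "S", "S"),
    dam = c("0", "0", "0", "0", "GD", "GD2", "D", "0")))
  cge <- compute_cge(ped)
  expect_equal(unname(cge["GS"]), 0)            # founder
  expect_equal(unname(cge["S"]), 1.0)           # two founder parents
  expect_equal(unname(cge["X"]), 2.0)           # parents + 4 grandparents
  expect_equal(unname(cge["P"]), 0.5 * (1 + 1)) # one known parent with CGE 1

  # filling in a previously unknown parent never decreases CGE
  ped_filled <- pedigree(data.frame(
    id = c("GS", "GD", "GS2", "GD2", "S", "D", "X", "P", "NEWDAM"),
    sire = c("0", "0", "0", "0", "GS", "GS2", "S", "S", "0"),
    dam = c("0", "0", "0", "0", "GD", "GD2", "D", "NEWDAM", "0")))
  cge2 <- compute_cge(ped_filled)
  expect_true(all(cge2[names(cge)] >= cge))
  expect_gt(cge2[["P"]], cge[["P"]])
})

test_that("generation_intervals routes pathways by offspring sex and parent role", {
  ped <- pedigree(data.frame(
    id = c("SIRE", "DAM", "SON", "DAU"),
    sire = c("0", "0", "SIRE", "SIRE"),
    dam = c("0", "0", "DAM", "DAM"),
    sex = c("male", "female", "male", "female"),
    birth_year = c(2000, 2001, 2005, 2006)))
  gi <- generation_intervals(ped)
  expect_equal(gi[pathway == "sire_of_bulls" & year == 2005]$mean_interval, 5)
  expect_equal(gi[pathway == "sire_of_cows" & year == 2006]$mean_interval, 6)
  expect_equal(gi[pathway == "dam_of_bulls" & year == 2005]$mean_interval, 4)
  expect_equal(gi[pathway == "dam_of_cows" & year == 2006]$mean_interval, 5)

  # negative interval: pair excluded with a warning, not emitted as zero
  ped_bad <- pedigree(data.frame(
    id = c("S", "D", "K"), sire = c("0", "0", "S"), dam = c("0", "0", "D"),
    sex = c("male", "female", "female"),
    birth_year = c(2005, 2000, 2003)))
  expect_warning(gi2 <- generation_intervals(ped_bad), "non-positive")
  expect_false("sire_of_cows" %in% gi2$pathway)
  expect_equal(attr(gi2, "skipped")[["nonpositive"]], 1L)
})

test_that("generation_intervals recovers a construction-fixed dam GI", {
  gi_fix <- list(pre = c(sire_of_bulls = 4, dam_of_bulls = 4,
                         sire_of_cows = 4, dam_of_cows = 4),
                 post = c(sire_of_bulls = 4, dam_of_bulls = 4,
                          sire_of_cows = 4, dam_of_cows = 4))
  sc <- herd_scenario(n_founders = 40, years = c(2000, 2006),
                      offspring_per_year = 30, gi = gi_fix, gi_sd = 0,
                      switch_year = 2003, seed = 7)
  sim <- simulate_pedigree(sc)
  gi <- generation_intervals(sim$pedigree)
  dam_rows <- gi[grepl("^dam", pathway)]
  expect_true(all(dam_rows$mean_interval == 4))
})

test_that("pedigree_ne inverts constructed inbreeding rates", {
  # geometric construction: F(t) = 1 - (1 - dF)^t per 5-year cohort
  years <- 1960:2019
  t_idx <- (years - 1960) %/% 5
  f_by_cohort <- 1 - (1 - 0.0025)^(t_idx + 1)
  ids <- sprintf("N%03d", seq_along(years) * 3)
  rec <- data.frame(id = unlist(lapply(seq_along(years), function(i)
    sprintf("N%d_%d", i, 1:10))), sire = "0", dam = "0", sex = "female",
    birth_year = rep(years, each = 10))
  ped <- pedigree(rec)
  fvals <- setNames(rep(f_by_cohort[match(ped$birth_year, years)]),
                    ped$animal_id)
  ne <- pedigree_ne(fvals, ped, window_years = 5, gi_years = 5, min_n = 10)
  expect_equal(ne$ne, rep(1 / (2 * 0.0025), nrow(ne)), tolerance = 1e-9)
  expect_equal(ne$delta_f_gen, rep(0.0025, nrow(ne)), tolerance = 1e-9)

  # exact dF = 0.005 -> Ne = 100
  f2 <- setNames(1 - (1 - 0.005)^(t_idx[match(ped$birth_year, years)] + 1),
                 ped$animal_id)
  ne2 <- pedigree_ne(f2, ped)
  expect_equal(ne2$ne, rep(100, nrow(ne2)), tolerance = 1e-9)

  # constant F -> infinite-Ne flag
  f3 <- setNames(rep(0.05, nrow(ped)), ped$animal_id)
  ne3 <- pedigree_ne(f3, ped)
  expect_true(all(ne3$flag == "infinite_ne"))
  expect_true(all(is.na(ne3$ne)))

  expect_error(pedigree_ne(f3[1:10], ped[1:10], min_n = 3), "at least 2 windows")
})

test_that("compute_fped is independent of input row order", {
  set.seed(99)
  ped <- random_pedigree(40)
  base <- data.frame(id = ped$animal_id,
                     sire = ifelse(is.na(ped$sire_id), "0", ped$sire_id),
                     dam = ifelse(is.na(ped$dam_id), "0", ped$dam_id))
  shuf <- base[sample.int(nrow(base)), ]
  f1 <- compute_fped(ped)
  f2 <- compute_fped(pedigree(shuf))
  expect_equal(f1, f2[names(f1)])
})
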