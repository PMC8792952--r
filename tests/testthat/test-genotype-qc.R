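test_that("genotype_panel validates map and dosages", {
  expect_error(make_panel(c(0, 1, 2), bp = c(100, 50, 200)), "increasing")
  expect_error(make_panel(c(0, 3, 2), bp = c(100, 200, 300)), "dosages")
  expect_error(genotype_panel(matrix(0, 1, 2),
                              data.frame(snp_id = c("a", "b"),
                                         chrom = c(1, 30), bp = c(1, 2))),
               "1-29")
  p <- make_panel(rbind(c(0, 1, 2), c(2, NA, 0)), bp = c(100, 200, 300))
  expect_equal(dim(p), c(2L, 3L))
})

test_that("read_plink recodes, handles missing, drops non-autosomes, errors on bad input", {
  d <- withr::local_tempdir()
  writeLines(c("1 s1 0 1000",
               "1 s2 0 2000",
               "30 sX 0 500"), file.path(d, "t.map"))
  writeLines(c("F1 I1 0 0 1 -9 A A G G T T",
               "F2 I2 0 0 2 -9 A C 0 0 T T"), file.path(d, "t.ped"))
  p <- read_plink(file.path(d, "t.ped"), file.path(d, "t.map"))
  expect_equal(ncol(p$geno), 2)            # chromosome-30 SNP dropped
  expect_equal(p$sample_ids, c("I1", "I2"))
  # s1: alleles A,C -> dosage of A: I1 = 2, I2 = 1
  expect_equal(unname(p$geno[, "s1"]), c(2, 1))
  # s2: "0 0" -> missing
  expect_true(is.na(p$geno["I2", "s2"]))
  expect_equal(unname(p$geno["I1", "s2"]), 2)

  writeLines(c("F1 I1 0 0 1 -9 A A G G",
               "F2 I2 0 0 2 -9 A C 0 0 T T"), file.path(d, "bad.ped"))
  expect_error(read_plink(file.path(d, "bad.ped"), file.path(d, "t.map")),
               "ragged|inconsistent")

  writeLines(c("1 s1 0 1000"), file.path(d, "tri.map"))
  writeLines(c("F1 I1 0 0 1 -9 A C",
               "F2 I2 0 0 2 -9 A G"), file.path(d, "tri.ped"))
  expect_error(read_plink(file.path(d, "tri.ped"), file.path(d, "tri.map")),
               ">2 alleles")
})

test_that("write_plink then read_plink is the identity on valid panels", {
  set.seed(11)
  g <- matrix(sample(c(0:2, NA), 60, replace = TRUE,
                     prob = c(0.3, 0.3, 0.3, 0.1)), 5, 12)
  # ensure every SNP is observed at least once so allele labels round-trip
  g[1, ] <- 1
  p <- genotype_panel(g, data.table::data.table(
    snp_id = sprintf("rt%02d", 1:12),
    chrom = rep(1:2, each = 6), bp = rep(seq(1e5, 6e5, 1e5), 2)))
  d <- withr::local_tempdir()
  write_plink(p, file.path(d, "rt.ped"), file.path(d, "rt.map"))
  p2 <- read_plink(file.path(d, "rt.ped"), file.path(d, "rt.map"))
  expect_equal(p2$geno, p$geno)
  expect_equal(p2$map$bp, p$map$bp)
  expect_equal(p2$map$chrom, p$map$chrom)
})

test_that("hwe_exact_test handles edge cases and matches the enumeration oracle", {
  expect_equal(hwe_exact_test(5, 0, 0), 1.0)        # monomorphic
  expect_equal(hwe_exact_test(0, 0, 7), 1.0)
  # (1,0,1): possible het counts {0,2} at 2+2 alleles
  expect_equal(hwe_exact_test(1, 0, 1), oracle_hwe(1, 0, 1))
  p_eq <- hwe_exact_test(20, 40, 20)                # equilibrium configuration
  expect_equal(p_eq, oracle_hwe(20, 40, 20))
  expect_gt(p_eq, 0.5)
  expect_error(hwe_exact_test(0, 0, 0), "at least one")
})

test_that("hwe_exact_test equals the oracle for all genotype configurations up to n = 30", {
  for (n in c(2, 5, 13, 30)) {
    for (nAA in seq(0, n, by = max(1, n %/% 5))) {
      for (nAa in seq(0, n - nAA, by = max(1, (n - nAA) %/% 4))) {
        naa <- n - nAA - nAa
        expect_equal(hwe_exact_test(nAA, nAa, naa), oracle_hwe(nAA, nAa, naa),
                     tolerance = 1e-10,
                     info = sprintf("counts %d/%d/%d", nAA, nAa, naa))
      }
    }
  }
})

test_that("mendel_mismatch_rates counts opposing homozygotes per parent pair", {
  ped <- pedigree(data.frame(id = c("S", "D", "K"), sire = c("0", "0", "S"),
                             dam = c("0", "0", "D")))
  # SNP1: offspring 2 vs sire 0 -> mismatch; SNP2: offspring 1 vs sire 0 ok
  g <- rbind(S = c(0, 0), D = c(NA, 1), K = c(2, 1))
  p <- make_panel(g, bp = c(1e5, 2e5), sample_ids = c("S", "D", "K"))
  r <- mendel_mismatch_rates(p, ped)
  expect_equal(unname(r), c(1.0, 0.0)) # SNP1: 1 mismatch / 1 informative pair (D missing)

  # both parents genotyped -> two pairs per offspring
  g2 <- rbind(S = c(0, 0), D = c(0, 1), K = c(2, 1))
  p2 <- make_panel(g2, bp = c(1e5, 2e5), sample_ids = c("S", "D", "K"))
  expect_equal(unname(mendel_mismatch_rates(p2, ped)), c(1.0, 0.0))

  ped_np <- pedigree(data.frame(id = c("A", "B"), sire = c("0", "0"),
                                dam = c("0", "0")))
  p3 <- make_panel(rbind(c(0, 1), c(1, 2)), bp = c(1e5, 2e5),
                   sample_ids = c("A", "B"))
  expect_warning(r3 <- mendel_mismatch_rates(p3, ped_np), "no genotyped")
  expect_true(all(is.na(r3)))
})

test_that("mendel_mismatch_rates equals a brute-force pair scan on random data", {
  set.seed(21)
  n_off <- 25; n_snp <- 30
  ids <- c(sprintf("P%02d", 1:10), sprintf("O%02d", 1:n_off))
  sire <- c(rep("0", 10), sample(sprintf("P%02d", 1:5), n_off, TRUE))
  dam <- c(rep("0", 10), sample(sprintf("P%02d", 6:10), n_off, TRUE))
  ped <- pedigree(data.frame(id = ids, sire = sire, dam = dam))
  g <- matrix(sample(c(0:2, NA), length(ids) * n_snp, TRUE,
                     prob = c(0.3, 0.3, 0.3, 0.1)), length(ids), n_snp)
  p <- make_panel(g, bp = seq(1e5, by = 1e5, length.out = n_snp),
                  sample_ids = ids)
  got <- mendel_mismatch_rates(p, ped)
  # brute force: loop over every offspring x parent x SNP
  mm <- den <- numeric(n_snp)
  for (o in which(!is.na(match(ids, ids)))) {
    prs <- c(ped$sire_id[match(ids[o], ped$animal_id)],
             ped$dam_id[match(ids[o], ped$animal_id)])
    for (pr in prs[!is.na(prs)]) {
      pi <- match(pr, ids)
      for (j in seq_len(n_snp)) {
        if (is.na(g[o, j]) || is.na(g[pi, j])) next
        den[j] <- den[j] + 1
        if (abs(g[o, j] - g[pi, j]) == 2) mm[j] <- mm[j] + 1
      }
    }
  }
  expect_equal(unname(got), ifelse(den > 0, mm / den, NA_real_))
})

test_that("qc_filter applies criteria in fixed order with one primary reason", {
  set.seed(5)
  n <- 200
  mk_snp <- function(maf) sample(0:2, n, TRUE, prob = c((1 - maf)^2,
                                                        2 * maf * (1 - maf),
                                                        maf^2))
  g <- sapply(c(rep(0.25, 8), 0.005, 0.005), mk_snp)
  p <- make_panel(g, bp = seq(1e5, by = 1e5, length.out = 10))
  res <- qc_filter(p)
  expect_equal(ncol(res$panel$geno), 8)
  expect_equal(sum(res$report$verdict == "dropped:maf"), 2)

  # call rate outranks MAF in the verdict
  g2 <- g
  g2[1:20, 1] <- NA                 # 90% call rate
  g2[, 1][!is.na(g2[, 1])] <- 0     # and extreme MAF
  g2[sample(which(!is.na(g2[, 1])), 1), 1] <- 1
  p2 <- make_panel(g2, bp = seq(1e5, by = 1e5, length.out = 10))
  res2 <- qc_filter(p2)
  expect_equal(res2$report$verdict[1], "dropped:call_rate")

  expect_error(qc_filter(p, thresholds = list(maf = 0.6)), "no SNPs survive")
})

test_that("qc_filter is idempotent and monotone in thresholds", {
  set.seed(31)
  n <- 150; m <- 50
  g <- matrix(sample(c(0:2, NA), n * m, TRUE, prob = c(0.35, 0.2, 0.35, 0.1)),
              n, m)
  # a few clean common SNPs so the filter never empties the panel
  for (j in 1:5) g[, j] <- sample(0:2, n, TRUE, prob = c(0.25, 0.5, 0.25))
  p <- make_panel(g, bp = seq(1e5, by = 1e5, length.out = m))
  r1 <- qc_filter(p)
  r2 <- qc_filter(r1$panel)
  expect_equal(ncol(r2$panel$geno), ncol(r1$panel$geno))
  expect_true(all(r2$report$verdict == "kept"))

  relaxed <- qc_filter(p, thresholds = list(maf = 0.001))
  expect_gte(ncol(relaxed$panel$geno), ncol(r1$panel$geno))
  relaxed2 <- qc_filter(p, thresholds = list(hwe_p = 0.0005))
  expect_gte(ncol(relaxed2$panel$geno), ncol(r1$panel$geno))
})

test_that("qc_filter kept set equals an independent full re-scan", {
  set.seed(41)
  n <- 120; m <- 50
  g <- matrix(sample(c(0:2, NA), n * m, TRUE, prob = c(0.3, 0.25, 0.3, 0.15)),
              n, m)
  for (j in 1:4) g[, j] <- sample(0:2, n, TRUE, prob = c(0.25, 0.5, 0.25))
  p <- make_panel(g, bp = seq(1e5, by = 1e5, length.out = m))
  th <- qc_thresholds()
  kept_direct <- vapply(seq_len(m), function(j) {
    x <- g[, j]
    cr <- mean(!is.na(x))
    if (cr < th$call_rate) return(FALSE)
    x <- x[!is.na(x)]
    pfrq <- mean(x) / 2
    if (min(pfrq, 1 - pfrq) < th$maf) return(FALSE)
    tab <- table(factor(x, levels = 0:2))
    tab <- tab[tab > 0]
    if (min(tab) / length(x) < th$min_genotype_freq) return(FALSE)
    oracle_hwe(sum(x == 2), sum(x == 1), sum(x == 0)) >= th$hwe_p
  }, logical(1))
  res <- qc_filter(p)
  expect_equal(res$report$verdict == "kept", kept_direct)
})

test_that("dosage orientation does not change MAF, homozygosity or r2", {
  set.seed(51)
  g <- matrix(sample(0:2, 200, TRUE), 20, 10)
  p1 <- make_panel(g, bp = seq(1e6, by = 1e6, length.out = 10))
  p2 <- make_panel(2 - g, bp = seq(1e6, by = 1e6, length.out = 10))
  s1 <- snp_qc_stats(p1); s2 <- snp_qc_stats(p2)
  expect_equal(s1$maf, s2$maf)
  expect_equal(s1$hwe_p, s2$hwe_p)
  r1 <- pairwise_r2(p1, max_distance_bp = 1e7, min_maf = 0)
  r2 <- pairwise_r2(p2, max_distance_bp = 1e7, min_maf = 0)
  expect_equal(r1$r2, r2$r2)
})
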