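# SNP quality control: call rate, parent-offspring (Mendelian) mismatch,
# minor-allele and genotype-class frequencies, and an exact Hardy-Weinberg
# test. Filtering removes SNPs only; sample inclusion is assumed handled
# upstream (e.g. by the genotyping/imputation pipeline).

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test for a biallelic SNP, conditioning on the observed
#' allele counts: the p-value is the sum of probabilities of all heterozygote
#' counts whose conditional probability does not exceed that of the observed
#' count (probability-ordering convention). Computed with log-factorials,
#' so it is stable for large samples. A monomorphic SNP returns p = 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total >= 1).
#' @param midp if `TRUE`, use the mid-p variant (half weight on the observed
#'   configuration).
#' @return p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa, midp = FALSE) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop_hd("hwe_exact_test needs at least one genotype")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1.0)
  rare <- min(nA, na)
  # heterozygote counts share the parity of the rare-allele count
  hets <- seq(rare %% 2, rare, by = 2)
  # P(n_Aa = h | nA, na) via log factorials
  logp <- lgamma(n + 1) - lgamma((nA - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((na - hets) / 2 + 1) + hets * log(2) +
    lgamma(nA + 1) + lgamma(na + 1) - lgamma(2 * n + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- which(hets == n_Aa)
  if (!length(obs)) stop_hd("observed heterozygote count inconsistent with allele counts")
  tol <- 1e-12                         # ties at the observed probability count as "as extreme"
  pv <- sum(p[p <= p[obs] * (1 + tol)])
  if (midp) pv <- pv - 0.5 * p[obs]
  min(1, pv)
}

#' Per-SNP Mendelian mismatch rates from parent-offspring pairs
#'
#' For every genotyped parent-offspring pair resolvable through the
#' pedigree, a mismatch at a SNP is an opposing-homozygote configuration
#' (parent 0, offspring 2 or vice versa). The rate is mismatches divided by
#' pairs with both calls non-missing; an animal with two genotyped parents
#' contributes two pairs. SNPs with no informative pair get `NA`.
#'
#' @param panel a [genotype_panel].
#' @param ped a [pedigree] linking samples to their parents.
#' @return Named numeric vector (by `snp_id`), one rate (or `NA`) per SNP.
#' @export
mendel_mismatch_rates <- function(panel, ped) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(ped, "pedigree"))
  g <- panel$geno
  idx <- match(panel$sample_ids, ped$animal_id)
  pairs <- list()
  for (role in c("sire_id", "dam_id")) {
    par_of <- ped[[role]][idx]                    # parent id per sample, NA ok
    pi <- match(par_of, panel$sample_ids)          # genotyped parent row
    ok <- which(!is.na(pi))
    if (length(ok)) pairs[[role]] <- cbind(off = ok, par = pi[ok])
  }
  m <- ncol(g)
  if (!length(pairs)) {
    warning("no genotyped parent-offspring pairs; Mendel rates all NA",
            call. = FALSE)
    return(rep(NA_real_, m))
  }
  pr <- do.call(rbind, pairs)
  go <- g[pr[, "off"], , drop = FALSE]
  gp <- g[pr[, "par"], , drop = FALSE]
  informative <- !is.na(go) & !is.na(gp)
  opposing <- informative & ((go == 0 & gp == 2) | (go == 2 & gp == 0))
  denom <- colSums(informative)
  rate <- ifelse(denom > 0, colSums(opposing) / denom, NA_real_)
  setNames(unname(rate), panel$map$snp_id)
}

#' Per-SNP quality-control statistics
#'
#' @param panel a [genotype_panel].
#' @param ped optional [pedigree] for the Mendelian mismatch criterion
#'   (`NA` when absent).
#' @param midp_hwe use the mid-p HWE variant.
#' @return data.table with one row per SNP: `snp_id`, `call_rate`, `maf`,
#'   `min_genotype_freq`, `mendel_mismatch_rate`, `hwe_p`.
#' @export
snp_qc_stats <- function(panel, ped = NULL, midp_hwe = FALSE) {
  g <- panel$geno
  n <- nrow(g)
  nAA <- colSums(g == 2, na.rm = TRUE)
  nAa <- colSums(g == 1, na.rm = TRUE)
  naa <- colSums(g == 0, na.rm = TRUE)
  ncall <- nAA + nAa + naa
  call_rate <- ncall / n
  p1 <- ifelse(ncall > 0, (2 * nAA + nAa) / (2 * ncall), NA_real_)
  maf <- pmin(p1, 1 - p1)
  min_gf <- rep(NA_real_, ncol(g))
  has <- ncall > 0
  # least frequent *observed* genotype class among non-missing calls
  cnt <- rbind(nAA, nAa, naa)
  for (j in which(has)) {
    cc <- cnt[, j]
    min_gf[j] <- min(cc[cc > 0]) / ncall[j]
  }
  hwe_p <- rep(NA_real_, ncol(g))
  for (j in which(has))
    hwe_p[j] <- hwe_exact_test(nAA[j], nAa[j], naa[j], midp = midp_hwe)
  mendel <- if (!is.null(ped)) mendel_mismatch_rates(panel, ped)
            else rep(NA_real_, ncol(g))
  data.table::data.table(snp_id = panel$map$snp_id, call_rate = call_rate,
                         maf = maf, min_genotype_freq = min_gf,
                         mendel_mismatch_rate = mendel, hwe_p = hwe_p)
}

#' Default SNP quality-control thresholds
#'
#' Exclusion bounds for the five criteria, in their fixed evaluation order:
#' drop when call rate < 0.95, Mendelian mismatch rate > 0.01, MAF < 0.01,
#' minimum genotype-class frequency < 0.001, or exact HWE p < 0.005.
#'
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function() {
  list(call_rate = 0.95, mendel_mismatch = 0.01, maf = 0.01,
       min_genotype_freq = 0.001, hwe_p = 0.005)
}

#' Filter SNPs by the five quality-control criteria
#'
#' Criteria are evaluated in the fixed order call rate, Mendelian mismatch,
#' MAF, genotype-class frequency, HWE; each dropped SNP records the first
#' failing criterion as its primary reason. Samples are never removed.
#' A SNP with `NA` for a statistic (e.g. no informative Mendel pairs)
#' passes that criterion silently.
#'
#' @param panel a [genotype_panel].
#' @param ped optional [pedigree]; without it the Mendel criterion is
#'   skipped.
#' @param thresholds named list as from [qc_thresholds()] (partial lists are
#'   merged over the defaults).
#' @param midp_hwe use the mid-p HWE variant.
#' @return List with `panel` (filtered [genotype_panel]) and `report`
#'   (data.table: per-SNP statistics plus `verdict`, `"kept"` or
#'   `"dropped:<reason>"`).
#' @export
qc_filter <- function(panel, ped = NULL, thresholds = qc_thresholds(),
                      midp_hwe = FALSE) {
  th <- utils::modifyList(qc_thresholds(), as.list(thresholds))
  st <- snp_qc_stats(panel, ped, midp_hwe = midp_hwe)
  fail <- function(x, bad) !is.na(x) & bad
  reasons <- rep("", nrow(st))
  mark <- function(reasons, failing, label)
    ifelse(reasons == "" & failing, label, reasons)
  reasons <- mark(reasons, fail(st$call_rate, st$call_rate < th$call_rate), "call_rate")
  reasons <- mark(reasons, fail(st$mendel_mismatch_rate,
                                st$mendel_mismatch_rate > th$mendel_mismatch), "mendel")
  reasons <- mark(reasons, fail(st$maf, st$maf < th$maf), "maf")
  reasons <- mark(reasons, fail(st$min_genotype_freq,
                                st$min_genotype_freq < th$min_genotype_freq),
                  "genotype_freq")
  reasons <- mark(reasons, fail(st$hwe_p, st$hwe_p < th$hwe_p), "hwe")
  report <- data.table::copy(st)
  report[, verdict := ifelse(reasons == "", "kept", paste0("dropped:", reasons))]
  keep <- reasons == ""
  if (!any(keep)) stop_hd("no SNPs survive quality control")
  hd_log(sum(!keep), " SNP(s) removed by QC")
  list(panel = subset_panel(panel, snps = keep), report = report[])
}
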