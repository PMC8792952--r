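# Genotype container (sample x SNP dosage matrix plus sorted genomic map)
# and PLINK-style text PED/MAP input/output.

AUTOSOMES <- 1:29  # bovine autosome set

#' Construct a genotype panel
#'
#' The central genotype container: a sample x SNP matrix of allele dosages
#' (0/1/2 copies of the counted allele, `NA` = missing call) together with
#' a genomic map ordered by chromosome and physical position, and the two
#' allele labels per SNP (`a1` is the counted allele).
#'
#' @param geno integer/numeric matrix, samples in rows, SNPs in columns;
#'   values 0, 1, 2 or `NA`.
#' @param map data.frame with `snp_id`, `chrom` (1-29), `bp` (1-based);
#'   positions must be strictly increasing within a chromosome.
#' @param sample_ids character vector, one per row of `geno`.
#' @param alleles optional data.frame with `a1`, `a2` per SNP (defaults
#'   `"A"`/`"B"`).
#' @return An object of class `genotype_panel` (a list with `geno`, `map`,
#'   `sample_ids`, `alleles`).
#' @export
genotype_panel <- function(geno, map, sample_ids = rownames(geno),
                           alleles = NULL) {
  geno <- as.matrix(geno)
  map <- data.table::as.data.table(map)
  if (!all(c("snp_id", "chrom", "bp") %in% names(map)))
    stop_hd("map needs columns snp_id, chrom, bp")
  map[, chrom := as.integer(chrom)]
  map[, bp := as.double(bp)]
  if (is.null(sample_ids)) sample_ids <- sprintf("S%d", seq_len(nrow(geno)))
  if (nrow(map) != ncol(geno))
    stop_hd("map rows (", nrow(map), ") != genotype columns (", ncol(geno), ")")
  if (length(sample_ids) != nrow(geno))
    stop_hd("sample_ids length != genotype rows")
  if (!all(map$chrom %in% AUTOSOMES))
    stop_hd("map chromosomes outside 1-29; drop non-autosomal SNPs first")
  bad <- map[, .(ok = all(diff(bp) > 0)), by = chrom][ok == FALSE]
  if (nrow(bad))
    stop_hd("map positions not strictly increasing on chromosome ",
            bad$chrom[1])
  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% 0:2))
    stop_hd("genotype dosages must be 0, 1, 2 or NA")
  if (is.null(alleles))
    alleles <- data.table::data.table(a1 = rep("A", nrow(map)),
                                      a2 = rep("B", nrow(map)))
  alleles <- data.table::as.data.table(alleles)
  dimnames(geno) <- list(sample_ids, map$snp_id)
  structure(list(geno = geno, map = map, sample_ids = as.character(sample_ids),
                 alleles = alleles),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d samples x %d SNPs on %d chromosome(s); %.2f%% missing\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chrom)),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$geno)

#' Subset a genotype panel by SNPs and/or samples
#'
#' @param panel a [genotype_panel].
#' @param snps logical/integer index over SNPs (columns).
#' @param samples logical/integer index over samples (rows).
#' @return A new [genotype_panel].
#' @export
subset_panel <- function(panel, snps = NULL, samples = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  snps <- snps %||% seq_len(ncol(panel$geno))
  samples <- samples %||% seq_len(nrow(panel$geno))
  genotype_panel(panel$geno[samples, snps, drop = FALSE],
                 panel$map[snps], panel$sample_ids[samples],
                 panel$alleles[snps])
}

#' Read PLINK text PED/MAP files into a genotype panel
#'
#' Alleles at each SNP are recoded to the dosage of the lexicographically
#' smaller observed allele, which fixes orientation so downstream statistics
#' (MAF, homozygosity, r2) are orientation-invariant. `0 0` allele pairs
#' become missing. Rows of the map outside chromosomes 1-29 are dropped
#' (count reported via message). A SNP with three or more observed alleles
#' is a hard error.
#'
#' @param ped_path text PED file (FID IID PAT MAT SEX PHENO + 2 allele
#'   columns per SNP).
#' @param map_path text MAP file (chrom, snp_id, cM, bp).
#' @return A [genotype_panel].
#' @export
read_plink <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop_hd("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop_hd("MAP file not found: ", map_path)
  map <- data.table::fread(map_path, header = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "bp"),
                           colClasses = list(character = 1:2, numeric = 3:4))
  map[, chrom_i := suppressWarnings(as.integer(chrom))]
  keep <- !is.na(map$chrom_i) & map$chrom_i %in% AUTOSOMES
  n_drop <- sum(!keep)
  if (n_drop) hd_log(n_drop, " non-autosomal SNP(s) dropped")

  ped <- data.table::fread(ped_path, header = FALSE, colClasses = "character",
                           fill = TRUE)
  n_snps_file <- nrow(map)
  if (ncol(ped) != 6 + 2 * n_snps_file || anyNA(ped) || any(ped == ""))
    stop_hd("ragged or inconsistent PED: expected ", 6 + 2 * n_snps_file,
            " columns for ", n_snps_file, " SNPs")
  sample_ids <- ped[[2]]
  n <- nrow(ped)

  keep_idx <- which(keep)
  geno <- matrix(NA_real_, n, length(keep_idx))
  a1 <- a2 <- character(length(keep_idx))
  for (k in seq_along(keep_idx)) {
    j <- keep_idx[k]
    al1 <- ped[[6 + 2 * j - 1]]
    al2 <- ped[[6 + 2 * j]]
    miss <- al1 == "0" | al2 == "0"
    obs <- sort(unique(c(al1[!miss], al2[!miss])))
    if (length(obs) > 2)
      stop_hd("SNP ", map$snp_id[j], " has >2 alleles: ",
              paste(obs, collapse = ","))
    if (length(obs) == 0) obs <- c("A", "B")
    if (length(obs) == 1) obs <- c(obs, if (obs == "A") "B" else "A") # monomorphic
    counted <- obs[1]
    geno[, k] <- (al1 == counted) + (al2 == counted)
    geno[miss, k] <- NA_real_
    a1[k] <- obs[1]; a2[k] <- obs[2]
  }
  mp <- map[keep_idx, .(snp_id, chrom = chrom_i, bp)]
  ord <- order(mp$chrom, mp$bp)
  genotype_panel(geno[, ord, drop = FALSE], mp[ord], sample_ids,
                 data.table::data.table(a1 = a1[ord], a2 = a2[ord]))
}

#' Write a genotype panel as PLINK text PED/MAP
#'
#' Inverse of [read_plink()]: dosages are expanded back to allele pairs
#' using the panel's stored allele labels, missing calls become `0 0`.
#'
#' @param panel a [genotype_panel].
#' @param ped_path,map_path output file paths.
#' @param pedigree optional [pedigree] supplying PAT/MAT/SEX columns.
#' @return Invisibly, the two paths.
#' @export
write_plink <- function(panel, ped_path, map_path, pedigree = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  m <- ncol(panel$geno); n <- nrow(panel$geno)
  map_out <- panel$map[, .(chrom, snp_id, cm = 0, bp = format(bp, scientific = FALSE, trim = TRUE))]
  utils::write.table(map_out, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  pat <- mat <- rep("0", n); sex <- rep("0", n)
  if (!is.null(pedigree)) {
    i <- match(panel$sample_ids, pedigree$animal_id)
    pat <- ifelse(is.na(i) | is.na(pedigree$sire_id[i]), "0", pedigree$sire_id[i])
    mat <- ifelse(is.na(i) | is.na(pedigree$dam_id[i]), "0", pedigree$dam_id[i])
    sex <- ifelse(is.na(i), "0",
                  c(male = "1", female = "2", unknown = "0")[pedigree$sex[i]])
  }
  allele_cols <- matrix("0", n, 2 * m)
  for (j in seq_len(m)) {
    g <- panel$geno[, j]
    a1 <- panel$alleles$a1[j]; a2 <- panel$alleles$a2[j]
    first <- ifelse(is.na(g), "0", ifelse(g >= 1, a1, a2))
    second <- ifelse(is.na(g), "0", ifelse(g == 2, a1, a2))
    allele_cols[, 2 * j - 1] <- first
    allele_cols[, 2 * j] <- second
  }
  out <- cbind(panel$sample_ids, panel$sample_ids, pat, mat, sex, "-9",
               allele_cols)
  utils::write.table(out, ped_path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(ped = ped_path, map = map_path))
}
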