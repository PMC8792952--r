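# LD-based historical effective population size: pairwise r2 between
# intra-chromosomal SNPs, assignment of pairs to "generations ago" bins via
# the c = 1/(2t) correspondence, sample-size correction, and inversion of
# the drift-LD expectation E[r2] = 1/(alpha + 4 Ne c).

#' Pairwise linkage disequilibrium (r-squared) within chromosomes
#'
#' r2 between two SNPs is the squared Pearson correlation of their dosage
#' vectors over samples with both calls non-missing (unphased genotype
#' convention), so it is invariant to allele orientation and sample order.
#' Only intra-chromosomal pairs up to `max_distance_bp` apart are computed;
#' pairs where either SNP has MAF below `min_maf` (among the samples used)
#' or fewer than 2 informative samples, and monomorphic pairs, are skipped
#' and tallied.
#'
#' @param panel a [genotype_panel].
#' @param max_distance_bp maximum inter-SNP distance.
#' @param min_maf minimum minor allele frequency per SNP (default 0.05).
#' @return data.table of pairs: `chrom`, `snp_a`, `snp_b`, `distance_bp`,
#'   `r2`; attribute `"skipped"` tallies skipped pairs.
#' @export
pairwise_r2 <- function(panel, max_distance_bp, min_maf = 0.05) {
  stopifnot(inherits(panel, "genotype_panel"), max_distance_bp > 0)
  out <- list()
  n_skip <- c(low_maf = 0L, monomorphic = 0L, too_few = 0L)
  for (ch in unique(panel$map$chrom)) {
    jj <- which(panel$map$chrom == ch)
    if (length(jj) < 2) next
    g <- panel$geno[, jj, drop = FALSE]
    bp <- panel$map$bp[jj]
    ids <- panel$map$snp_id[jj]
    p <- colMeans(g, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
    use <- !is.na(maf) & maf > 0
    n_skip["monomorphic"] <- n_skip["monomorphic"] + sum(!use)
    ok_maf <- use & maf >= min_maf
    n_skip["low_maf"] <- n_skip["low_maf"] + sum(use & !ok_maf)
    keep <- which(ok_maf)
    if (length(keep) < 2) next
    g <- g[, keep, drop = FALSE]; bp <- bp[keep]; ids <- ids[keep]
    # pair index set within distance
    m <- length(keep)
    hi <- findInterval(bp + max_distance_bp, bp)
    a <- rep.int(seq_len(m), pmax(hi - seq_len(m), 0L))
    b <- unlist(lapply(seq_len(m), function(i)
      if (hi[i] > i) (i + 1L):hi[i] else integer(0)), use.names = FALSE)
    if (!length(a)) next
    if (anyNA(g)) {
      r2 <- vapply(seq_along(a), function(k) {
        x <- g[, a[k]]; y <- g[, b[k]]
        cc <- !is.na(x) & !is.na(y)
        if (sum(cc) < 2) return(NA_real_)
        sx <- sd(x[cc]); sy <- sd(y[cc])
        if (sx == 0 || sy == 0) return(NA_real_)
        cor(x[cc], y[cc])^2
      }, double(1))
    } else {
      cm <- suppressWarnings(cor(g))
      r2 <- cm[cbind(a, b)]^2
    }
    bad <- is.na(r2)
    n_skip["too_few"] <- n_skip["too_few"] + sum(bad)
    if (all(bad)) next
    out[[length(out) + 1L]] <- data.table::data.table(
      chrom = ch, snp_a = ids[a[!bad]], snp_b = ids[b[!bad]],
      distance_bp = bp[b[!bad]] - bp[a[!bad]], r2 = r2[!bad])
  }
  if (!length(out))
    stop_hd("no usable SNP pairs within ", max_distance_bp, " bp")
  res <- data.table::rbindlist(out)
  data.table::setattr(res, "skipped", n_skip)
  res[]
}

#' Map distance to recombination fraction
#'
#' @param d map distance in Morgans.
#' @param mapping `"linear"` (c = d, capped at 0.5), `"haldane"`
#'   (c = (1 - exp(-2d))/2), or `"sved_feldman"` (hyperbolic form
#'   c = d / (1 + 2d), the mapping consistent with linear growth of 1/E[r2]
#'   with distance in the drift-LD model).
#' @return Recombination fraction in (0, 0.5].
#' @export
recombination_fraction <- function(d, mapping = c("linear", "haldane",
                                                  "sved_feldman")) {
  mapping <- match.arg(mapping)
  switch(mapping,
         linear = pmin(d, 0.5),
         haldane = (1 - exp(-2 * d)) / 2,
         sved_feldman = d / (1 + 2 * d))
}

#' Bin SNP pairs into generations-ago classes
#'
#' Each target generation t corresponds to recombination fraction
#' c_t = 1/(2t). Pair distances are converted from bp to Morgans at a flat
#' `cm_per_mb` rate, then to recombination fractions via `mapping`, and
#' each pair is assigned to the t whose c-interval (midpoints between
#' consecutive c_t) brackets it. Bins with fewer than `min_pairs` pairs are
#' omitted (logged via the `"dropped_bins"` attribute).
#'
#' @param pairs data.table from [pairwise_r2()].
#' @param generations increasing positive integer vector of target t
#'   (default 1:30).
#' @param mapping distance-to-recombination mapping; see
#'   [recombination_fraction()].
#' @param cm_per_mb map scale (default 1 cM/Mb).
#' @param min_pairs minimum pairs per emitted bin (default 10).
#' @return data.table with `t`, `c`, `mean_distance_bp`, `mean_r2`,
#'   `n_pairs`, ordered by `t`.
#' @export
bin_pairs_by_generation <- function(pairs, generations = 1:30,
                                    mapping = "linear", cm_per_mb = 1,
                                    min_pairs = 10) {
  stopifnot(all(generations > 0), !is.unsorted(generations, strictly = TRUE))
  d_morgan <- pairs$distance_bp * cm_per_mb * 1e-8  # bp * cM/Mb -> Morgans
  cc <- recombination_fraction(d_morgan, mapping)
  ct <- 1 / (2 * generations)                        # decreasing in t
  # interval edges: midpoints between consecutive c_t, outermost unbounded
  edges <- c(Inf, (ct[-1] + ct[-length(ct)]) / 2, 0)
  idx <- findInterval(-cc, -edges, left.open = TRUE)  # negate: edges ascending
  idx[idx < 1 | idx > length(generations)] <- NA_integer_
  dt <- data.table::data.table(t = generations[idx], c = cc,
                               dist = pairs$distance_bp, r2 = pairs$r2)
  dt <- dt[!is.na(t)]
  out <- dt[, .(c = 1 / (2 * t[1]), mean_distance_bp = mean(dist),
                mean_r2 = mean(r2), n_pairs = .N), by = t]
  dropped <- out[n_pairs < min_pairs, t]
  if (length(dropped)) hd_log("bins dropped (too few pairs): ",
                              paste(dropped, collapse = ","))
  out <- out[n_pairs >= min_pairs]
  data.table::setorder(out, t)
  data.table::setattr(out, "dropped_bins", dropped)
  out[]
}

#' Effective population size from binned LD
#'
#' Inverts the drift expectation for unphased r2,
#' E[r2] = 1/(alpha + 4 Ne c) plus a sample-size term, giving
#' Ne(t) = (1/(4 c_t)) * (1/r2_adj - alpha) with r2_adj the bin mean r2
#' minus the chosen sample-size correction. `alpha` = 1 for pure drift
#' without mutation; `alpha` = 2.2 accounts for mutation in cattle
#' applications. Non-positive adjusted r2 or Ne yields a flagged row
#' rather than a silent drop.
#'
#' @param binned data.table from [bin_pairs_by_generation()].
#' @param alpha mutation modifier (default 2.2).
#' @param n_samples number of genotyped individuals (for the correction).
#' @param correction `"1/n"` (default, unphased data), `"1/(2n)"`, or
#'   `"none"`.
#' @return data.table (`NeSeries`): `t`, `c`, `mean_distance_bp`,
#'   `mean_r2_adj`, `n_pairs`, `ne`, `flag`, ordered by `t`.
#' @export
estimate_ne <- function(binned, alpha = 2.2, n_samples,
                        correction = c("1/n", "1/(2n)", "none")) {
  correction <- match.arg(correction)
  if (!nrow(binned)) stop_hd("no LD bins to estimate Ne from")
  stopifnot(n_samples >= 2)
  corr <- switch(correction, "1/n" = 1 / n_samples,
                 "1/(2n)" = 1 / (2 * n_samples), none = 0)
  r2a <- binned$mean_r2 - corr
  ne <- ifelse(r2a > 0, (1 / (4 * binned$c)) * (1 / r2a - alpha), NA_real_)
  flag <- ifelse(r2a <= 0, "nonpositive_r2",
                 ifelse(ne <= 0, "nonpositive_ne", ""))
  ne[!is.na(ne) & ne <= 0] <- NA_real_
  out <- data.table::data.table(t = binned$t, c = binned$c,
                                mean_distance_bp = binned$mean_distance_bp,
                                mean_r2_adj = r2a, n_pairs = binned$n_pairs,
                                ne = ne, flag = flag)
  data.table::setorder(out, t)
  out[]
}
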