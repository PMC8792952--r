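# Runs of homozygosity: consecutive-runs detection under five criteria,
# the genomic inbreeding coefficient F_ROH, its decomposition into
# segment-length classes, and pedigree-vs-genomic inbreeding summaries.

#' Default ROH detection parameters
#'
#' The five criteria: at least 15 SNPs per run, minimum run length 1 Mb,
#' maximum gap between consecutive SNPs 500 kb, minimum density one SNP per
#' 100 kb, and at most one heterozygous and one missing call per run.
#'
#' @return Named list of parameters.
#' @export
roh_params <- function() {
  list(min_snps = 15L, min_length_bp = 1e6, max_gap_bp = 5e5,
       min_density = 1e-5, max_het = 1L, max_missing = 1L)
}

# greedy leftmost-longest scan of one dosage vector on one chromosome;
# returns candidate runs (start/end SNP indices) before size/length/density
# filters. A run must start and end on a homozygous, non-missing call and
# may contain at most max_het heterozygous and max_missing missing calls;
# it may not span an inter-SNP gap larger than max_gap_bp.
roh_candidate_runs <- function(g, bp, max_gap_bp, max_het, max_missing) {
  n <- length(g)
  is_hom <- !is.na(g) & (g == 0 | g == 2)
  if (!any(is_hom)) return(NULL)
  cumhet <- cumsum(!is.na(g) & g == 1)
  cummiss <- cumsum(is.na(g))
  biggap <- if (n > 1) which(diff(bp) > max_gap_bp) else integer(0)
  hom_idx <- which(is_hom)
  # prevhomo[i]: last homozygous index <= i (0 if none)
  prevhomo <- cummax(ifelse(is_hom, seq_len(n), 0L))
  starts <- ends <- integer(0)
  pos <- 1L
  repeat {
    k <- findInterval(pos - 1L, hom_idx) + 1L     # first homozygous >= pos
    if (k > length(hom_idx)) break
    s <- hom_idx[k]
    h0 <- if (s > 1) cumhet[s - 1L] else 0L
    m0 <- if (s > 1) cummiss[s - 1L] else 0L
    e_het <- findInterval(h0 + max_het, cumhet)    # last e with het count ok
    e_miss <- findInterval(m0 + max_missing, cummiss)
    gi <- findInterval(s - 1L, biggap) + 1L        # first big gap at/after s
    e_gap <- if (gi <= length(biggap)) biggap[gi] else n
    e <- prevhomo[min(e_het, e_miss, e_gap)]       # trim to homozygous end
    starts <- c(starts, s); ends <- c(ends, e)
    pos <- e + 1L
  }
  cbind(start = starts, end = ends)
}

#' Detect runs of homozygosity
#'
#' Consecutive-runs scan, per sample and chromosome: maximal runs of
#' consecutive SNPs containing at most `max_het` heterozygous and
#' `max_missing` missing calls, beginning and ending on a homozygous call,
#' split wherever the gap between consecutive SNPs exceeds `max_gap_bp`;
#' candidate runs are selected left to right (each run is the longest
#' admissible run starting at the leftmost available homozygous SNP, and
#' runs of one sample/chromosome are disjoint) and then filtered by
#' `min_snps`, `min_length_bp` and `min_density`. Deterministic and
#' independent of sample order.
#'
#' @param panel a [genotype_panel] with a position-sorted map.
#' @param params list as from [roh_params()]; partial lists are merged over
#'   the defaults.
#' @return data.table of segments: `sample_id`, `chrom`, `start_bp`,
#'   `end_bp` (positions of the first/last SNP in the run, closed
#'   interval), `n_snps`, `n_het`, `n_missing`,
#'   `length_bp = end_bp - start_bp`; ordered by sample, chromosome, start.
#' @export
detect_roh <- function(panel, params = roh_params()) {
  stopifnot(inherits(panel, "genotype_panel"))
  p <- utils::modifyList(roh_params(), as.list(params))
  stopifnot(p$min_snps > 0, p$min_length_bp > 0, p$max_gap_bp > 0,
            p$min_density > 0)
  map <- panel$map
  out <- vector("list", 0L)
  for (ch in unique(map$chrom)) {
    jj <- which(map$chrom == ch)
    bp <- map$bp[jj]
    if (is.unsorted(bp, strictly = TRUE)) stop_hd("unsorted map on chromosome ", ch)
    sub <- panel$geno[, jj, drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      runs <- roh_candidate_runs(sub[i, ], bp, p$max_gap_bp, p$max_het,
                                 p$max_missing)
      if (is.null(runs) || nrow(runs) == 0) next
      s <- runs[, "start"]; e <- runs[, "end"]
      n_snps <- e - s + 1L
      len <- bp[e] - bp[s]
      keep <- n_snps >= p$min_snps & len >= p$min_length_bp &
        n_snps / len >= p$min_density
      if (!any(keep)) next
      s <- s[keep]; e <- e[keep]
      g <- sub[i, ]
      n_het <- vapply(seq_along(s), function(k)
        sum(!is.na(g[s[k]:e[k]]) & g[s[k]:e[k]] == 1), integer(1))
      n_miss <- vapply(seq_along(s), function(k)
        sum(is.na(g[s[k]:e[k]])), integer(1))
      out[[length(out) + 1L]] <- data.table::data.table(
        sample_id = panel$sample_ids[i], chrom = ch,
        start_bp = bp[s], end_bp = bp[e], n_snps = e - s + 1L,
        n_het = n_het, n_missing = n_miss, length_bp = bp[e] - bp[s])
    }
  }
  if (!length(out))
    return(data.table::data.table(sample_id = character(0), chrom = integer(0),
                                  start_bp = double(0), end_bp = double(0),
                                  n_snps = integer(0), n_het = integer(0),
                                  n_missing = integer(0), length_bp = double(0)))
  seg <- data.table::rbindlist(out)
  data.table::setorder(seg, sample_id, chrom, start_bp)
  seg[]
}

#' SNP-covered autosome length of a panel
#'
#' Sum over chromosomes of (last SNP position - first SNP position); the
#' default denominator of [compute_froh()].
#'
#' @param panel a [genotype_panel].
#' @return Length in base pairs.
#' @export
autosome_length <- function(panel) {
  sum(panel$map[, .(span = max(bp) - min(bp)), by = chrom]$span)
}

#' Genomic inbreeding coefficient from ROH
#'
#' F_ROH per sample: the summed length of its ROH segments divided by the
#' SNP-covered autosome length L_AUTO. Samples without segments get 0.
#'
#' @param segments segment table from [detect_roh()].
#' @param panel the [genotype_panel] the segments came from (supplies
#'   `sample_ids` and the default `L_AUTO`; also used to check that
#'   segments lie within map bounds). Alternatively pass `sample_ids` and
#'   `L_AUTO` explicitly with `panel = NULL`.
#' @param L_AUTO autosome length denominator in bp; default
#'   [autosome_length()] of the panel.
#' @param sample_ids samples to report (default: the panel's).
#' @return Named numeric vector of F_ROH in `[0, 1]`.
#' @export
compute_froh <- function(segments, panel = NULL, L_AUTO = NULL,
                         sample_ids = NULL) {
  if (is.null(L_AUTO)) {
    if (is.null(panel)) stop_hd("need either panel or L_AUTO")
    L_AUTO <- autosome_length(panel)
  }
  stopifnot(L_AUTO > 0)
  if (is.null(sample_ids)) {
    if (is.null(panel)) stop_hd("need either panel or sample_ids")
    sample_ids <- panel$sample_ids
  }
  if (!is.null(panel) && nrow(segments)) {
    bounds <- panel$map[, .(lo = min(bp), hi = max(bp)), by = chrom]
    chk <- merge(segments, bounds, by = "chrom")
    if (nrow(chk) < nrow(segments) || any(chk$start_bp < chk$lo | chk$end_bp > chk$hi))
      stop_hd("segment outside panel map bounds")
  }
  tot <- if (nrow(segments))
    segments[sample_id %in% sample_ids, .(l = sum(length_bp)), by = sample_id]
  else data.table::data.table(sample_id = character(0), l = double(0))
  f <- setNames(rep(0, length(sample_ids)), sample_ids)
  f[tot$sample_id] <- tot$l / L_AUTO
  f
}

#' F_ROH decomposed by segment-length class and birth cohort
#'
#' Splits each sample's F_ROH across segment-length classes (half-open
#' intervals (lower, upper] in Mbp; default edges 1, 2, 4, 8, 16, 32, Inf,
#' separating old from recent inbreeding) and summarises per birth cohort:
#' mean and SD of the class F_ROH over all cohort samples (samples without
#' segments in a class contribute 0) and the mean number of segments.
#' Per sample, class values sum exactly to total F_ROH.
#'
#' @param segments segment table from [detect_roh()].
#' @param cohorts named character vector mapping `sample_id` to a cohort
#'   label; every sample to report must be present.
#' @param L_AUTO autosome length denominator in bp.
#' @param class_edges_mbp ascending class edges in Mbp, last may be `Inf`.
#' @return data.table with `cohort`, `length_class`, `mean_froh`,
#'   `sd_froh`, `mean_n_segments`, plus a `"total"` row per cohort.
#' @export
froh_by_length_class <- function(segments, cohorts, L_AUTO,
                                 class_edges_mbp = c(1, 2, 4, 8, 16, 32, Inf)) {
  stopifnot(L_AUTO > 0, !is.null(names(cohorts)))
  edges <- class_edges_mbp * 1e6
  k <- length(edges) - 1
  labs <- sprintf("(%s,%s]", class_edges_mbp[-length(class_edges_mbp)],
                  class_edges_mbp[-1])
  samples <- names(cohorts)
  fmat <- matrix(0, length(samples), k, dimnames = list(samples, labs))
  nmat <- matrix(0, length(samples), k, dimnames = list(samples, labs))
  if (nrow(segments)) {
    seg <- segments[sample_id %in% samples]
    if (nrow(seg)) {
      cls <- findInterval(seg$length_bp, edges, left.open = TRUE,
                          rightmost.closed = FALSE)
      cls[seg$length_bp <= edges[1]] <- 1L   # lengths at/below the lowest edge
      cls[cls > k] <- k
      for (r in seq_len(nrow(seg))) {
        i <- match(seg$sample_id[r], samples)
        fmat[i, cls[r]] <- fmat[i, cls[r]] + seg$length_bp[r] / L_AUTO
        nmat[i, cls[r]] <- nmat[i, cls[r]] + 1
      }
    }
  }
  res <- list()
  for (co in unique(cohorts)) {
    rows <- which(cohorts == co)
    res[[length(res) + 1L]] <- data.table::data.table(
      cohort = co, length_class = c(labs, "total"),
      mean_froh = c(colMeans(fmat[rows, , drop = FALSE]),
                    mean(rowSums(fmat[rows, , drop = FALSE]))),
      sd_froh = c(apply(fmat[rows, , drop = FALSE], 2, sd),
                  sd(rowSums(fmat[rows, , drop = FALSE]))),
      mean_n_segments = c(colMeans(nmat[rows, , drop = FALSE]),
                          mean(rowSums(nmat[rows, , drop = FALSE]))))
  }
  data.table::rbindlist(res)[]
}

#' Summary statistics comparing pedigree and genomic inbreeding
#'
#' Per-coefficient descriptive statistics (mean, SD, min, max, and the
#' coefficient of variation SD/mean), the Pearson correlation between the
#' two coefficients overall, per birth year, and within pedigree-depth
#' subgroups (CGE <= 10 vs > 10), and "highly inbred" flags: animals whose
#' coefficient exceeds its mean + 3 SD. The overlap of the two flag sets is
#' reported both as Jaccard (|A and B| / |A or B|) and relative to the
#' smaller set (|A and B| / min(|A|, |B|)).
#'
#' @param fped,froh aligned numeric vectors of per-animal coefficients.
#' @param birth_years optional aligned integer vector (enables per-year r).
#' @param cge optional aligned numeric vector (enables the CGE split).
#' @param cge_cut CGE subgroup boundary, default 10.
#' @return Named list; see Details in the package vignette.
#' @export
inbreeding_summary <- function(fped, froh, birth_years = NULL, cge = NULL,
                               cge_cut = 10) {
  stopifnot(length(fped) == length(froh))
  desc <- function(x) c(mean = mean(x), sd = sd(x), min = min(x),
                        max = max(x), cv = sd(x) / mean(x))
  safe_cor <- function(x, y) {
    if (length(x) < 3) return(NA_real_)
    if (sd(x) == 0 || sd(y) == 0) {
      warning("zero variance; correlation undefined", call. = FALSE)
      return(NA_real_)
    }
    cor(x, y)
  }
  thr_p <- mean(fped) + 3 * sd(fped)
  thr_r <- mean(froh) + 3 * sd(froh)
  hi_p <- which(fped > thr_p)
  hi_r <- which(froh > thr_r)
  inter <- length(intersect(hi_p, hi_r))
  uni <- length(union(hi_p, hi_r))
  res <- list(
    fped = desc(fped), froh = desc(froh),
    r_overall = safe_cor(fped, froh),
    threshold_fped = thr_p, threshold_froh = thr_r,
    n_high_fped = length(hi_p), n_high_froh = length(hi_r),
    overlap_jaccard = if (uni > 0) inter / uni else NA_real_,
    overlap_min = if (min(length(hi_p), length(hi_r)) > 0)
      inter / min(length(hi_p), length(hi_r)) else NA_real_)
  if (!is.null(birth_years)) {
    dt <- data.table::data.table(fped = fped, froh = froh, year = birth_years)
    dt <- dt[!is.na(year)]
    res$r_by_year <- dt[, .(r = safe_cor(fped, froh), n = .N), by = year][order(year)]
  }
  if (!is.null(cge)) {
    lo <- cge <= cge_cut
    res$r_cge_low <- safe_cor(fped[lo], froh[lo])
    res$r_cge_high <- safe_cor(fped[!lo], froh[!lo])
    res$n_cge_low <- sum(lo); res$n_cge_high <- sum(!lo)
  }
  res
}
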