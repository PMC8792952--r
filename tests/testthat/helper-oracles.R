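# Independent oracles used to validate the fast implementations.
# These deliberately use naive algorithms (recursive kinship, exhaustive
# window enumeration, direct probability enumeration) so they share no code
# path with the functions under test.

# --- recursive-kinship oracle for pedigree inbreeding -----------------------
# phi(a, b): coancestry via the classical recursion on the later-born animal
# (valid because pedigree rows are topologically ordered).
oracle_fped <- function(ped) {
  si <- ped$sire_idx
  di <- ped$dam_idx
  memo <- new.env(parent = emptyenv())
  z <- function(x) if (is.na(x)) 0L else x
  phi <- function(a, b) {
    if (a == 0L || b == 0L) return(0)
    if (a > b) { tmp <- a; a <- b; b <- tmp }
    key <- paste(a, b)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    v <- if (a == b) 0.5 * (1 + phi(z(si[a]), z(di[a])))
         else 0.5 * (phi(a, z(si[b])) + phi(a, z(di[b])))
    assign(key, v, envir = memo)
    v
  }
  f <- vapply(seq_len(nrow(ped)), function(i) {
    if (is.na(si[i]) || is.na(di[i])) 0 else phi(si[i], di[i])
  }, double(1))
  stats::setNames(f, ped$animal_id)
}

# random pedigree: each animal after the first few draws parents (or
# unknown) from earlier animals
random_pedigree <- function(n, p_known = 0.8, n_founders = max(3, n %/% 5)) {
  id <- sprintf("A%03d", seq_len(n))
  sire <- dam <- rep("0", n)
  for (i in (n_founders + 1):n) {
    if (stats::runif(1) < p_known) {
      pp <- sample.int(i - 1L, 2L)
      sire[i] <- id[pp[1]]; dam[i] <- id[pp[2]]
    }
  }
  pedigree(data.frame(id = id, sire = sire, dam = dam,
                      sex = rep(c("male", "female"), length.out = n),
                      birth_year = 2000 + (seq_len(n) %/% 5)))
}

# --- exhaustive-window oracle for ROH detection -----------------------------
# enumerates the full validity matrix over all [s, e] windows, then applies
# the leftmost-longest disjoint selection and the size/length/density
# filters.
oracle_roh_one <- function(g, bp, params) {
  n <- length(g)
  hom <- !is.na(g) & g != 1
  het_c <- cumsum(!is.na(g) & g == 1)
  mis_c <- cumsum(is.na(g))
  HET <- outer(c(0, het_c[-n]), het_c, function(a, b) b - a)
  MIS <- outer(c(0, mis_c[-n]), mis_c, function(a, b) b - a)
  GAP <- matrix(0, n, n)
  if (n > 1) {
    gaps <- diff(bp)
    for (s in 1:(n - 1)) GAP[s, (s + 1):n] <- cummax(gaps[s:(n - 1)])
  }
  valid <- outer(hom, hom, "&") & HET <= params$max_het &
    MIS <= params$max_missing & GAP <= params$max_gap_bp
  valid[lower.tri(valid)] <- FALSE
  segs <- NULL
  pos <- 1L
  while (pos <= n) {
    rows <- pos:n
    has <- rows[rowSums(valid[rows, , drop = FALSE]) > 0]
    if (!length(has)) break
    s <- has[1]
    e <- max(which(valid[s, ]))
    segs <- rbind(segs, c(s, e))
    pos <- e + 1L
  }
  if (is.null(segs)) return(NULL)
  s <- segs[, 1]; e <- segs[, 2]
  ns <- e - s + 1L
  len <- bp[e] - bp[s]
  keep <- ns >= params$min_snps & len >= params$min_length_bp &
    ns / len >= params$min_density
  if (!any(keep)) return(NULL)
  data.frame(start = s[keep], end = e[keep])
}

oracle_roh <- function(panel, params) {
  out <- list()
  for (ch in unique(panel$map$chrom)) {
    jj <- which(panel$map$chrom == ch)
    bp <- panel$map$bp[jj]
    for (i in seq_len(nrow(panel$geno))) {
      se <- oracle_roh_one(panel$geno[i, jj], bp, params)
      if (is.null(se)) next
      out[[length(out) + 1L]] <- data.table::data.table(
        sample_id = panel$sample_ids[i], chrom = ch,
        start_bp = bp[se$start], end_bp = bp[se$end],
        n_snps = se$end - se$start + 1L)
    }
  }
  if (!length(out))
    return(data.table::data.table(sample_id = character(0), chrom = integer(0),
                                  start_bp = double(0), end_bp = double(0),
                                  n_snps = integer(0)))
  seg <- data.table::rbindlist(out)
  data.table::setorder(seg, sample_id, chrom, start_bp)
  seg
}

# random single-chromosome panel tuned to produce borderline runs: blocks of
# homozygosity interrupted by hets/missing, irregular spacing with
# occasional large gaps
random_roh_panel <- function(n_snps, n_samples = 3) {
  steps <- stats::runif(n_snps - 1, 2e4, 2e5)
  big <- stats::runif(n_snps - 1) < 0.02
  steps[big] <- stats::runif(sum(big), 5e5, 1.2e6)
  bp <- cumsum(c(1e5, steps))
  geno <- matrix(0, n_samples, n_snps)
  for (i in seq_len(n_samples)) {
    g <- sample(c(0, 2), n_snps, replace = TRUE)
    n_het <- rpois(1, n_snps / 30)
    n_mis <- rpois(1, n_snps / 60)
    g[sample.int(n_snps, min(n_het, n_snps))] <- 1
    g[sample.int(n_snps, min(n_mis, n_snps))] <- NA
    geno[i, ] <- g
  }
  genotype_panel(geno, data.table::data.table(
    snp_id = sprintf("s%d", seq_len(n_snps)), chrom = 1, bp = bp),
    sprintf("S%d", seq_len(n_samples)))
}

# --- enumeration oracle for the exact HWE test ------------------------------
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1.0)
  rare <- min(nA, na)
  hets <- seq(rare %% 2, rare, by = 2)
  # P(het = h | allele counts) by direct combinatorial enumeration
  pr <- vapply(hets, function(h) {
    choose(n, (nA - h) / 2) * choose(n - (nA - h) / 2, h) * 2^h /
      choose(2 * n, nA)
  }, double(1))
  pr <- pr / sum(pr)
  obs <- pr[hets == n_Aa]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# --- helpers ----------------------------------------------------------------
make_panel <- function(geno, bp, chrom = 1, sample_ids = NULL) {
  geno <- rbind(geno)
  genotype_panel(geno, data.table::data.table(
    snp_id = sprintf("m%d", seq_along(bp)), chrom = chrom, bp = bp),
    sample_ids %||% sprintf("S%d", seq_len(nrow(geno))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
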