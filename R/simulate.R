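# Synthetic herds with known ground truth: an overlapping-generation
# pedigree simulator with era-specific generation intervals for the four
# selection pathways, gene dropping of labeled founder haplotypes (true
# autozygosity known by construction), and a forward Wright-Fisher
# simulator of known effective size for validating LD-based Ne recovery.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Define a synthetic genome
#'
#' @param n_chrom number of autosomes.
#' @param length_bp chromosome length in bp (recycled).
#' @param snps_per_chrom evenly spaced SNPs per chromosome.
#' @return data.table with `chrom`, `length_bp`, `n_snps`.
#' @export
default_genome <- function(n_chrom = 5, length_bp = 1e8, snps_per_chrom = 2000) {
  data.table::data.table(chrom = seq_len(n_chrom),
                         length_bp = rep(length_bp, length.out = n_chrom),
                         n_snps = rep(snps_per_chrom, length.out = n_chrom))
}

genome_snp_positions <- function(genome) {
  lapply(seq_len(nrow(genome)), function(i)
    round(seq(1, genome$length_bp[i], length.out = genome$n_snps[i])))
}

#' Describe a synthetic herd scenario
#'
#' A stated world for the pedigree simulator: a multi-decade
#' overlapping-generation herd with four selection pathways whose
#' generation intervals change at a breeding-program switch year (long
#' progeny-test sire pathways before, short genomic-selection pathways
#' after), and optionally a sire-dominant mating scheme in which a few
#' elite sires father each year's crop.
#'
#' @param n_founders founder animals (half male); born over the decade
#'   before `years[1]`.
#' @param years `c(first, last)` offspring birth years.
#' @param offspring_per_year calves born per year.
#' @param male_fraction fraction of male calves.
#' @param switch_year first year of the post-switch era; default
#'   `years[2] + 1`, i.e. a single pre-switch era.
#' @param gi named list `pre`/`post`, each a named vector of mean parent
#'   ages (years) for `sire_of_bulls`, `dam_of_bulls`, `sire_of_cows`,
#'   `dam_of_cows`.
#' @param gi_sd SD of parent age around the pathway mean (0 = exact).
#' @param mating `"random"` or `"sire_dominant"`.
#' @param top_k_sires named vector `pre`/`post`: elite sires per year under
#'   the sire-dominant scheme.
#' @param genome a [default_genome()]-style table.
#' @param seed integer seed; all outputs are byte-identical per seed.
#' @return List of class `herd_scenario`.
#' @export
herd_scenario <- function(n_founders = 60, years = c(2000, 2020),
                          offspring_per_year = 60, male_fraction = 0.5,
                          switch_year = NULL,
                          gi = list(pre = c(sire_of_bulls = 7, dam_of_bulls = 5,
                                            sire_of_cows = 7, dam_of_cows = 4.5),
                                    post = c(sire_of_bulls = 3, dam_of_bulls = 3,
                                             sire_of_cows = 3.5, dam_of_cows = 4)),
                          gi_sd = 1, mating = c("random", "sire_dominant"),
                          top_k_sires = c(pre = 10, post = 3),
                          genome = default_genome(), seed = 1) {
  mating <- match.arg(mating)
  switch_year <- switch_year %||% (years[2] + 1)   # default: single pre era
  stopifnot(n_founders >= 4, offspring_per_year >= 1,
            years[2] >= years[1],
            switch_year > years[1], switch_year <= years[2] + 1,
            all(unlist(gi) > 0), gi_sd >= 0, all(top_k_sires >= 1))
  structure(list(n_founders = n_founders, years = years,
                 offspring_per_year = offspring_per_year,
                 male_fraction = male_fraction, switch_year = switch_year,
                 gi = gi, gi_sd = gi_sd, mating = mating,
                 top_k_sires = top_k_sires, genome = genome, seed = seed),
            class = "herd_scenario")
}

# sample one parent age from the cohorts that actually have candidates,
# weighted by a (possibly degenerate) normal around the pathway mean
sample_parent_age <- function(avail_ages, mu, sd_, year, role) {
  if (sd_ == 0) {
    a <- round(mu)
    if (!a %in% avail_ages)
      stop_hd("infeasible scenario: no eligible ", role, " of exact age ", a,
              " in year ", year)
    return(a)
  }
  w <- dnorm(avail_ages, mu, sd_)
  if (!any(w > 0)) w <- rep(1, length(avail_ages))
  if (length(avail_ages) == 1L) return(avail_ages)
  sample(avail_ages, 1L, prob = w)
}

#' Simulate an overlapping-generation herd pedigree
#'
#' Parent ages are drawn from era-specific pathway distributions; under the
#' sire-dominant scheme each year's offspring are fathered by a small elite
#' sire set (`top_k_sires` of the era), concentrating paternal
#' contributions the way progeny-test/genomic-selection programs do.
#'
#' @param scenario a [herd_scenario()].
#' @return List with `pedigree` (a [pedigree]) and `true_gi` (data.table of
#'   the stated era x pathway mean generation intervals).
#' @export
simulate_pedigree <- function(scenario) {
  stopifnot(inherits(scenario, "herd_scenario"))
  sc <- scenario
  with_seed(sc$seed, {
    nf <- sc$n_founders
    n_fm <- ceiling(nf / 2)
    f_years <- sc$years[1] - (((seq_len(nf) - 1L) %% 10L) + 1L)
    id <- sprintf("F%04d", seq_len(nf))
    sire <- rep(NA_character_, nf)
    dam <- rep(NA_character_, nf)
    sex <- c(rep("male", n_fm), rep("female", nf - n_fm))
    by <- f_years
    min_age <- 2L; max_age <- 12L

    for (y in seq(sc$years[1], sc$years[2])) {
      era <- if (y < sc$switch_year) "pre" else "post"
      n_off <- sc$offspring_per_year
      n_male <- round(n_off * sc$male_fraction)
      off_sex <- c(rep("male", n_male), rep("female", n_off - n_male))
      males <- which(sex == "male" & by <= y - min_age & by >= y - max_age)
      females <- which(sex == "female" & by <= y - min_age & by >= y - max_age)
      if (!length(males)) stop_hd("infeasible scenario: no eligible sires in year ", y)
      if (!length(females)) stop_hd("infeasible scenario: no eligible dams in year ", y)
      m_by_age <- split(males, y - by[males])
      f_by_age <- split(females, y - by[females])

      elite <- NULL
      if (sc$mating == "sire_dominant") {
        k <- min(sc$top_k_sires[[era]], length(males))
        mu_e <- sc$gi[[era]][["sire_of_cows"]]
        ages <- as.integer(names(m_by_age))
        w <- if (sc$gi_sd == 0) as.numeric(ages == round(mu_e))
             else dnorm(ages, mu_e, sc$gi_sd)
        if (!any(w > 0)) {
          if (sc$gi_sd == 0)
            stop_hd("infeasible scenario: no eligible sires of exact age ",
                    round(mu_e), " in year ", y)
          w <- rep(1, length(ages))
        }
        pool_w <- unlist(lapply(seq_along(ages), function(i)
          rep(w[i] / length(m_by_age[[i]]), length(m_by_age[[i]]))))
        pool <- unlist(m_by_age, use.names = FALSE)
        elite <- if (length(pool) <= k) pool
                 else pool[sample.int(length(pool), k, prob = pool_w)]
      }

      new_id <- sprintf("Y%d_%03d", y, seq_len(n_off))
      new_sire <- character(n_off)
      new_dam <- character(n_off)
      for (i in seq_len(n_off)) {
        pw_s <- if (off_sex[i] == "male") "sire_of_bulls" else "sire_of_cows"
        pw_d <- if (off_sex[i] == "male") "dam_of_bulls" else "dam_of_cows"
        if (is.null(elite)) {
          a_s <- sample_parent_age(as.integer(names(m_by_age)),
                                   sc$gi[[era]][[pw_s]], sc$gi_sd, y, "sire")
          cands <- m_by_age[[as.character(a_s)]]
          new_sire[i] <- id[cands[sample.int(length(cands), 1L)]]
        } else {
          new_sire[i] <- id[elite[sample.int(length(elite), 1L)]]
        }
        a_d <- sample_parent_age(as.integer(names(f_by_age)),
                                 sc$gi[[era]][[pw_d]], sc$gi_sd, y, "dam")
        cands <- f_by_age[[as.character(a_d)]]
        new_dam[i] <- id[cands[sample.int(length(cands), 1L)]]
      }
      id <- c(id, new_id); sire <- c(sire, new_sire); dam <- c(dam, new_dam)
      sex <- c(sex, off_sex); by <- c(by, rep(y, n_off))
    }
    ped <- pedigree(data.frame(id = id, sire = sire, dam = dam, sex = sex,
                               birth_year = by))
    tg <- data.table::rbindlist(lapply(c("pre", "post"), function(e)
      data.table::data.table(era = e, pathway = names(sc$gi[[e]]),
                             mean_gi = unname(sc$gi[[e]]))))
    list(pedigree = ped, true_gi = tg)
  })
}

# ---- gene dropping ---------------------------------------------------------

# a gamete track on one chromosome: list(b = segment start positions
# (first 0, strictly increasing), l = founder-haplotype labels)
meiosis_track <- function(g1, g2, length_bp) {
  nx <- rpois(1L, length_bp * 1e-8)          # 1 Morgan per 100 Mb, Haldane
  xs <- if (nx > 0) sort(runif(nx, 0, length_bp)) else numeric(0)
  xs <- xs[!duplicated(xs)]
  src <- if (runif(1) < 0.5) list(g1, g2) else list(g2, g1)
  cuts <- c(0, xs)
  ends <- c(xs, length_bp)
  b_out <- numeric(0); l_out <- integer(0)
  for (k in seq_along(cuts)) {
    g <- src[[1L + (k - 1L) %% 2L]]
    i1 <- findInterval(cuts[k], g$b)
    i2 <- findInterval(ends[k], g$b, left.open = TRUE)
    if (i2 < i1) next
    idx <- i1:i2
    bb <- g$b[idx]; bb[1] <- cuts[k]
    b_out <- c(b_out, bb); l_out <- c(l_out, g$l[idx])
  }
  keep <- c(TRUE, l_out[-1] != l_out[-length(l_out)])
  list(b = b_out[keep], l = l_out[keep])
}

track_shared_intervals <- function(g1, g2, length_bp) {
  b <- sort(unique(c(g1$b, g2$b)))
  l1 <- g1$l[findInterval(b, g1$b)]
  l2 <- g2$l[findInterval(b, g2$b)]
  ends <- c(b[-1], length_bp)
  same <- l1 == l2
  if (!any(same)) return(NULL)
  cbind(start = b[same], end = ends[same])
}

track_labels_at <- function(g, pos) g$l[findInterval(pos, g$b)]

#' Gene-drop founder haplotypes through a pedigree
#'
#' Every founder carries two uniquely labeled haplotypes; meioses recombine
#' with Poisson crossovers at 1 Morgan per 100 Mb (Haldane model, no
#' interference). True autozygous intervals are the regions where an
#' animal's two inherited labels descend from the same founder haplotype —
#' known exactly, which makes the drop the ground truth for ROH-based
#' inbreeding. Optionally, biallelic SNP alleles are assigned to founder
#' haplotypes at per-SNP frequencies drawn from `freq_range`, yielding a
#' genotype panel consistent with the autozygosity.
#'
#' @param ped a [pedigree].
#' @param genome a [default_genome()]-style table.
#' @param seed integer seed (or `NULL` to use the current RNG stream).
#' @param genotypes emit a [genotype_panel] (set `FALSE` for
#'   autozygosity-only drops, which are much faster).
#' @param freq_range range of the counted-allele frequency per SNP.
#' @param samples animals to genotype (default: all).
#' @return List with `autozygosity` (named fraction per animal),
#'   `true_segments` (data.table: `animal_id`, `chrom`, `start_bp`,
#'   `end_bp`), and `panel` (or `NULL`).
#' @export
gene_drop <- function(ped, genome = default_genome(), seed = NULL,
                      genotypes = TRUE, freq_range = c(0.1, 0.9),
                      samples = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  si <- ped$sire_idx; di <- ped$dam_idx
  n_chr <- nrow(genome)
  with_seed(seed, {
    # gam[[chr]][[2*i-1 / 2*i]]: the two gamete tracks of animal i
    gam <- lapply(seq_len(n_chr), function(ch) vector("list", 2L * n))
    lab <- 0L
    total_len <- sum(genome$length_bp)
    auto <- numeric(n)
    segs <- list()
    for (i in seq_len(n)) {
      # an unknown parental side contributes a fresh uniquely labeled
      # haplotype (never autozygous with anything), matching F = 0 for
      # animals with at most one known parent
      if (is.na(si[i])) { lab <- lab + 1L; l1 <- lab }
      if (is.na(di[i])) { lab <- lab + 1L; l2 <- lab }
      for (ch in seq_len(n_chr)) {
        L <- genome$length_bp[ch]
        g1 <- if (is.na(si[i])) list(b = 0, l = l1)
              else meiosis_track(gam[[ch]][[2L * si[i] - 1L]],
                                 gam[[ch]][[2L * si[i]]], L)
        g2 <- if (is.na(di[i])) list(b = 0, l = l2)
              else meiosis_track(gam[[ch]][[2L * di[i] - 1L]],
                                 gam[[ch]][[2L * di[i]]], L)
        gam[[ch]][[2L * i - 1L]] <- g1
        gam[[ch]][[2L * i]] <- g2
        sh <- track_shared_intervals(g1, g2, L)
        if (!is.null(sh)) {
          auto[i] <- auto[i] + sum(sh[, "end"] - sh[, "start"])
          segs[[length(segs) + 1L]] <- data.table::data.table(
            animal_id = ped$animal_id[i], chrom = genome$chrom[ch],
            start_bp = sh[, "start"], end_bp = sh[, "end"])
        }
      }
    }
    auto <- auto / total_len
    true_segments <- if (length(segs)) data.table::rbindlist(segs)
      else data.table::data.table(animal_id = character(0), chrom = integer(0),
                                  start_bp = double(0), end_bp = double(0))
    panel <- NULL
    if (genotypes) {
      pos <- genome_snp_positions(genome)
      rows <- if (is.null(samples)) seq_len(n) else match(samples, ped$animal_id)
      stopifnot(!anyNA(rows))
      geno_list <- vector("list", n_chr)
      for (ch in seq_len(n_chr)) {
        m <- length(pos[[ch]])
        p <- runif(m, freq_range[1], freq_range[2])
        hap_alleles <- matrix(rbinom(lab * m, 1L, rep(p, each = lab)), lab, m)
        g <- matrix(0L, length(rows), m)
        for (r in seq_along(rows)) {
          i <- rows[r]
          l1 <- track_labels_at(gam[[ch]][[2L * i - 1L]], pos[[ch]])
          l2 <- track_labels_at(gam[[ch]][[2L * i]], pos[[ch]])
          g[r, ] <- hap_alleles[cbind(l1, seq_len(m))] +
            hap_alleles[cbind(l2, seq_len(m))]
        }
        geno_list[[ch]] <- g
      }
      map <- data.table::rbindlist(lapply(seq_len(n_chr), function(ch)
        data.table::data.table(
          snp_id = sprintf("snp%d_%d", genome$chrom[ch], seq_along(pos[[ch]])),
          chrom = genome$chrom[ch], bp = pos[[ch]])))
      panel <- genotype_panel(do.call(cbind, geno_list), map,
                              ped$animal_id[rows])
    }
    list(autozygosity = setNames(auto, ped$animal_id),
         true_segments = true_segments, panel = panel)
  })
}

# ---- Wright-Fisher ---------------------------------------------------------

#' Forward Wright-Fisher simulation with recombination
#'
#' Discrete generations of `ne` random-mating diploids; each offspring
#' gamete is a recombinant of one parent's two haplotypes, with
#' per-interval switch probabilities from the Haldane map at 1 cM/Mb.
#' Sites start in linkage equilibrium at frequency `init_freq` and drift;
#' sites are ascertained at final-generation MAF >= `maf_floor` (an
#' array-like panel), and `n_sampled` diploids are returned.
#'
#' @param ne diploid population size (= effective size; >= 2).
#' @param n_generations generations to evolve (>= 1).
#' @param genome a [default_genome()]-style table.
#' @param n_sampled diploids to sample at the end (<= `ne`).
#' @param seed integer seed.
#' @param init_freq initial derived-allele frequency per site.
#' @param maf_floor ascertainment MAF threshold.
#' @return A [genotype_panel] of `n_sampled` samples.
#' @export
simulate_wright_fisher <- function(ne, n_generations, genome = default_genome(),
                                   n_sampled = ne, seed = 1, init_freq = 0.5,
                                   maf_floor = 0.05) {
  stopifnot(ne >= 2, n_generations >= 1)
  if (n_sampled > ne)
    stop_hd("n_sampled (", n_sampled, ") exceeds population size (", ne, ")")
  pos <- genome_snp_positions(genome)
  m_per <- lengths(pos)
  # per-chromosome vector of switch probabilities: 0.5 start phase, then
  # Haldane per inter-SNP interval
  rvecs <- lapply(seq_len(nrow(genome)), function(ch) {
    d <- diff(pos[[ch]]) * 1e-8
    c(0.5, (1 - exp(-2 * d)) / 2)
  })
  nh <- 2L * ne
  with_seed(seed, {
    H <- lapply(m_per, function(m)
      matrix(rbinom(m * nh, 1L, init_freq), m, nh))
    for (gen in seq_len(n_generations)) {
      par <- sample.int(ne, nh, replace = TRUE)
      for (ch in seq_along(H)) {
        m <- m_per[ch]
        sw <- matrix(rbinom(m * nh, 1L, rvecs[[ch]]), m, nh)
        phase <- apply(sw, 2, cumsum) %% 2L
        A <- H[[ch]][, 2L * par - 1L, drop = FALSE]
        B <- H[[ch]][, 2L * par, drop = FALSE]
        H[[ch]] <- A * (1L - phase) + B * phase
      }
    }
    samp <- sample.int(ne, n_sampled)
    keep_panels <- list(); maps <- list()
    for (ch in seq_along(H)) {
      freq <- rowMeans(H[[ch]])
      keep <- pmin(freq, 1 - freq) >= maf_floor
      if (!any(keep)) next
      G <- H[[ch]][keep, 2L * samp - 1L, drop = FALSE] +
        H[[ch]][keep, 2L * samp, drop = FALSE]
      keep_panels[[length(keep_panels) + 1L]] <- t(G)
      maps[[length(maps) + 1L]] <- data.table::data.table(
        snp_id = sprintf("wf%d_%d", genome$chrom[ch], which(keep)),
        chrom = genome$chrom[ch], bp = pos[[ch]][keep])
    }
    if (!length(keep_panels))
      stop_hd("all sites fixed or below the MAF floor; increase init_freq, ",
              "site count, or reduce generations")
    genotype_panel(do.call(cbind, keep_panels), data.table::rbindlist(maps),
                   sprintf("WF%04d", samp))
  })
}

# ---- fixtures --------------------------------------------------------------

fixture_registry <- function() c("small_herd", "gs_transition_herd",
                                 "wf_ne100", "toy_worked_examples")

#' Write a registered synthetic fixture to disk
#'
#' Emits, under `dir`, the pedigree CSV, PLINK text PED/MAP and ground
#' truth TSV of a named scenario. Outputs are byte-stable: fixed internal
#' seeds, sorted rows.
#'
#' @param name one of `small_herd` (small random-mating herd),
#'   `gs_transition_herd` (sire concentration increases at the switch year,
#'   so the true inbreeding rate accelerates), `wf_ne100` (Wright-Fisher
#'   panel of known Ne = 100), `toy_worked_examples` (the tiny pedigrees
#'   and genotypes used in the documentation).
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
make_fixture <- function(name, dir) {
  if (!name %in% fixture_registry())
    stop_hd("unknown fixture '", name, "'; registered: ",
            paste(fixture_registry(), collapse = ", "))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  files <- c()
  write_ped_csv <- function(ped, path) {
    out <- data.table::data.table(id = ped$animal_id,
                                  sire = ifelse(is.na(ped$sire_id), "0", ped$sire_id),
                                  dam = ifelse(is.na(ped$dam_id), "0", ped$dam_id),
                                  sex = ped$sex, birth_year = ped$birth_year)
    data.table::fwrite(out, path)
    path
  }
  if (name == "small_herd" || name == "gs_transition_herd") {
    sc <- if (name == "small_herd")
      herd_scenario(n_founders = 20, years = c(2000, 2012),
                    offspring_per_year = 30,
                    genome = default_genome(3, 5e7, 1000), seed = 101)
    else
      herd_scenario(n_founders = 40, years = c(2000, 2020),
                    offspring_per_year = 50, mating = "sire_dominant",
                    top_k_sires = c(pre = 999, post = 1), switch_year = 2010,
                    genome = default_genome(3, 5e7, 1000), seed = 202)
    sim <- simulate_pedigree(sc)
    drop <- gene_drop(sim$pedigree, sc$genome, seed = sc$seed + 1)
    files["pedigree"] <- write_ped_csv(sim$pedigree, p("pedigree.csv"))
    write_plink(drop$panel, p("geno.ped"), p("geno.map"), sim$pedigree)
    files["ped"] <- p("geno.ped"); files["map"] <- p("geno.map")
    truth <- data.table::data.table(animal_id = names(drop$autozygosity),
                                    true_autozygosity = unname(drop$autozygosity))
    files["truth"] <- write_tsv(truth, p("truth_autozygosity.tsv"))
    files["true_gi"] <- write_tsv(sim$true_gi, p("truth_gi.tsv"))
  } else if (name == "wf_ne100") {
    panel <- simulate_wright_fisher(100, 60, default_genome(5, 1e8, 400),
                                    n_sampled = 100, seed = 303)
    write_plink(panel, p("geno.ped"), p("geno.map"))
    files["ped"] <- p("geno.ped"); files["map"] <- p("geno.map")
    files["truth"] <- write_tsv(data.table::data.table(true_ne = 100),
                                p("truth_ne.tsv"))
  } else if (name == "toy_worked_examples") {
    # full-sib mating: X has F = 0.25; H has one known parent, F = 0
    ped <- pedigree(data.frame(
      id = c("A", "B", "S1", "S2", "X", "H"),
      sire = c("0", "0", "A", "A", "S1", "S1"),
      dam = c("0", "0", "B", "B", "S2", "0"),
      sex = c("male", "female", "male", "female", "female", "female"),
      birth_year = c(2000, 2000, 2003, 2003, 2007, 2008)))
    files["pedigree"] <- write_ped_csv(ped, p("pedigree.csv"))
    # one clean 20-SNP homozygous run over 2 Mb on chromosome 1
    bp <- seq(1e6, 3e6, length.out = 20)
    geno <- rbind(rep(2, 20), c(rep(1, 10), rep(0, 10)))
    panel <- genotype_panel(geno, data.table::data.table(
      snp_id = sprintf("toy%02d", 1:20), chrom = 1, bp = bp), c("X", "H"))
    write_plink(panel, p("geno.ped"), p("geno.map"), ped)
    files["ped"] <- p("geno.ped"); files["map"] <- p("geno.map")
  }
  invisible(files)
}
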