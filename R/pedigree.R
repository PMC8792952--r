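# Pedigree container and genealogy-based statistics: inbreeding by the
# tabular (recursive kinship) method, complete generation equivalents,
# generation intervals by selection pathway, and pedigree-based Ne.

#' Construct a validated pedigree
#'
#' Builds the pedigree object used throughout the package from a data.frame
#' of animal records. Parents referenced but not listed as animals are added
#' as founders with missing birth year; unknown parents are normalized to
#' `NA`. Records are topologically ordered (every parent precedes its
#' offspring), which the inbreeding and generation-equivalent recursions
#' rely on.
#'
#' @param records data.frame with columns `id`, `sire`, `dam` and optionally
#'   `sex` (`"male"`, `"female"`, `"unknown"`, or PLINK-style 1/2/0) and
#'   `birth_year`.
#' @param unknown_codes character values (besides `NA`) that mean "parent
#'   unknown"; default `c("0", "")`.
#' @return An object of class `pedigree`: a `data.table` with columns
#'   `animal_id`, `sire_id`, `dam_id`, `sex`, `birth_year`, and internal
#'   integer columns `sire_idx`/`dam_idx` pointing at the parents' rows.
#' @details A cycle (an animal that is its own ancestor) is a hard error
#'   naming one animal on the cycle, as is a duplicated `animal_id`.
#' @export
pedigree <- function(records, unknown_codes = c("0", "")) {
  records <- as.data.frame(records)
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(records)))
    stop_hd("pedigree records need columns: ", paste(need, collapse = ", "))

  norm_id <- function(x) {
    x <- trimws(as.character(x))
    x[x %in% unknown_codes | is.na(x)] <- NA_character_
    x
  }
  id   <- norm_id(records$id)
  sire <- norm_id(records$sire)
  dam  <- norm_id(records$dam)
  if (anyNA(id)) stop_hd("missing/unknown-coded animal id in pedigree input")
  if (anyDuplicated(id)) {
    dup <- id[duplicated(id)][1L]
    stop_hd("duplicate animal id in pedigree: ", dup)
  }

  sex <- if ("sex" %in% names(records)) tolower(trimws(as.character(records$sex)))
         else rep(NA_character_, length(id))
  sex[sex %in% c("1", "m")] <- "male"
  sex[sex %in% c("2", "f")] <- "female"
  sex[!(sex %in% c("male", "female"))] <- "unknown"

  birth_year <- if ("birth_year" %in% names(records))
    suppressWarnings(as.integer(records$birth_year))
  else rep(NA_integer_, length(id))

  # referenced-but-unlisted parents become founders (sex from the role)
  extra_sires <- setdiff(stats::na.omit(unique(sire)), id)
  extra_dams  <- setdiff(stats::na.omit(unique(dam)), id)
  extra_dams  <- setdiff(extra_dams, extra_sires)
  if (length(extra_sires) || length(extra_dams)) {
    id   <- c(id, extra_sires, extra_dams)
    sire <- c(sire, rep(NA_character_, length(extra_sires) + length(extra_dams)))
    dam  <- c(dam,  rep(NA_character_, length(extra_sires) + length(extra_dams)))
    sex  <- c(sex, rep("male", length(extra_sires)), rep("female", length(extra_dams)))
    birth_year <- c(birth_year,
                    rep(NA_integer_, length(extra_sires) + length(extra_dams)))
  }

  n <- length(id)
  si <- match(sire, id)
  di <- match(dam, id)

  # generation rank by iterated relaxation; stalling before all ranks are
  # assigned means a cycle
  rank <- ifelse(is.na(si) & is.na(di), 0L, NA_integer_)
  repeat {
    todo <- which(is.na(rank))
    if (!length(todo)) break
    rs <- ifelse(is.na(si[todo]), -1L, rank[si[todo]])
    rd <- ifelse(is.na(di[todo]), -1L, rank[di[todo]])
    ok <- !is.na(rs) & !is.na(rd)
    if (!any(ok))
      stop_hd("pedigree cycle detected involving animal: ", id[todo[1L]])
    rank[todo[ok]] <- pmax(rs[ok], rd[ok]) + 1L
  }

  ord <- order(rank, seq_len(n))
  ped <- data.table::data.table(
    animal_id = id[ord], sire_id = sire[ord], dam_id = dam[ord],
    sex = sex[ord], birth_year = birth_year[ord])
  ped[, sire_idx := match(sire_id, animal_id)]
  ped[, dam_idx := match(dam_id, animal_id)]
  data.table::setattr(ped, "class", c("pedigree", class(data.table::data.table())))
  ped[]
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree> %d animals (%d founders), birth years %s\n",
              nrow(x), sum(is.na(x$sire_idx) & is.na(x$dam_idx)),
              if (all(is.na(x$birth_year))) "unknown"
              else paste(range(x$birth_year, na.rm = TRUE), collapse = "-")))
  NextMethod()
}

#' Read a pedigree from a delimited text file
#'
#' @param path CSV/TSV file with a header row (delimiter sniffed by
#'   [data.table::fread()]).
#' @param columns named character vector mapping the roles `id`, `sire`,
#'   `dam`, `sex`, `birth_year` to column names in the file. `sex` and
#'   `birth_year` are optional.
#' @param unknown_codes values denoting an unknown parent; default `"0"`
#'   and empty string.
#' @return A [pedigree] object.
#' @export
load_pedigree <- function(path,
                          columns = c(id = "id", sire = "sire", dam = "dam",
                                      sex = "sex", birth_year = "birth_year"),
                          unknown_codes = c("0", "")) {
  if (!file.exists(path)) stop_hd("pedigree file not found: ", path)
  raw <- data.table::fread(path, colClasses = "character", na.strings = NULL)
  for (role in c("id", "sire", "dam"))
    if (!columns[[role]] %in% names(raw))
      stop_hd("pedigree file lacks required column '", columns[[role]],
              "' (role: ", role, ")")
  rec <- data.frame(id = raw[[columns[["id"]]]],
                    sire = raw[[columns[["sire"]]]],
                    dam = raw[[columns[["dam"]]]])
  if (!is.na(columns["sex"]) && columns[["sex"]] %in% names(raw))
    rec$sex <- raw[[columns[["sex"]]]]
  if (!is.na(columns["birth_year"]) && columns[["birth_year"]] %in% names(raw))
    rec$birth_year <- raw[[columns[["birth_year"]]]]
  pedigree(rec, unknown_codes = unknown_codes)
}

#' Pedigree inbreeding coefficients by the tabular method
#'
#' Computes, for every animal, the probability F of carrying two alleles
#' identical by descent, using the recursive kinship (tabular,
#' Meuwissen-Luo style) algorithm: F of an animal equals half the additive
#' relationship of its parents, accumulated by a single descending sweep per
#' animal over the within-pedigree ancestor contributions. Runs in
#' O(pedigree size x depth) and is independent of input row order.
#'
#' @param ped a [pedigree].
#' @return Named numeric vector of F values in `[0, 1)`, one per animal,
#'   in pedigree (topological) order. Founders and animals with at most one
#'   known parent have F = 0.
#' @export
compute_fped <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  si <- ped$sire_idx
  di <- ped$dam_idx
  f <- numeric(n)
  if (n == 0L) return(setNames(f, character(0)))
  L <- numeric(n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (is.na(s) || is.na(d)) next      # F = 0 with <2 known parents
    top <- max(s, d)
    L[seq_len(top)] <- 0
    L[s] <- L[s] + 0.5
    L[d] <- L[d] + 0.5
    a <- 0.5 - 0.25 * (f[s] + f[d])     # within-family segregation variance of i
    for (j in top:1L) {
      lj <- L[j]
      if (lj == 0) next
      sj <- si[j]; dj <- di[j]
      vj <- if (!is.na(sj) && !is.na(dj)) 0.5 - 0.25 * (f[sj] + f[dj])
            else if (!is.na(sj)) 0.75 - 0.25 * f[sj]
            else if (!is.na(dj)) 0.75 - 0.25 * f[dj]
            else 1
      a <- a + lj * lj * vj
      if (!is.na(sj)) L[sj] <- L[sj] + 0.5 * lj
      if (!is.na(dj)) L[dj] <- L[dj] + 0.5 * lj
    }
    f[i] <- a - 1
  }
  setNames(f, ped$animal_id)
}

#' Complete generation equivalents
#'
#' Pedigree-depth measure per animal: the sum over all known-ancestor paths
#' of (1/2)^g, where g is the number of generations back along the path
#' (parents g = 1). Computed by the recursion
#' CGE(i) = sum over known parents p of 0.5 * (1 + CGE(p)).
#'
#' @param ped a [pedigree].
#' @return Named numeric vector of CGE values (founders 0) in pedigree order.
#' @export
compute_cge <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  cge <- numeric(n)
  si <- ped$sire_idx; di <- ped$dam_idx
  for (i in seq_len(n)) {
    v <- 0
    if (!is.na(si[i])) v <- v + 0.5 * (1 + cge[si[i]])
    if (!is.na(di[i])) v <- v + 0.5 * (1 + cge[di[i]])
    cge[i] <- v
  }
  setNames(cge, ped$animal_id)
}

#' Per-animal inbreeding and pedigree-depth table
#'
#' @param ped a [pedigree].
#' @return data.table with `animal_id`, `F_ped`, `CGE`, `birth_year`, `sex`.
#' @export
inbreeding_table <- function(ped) {
  data.table::data.table(animal_id = ped$animal_id,
                         F_ped = unname(compute_fped(ped)),
                         CGE = unname(compute_cge(ped)),
                         birth_year = ped$birth_year,
                         sex = ped$sex)
}

#' Generation intervals by selection pathway
#'
#' The generation interval is the average age of parents when their
#' offspring are born, split into the four classical dairy-breeding
#' pathways: sire of bulls, dam of bulls, sire of cows, dam of cows
#' (offspring sex routes the pair, parent role picks sire/dam). Pairs where
#' either birth year is missing, or where the offspring sex is unknown, are
#' skipped and tallied; non-positive intervals (parent born in or after the
#' offspring's birth year) are excluded with a warning.
#'
#' @param ped a [pedigree].
#' @param year_range optional `c(first, last)` filter on offspring birth year.
#' @return data.table with `pathway`, `year`, `mean_interval`, `n_offspring`,
#'   ordered by pathway then year; empty pathway-year cells are omitted.
#'   Attribute `"skipped"` holds the skip tallies.
#' @export
generation_intervals <- function(ped, year_range = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  pairs_for <- function(parent_idx, parent_role) {
    off <- which(!is.na(parent_idx))
    data.table::data.table(
      off_year = ped$birth_year[off],
      par_year = ped$birth_year[parent_idx[off]],
      off_sex = ped$sex[off],
      role = parent_role)
  }
  pp <- rbind(pairs_for(ped$sire_idx, "sire"), pairs_for(ped$dam_idx, "dam"))
  skipped <- c(missing_year = 0L, unknown_sex = 0L, nonpositive = 0L)
  if (nrow(pp)) {
    miss <- is.na(pp$off_year) | is.na(pp$par_year)
    skipped["missing_year"] <- sum(miss)
    pp <- pp[!miss]
    unk <- pp$off_sex == "unknown"
    skipped["unknown_sex"] <- sum(unk)
    pp <- pp[!unk]
    pp[, interval := off_year - par_year]
    neg <- pp$interval <= 0
    if (any(neg)) {
      skipped["nonpositive"] <- sum(neg)
      warning(sum(neg), " parent-offspring pair(s) with non-positive interval excluded",
              call. = FALSE)
      pp <- pp[!neg]
    }
    if (!is.null(year_range))
      pp <- pp[off_year >= year_range[1] & off_year <= year_range[2]]
  }
  pp[, pathway := paste0(role, "_of_", ifelse(off_sex == "male", "bulls", "cows"))]
  out <- pp[, .(mean_interval = mean(interval), n_offspring = .N),
            by = .(pathway, year = off_year)]
  data.table::setorder(out, pathway, year)
  data.table::setattr(out, "skipped", skipped)
  out[]
}

#' Effective population size from pedigree inbreeding trends
#'
#' Annual mean inbreeding is windowed into generation-length cohorts; the
#' per-generation inbreeding rate at each cohort boundary comes from the
#' change in ln(1 - F) between consecutive cohorts (the two-point form of
#' the log-linear rate regression used throughout the package), rescaled
#' from window length to generation length when the two differ, and
#' Ne = 1 / (2 * dF_gen). A non-positive rate is reported as an infinite-Ne
#' flag rather than a number.
#'
#' @param inbreeding named numeric vector of per-animal inbreeding (e.g. from
#'   [compute_fped()]).
#' @param ped the matching [pedigree] (for birth years).
#' @param window_years cohort window width in years (default 5).
#' @param gi_years generation interval in years used to scale rates
#'   (default 5).
#' @param min_n minimum animals per window for the window to count.
#' @return data.table with one row per cohort boundary: `cohort` (label of
#'   the later window), `t` (cohort index), `mean_f`, `delta_f_gen`, `ne`,
#'   `flag` (`""` or `"infinite_ne"`).
#' @export
pedigree_ne <- function(inbreeding, ped, window_years = 5, gi_years = 5,
                        min_n = 10) {
  stopifnot(inherits(ped, "pedigree"), window_years > 0, gi_years > 0)
  dt <- data.table::data.table(f = unname(inbreeding[ped$animal_id]),
                               year = ped$birth_year)
  dt <- dt[!is.na(year)]
  if (!nrow(dt)) stop_hd("no animals with birth years for pedigree Ne")
  y0 <- min(dt$year)
  dt[, win := (year - y0) %/% window_years]
  ann <- dt[, .(mean_f = mean(f), n = .N), by = .(win, year)]
  coh <- ann[, .(mean_f = mean(mean_f), n = sum(n)), by = win]
  coh <- coh[n >= min_n]
  data.table::setorder(coh, win)
  if (nrow(coh) < 2)
    stop_hd("pedigree Ne needs at least 2 windows with >= ", min_n, " animals")
  lab <- function(w) sprintf("%d-%d", y0 + w * window_years,
                             y0 + (w + 1) * window_years - 1)
  dly <- diff(log1p(-coh$mean_f))            # per-window change in ln(1-F)
  df_win <- 1 - exp(dly)
  df_gen <- 1 - (1 - df_win)^(gi_years / window_years)
  out <- data.table::data.table(
    cohort = lab(coh$win[-1]), t = seq_along(df_gen),
    mean_f = coh$mean_f[-1], delta_f_gen = df_gen,
    ne = ifelse(df_gen > 0, 1 / (2 * df_gen), NA_real_),
    flag = ifelse(df_gen > 0, "", "infinite_ne"))
  out[]
}
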