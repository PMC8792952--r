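# Inbreeding-rate statistics: annual and per-generation rates from the
# log-linear regression of ln(1 - mean F) on birth year, the segmented
# two-era model contrasting progeny-test (PTS) and genomic-selection (GS)
# cohorts, and the two-sample cohort comparison.

#' Annual inbreeding rate from yearly mean inbreeding
#'
#' Ordinary least squares of ln(1 - x) on birth year, where x is the annual
#' mean of the inbreeding coefficient; under the classical recursion
#' (1 - F_t) = (1 - dF)^t the slope b satisfies dF = 1 - exp(b), which is
#' the default rate convention (`"exp"`). The first-order alternative
#' dF = -b is available as `"neg-slope"`.
#'
#' @param years integer vector of birth years.
#' @param means aligned annual mean inbreeding values, each in `[0, 1)`.
#' @param convention `"exp"` (default) or `"neg-slope"`.
#' @param min_n_years minimum number of years (default 3).
#' @return List with `slope` (per-year slope of ln(1 - x)), `delta_f_year`,
#'   `convention`, `n_years`.
#' @export
delta_f_per_year <- function(years, means, convention = c("exp", "neg-slope"),
                             min_n_years = 3) {
  convention <- match.arg(convention)
  stopifnot(length(years) == length(means))
  keep <- !is.na(years) & !is.na(means)
  years <- years[keep]; means <- means[keep]
  if (length(years) < min_n_years)
    stop_hd("need at least ", min_n_years, " annual means")
  if (any(means >= 1) || any(means < 0))
    stop_hd("annual mean inbreeding must lie in [0, 1)")
  fit <- lm(log1p(-means) ~ years)
  b <- unname(coef(fit)[2])
  dfy <- if (convention == "exp") 1 - exp(b) else -b
  list(slope = b, delta_f_year = dfy, convention = convention,
       n_years = length(years))
}

#' Per-generation inbreeding rate
#'
#' The annual rate multiplied by the generation interval in years.
#'
#' @param delta_f_year annual inbreeding rate.
#' @param gi_years generation interval (> 0), e.g. 5 for dairy cattle.
#' @return Rate per generation.
#' @export
delta_f_per_generation <- function(delta_f_year, gi_years) {
  stopifnot(gi_years > 0)
  delta_f_year * gi_years
}

#' Segmented two-era inbreeding trend model
#'
#' Fits, over the animals of two 5-year birth cohorts (pre- and post-GS;
#' gap years excluded), the segmented regression
#' `value = a + b_PTS * year` in the first era and
#' `value = a' + (b_PTS + delta) * year` in the second, and tests the
#' slope shift `delta` by the model ANOVA. By default each era has its own
#' intercept, so `delta` is the pure within-era slope contrast
#' (`b_GS - b_PTS`) -- the only reading under which published worked
#' values of the form `b_GS = b_PTS + delta` and `RC = delta/b` are
#' self-consistent. Setting `shared_intercept = TRUE` constrains both era
#' lines through one intercept at year 0, the literal single-alpha form;
#' on era-continuous field data that constraint makes `delta` absorb
#' level differences and is rarely what is wanted (see the vignette).
#' The relative change RC defaults to `delta / b_PTS`; `rc_denominator =
#' "gs"` divides by the second-period slope `b_GS` instead.
#'
#' @param birth_year,value aligned per-animal vectors.
#' @param pts_range,gs_range inclusive year ranges of the two cohorts
#'   (defaults 2006-2010 and 2015-2019).
#' @param rc_denominator `"pts"` (default) or `"gs"`.
#' @param shared_intercept constrain both eras to one year-0 intercept
#'   (default `FALSE`).
#' @return List of class `trend_fit`: `beta_pts`, `beta_gs`, `delta`,
#'   `p_delta`, `rc`, `alpha1`, `n_pts`, `n_gs`, `model`.
#' @export
segmented_gs_model <- function(birth_year, value,
                               pts_range = c(2006, 2010),
                               gs_range = c(2015, 2019),
                               rc_denominator = c("pts", "gs"),
                               shared_intercept = FALSE) {
  rc_denominator <- match.arg(rc_denominator)
  stopifnot(length(birth_year) == length(value))
  in_pts <- !is.na(birth_year) & birth_year >= pts_range[1] & birth_year <= pts_range[2]
  in_gs <- !is.na(birth_year) & birth_year >= gs_range[1] & birth_year <= gs_range[2]
  keep <- (in_pts | in_gs) & !is.na(value)
  x <- birth_year[keep]; y <- value[keep]; gs <- in_gs[keep]
  if (sum(!gs) < 2 || sum(gs) < 2)
    stop_hd("each cohort needs at least 2 animals")
  if (length(unique(x[!gs])) < 2 || length(unique(x[gs])) < 2)
    stop_hd("singular design: each cohort needs at least 2 distinct years")
  # the delta term goes last so its sequential ANOVA row is the partial test
  fit <- if (shared_intercept) lm(y ~ x + I(x * gs)) else lm(y ~ x + gs + I(x * gs))
  cf <- coef(fit)
  beta_pts <- unname(cf["x"])
  delta <- unname(cf["I(x * gs)"])
  # a perfect (zero-residual) fit has no valid F test; report NA rather
  # than fail
  p_delta <- tryCatch(suppressWarnings(anova(fit)["I(x * gs)", "Pr(>F)"]),
                      error = function(e) NA_real_)
  if (is.null(p_delta) || is.nan(p_delta)) p_delta <- NA_real_
  beta_gs <- beta_pts + delta
  denom <- if (rc_denominator == "pts") beta_pts else beta_gs
  rc <- if (delta == 0) 0 else delta / denom
  structure(list(beta_pts = beta_pts, beta_gs = beta_gs, delta = delta,
                 p_delta = p_delta, rc = rc, alpha1 = unname(cf["(Intercept)"]),
                 n_pts = sum(!gs), n_gs = sum(gs), model = fit),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(paste0("<trend_fit> beta_PTS = %.5g, beta_GS = %.5g, ",
                     "delta = %.5g (p = %.3g), RC = %.3g\n"),
              x$beta_pts, x$beta_gs, x$delta, x$p_delta, x$rc))
  invisible(x)
}

#' Compare inbreeding between two birth cohorts
#'
#' Welch two-sample t-test on the per-animal values of the two eras.
#'
#' @param values_pts,values_gs numeric vectors (each n >= 2).
#' @return List with `mean_pts`, `mean_gs`, `t`, `df`, `p`.
#' @export
cohort_comparison <- function(values_pts, values_gs) {
  stopifnot(length(values_pts) >= 2, length(values_gs) >= 2)
  if (sd(values_pts) == 0 && sd(values_gs) == 0) {
    if (mean(values_pts) == mean(values_gs))
      return(list(mean_pts = mean(values_pts), mean_gs = mean(values_gs),
                  t = 0, df = NA_real_, p = 1))
    stop_hd("zero variance in both cohorts with unequal means")
  }
  tt <- stats::t.test(values_pts, values_gs, var.equal = FALSE)
  list(mean_pts = mean(values_pts), mean_gs = mean(values_gs),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Full inbreeding-trend report for one coefficient
#'
#' Convenience wrapper producing the per-year rate, per-generation rate and
#' segmented-model statistics from per-animal data.
#'
#' @param birth_year,value aligned per-animal vectors.
#' @param gi_years generation interval for the per-generation rate.
#' @param pts_range,gs_range cohort year ranges for the segmented model.
#' @param min_n_year years with fewer animals are flagged (not dropped).
#' @param ... passed to [segmented_gs_model()].
#' @return List with `annual` (year, mean, n, flagged), `rate`
#'   ([delta_f_per_year()] output plus `delta_f_gen`), `segmented`
#'   (`trend_fit`), `cohort_test`.
#' @export
trend_report <- function(birth_year, value, gi_years = 5,
                         pts_range = c(2006, 2010), gs_range = c(2015, 2019),
                         min_n_year = 10, ...) {
  dt <- data.table::data.table(year = birth_year, v = value)
  dt <- dt[!is.na(year) & !is.na(v)]
  ann <- dt[, .(mean = mean(v), n = .N), by = year][order(year)]
  ann[, flagged := n < min_n_year]
  rate <- delta_f_per_year(ann$year, ann$mean)
  rate$delta_f_gen <- delta_f_per_generation(rate$delta_f_year, gi_years)
  seg <- segmented_gs_model(birth_year, value, pts_range, gs_range, ...)
  ct <- cohort_comparison(
    value[!is.na(birth_year) & birth_year >= pts_range[1] & birth_year <= pts_range[2]],
    value[!is.na(birth_year) & birth_year >= gs_range[1] & birth_year <= gs_range[2]])
  list(annual = ann[], rate = rate, segmented = seg, cohort_test = ct)
}
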