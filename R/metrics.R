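#' Census a lattice into a metrics record
#'
#' A pure function of the lattice: population size, monokaryon and
#' dikaryon counts, the dikaryotic fraction of occupied sites, per-role
#' mean fitness triples (monokaryon nuclei; dikaryon nucleus 1, the
#' resident "female" haplotype; dikaryon nucleus 2, the fertilizing "male"
#' haplotype), parasitic-nucleus fractions (nuclei allocating more than
#' `parasite_threshold` of their budget to mating fitness) and DMF allele
#' frequencies per role. Ratios with an empty denominator are `NA`, never
#' 0, so an extinct population is distinguishable from, say, an
#' all-monokaryon one.
#'
#' @param lattice a [new_lattice()].
#' @param generation value for the `generation` column.
#' @param parasite_threshold mating-fitness threshold, default `2/3`
#'   (strictly greater counts as parasitic).
#' @return A one-row data frame; fitness triples are flattened to three
#'   columns each (`mean_wv_*`, `mean_wr_*`, `mean_wm_*`).
#' @export
summarize_lattice <- function(lattice, generation = NA_integer_,
                              parasite_threshold = 2 / 3) {
  mono <- lattice$state == 1L
  di <- lattice$state == 2L
  n_mono <- sum(mono)
  n_di <- sum(di)
  pop <- n_mono + n_di
  nuclei <- n_mono + 2L * n_di
  mean_or_na <- function(x, keep) if (any(keep)) mean(x[keep]) else NA_real_
  frac_or_na <- function(x, keep) if (any(keep)) mean(x[keep]) else NA_real_
  para_mono <- lattice$wm1 > parasite_threshold
  para_1 <- lattice$wm1 > parasite_threshold
  para_2 <- lattice$wm2 > parasite_threshold
  n_para <- sum(para_mono[mono]) + sum(para_1[di]) + sum(para_2[di])
  df <- data.frame(
    generation = generation,
    pop_size = pop, n_mono = n_mono, n_di = n_di,
    frac_dikaryotic = if (pop > 0) n_di / pop else NA_real_,
    mean_wv_mono = mean_or_na(lattice$wv1, mono),
    mean_wr_mono = mean_or_na(lattice$wr1, mono),
    mean_wm_mono = mean_or_na(lattice$wm1, mono),
    mean_wv_role1 = mean_or_na(lattice$wv1, di),
    mean_wr_role1 = mean_or_na(lattice$wr1, di),
    mean_wm_role1 = mean_or_na(lattice$wm1, di),
    mean_wv_role2 = mean_or_na(lattice$wv2, di),
    mean_wr_role2 = mean_or_na(lattice$wr2, di),
    mean_wm_role2 = mean_or_na(lattice$wm2, di),
    frac_parasitic = if (nuclei > 0) n_para / nuclei else NA_real_,
    frac_parasitic_mono = frac_or_na(para_mono, mono),
    frac_parasitic_role1 = frac_or_na(para_1, di),
    frac_parasitic_role2 = frac_or_na(para_2, di),
    dmf_freq_mono = frac_or_na(lattice$dmf1 == 1L, mono),
    dmf_freq_role1 = frac_or_na(lattice$dmf1 == 1L, di),
    dmf_freq_role2 = frac_or_na(lattice$dmf2 == 1L, di))
  rownames(df) <- NULL
  df
}

#' Histogram of mating fitness in 10% bins
#'
#' Bins `w_m` values into the ten right-open intervals `[0, 0.1), ...,
#' [0.9, 1.0]` (the top bin is closed so `w_m = 1` is counted). A value
#' exactly on a boundary falls into the upper bin (`w_m = 0.1` lands in
#' the second bin).
#'
#' @param wm numeric vector of mating-fitness values in `[0, 1]`.
#' @return Named integer vector of 10 counts; the counts sum to
#'   `length(wm)`.
#' @export
mating_fitness_histogram <- function(wm) {
  stopifnot(all(wm >= 0 & wm <= 1))
  bin <- pmin(floor(wm / 0.1) + 1L, 10L)
  counts <- tabulate(bin, nbins = 10L)
  names(counts) <- sprintf("[%.1f,%.1f%s", seq(0, 0.9, 0.1),
                           seq(0.1, 1, 0.1),
                           c(rep(")", 9), "]"))
  counts
}

#' Ternary cloud of nuclear fitness triples
#'
#' Collects the raw simplex coordinates of a set of nuclei together with
#' the share of points falling in each corner region (component greater
#' than the threshold, by default `2/3` — the "parasitic" corner for
#' `w_m`).
#'
#' @param nuclei a data frame with columns `w_v`, `w_r`, `w_m` (e.g. from
#'   [nuclei_table()]), or a numeric `n x 3` matrix.
#' @param threshold corner-region threshold (strict), default `2/3`.
#' @return A list with `points` (an `n x 3` matrix) and `corner_shares`
#'   (named vector over `vegetative`, `reproductive`, `mating`).
#' @export
ternary_cloud <- function(nuclei, threshold = 2 / 3) {
  pts <- if (is.matrix(nuclei)) nuclei
         else cbind(w_v = nuclei$w_v, w_r = nuclei$w_r, w_m = nuclei$w_m)
  colnames(pts) <- c("w_v", "w_r", "w_m")
  n <- nrow(pts)
  shares <- if (n > 0) colMeans(pts > threshold) else rep(NA_real_, 3L)
  names(shares) <- c("vegetative", "reproductive", "mating")
  list(points = pts, corner_shares = shares)
}

#' Generation at which a fitness series returns to its baseline after a peak
#'
#' Finds the peak of a per-generation series at or after the baseline
#' generation and returns the first later generation at which the series
#' has fallen back to (or below) its baseline value. Used to time the
#' purge of an initial rise, e.g. of mean female-role mating fitness.
#'
#' @param x numeric series indexed by generation (element `g` is
#'   generation `g`).
#' @param baseline_gen generation whose value defines the baseline
#'   (default 10).
#' @return The return generation, or `NA` if the series has not fallen
#'   back to its baseline by the end (a censored observation).
#' @export
peak_return_generation <- function(x, baseline_gen = 10L) {
  n <- length(x)
  if (n < baseline_gen) return(NA_integer_)
  base <- x[baseline_gen]
  if (is.na(base)) return(NA_integer_)
  tail_x <- x[baseline_gen:n]
  if (all(is.na(tail_x))) return(NA_integer_)
  pk <- which.max(tail_x) + baseline_gen - 1L
  after <- x[pk:n]
  hit <- which(!is.na(after) & after <= base)
  if (!length(hit)) return(NA_integer_)
  as.integer(pk + hit[1] - 1L)
}

#' First generation from which a series stays below a threshold
#'
#' Returns the earliest generation `g` such that the series is below
#' `threshold` at `g` and at every later generation; `NA` values count as
#' violations. Used to time the purge of parasitic nuclei (e.g. the
#' female-role parasite fraction staying below 5%).
#'
#' @param x numeric series indexed by generation.
#' @param threshold strict upper bound.
#' @return The settling generation (1 if the series never reaches the
#'   threshold at all), or `NA` if it is still at or above the threshold
#'   at the end of the series.
#' @export
sustained_below <- function(x, threshold) {
  bad <- which(is.na(x) | x >= threshold)
  if (!length(bad)) return(1L)
  if (bad[length(bad)] == length(x)) return(NA_integer_)
  as.integer(bad[length(bad)] + 1L)
}
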