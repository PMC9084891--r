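#' Describe a simulation experiment
#'
#' An experiment is a base parameter set, an explicit list of swept
#' parameter combinations and a set of replicate seeds. Sweeps are
#' explicit combination tables, not factorial closures: pass either a
#' named list of value vectors (crossed with `expand.grid`) or a data
#' frame whose rows are the exact combinations to run.
#'
#' @param name short experiment label.
#' @param base a [sim_params()] object.
#' @param sweep named list of parameter value vectors, or a data frame of
#'   combinations; empty for a single-condition experiment.
#' @param seeds integer vector of replicate seeds (>= 1 seed).
#' @return A list of class `"experiment_spec"`.
#' @export
experiment_spec <- function(name, base, sweep = list(), seeds = 1:4) {
  stopifnot(inherits(base, "sim_params"), length(seeds) >= 1L)
  combos <- if (is.data.frame(sweep)) sweep
            else if (length(sweep)) expand.grid(sweep, KEEP.OUT.ATTRS = FALSE)
            else data.frame(row.names = 1L)[, FALSE, drop = FALSE]
  if (nrow(combos) == 0L) combos <- combos[1L, , drop = FALSE]
  structure(list(name = name, base = base, combos = combos,
                 seeds = as.integer(seeds)),
            class = "experiment_spec")
}

#' Run an experiment panel
#'
#' Runs one simulation per parameter combination and seed and returns the
#' concatenated per-generation metrics in long format, with the combo
#' identifiers, the seed and an `extinct` flag attached. Extinct runs are
#' recorded, not dropped, so survival can be tabulated separately from
#' fitness averages.
#'
#' @param spec an [experiment_spec()].
#' @param keep_final_lattices logical; also return the final lattices
#'   (one per run) as an attribute `"lattices"`?
#' @return A long data frame of metrics rows.
#' @export
run_panel <- function(spec, keep_final_lattices = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  out <- vector("list", nrow(spec$combos) * length(spec$seeds))
  lats <- if (keep_final_lattices) list() else NULL
  k <- 0L
  for (ci in seq_len(nrow(spec$combos))) {
    overrides <- as.list(spec$combos[ci, , drop = FALSE])
    for (seed in spec$seeds) {
      k <- k + 1L
      p <- do.call(update_params,
                   c(list(spec$base), overrides, list(seed = seed)))
      sim <- run_simulation(p)
      m <- sim$metrics
      for (nm in names(overrides)) m[[nm]] <- overrides[[nm]]
      m$seed <- seed
      m$extinct <- !is.na(sim$extinct_gen)
      out[[k]] <- m
      if (keep_final_lattices) lats[[k]] <- sim$lattice
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (keep_final_lattices) attr(res, "lattices") <- lats
  res
}

#' DMF-allele invasion competition
#'
#' Competes nuclei with and without the dikaryotic-male-function (DMF)
#' allele in the standard-dikaryon scenario. The mating-type space is
#' split into a DMF-carrying class and a non-carrying class (by default
#' 15 of `m = 30` types carry the allele, linked to the mating locus);
#' founder fitness is drawn from the same distribution for both classes.
#' Per generation the returned series track the DMF allele frequency and
#' the parasitic-nucleus fraction separately for the female (nucleus 1)
#' and male (nucleus 2) dikaryon roles, plus the population size.
#'
#' @param base a [sim_params()] object; scenario is forced to
#'   `"standard"` and the DMF class structure applied on top.
#' @param start_props initial DMF class proportions to compete.
#' @param dmf_modes DMF expression modes to run (`"dominant"`,
#'   `"codominant"`, `"recessive"`).
#' @param seeds replicate seeds.
#' @param dmf_types mating types carrying the allele.
#' @return A long data frame of per-generation metrics with `start_prop`,
#'   `dmf_mode`, `seed` and `extinct` columns.
#' @export
run_dmf_competition <- function(base,
                                start_props = c(0.1, 0.5, 0.9),
                                dmf_modes = c("dominant", "codominant"),
                                seeds = 1:4,
                                dmf_types = 0:14) {
  stopifnot(inherits(base, "sim_params"))
  combos <- expand.grid(start_prop = start_props, dmf_mode = dmf_modes,
                        stringsAsFactors = FALSE)
  out <- list()
  for (ci in seq_len(nrow(combos))) {
    for (seed in seeds) {
      p <- update_params(base, scenario = "standard",
                         dmf_mode = combos$dmf_mode[ci],
                         dmf_types = dmf_types,
                         dmf_start_prop = combos$start_prop[ci],
                         seed = seed)
      sim <- run_simulation(p)
      m <- sim$metrics
      m$start_prop <- combos$start_prop[ci]
      m$dmf_mode <- combos$dmf_mode[ci]
      m$seed <- seed
      m$extinct <- !is.na(sim$extinct_gen)
      out[[length(out) + 1L]] <- m
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Scan genetic and ecological factors against linkage
#'
#' For each level of one factor (`m`, `r`, `g` or `theta`) crossed with a
#' set of linkage values, runs replicate standard-dikaryon simulations
#' and reports the final-generation mating-fitness distribution of all
#' surviving nuclei in 10% bins.
#'
#' @param base a [sim_params()] object (scenario forced to
#'   `"standard"`).
#' @param factor name of the swept parameter: `"m"`, `"r"`, `"g"` or
#'   `"theta"`.
#' @param values values of the swept parameter.
#' @param lam_values linkage values to cross with the factor.
#' @param seeds replicate seeds.
#' @return A long data frame with one row per (factor value, lambda,
#'   seed, bin): columns `factor`, `value`, `lam`, `seed`, `bin`
#'   (bin lower edge), `count`, `n_nuclei`, `extinct`.
#' @export
run_factor_scan <- function(base, factor = c("m", "r", "g", "theta"),
                            values, lam_values = c(0.95, 0.99, 1),
                            seeds = 1:4) {
  factor <- match.arg(factor)
  stopifnot(inherits(base, "sim_params"))
  out <- list()
  for (v in values) {
    for (lam in lam_values) {
      for (seed in seeds) {
        overrides <- stats::setNames(list(v), factor)
        p <- do.call(update_params,
                     c(list(base), overrides,
                       list(scenario = "standard", lam = lam, seed = seed)))
        sim <- run_simulation(p)
        wm <- sim$nuclei$w_m
        counts <- mating_fitness_histogram(if (length(wm)) wm else numeric(0))
        out[[length(out) + 1L]] <- data.frame(
          factor = factor, value = v, lam = lam, seed = seed,
          bin = seq(0, 0.9, 0.1), count = as.integer(counts),
          n_nuclei = length(wm), extinct = !is.na(sim$extinct_gen),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
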