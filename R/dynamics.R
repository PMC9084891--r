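.metrics_cols <- c(
  "pop_size", "n_mono", "n_di", "frac_dikaryotic",
  "mean_wv_mono", "mean_wr_mono", "mean_wm_mono",
  "mean_wv_role1", "mean_wr_role1", "mean_wm_role1",
  "mean_wv_role2", "mean_wr_role2", "mean_wm_role2",
  "frac_parasitic", "frac_parasitic_mono",
  "frac_parasitic_role1", "frac_parasitic_role2",
  "dmf_freq_mono", "dmf_freq_role1", "dmf_freq_role2")

.reclass_lattice <- function(lat) {
  class(lat) <- "dik_lattice"
  lat
}

.metrics_df <- function(mat, generations) {
  df <- as.data.frame(mat)
  names(df) <- .metrics_cols
  cbind(data.frame(generation = generations), df)
}

#' Expressed vegetative growth rate of a site
#'
#' A monokaryon grows into neighbouring empty sites at rate `g * w_v`. A
#' dikaryon expresses a dominance-weighted blend of its two nuclei:
#' `g * (w_v_max * Theta + w_v_min * (1 - Theta))`, where `Theta = 1` is
#' full dominance of the fitter nucleus and `Theta = 0` full recessivity.
#'
#' @param site a SiteState from [get_site()] (non-empty).
#' @param params a [sim_params()] object (fields `g` and `theta` used).
#' @return The growth rate, used as a per-opportunity colonization
#'   probability.
#' @export
vegetative_rate <- function(site, params) {
  if (site$tag == "empty") stop("empty site has no growth rate")
  if (site$tag == "monokaryon")
    return(params$g * site$nucleus1$fitness[[1]])
  wv <- c(site$nucleus1$fitness[[1]], site$nucleus2$fitness[[1]])
  params$g * (max(wv) * params$theta + min(wv) * (1 - params$theta))
}

#' Expressed spore production rate of a site
#'
#' Only dikaryons produce spores; a monokaryon's reproductive fitness has
#' an effective value of zero. A dikaryon sporulates at rate
#' `r*(w_r_max*Theta + w_r_min*(1-Theta))`.
#'
#' @param site a SiteState from [get_site()] (non-empty).
#' @param params a [sim_params()] object (fields `r` and `theta` used).
#' @return The expected spore count per elementary step in which the site
#'   is chosen.
#' @export
reproductive_rate <- function(site, params) {
  if (site$tag == "empty") stop("empty site has no reproduction rate")
  if (site$tag == "monokaryon") return(0)
  wr <- c(site$nucleus1$fitness[[2]], site$nucleus2$fitness[[2]])
  params$r * (max(wr) * params$theta + min(wr) * (1 - params$theta))
}

#' One elementary updating step
#'
#' Performs a single updating step of the asynchronous lattice dynamics.
#' A site is chosen (uniformly at random, or fixed via `site` for
#' controlled experiments). If it is occupied it dies with probability
#' `d`; if it survives it attempts mating in the female role (monokaryons
#' in all scenarios; dikaryons only under the open scenario), and if it is
#' then dikaryotic it sporulates, drawing a Poisson number of spores with
#' mean equal to its [reproductive_rate()] and scattering them uniformly
#' over the Chebyshev ball of radius `disp_radius` (centre excluded). If
#' the chosen site is empty and habitable, the eight neighbouring mycelia
#' compete to occupy it: each succeeds independently with probability
#' equal to its [vegetative_rate()] and the winner is drawn among the
#' successes proportionally to that rate.
#'
#' @param lattice a [new_lattice()].
#' @param params a [sim_params()] object.
#' @param site optional fixed 1-based site index; `NULL` chooses
#'   uniformly at random.
#' @return A list with the updated `lattice`, the `spores` produced during
#'   this step (a data frame destined for the generation's spore bank) and
#'   the chosen `site`.
#' @export
elementary_step <- function(lattice, params, site = NULL) {
  res <- .cpp_step_at(lattice, .engine_par(params),
                      if (is.null(site)) 0L else as.integer(site))
  list(lattice = .reclass_lattice(res$lattice), spores = res$spores,
       site = res$site)
}

#' Germinate the spore bank
#'
#' Called once per generation after all elementary steps: on every empty
#' habitable site that received at least one spore, a single survivor is
#' chosen uniformly at random and germinates into a monokaryon; spores on
#' occupied or uninhabitable sites are discarded, and the bank is cleared.
#'
#' @param lattice a [new_lattice()].
#' @param spores data frame of banked spores (as produced by
#'   [elementary_step()]).
#' @return The updated lattice.
#' @export
germinate <- function(lattice, spores) {
  .reclass_lattice(.cpp_germinate(lattice, spores))
}

#' Run one generation
#'
#' One generation consists of `width * height` elementary updating steps
#' followed by germination of the spore bank and a metrics census.
#'
#' @param lattice a [new_lattice()].
#' @param params a [sim_params()] object.
#' @return A list with the updated `lattice` and a one-row `metrics` data
#'   frame (see [summarize_lattice()] for the columns).
#' @export
run_generation <- function(lattice, params) {
  res <- .cpp_run_sim(lattice, .engine_par(params), 1L)
  list(lattice = .reclass_lattice(res$lattice),
       metrics = .metrics_df(res$metrics, NA_integer_))
}

#' Run a full simulation
#'
#' Inoculates a lattice (unless one is supplied), runs `n_generations`
#' generations and collects per-generation metrics. If `params$seed` is
#' set, the RNG is seeded first; identical parameters and seed yield an
#' identical trajectory.
#'
#' @param params a [sim_params()] object.
#' @param lattice optional pre-built initial lattice; default
#'   [init_lattice()] under `params`.
#' @return An object of class `"dikaryon_sim"`: a list with `params`, the
#'   `metrics` data frame (generation 0 is the initial census), the final
#'   `lattice`, the final `nuclei` table, an `events` data frame of
#'   per-generation event tallies (deaths, colonizations, matings by
#'   class, spores, germinations) and `extinct_gen` (first generation
#'   with an empty population, `NA` if the population survived).
#' @examples
#' p <- sim_params(scenario = "standard", width = 40, height = 40,
#'                 n_generations = 10, seed = 1)
#' sim <- run_simulation(p)
#' summary(sim)
#' @export
run_simulation <- function(params, lattice = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  if (is.null(lattice)) lattice <- init_lattice(params)
  gen0 <- summarize_lattice(lattice, generation = 0L,
                            parasite_threshold = params$parasite_threshold)
  if (params$n_generations == 0L) {
    metrics <- gen0
    final <- lattice
    events <- NULL
  } else {
    res <- .cpp_run_sim(lattice, .engine_par(params), params$n_generations)
    metrics <- rbind(gen0,
                     .metrics_df(res$metrics, seq_len(params$n_generations)))
    final <- .reclass_lattice(res$lattice)
    events <- as.data.frame(res$events)
    names(events) <- c("deaths", "colonizations", "monmon_matings",
                       "dimon_matings", "didi_matings", "monodi_matings",
                       "spores", "germinations")
    events <- cbind(data.frame(generation = seq_len(params$n_generations)),
                    events)
  }
  rownames(metrics) <- NULL
  dead <- which(metrics$pop_size == 0)
  structure(
    list(params = params, metrics = metrics, lattice = final,
         nuclei = nuclei_table(final, params$n_generations),
         events = events,
         extinct_gen = if (length(dead)) metrics$generation[dead[1]]
                       else NA_integer_),
    class = "dikaryon_sim")
}

#' @export
print.dikaryon_sim <- function(x, ...) {
  last <- x$metrics[nrow(x$metrics), ]
  cat(sprintf(
    "<dikaryon_sim> %s scenario, %d x %d, %d generations\n",
    x$params$scenario, x$params$height, x$params$width,
    x$params$n_generations))
  if (!is.na(x$extinct_gen)) {
    cat(sprintf("  population extinct at generation %d\n", x$extinct_gen))
  } else {
    cat(sprintf(
      "  final population %d sites (%.1f%% dikaryotic), parasitic nuclei %.1f%%\n",
      last$pop_size, 100 * last$frac_dikaryotic, 100 * last$frac_parasitic))
  }
  invisible(x)
}

#' @export
summary.dikaryon_sim <- function(object, ...) {
  m <- object$metrics
  last <- m[nrow(m), ]
  out <- list(
    scenario = object$params$scenario,
    generations = object$params$n_generations,
    extinct_gen = object$extinct_gen,
    final_pop_size = last$pop_size,
    final_frac_dikaryotic = last$frac_dikaryotic,
    final_frac_parasitic = last$frac_parasitic,
    final_mean_wm_role1 = last$mean_wm_role1,
    final_mean_wm_role2 = last$mean_wm_role2,
    final_mean_wm_mono = last$mean_wm_mono)
  class(out) <- "summary.dikaryon_sim"
  out
}

#' @export
print.summary.dikaryon_sim <- function(x, ...) {
  cat(sprintf("Scenario:            %s\n", x$scenario))
  cat(sprintf("Generations:         %d\n", x$generations))
  if (!is.na(x$extinct_gen))
    cat(sprintf("Extinct at:          generation %d\n", x$extinct_gen))
  cat(sprintf("Final population:    %s sites\n",
              format(x$final_pop_size, big.mark = ",")))
  cat(sprintf("Dikaryotic fraction: %s\n", .fmt_frac(x$final_frac_dikaryotic)))
  cat(sprintf("Parasitic nuclei:    %s\n", .fmt_frac(x$final_frac_parasitic)))
  cat(sprintf("Mean w_m (female / male / mono): %s / %s / %s\n",
              .fmt_frac(x$final_mean_wm_role1),
              .fmt_frac(x$final_mean_wm_role2),
              .fmt_frac(x$final_mean_wm_mono)))
  invisible(x)
}

.fmt_frac <- function(x) {
  if (is.na(x)) "NA" else sprintf("%.3f", x)
}
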