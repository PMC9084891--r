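#' Simulation parameters
#'
#' Collects and validates all model constants and scenario switches.
#' Defaults follow the base parameterisation used throughout the model
#' analyses: `g = 0.1`, `r=1`, `d = 0.3`, `sigma = 0.01`, a 300 x 300
#' torus run for 1000 generations, inoculated on two thirds of the
#' habitable sites (a 300 x 300 grid thus starts with 60,000 founder
#' monokaryons).
#'
#' @param scenario life-cycle scenario: `"diploid"` (mon-mon matings only),
#'   `"standard"` (mon-mon and di-mon) or `"open"` (mon-mon, di-mon and
#'   di-di).
#' @param width,height lattice dimensions in sites (>= 3; outcomes get
#'   strongly stochastic below about 150 sites per side).
#' @param m number of mating types (>= 2).
#' @param g basic mycelial growth rate; a monokaryon's colonization
#'   probability per opportunity is `g * w_v`.
#' @param r basic spore production rate; a dikaryon's expected spore count
#'   per chosen site per step is `r*W_r`.
#' @param d death probability of a chosen occupied site per elementary
#'   step.
#' @param sigma standard deviation of the Gaussian fitness mutation step.
#' @param sigma_init spread of the initial fitness cloud around the
#'   barycentre.
#' @param beta trade-off exponent; `beta = 1` is the linear budget
#'   `w_v + w_r + w_m = 1`.
#' @param lam linkage parameter `lambda` in `[0, 1]`: 0 polygenic
#'   (blending) inheritance, 1 monogenic (Mendelian) inheritance.
#' @param theta phenotypic dominance `Theta` in `[0, 1]` of the fitter
#'   nucleus in a dikaryon's expressed vegetative/reproductive rates
#'   (0 recessive, 0.5 codominant, 1 fully dominant).
#' @param disp_radius spore dispersal radius in sites (Chebyshev metric).
#' @param n_generations number of generations; one generation is
#'   `width * height` elementary updating steps followed by germination.
#' @param init_occupied number of inoculated founder sites; default two
#'   thirds of the habitable sites.
#' @param seed optional RNG seed applied by [run_simulation()].
#' @param dmf_mode dikaryotic-male-function allele mode for di-mon
#'   matings: `"off"` (all dikaryon nuclei may fertilize), `"dominant"`,
#'   `"codominant"` or `"recessive"`.
#' @param dmf_types integer vector of mating types whose founders carry
#'   the DMF allele (used by competition experiments; empty = no DMF
#'   bookkeeping).
#' @param dmf_start_prop probability that a founder nucleus belongs to
#'   the DMF-carrying class.
#' @param patch_size optional habitable patch side for fragmentation
#'   experiments (see [build_patch_mask()]); `NULL` = uniform habitat.
#' @param patch_gap uninhabitable strip width between patches.
#' @param open_mono_fertilizes_di in the open scenario, may a monokaryon
#'   nucleus fertilize an established dikaryon (displacing one resident)?
#'   Set `FALSE` to restrict strictly to mon-mon, di-mon and di-di.
#' @param dimon_converts_donor in a di-mon mating, does the winning pair
#'   spread over both affected mycelia, rewriting the donor dikaryon's
#'   territory and evicting its losing partner nucleus (the default,
#'   which makes the fertilization race a genuine within-dikaryon
#'   competition)?  Set `FALSE` to leave the donor mycelium unchanged,
#'   as in a natural Buller mating where the donor persists.
#' @param spores_per_basidium number of meiotic spores released per
#'   sporulation event; basidia release tetrads, so the default is 4.
#'   The expected spore output of a visited dikaryon is
#'   `spores_per_basidium * r * W_r`.
#' @param spore_blanket alternative fecundity/dispersal reading: a
#'   sporulation event fires with probability `r*W_r` and drops one
#'   spore on every site of the dispersal ball instead of drawing a
#'   Poisson count; default `FALSE`.
#' @param parasite_threshold mating-fitness level above which a nucleus is
#'   counted as parasitic; default `2/3`.
#' @return A validated list of class `"sim_params"`.
#' @examples
#' p <- sim_params(scenario = "standard", width = 60, height = 60,
#'                 n_generations = 20, seed = 1)
#' @export
sim_params <- function(scenario = c("standard", "diploid", "open"),
                       width = 300L, height = 300L, m = 30L,
                       g = 0.1, r = 1, d = 0.3,
                       sigma = 0.01, sigma_init = 0.1, beta = 1,
                       lam = 1, theta = 0.5,
                       disp_radius = 3L, n_generations = 1000L,
                       init_occupied = NULL, seed = NULL,
                       dmf_mode = c("off", "dominant", "codominant",
                                    "recessive"),
                       dmf_types = integer(0), dmf_start_prop = 0.5,
                       patch_size = NULL, patch_gap = 1L,
                       open_mono_fertilizes_di = TRUE,
                       dimon_converts_donor = TRUE,
                       spores_per_basidium = 4L,
                       spore_blanket = FALSE,
                       parasite_threshold = 2 / 3) {
  scenario <- match.arg(scenario)
  dmf_mode <- match.arg(dmf_mode)
  width <- as.integer(width); height <- as.integer(height)
  stopifnot(width >= 3L, height >= 3L, m >= 2L,
            g >= 0, r >= 0, d >= 0, d <= 1,
            sigma >= 0, sigma_init >= 0, beta > 0,
            lam >= 0, lam <= 1, theta >= 0, theta <= 1,
            disp_radius >= 1L, n_generations >= 0L,
            dmf_start_prop >= 0, dmf_start_prop <= 1,
            spores_per_basidium >= 1L,
            parasite_threshold >= 0, parasite_threshold <= 1)
  if (length(dmf_types) > 0L) {
    dmf_types <- as.integer(dmf_types)
    if (any(dmf_types < 0L | dmf_types >= m))
      stop("dmf_types must be mating types in [0, m)")
  }
  n_habitable <- if (!is.null(patch_size))
    sum(build_patch_mask(width, height, patch_size, patch_gap))
  else width * height
  if (is.null(init_occupied)) init_occupied <- round(2 / 3 * n_habitable)
  init_occupied <- as.integer(init_occupied)
  if (init_occupied > n_habitable)
    stop("init_occupied exceeds the number of habitable sites")
  structure(
    list(scenario = scenario, width = width, height = height,
         m = as.integer(m), g = g, r = r, d = d,
         sigma = sigma, sigma_init = sigma_init, beta = beta,
         lam = lam, theta = theta,
         disp_radius = as.integer(disp_radius),
         n_generations = as.integer(n_generations),
         init_occupied = init_occupied, seed = seed,
         dmf_mode = dmf_mode, dmf_types = dmf_types,
         dmf_start_prop = dmf_start_prop,
         patch_size = patch_size, patch_gap = as.integer(patch_gap),
         open_mono_fertilizes_di = isTRUE(open_mono_fertilizes_di),
         dimon_converts_donor = isTRUE(dimon_converts_donor),
         spores_per_basidium = as.integer(spores_per_basidium),
         spore_blanket = isTRUE(spore_blanket),
         parasite_threshold = parasite_threshold),
    class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_params> %s scenario, %d x %d torus, m = %d\n",
           "  g = %g, r = %g, d = %g, sigma = %g, beta = %g\n",
           "  lambda = %g, theta = %g, dispersal radius = %d\n",
           "  %d generations, %d founder sites, dmf_mode = %s\n"),
    x$scenario, x$height, x$width, x$m, x$g, x$r, x$d, x$sigma, x$beta,
    x$lam, x$theta, x$disp_radius, x$n_generations, x$init_occupied,
    x$dmf_mode))
  invisible(x)
}

#' Update simulation parameters
#'
#' Returns a copy of `params` with the named fields replaced and the
#' result revalidated, so derived defaults (like `init_occupied`) stay
#' consistent when the grid or habitat changes.
#'
#' @param params a [sim_params()] object.
#' @param ... named fields to replace; `init_occupied` is re-derived
#'   unless supplied explicitly.
#' @return A [sim_params()] object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "sim_params"))
  new <- list(...)
  args <- unclass(params)
  geometry_changed <- any(c("width", "height", "patch_size", "patch_gap")
                          %in% names(new))
  if (geometry_changed && !"init_occupied" %in% names(new))
    args$init_occupied <- NULL
  args[names(new)] <- new
  do.call(sim_params, args)
}

# flat list consumed by the compiled engine
.engine_par <- function(params) {
  list(scenario_code = match(params$scenario,
                             c("diploid", "standard", "open")) - 1L,
       g = params$g, r = params$r, d = params$d,
       sigma = params$sigma, beta = params$beta,
       lam = params$lam, theta = params$theta,
       disp_radius = params$disp_radius,
       dmf_mode_code = match(params$dmf_mode,
                             c("off", "dominant", "codominant",
                               "recessive")) - 1L,
       open_mono_fertilizes_di = params$open_mono_fertilizes_di,
       dimon_converts_donor = params$dimon_converts_donor,
       spore_blanket = params$spore_blanket,
       spores_per_basidium = params$spores_per_basidium,
       parasite_threshold = params$parasite_threshold)
}
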