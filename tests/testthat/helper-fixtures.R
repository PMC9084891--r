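# small builders used across the suite; all fixtures are constructed in code

# nucleus with the triple normalised onto the linear trade-off surface
nuc <- function(wv, wr, wm, mt = 0L, dmf = FALSE, lin = 1L) {
  nucleus(c(wv, wr, wm) / (wv + wr + wm), mating_type = mt, dmf = dmf,
          lineage_id = lin)
}

# parameters scaled for unit tests; always override the 300x300 default
tiny_params <- function(...) {
  args <- list(...)
  defaults <- list(width = 21L, height = 21L, n_generations = 5L)
  args <- c(args, defaults[!names(defaults) %in% names(args)])
  if (!"init_occupied" %in% names(args)) {
    args$init_occupied <-
      min(200L, floor(2 / 3 * args$width * args$height))
  }
  do.call(sim_params, args)
}

# total variation distance between an empirical table and exact probs
tv_dist <- function(emp_counts, exact_probs) {
  keys <- union(names(emp_counts), names(exact_probs))
  emp <- emp_counts[keys] / sum(emp_counts)
  emp[is.na(emp)] <- 0
  ex <- exact_probs[keys]
  ex[is.na(ex)] <- 0
  sum(abs(emp - ex)) / 2
}
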