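.tsv_header <- function(con, seed = NULL) {
  ver <- as.character(utils::packageVersion("dikaryosim"))
  writeLines(sprintf("# dikaryosim %s", ver), con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %s", seed), con)
}

#' Write per-generation metrics as TSV
#'
#' One row per generation, columns as in [summarize_lattice()]; undefined
#' ratios are written as `NA`. A comment header records the package
#' version and seed.
#'
#' @param metrics metrics data frame (or a `"dikaryon_sim"` object).
#' @param file output path.
#' @param seed seed to record in the header.
#' @return `file`, invisibly.
#' @export
write_metrics_tsv <- function(metrics, file, seed = NULL) {
  if (inherits(metrics, "dikaryon_sim")) {
    if (is.null(seed)) seed <- metrics$params$seed
    metrics <- metrics$metrics
  }
  con <- file(file, "w")
  on.exit(close(con))
  .tsv_header(con, seed)
  utils::write.table(metrics, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(file)
}

#' Write the nucleus table as TSV
#'
#' One row per nucleus on the lattice with columns `site_row`,
#' `site_col`, `role` (`mono`/`female`/`male`), `w_v`, `w_r`, `w_m`,
#' `mating_type`, `dmf`, `generation`; fitness written with 6 significant
#' digits.
#'
#' @param lattice a [new_lattice()] (or a `"dikaryon_sim"` object, whose
#'   final lattice is used).
#' @param file output path.
#' @param generation generation stamp.
#' @param seed seed to record in the header.
#' @return `file`, invisibly.
#' @export
write_nuclei_tsv <- function(lattice, file, generation = NA_integer_,
                             seed = NULL) {
  if (inherits(lattice, "dikaryon_sim")) {
    if (is.null(seed)) seed <- lattice$params$seed
    if (is.na(generation)) generation <- lattice$params$n_generations
    lattice <- lattice$lattice
  }
  tab <- nuclei_table(lattice, generation)
  tab$w_v <- signif(tab$w_v, 6)
  tab$w_r <- signif(tab$w_r, 6)
  tab$w_m <- signif(tab$w_m, 6)
  con <- file(file, "w")
  on.exit(close(con))
  .tsv_header(con, seed)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(file)
}
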