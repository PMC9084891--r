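#' Enumerate compatible "male" candidate nuclei around a focal site
#'
#' A focal mycelium in the female role surveys its eight neighbouring
#' sites for nuclei that could fertilize it. Candidacy is per contact
#' site: a mycelium touching the focal site on several neighbour sites
#' competes once per contact. Neighbour sites carrying the focal
#' mycelium's own nucleotype are not mates — identical nucleotypes fuse
#' somatically instead. Which nuclei are eligible depends on the
#' life-cycle scenario:
#'
#' * focal monokaryon — nuclei of neighbouring monokaryons of a different
#'   mating type (all scenarios); plus, under `"standard"` and `"open"`,
#'   each compatible nucleus of neighbouring dikaryons (di-mon mating),
#'   filtered by `dmf_mode`: `"dominant"` makes both nuclei eligible if
#'   either carries the DMF allele, `"codominant"` only the carrier
#'   nuclei, `"recessive"` both only if both carry it, `"off"` all.
#' * focal dikaryon (`"open"` scenario only) — both nuclei of neighbouring
#'   dikaryons (di-di mating), and, if `open_mono_fertilizes_di`, the
#'   nuclei of neighbouring monokaryons.
#'
#' @param lattice a [new_lattice()].
#' @param focal linear index of a non-empty site.
#' @param scenario `"diploid"`, `"standard"` or `"open"`.
#' @param dmf_mode `"off"`, `"dominant"`, `"codominant"` or `"recessive"`.
#' @param open_mono_fertilizes_di logical, see [sim_params()].
#' @return A data frame with one row per candidate nucleus: `source_site`,
#'   `source_kind` (`"monokaryon"`/`"dikaryon"`), `which` (nucleus slot at
#'   the source), `w_v`, `w_r`, `w_m`, `mating_type`, `dmf`, `lineage_id`.
#' @export
list_candidates <- function(lattice, focal,
                            scenario = c("standard", "diploid", "open"),
                            dmf_mode = c("off", "dominant", "codominant",
                                         "recessive"),
                            open_mono_fertilizes_di = TRUE) {
  scenario <- match.arg(scenario)
  dmf_mode <- match.arg(dmf_mode)
  if (lattice$state[focal] == 0L) stop("focal site is empty")
  focal_mono <- lattice$state[focal] == 1L
  if (!focal_mono && scenario != "open")
    return(.empty_candidates())
  fmt1 <- lattice$mt1[focal]
  rows <- list()
  add <- function(site, kind, which) {
    sfx <- as.character(which)
    data.frame(
      source_site = site, source_kind = kind, which = which,
      w_v = lattice[[paste0("wv", sfx)]][site],
      w_r = lattice[[paste0("wr", sfx)]][site],
      w_m = lattice[[paste0("wm", sfx)]][site],
      mating_type = lattice[[paste0("mt", sfx)]][site],
      dmf = lattice[[paste0("dmf", sfx)]][site] == 1L,
      lineage_id = lattice[[paste0("lin", sfx)]][site],
      stringsAsFactors = FALSE)
  }
  for (j in neighbors8(lattice, focal)) {
    if (lattice$state[j] == 0L) next
    if (same_genotype(lattice, focal, j)) next
    if (focal_mono) {
      if (lattice$state[j] == 1L) {
        if (lattice$mt1[j] != fmt1)
          rows[[length(rows) + 1L]] <- add(j, "monokaryon", 1L)
      } else if (scenario != "diploid") {
        d1 <- lattice$dmf1[j] == 1L
        d2 <- lattice$dmf2[j] == 1L
        elig <- switch(dmf_mode,
                       off = c(TRUE, TRUE),
                       dominant = rep(d1 || d2, 2L),
                       codominant = c(d1, d2),
                       recessive = rep(d1 && d2, 2L))
        if (elig[1] && lattice$mt1[j] != fmt1)
          rows[[length(rows) + 1L]] <- add(j, "dikaryon", 1L)
        if (elig[2] && lattice$mt2[j] != fmt1)
          rows[[length(rows) + 1L]] <- add(j, "dikaryon", 2L)
      }
    } else {
      if (lattice$state[j] == 2L) {
        rows[[length(rows) + 1L]] <- add(j, "dikaryon", 1L)
        rows[[length(rows) + 1L]] <- add(j, "dikaryon", 2L)
      } else if (open_mono_fertilizes_di) {
        rows[[length(rows) + 1L]] <- add(j, "monokaryon", 1L)
      }
    }
  }
  if (!length(rows)) return(.empty_candidates())
  do.call(rbind, rows)
}

.empty_candidates <- function() {
  data.frame(source_site = integer(0), source_kind = character(0),
             which = integer(0), w_v = numeric(0), w_r = numeric(0),
             w_m = numeric(0), mating_type = integer(0),
             dmf = logical(0), lineage_id = integer(0),
             stringsAsFactors = FALSE)
}

#' Choose the winning male nucleus by mating fitness
#'
#' Candidate `i` wins with probability `w_m(i) / sum(w_m)`; when every
#' candidate has zero mating fitness the choice is uniform.
#'
#' @param candidates a data frame from [list_candidates()] (non-empty).
#' @return The winning row (one-row data frame).
#' @export
choose_male <- function(candidates) {
  n <- nrow(candidates)
  if (n == 0L) stop("no candidates to choose from")
  w <- candidates$w_m
  k <- if (sum(w) > 0) sample.int(n, 1L, prob = w) else sample.int(n, 1L)
  candidates[k, , drop = FALSE]
}

#' Resolve a di-di mating between two nuclear pairs
#'
#' In the open-dikaryon scenario two dikaryons exchange nuclei: among all
#' mating-type-compatible unordered pairs drawn from the four nuclei, pair
#' `{i, j}` is sampled with weight `w_m(i) * w_m(j)` (uniform over
#' compatible pairs if all weights vanish). If the focal pair itself is
#' sampled the mating is a no-op. The winning nucleus originating from the
#' focal (female) side keeps role 1; if both winners come from the donor,
#' roles are assigned at random.
#'
#' @param focal_pair list of the focal dikaryon's two [nucleus()] objects.
#' @param donor_pair list of the donor dikaryon's two [nucleus()] objects.
#' @return A list with `nucleus1`, `nucleus2` and `changed` (`FALSE` when
#'   the focal pair was retained or no compatible pair exists).
#' @export
resolve_di_di <- function(focal_pair, donor_pair) {
  four <- c(focal_pair, donor_pair)
  mts <- vapply(four, function(n) n$mating_type, integer(1))
  wms <- vapply(four, function(n) n$fitness[[3]], numeric(1))
  pairs <- list()
  w <- numeric(0)
  for (i in 1:3) for (j in (i + 1):4) {
    if (mts[i] != mts[j]) {
      pairs[[length(pairs) + 1L]] <- c(i, j)
      w <- c(w, wms[i] * wms[j])
    }
  }
  if (!length(pairs))
    return(list(nucleus1 = focal_pair[[1]], nucleus2 = focal_pair[[2]],
                changed = FALSE))
  k <- if (sum(w) > 0) sample.int(length(pairs), 1L, prob = w)
       else sample.int(length(pairs), 1L)
  pr <- pairs[[k]]
  if (pr[1] == 1L && pr[2] == 2L)
    return(list(nucleus1 = focal_pair[[1]], nucleus2 = focal_pair[[2]],
                changed = FALSE))
  if (pr[1] <= 2L) {
    n1 <- four[[pr[1]]]; n2 <- four[[pr[2]]]
  } else if (runif(1L) < 0.5) {
    n1 <- four[[pr[1]]]; n2 <- four[[pr[2]]]
  } else {
    n1 <- four[[pr[2]]]; n2 <- four[[pr[1]]]
  }
  list(nucleus1 = n1, nucleus2 = n2, changed = TRUE)
}

#' Apply a mating outcome to the lattice
#'
#' The winning pair of nuclei spreads over the spatially connected parts
#' of the affected mycelia, transforming them into the same dikaryon:
#'
#' * mon-mon (focal monokaryon, winner from a monokaryon): both mycelia
#'   become one dikaryon with the focal nucleus in role 1 (female) and
#'   the winner in role 2 (male);
#' * di-mon (focal monokaryon, winner from a dikaryon): by default both
#'   the focal mycelium and the donor dikaryon's mycelium are rewritten
#'   to the new pair, evicting the donor's losing partner nucleus from
#'   its own territory (set `dimon_converts_donor = FALSE` to leave the
#'   donor unchanged, as in a natural Buller mating);
#' * di-di (focal dikaryon, `winner` a [resolve_di_di()] result plus
#'   `donor_site`): both mycelia are rewritten to carry the winning pair.
#'
#' Occupancy is conserved: mating converts site states, it never creates
#' or destroys occupied sites.
#'
#' @param lattice a [new_lattice()].
#' @param focal linear index of the focal (female-role) site.
#' @param winner for a focal monokaryon, a one-row data frame from
#'   [choose_male()]; for di-di, a list with `nucleus1`, `nucleus2`,
#'   `changed` and `donor_site`.
#' @param dimon_converts_donor logical, see [sim_params()].
#' @return The updated lattice.
#' @export
apply_mating <- function(lattice, focal, winner,
                         dimon_converts_donor = TRUE) {
  if (is.data.frame(winner)) {
    if (lattice$state[focal] != 1L)
      stop("candidate-row winners apply to a focal monokaryon")
    female <- get_site(lattice, focal)$nucleus1
    male <- nucleus(c(winner$w_v, winner$w_r, winner$w_m),
                    winner$mating_type, winner$dmf, winner$lineage_id)
    if (male$mating_type == female$mating_type)
      stop("winner is incompatible with the focal nucleus")
    comp <- mycelium_of(lattice, focal)
    if (winner$source_kind == "monokaryon" || dimon_converts_donor)
      comp <- union(comp, mycelium_of(lattice, winner$source_site))
    for (s in comp) lattice <- place_dikaryon(lattice, s, female, male)
    return(lattice)
  }
  if (!isTRUE(winner$changed)) return(lattice)
  comp <- union(mycelium_of(lattice, focal),
                mycelium_of(lattice, winner$donor_site))
  for (s in comp)
    lattice <- place_dikaryon(lattice, s, winner$nucleus1, winner$nucleus2)
  lattice
}
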