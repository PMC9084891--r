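#' Create an empty toroidal lattice
#'
#' The arena is a `height x width` square lattice with toroidal topology:
#' the first and last site of every row and column are neighbours, so the
#' lattice has no edges and every site has exactly eight distinct Moore
#' neighbours (which requires `width >= 3` and `height >= 3`). Each site is
#' empty, a monokaryon (one nucleus) or a dikaryon (resident "female"
#' nucleus 1 plus fertilizing "male" nucleus 2). Uninhabitable sites are
#' always empty; mycelia cannot grow across them, but spores can.
#'
#' Sites are addressed by 1-based linear indices in column-major order
#' (matching R matrix indexing of the `height x width` field matrices).
#'
#' @param width,height lattice dimensions in sites (both >= 3).
#' @param habitable optional logical `height x width` matrix (e.g. from
#'   [build_patch_mask()]); default all habitable.
#' @return A list of class `"dik_lattice"` holding the state matrix
#'   (0 empty, 1 monokaryon, 2 dikaryon), the habitability mask, and one
#'   `height x width` matrix per nucleus field (`wv1 ... lin2`, `NA` where
#'   absent), plus the next free lineage id.
#' @export
new_lattice <- function(width, height, habitable = NULL) {
  stopifnot(width >= 3, height >= 3)
  if (is.null(habitable)) {
    habitable <- matrix(TRUE, height, width)
  } else {
    stopifnot(is.logical(habitable), nrow(habitable) == height,
              ncol(habitable) == width)
  }
  num <- function() matrix(NA_real_, height, width)
  int <- function() matrix(NA_integer_, height, width)
  structure(
    list(state = matrix(0L, height, width), habitable = habitable,
         wv1 = num(), wr1 = num(), wm1 = num(),
         mt1 = int(), dmf1 = int(), lin1 = int(),
         wv2 = num(), wr2 = num(), wm2 = num(),
         mt2 = int(), dmf2 = int(), lin2 = int(),
         next_lineage = 1L),
    class = "dik_lattice")
}

#' @export
print.dik_lattice <- function(x, ...) {
  h <- nrow(x$state); w <- ncol(x$state)
  cat(sprintf(
    "<dik_lattice> %d x %d torus, %d habitable; %d monokaryons, %d dikaryons\n",
    h, w, sum(x$habitable), sum(x$state == 1L), sum(x$state == 2L)))
  invisible(x)
}

#' Habitability mask of periodic square patches
#'
#' Tiles the lattice with habitable `patch_size x patch_size` blocks
#' separated by uninhabitable strips of width `gap`, used to study habitat
#' fragmentation. The tiling is periodic with period `patch_size + gap`
#' and wraps toroidally (partial patches can occur at the wrap when the
#' lattice dimension is not a multiple of the period).
#'
#' @param width,height lattice dimensions.
#' @param patch_size side of the habitable patches (>= 1).
#' @param gap width of the uninhabitable strips (>= 0); `gap = 0` makes
#'   every site habitable.
#' @return A logical `height x width` matrix.
#' @examples
#' sum(build_patch_mask(10, 10, patch_size = 3, gap = 2))  # 36
#' @export
build_patch_mask <- function(width, height, patch_size, gap = 1) {
  stopifnot(patch_size >= 1, gap >= 0)
  if (patch_size + gap > min(width, height))
    stop("patch_size + gap exceeds the lattice dimensions")
  period <- patch_size + gap
  row_ok <- ((seq_len(height) - 1L) %% period) < patch_size
  col_ok <- ((seq_len(width) - 1L) %% period) < patch_size
  outer(row_ok, col_ok, "&")
}

#' Linear site index from row and column
#' @param lattice a [new_lattice()].
#' @param row,col 1-based coordinates.
#' @return 1-based linear (column-major) index.
#' @export
site_index <- function(lattice, row, col) {
  h <- nrow(lattice$state)
  as.integer(row + (col - 1L) * h)
}

#' Row and column of a linear site index
#' @param lattice a [new_lattice()].
#' @param idx 1-based linear index.
#' @return Integer vector `c(row, col)`.
#' @export
site_rowcol <- function(lattice, idx) {
  h <- nrow(lattice$state)
  idx <- as.integer(idx)
  c(row = (idx - 1L) %% h + 1L, col = (idx - 1L) %/% h + 1L)
}

#' Moore neighbourhood on the torus
#'
#' The eight neighbours of a site, with toroidal wrap, in deterministic
#' row-major offset order: `(-1,-1), (-1,0), (-1,+1), (0,-1), (0,+1),
#' (+1,-1), (+1,0), (+1,+1)` relative `(row, col)` offsets.
#'
#' @param lattice a [new_lattice()].
#' @param idx 1-based linear site index.
#' @return Integer vector of 8 distinct linear indices.
#' @export
neighbors8 <- function(lattice, idx) {
  h <- nrow(lattice$state); w <- ncol(lattice$state)
  rc <- site_rowcol(lattice, idx)
  dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  r2 <- (rc[[1]] - 1L + dr) %% h + 1L
  c2 <- (rc[[2]] - 1L + dc) %% w + 1L
  as.integer(r2 + (c2 - 1L) * h)
}

#' Read a site as a SiteState
#'
#' @param lattice a [new_lattice()].
#' @param idx linear site index.
#' @return A list with `tag` (`"empty"`, `"monokaryon"` or `"dikaryon"`),
#'   `nucleus1` (resident/"female" haplotype; `NULL` if empty) and
#'   `nucleus2` (fertilizing/"male" haplotype; `NULL` unless dikaryon).
#' @export
get_site <- function(lattice, idx) {
  st <- lattice$state[idx]
  n1 <- NULL
  n2 <- NULL
  if (st >= 1L)
    n1 <- nucleus(c(lattice$wv1[idx], lattice$wr1[idx], lattice$wm1[idx]),
                  lattice$mt1[idx], lattice$dmf1[idx] == 1L,
                  lattice$lin1[idx])
  if (st == 2L)
    n2 <- nucleus(c(lattice$wv2[idx], lattice$wr2[idx], lattice$wm2[idx]),
                  lattice$mt2[idx], lattice$dmf2[idx] == 1L,
                  lattice$lin2[idx])
  list(tag = c("empty", "monokaryon", "dikaryon")[st + 1L],
       nucleus1 = n1, nucleus2 = n2)
}

.set_nuc <- function(lattice, idx, slot, nuc) {
  sfx <- as.character(slot)
  lattice[[paste0("wv", sfx)]][idx] <- nuc$fitness[[1]]
  lattice[[paste0("wr", sfx)]][idx] <- nuc$fitness[[2]]
  lattice[[paste0("wm", sfx)]][idx] <- nuc$fitness[[3]]
  lattice[[paste0("mt", sfx)]][idx] <- nuc$mating_type
  lattice[[paste0("dmf", sfx)]][idx] <- as.integer(nuc$dmf)
  lattice[[paste0("lin", sfx)]][idx] <- nuc$lineage_id
  lattice
}

.clear_nuc <- function(lattice, idx, slot) {
  sfx <- as.character(slot)
  lattice[[paste0("wv", sfx)]][idx] <- NA_real_
  lattice[[paste0("wr", sfx)]][idx] <- NA_real_
  lattice[[paste0("wm", sfx)]][idx] <- NA_real_
  lattice[[paste0("mt", sfx)]][idx] <- NA_integer_
  lattice[[paste0("dmf", sfx)]][idx] <- NA_integer_
  lattice[[paste0("lin", sfx)]][idx] <- NA_integer_
  lattice
}

#' Place a monokaryon on a site
#' @param lattice a [new_lattice()].
#' @param idx linear site index (must be habitable).
#' @param nuc the resident [nucleus()].
#' @return The updated lattice.
#' @export
place_monokaryon <- function(lattice, idx, nuc) {
  if (!lattice$habitable[idx]) stop("site is uninhabitable")
  lattice$state[idx] <- 1L
  lattice <- .set_nuc(lattice, idx, 1L, nuc)
  .clear_nuc(lattice, idx, 2L)
}

#' Place a dikaryon on a site
#' @param lattice a [new_lattice()].
#' @param idx linear site index (must be habitable).
#' @param nucleus1 resident ("female") nucleus.
#' @param nucleus2 fertilizing ("male") nucleus; must differ from
#'   `nucleus1` in mating type.
#' @return The updated lattice.
#' @export
place_dikaryon <- function(lattice, idx, nucleus1, nucleus2) {
  if (!lattice$habitable[idx]) stop("site is uninhabitable")
  if (nucleus1$mating_type == nucleus2$mating_type)
    stop("dikaryon nuclei must have different mating types")
  lattice$state[idx] <- 2L
  lattice <- .set_nuc(lattice, idx, 1L, nucleus1)
  .set_nuc(lattice, idx, 2L, nucleus2)
}

#' Empty a site
#' @param lattice a [new_lattice()].
#' @param idx linear site index.
#' @return The updated lattice.
#' @export
clear_site <- function(lattice, idx) {
  lattice$state[idx] <- 0L
  lattice <- .clear_nuc(lattice, idx, 1L)
  .clear_nuc(lattice, idx, 2L)
}

#' Do two sites carry the same nucleotype?
#'
#' Two non-empty sites are somatically identical when the multisets of
#' their nuclear lineage ids coincide (one id for a monokaryon, two for a
#' dikaryon). Identical nucleotypes in spatial contact are one mycelium.
#'
#' @param lattice a [new_lattice()].
#' @param i,j linear indices of two non-empty sites.
#' @return Logical.
#' @export
same_genotype <- function(lattice, i, j) {
  si <- lattice$state[i]; sj <- lattice$state[j]
  if (si == 0L || sj == 0L) stop("same_genotype is undefined for empty sites")
  if (si != sj) return(FALSE)
  if (si == 1L) return(lattice$lin1[i] == lattice$lin1[j])
  a <- sort(c(lattice$lin1[i], lattice$lin2[i]))
  b <- sort(c(lattice$lin1[j], lattice$lin2[j]))
  all(a == b)
}

#' Sites of the mycelium containing a site
#'
#' The maximal 8-connected component of sites carrying the same nucleotype
#' as `idx` (see [same_genotype()]). Components never cross uninhabitable
#' sites because those are always empty. This is an equivalence-class
#' query: `idx` is always a member, and every member yields the same set.
#'
#' @param lattice a [new_lattice()].
#' @param idx linear index of a non-empty site.
#' @return Sorted integer vector of linear site indices.
#' @export
mycelium_of <- function(lattice, idx) {
  if (lattice$state[idx] == 0L) stop("empty site has no mycelium")
  seen <- integer(0)
  queue <- idx
  visited <- logical(length(lattice$state))
  visited[idx] <- TRUE
  while (length(queue)) {
    i <- queue[[1]]
    queue <- queue[-1]
    seen <- c(seen, i)
    for (j in neighbors8(lattice, i)) {
      if (!visited[j] && lattice$state[j] != 0L &&
          same_genotype(lattice, idx, j)) {
        visited[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  sort(seen)
}

#' Table of all nuclei on the lattice
#'
#' One row per nucleus: monokaryons contribute one row (`role = "mono"`),
#' dikaryons two (`role = "female"` for nucleus 1, `"male"` for nucleus 2).
#'
#' @param lattice a [new_lattice()].
#' @param generation generation stamp for the `generation` column.
#' @return A data frame with columns `site_row`, `site_col`, `role`,
#'   `w_v`, `w_r`, `w_m`, `mating_type`, `dmf`, `generation`.
#' @export
nuclei_table <- function(lattice, generation = NA_integer_) {
  h <- nrow(lattice$state)
  occ1 <- which(lattice$state >= 1L)
  occ2 <- which(lattice$state == 2L)
  row1 <- (occ1 - 1L) %% h + 1L
  col1 <- (occ1 - 1L) %/% h + 1L
  row2 <- (occ2 - 1L) %% h + 1L
  col2 <- (occ2 - 1L) %/% h + 1L
  data.frame(
    site_row = c(row1, row2),
    site_col = c(col1, col2),
    role = c(ifelse(lattice$state[occ1] == 1L, "mono", "female"),
             rep("male", length(occ2))),
    w_v = c(lattice$wv1[occ1], lattice$wv2[occ2]),
    w_r = c(lattice$wr1[occ1], lattice$wr2[occ2]),
    w_m = c(lattice$wm1[occ1], lattice$wm2[occ2]),
    mating_type = c(lattice$mt1[occ1], lattice$mt2[occ2]),
    dmf = c(lattice$dmf1[occ1], lattice$dmf2[occ2]) == 1L,
    generation = rep(generation, length(occ1) + length(occ2)),
    stringsAsFactors = FALSE)
}

#' Inoculate a lattice according to simulation parameters
#'
#' Draws `init_occupied` distinct habitable sites and places founder
#' monokaryons there, with fitness and mating types from [init_nucleus()].
#' When a DMF competition is configured, each founder belongs to the
#' DMF-carrying class with probability `dmf_start_prop` and draws its
#' mating type uniformly within its class; fitness is drawn identically
#' for both classes.
#'
#' @param params a [sim_params()] object.
#' @return A [new_lattice()] with the initial inoculation.
#' @export
init_lattice <- function(params) {
  hab <- if (!is.null(params$patch_size))
    build_patch_mask(params$width, params$height, params$patch_size,
                     params$patch_gap)
  else NULL
  lat <- new_lattice(params$width, params$height, hab)
  open_sites <- which(lat$habitable)
  k <- params$init_occupied
  if (k > length(open_sites))
    stop("init_occupied exceeds the number of habitable sites")
  sites <- if (k == length(open_sites)) open_sites
           else sample(open_sites, k)
  dmf_types <- params$dmf_types
  has_dmf_classes <- length(dmf_types) > 0L
  all_types <- 0:(params$m - 1L)
  non_dmf_types <- setdiff(all_types, dmf_types)
  for (i in seq_along(sites)) {
    if (has_dmf_classes) {
      carrier <- runif(1L) < params$dmf_start_prop
      pool <- if (carrier) dmf_types else non_dmf_types
      mt <- if (length(pool) == 1L) pool else sample(pool, 1L)
      nuc <- init_nucleus(params$m, params$sigma_init, params$beta,
                          mating_type = mt, dmf = carrier, lineage_id = i)
    } else {
      nuc <- init_nucleus(params$m, params$sigma_init, params$beta,
                          dmf = FALSE, lineage_id = i)
    }
    lat <- place_monokaryon(lat, sites[i], nuc)
  }
  lat$next_lineage <- length(sites) + 1L
  lat
}
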