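#' Project a raw fitness vector onto the trade-off surface
#'
#' Every nucleus allocates its fitness budget between vegetative growth
#' (`w_v`), spore production (`w_r`) and mating success (`w_m`), constrained
#' to the surface `w_v^beta + w_r^beta + w_m^beta = 1`. For the linear
#' trade-off (`beta = 1`) this is the unit simplex. Projection rescales a
#' non-negative vector by the single positive factor
#' `c = (sum(x^beta))^(-1/beta)` so that the result lies exactly on the
#' surface; the projected point is proportional to the input, and for
#' `beta = 1` projection reduces to division by the component sum.
#'
#' @param w numeric vector of length 3 `(w_v, w_r, w_m)`, or an `n x 3`
#'   matrix of such vectors; all components must be non-negative with at
#'   least one positive per vector.
#' @param beta trade-off exponent (> 0); `beta = 1` is the linear trade-off.
#' @return An object of the same shape as `w`, lying on the trade-off
#'   surface. Projection is idempotent and scale-invariant.
#' @examples
#' project_to_surface(c(0.4, 0.4, 1.2))            # -> (0.2, 0.2, 0.6)
#' project_to_surface(c(0.5, 0.5, 0.5), beta = 2)  # -> each 1/sqrt(3)
#' @export
project_to_surface <- function(w, beta = 1) {
  stopifnot(is.numeric(beta), length(beta) == 1L, beta > 0)
  if (is.matrix(w)) {
    if (ncol(w) != 3L) stop("fitness matrix must have 3 columns")
    if (any(w < 0)) stop("fitness components must be non-negative")
    s <- rowSums(w^beta)
    if (any(s <= 0)) stop("degenerate fitness vector")
    return(w * s^(-1 / beta))
  }
  if (length(w) != 3L) stop("fitness vector must have length 3")
  if (any(w < 0)) stop("fitness components must be non-negative")
  s <- sum(w^beta)
  if (s <= 0) stop("degenerate fitness vector")
  out <- w * s^(-1 / beta)
  names(out) <- c("w_v", "w_r", "w_m")
  out
}

#' Construct a nucleus
#'
#' A nucleus is the heritable unit of the model: a fitness triple on the
#' trade-off surface, a mating-type allele, an optional allele conferring
#' dikaryotic male function (DMF), and an opaque clonal lineage id used to
#' recognise somatic identity between mycelia.
#'
#' @param fitness numeric triple `(w_v, w_r, w_m)`; it is validated to lie
#'   on the trade-off surface for the given `beta` (tolerance `1e-9`).
#' @param mating_type integer mating-type allele, `0 <= mating_type < m`.
#' @param dmf logical; does this nucleus carry the DMF allele?
#' @param lineage_id integer identifier of the clonal lineage.
#' @param beta trade-off exponent used for validation.
#' @return A list of class `"nucleus"`.
#' @examples
#' nucleus(c(0.2, 0.2, 0.6), mating_type = 0)
#' @export
nucleus <- function(fitness, mating_type, dmf = FALSE, lineage_id = 0L,
                    beta = 1) {
  fitness <- as.numeric(fitness)
  if (length(fitness) != 3L || any(fitness < 0))
    stop("fitness must be 3 non-negative components")
  if (abs(sum(fitness^beta) - 1) > 1e-9)
    stop("fitness triple is not on the trade-off surface")
  mating_type <- as.integer(mating_type)
  if (is.na(mating_type) || mating_type < 0L)
    stop("mating_type must be a non-negative integer")
  names(fitness) <- c("w_v", "w_r", "w_m")
  structure(
    list(fitness = fitness, mating_type = mating_type,
         dmf = isTRUE(dmf), lineage_id = as.integer(lineage_id)),
    class = "nucleus")
}

#' @export
print.nucleus <- function(x, ...) {
  cat(sprintf(
    "<nucleus> w_v=%.4f w_r=%.4f w_m=%.4f  mating type %d%s  lineage %d\n",
    x$fitness[1], x$fitness[2], x$fitness[3], x$mating_type,
    if (x$dmf) " [DMF]" else "", x$lineage_id))
  invisible(x)
}

#' Mutate a nucleus on the trade-off surface
#'
#' Each fitness component is perturbed by an independent Gaussian step with
#' standard deviation `sigma`; negative components are clipped at zero (an
#' all-zero draw, possible only for large `sigma`, is redrawn) and the
#' triple is projected back onto the trade-off surface. Mating type, DMF
#' allele and lineage id are untouched: mutation acts on the fitness
#' phenotype only.
#'
#' @param nuc a [nucleus()].
#' @param sigma standard deviation of the Gaussian mutation step.
#' @param beta trade-off exponent.
#' @return The mutated nucleus.
#' @export
mutate_nucleus <- function(nuc, sigma, beta = 1) {
  stopifnot(inherits(nuc, "nucleus"), sigma >= 0)
  if (sigma == 0) return(nuc)
  repeat {
    w <- pmax(nuc$fitness + rnorm(3L, 0, sigma), 0)
    if (sum(w) > 0) break
  }
  nuc$fitness <- project_to_surface(w, beta)
  nuc
}

#' Recombine two parental fitness triples
#'
#' The linkage parameter `lambda` interpolates between polygenic blending
#' inheritance (`lambda = 0`: offspring take the midparent phenotype) and
#' monogenic Mendelian inheritance (`lambda = 1`: offspring take one
#' parental phenotype, chosen uniformly). For intermediate `lambda` the
#' offspring triple is the convex blend
#' `lambda * template + (1 - lambda) * midparent`, projected back onto the
#' trade-off surface, where the template parent is chosen uniformly at
#' random.
#'
#' @param parent_a,parent_b [nucleus()] objects on the trade-off surface.
#' @param lam linkage parameter `lambda` in `[0, 1]`.
#' @param beta trade-off exponent.
#' @return The offspring fitness triple, with attribute `"template"` (1 or
#'   2) recording which parent supplied the template phenotype (and hence
#'   the linked mating-type and DMF alleles, see [make_spore()]).
#' @export
recombine <- function(parent_a, parent_b, lam, beta = 1) {
  stopifnot(inherits(parent_a, "nucleus"), inherits(parent_b, "nucleus"))
  if (!is.numeric(lam) || length(lam) != 1L || lam < 0 || lam > 1)
    stop("lam must be a single value in [0, 1]")
  template <- if (runif(1L) < 0.5) 1L else 2L
  tpl <- if (template == 1L) parent_a$fitness else parent_b$fitness
  mid <- (parent_a$fitness + parent_b$fitness) / 2
  out <- project_to_surface(lam * tpl + (1 - lam) * mid, beta)
  attr(out, "template") <- template
  out
}

#' Produce a meiotic spore from a dikaryon's nuclear pair
#'
#' Spore production composes the mutation and inheritance operators:
#' both parental nuclei mutate (mutation accumulates during the dikaryotic
#' state, before karyogamy and meiosis), the fitness triple is then
#' recombined under linkage `lambda`, and the spore inherits the mating
#' type and DMF allele of the template parent, reflecting linkage of both
#' loci to the locus carrying the fitness variation.
#'
#' @param parent_a,parent_b the two nuclei of the dikaryon (different
#'   mating types).
#' @param sigma mutation standard deviation.
#' @param lam linkage parameter in `[0, 1]`.
#' @param beta trade-off exponent.
#' @param lineage_id lineage id assigned to the new spore (each meiotic
#'   spore founds a fresh clonal lineage).
#' @return A [nucleus()].
#' @export
make_spore <- function(parent_a, parent_b, sigma, lam, beta = 1,
                       lineage_id = 0L) {
  if (parent_a$mating_type == parent_b$mating_type)
    stop("dikaryon nuclei must have different mating types")
  ma <- mutate_nucleus(parent_a, sigma, beta)
  mb <- mutate_nucleus(parent_b, sigma, beta)
  fit <- recombine(ma, mb, lam, beta)
  tpl <- if (attr(fit, "template") == 1L) parent_a else parent_b
  attr(fit, "template") <- NULL
  nucleus(fit, mating_type = tpl$mating_type, dmf = tpl$dmf,
          lineage_id = lineage_id, beta = beta)
}

#' Draw an initial nucleus
#'
#' Initial fitness values are drawn around the barycentre of the trade-off
#' surface: each component is `1/3` plus an independent Gaussian deviate
#' with standard deviation `sigma_init` (negatives clipped, all-zero draws
#' redrawn), projected onto the surface. The mating type is uniform on
#' `0:(m - 1)` unless given explicitly.
#'
#' @param m number of mating types (>= 2).
#' @param sigma_init spread of the initial fitness cloud.
#' @param beta trade-off exponent.
#' @param mating_type optional fixed mating type.
#' @param dmf logical DMF allele.
#' @param lineage_id lineage id of the founder.
#' @return A [nucleus()].
#' @export
init_nucleus <- function(m, sigma_init = 0.1, beta = 1, mating_type = NULL,
                         dmf = FALSE, lineage_id = 0L) {
  stopifnot(m >= 2)
  repeat {
    w <- pmax(1 / 3 + rnorm(3L, 0, sigma_init), 0)
    if (sum(w) > 0) break
  }
  if (is.null(mating_type)) mating_type <- sample.int(m, 1L) - 1L
  nucleus(project_to_surface(w, beta), mating_type = mating_type,
          dmf = dmf, lineage_id = lineage_id, beta = beta)
}
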