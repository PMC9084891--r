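---
title: "dikaryosim: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dikaryosim: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dikaryosim)
```

## The question the simulator addresses

In most sexual organisms the two parental genomes fuse at fertilization,
which aligns their evolutionary interests until the next meiosis.
Mushroom-forming fungi (Basidiomycetes) are a striking exception: after
two monokaryotic mycelia mate, the two haploid nuclei remain separate in
a *dikaryon*, and each retains the ability to fertilize further
monokaryons it meets (di-mon or "Buller" mating). The nuclei of a
dikaryon are therefore simultaneously partners — their shared mycelium
must grow and produce spores — and rivals for additional matings.

`dikaryosim` is a spatially explicit stochastic simulator built to study
that tension. Each haploid nucleus carries a heritable fitness budget
split three ways,

$$w_v + w_r + w_m = 1 ,$$

between vegetative growth ($w_v$), spore production ($w_r$) and mating
success ($w_m$). Because the budget is conserved, any nuclear lineage
that improves its mating success necessarily degrades the growth and
reproduction of every mycelium that carries it — mating specialists are
*parasitic* at the mycelium level. The simulator contrasts three life
cycles that differ only in which matings are permitted:

* **diploid** — mon-mon matings only (fusion seals the pair);
* **standard dikaryon** — mon-mon and di-mon (the natural case);
* **open dikaryon** — mon-mon, di-mon and di-di (a hypothetical cycle in
  which even established dikaryons exchange nuclei).

## The model

### Arena

Mycelia live on a `width` x `height` square lattice with toroidal
topology; every site has exactly eight Moore neighbours and supports one
mycelial section. A site is empty, monokaryotic (one nucleus) or
dikaryotic (nucleus 1, the resident "female" haplotype that founded the
mycelium as a monokaryon, and nucleus 2, the fertilizing "male"
haplotype). A habitability mask of square patches separated by
uninhabitable strips (`build_patch_mask()`) supports fragmentation
experiments; mycelia cannot grow across strips, spores can cross them.

### Nuclear and dikaryotic fitness

A monokaryon colonizes an adjacent empty site with probability
$G = g\,w_v$ per opportunity and produces no spores. A dikaryon
expresses a dominance-weighted blend of its two nuclei: with
$\Theta \in [0,1]$ the phenotypic dominance of the fitter nucleus,

$$W_v = g\,[w_{v,\max}\Theta + w_{v,\min}(1-\Theta)], \qquad
  W_r = r\,[w_{r,\max}\Theta + w_{r,\min}(1-\Theta)].$$

$\Theta = 1$ is full dominance (a parasitic partner is completely
sheltered), $\Theta = 0$ full recessivity, $\Theta = 0.5$ codominance.

### Mating

When an occupied site is visited and survives, it may mate in the
female role. Candidate "male" nuclei are collected from the eight
neighbouring sites — one entry per compatible nucleus per contact site,
so a mycelium touching the focal site in several places competes once
per contact. Compatibility requires different mating-type alleles
(`m` types, default 30). Which nuclei are eligible depends on the life
cycle: monokaryon neighbours always; dikaryon nuclei (di-mon) under the
standard and open cycles; and under the open cycle a focal dikaryon can
itself receive, from neighbouring dikaryons (di-di) and, by default,
from monokaryons. The winner is drawn with probability proportional to
its $w_m$ (uniform if all weights vanish). In a di-di encounter all
four nuclei compete: each mating-type-compatible pair $\{i,j\}$ is
sampled with weight $w_m(i)\,w_m(j)$, and sampling the focal pair
leaves the lattice unchanged.

The winning pair then spreads over the spatially connected extents of
the affected mycelia, transforming them into one dikaryon. In a mon-mon
mating both partners convert; in a di-mon mating the package's default
(`dimon_converts_donor = TRUE`) also rewrites the donor dikaryon's
mycelium, evicting the donor's losing partner from its own territory.
This literal reading of the takeover rule is what makes the
fertilization race a genuine *within-dikaryon* competition: without it
(the strict-Buller switch, `FALSE`) a male win gains a single site and
the mating channel is dominated by growth and spore production for all
parameter values we examined, and none of the nuclear-parasitism
phenomenology emerges.

### Mutation and inheritance

Fitness mutates during the dikaryotic state: each time a dikaryon is
visited, both resident haplotypes take one step of an isotropic
Gaussian walk (s.d. `sigma`, default 0.01), clipped at zero and
projected back onto the trade-off surface (for exponent `beta`,
$\sum w_i^\beta = 1$; projection rescales by the closed-form factor
$c = (\sum x_i^\beta)^{-1/\beta}$). Monokaryon nuclei do not mutate.

Meiosis compresses an implicit multi-locus genetics into the linkage
parameter $\lambda$: a spore's fitness triple is
$\lambda\,(\text{template parent}) + (1-\lambda)\,(\text{midparent})$,
re-projected, with the template parent chosen uniformly. $\lambda = 1$
is the monogenic (Mendelian) extreme — offspring resemble one parent —
and $\lambda = 0$ the polygenic (blending) extreme. (Note one figure
caption in the source literature states this orientation reversed; the
package follows the convention above throughout.) The mating-type
allele and the dikaryotic-male-function (DMF) allele travel with the
template parent, i.e. they are linked to the locus carrying the fitness
variation.

### Updating algorithm

One generation is `width * height` elementary steps. Each step picks a
site uniformly at random (with replacement):

1. an occupied site dies with probability `d` (site-level death);
2. a survivor mutates (if dikaryotic), then attempts mating in the
   female role;
3. if it is then dikaryotic it sporulates: a Poisson(`r * W_r`) number
   of basidia each release a tetrad of four independent meiotic spores
   (`spores_per_basidium = 4`), each landing uniformly in the Chebyshev
   ball of radius `disp_radius` (default 3) around the parent, centre
   excluded;
4. an empty habitable site is contested by its occupied neighbours:
   each succeeds independently with probability equal to its expressed
   vegetative rate and the winner, drawn proportionally to that rate,
   copies its state into the site.

Spores are banked during the generation and germinate *into the next
generation*: after the generation's census, every empty habitable site
that received spores keeps one uniform survivor as a new monokaryon.
Censuses therefore never count a monokaryon that has not yet had a
mating opportunity. Identical nucleotypes (equal nuclear lineage
multisets) in spatial contact fuse somatically into one mycelium.

### Why tetrads

The printed production rate $R = r\,w_r$ fixes the *rate* of
sporulation events but not the spore multiplicity per event. We treat
an event as a basidium releasing four meiotic products — the canonical
basidiomycete tetrad. This choice matters: with one spore per event the
spore rain is so dilute that site turnover is dominated by vegetative
growth, the diploid life cycle optimises $w_v$ instead of the expected
spore-production maximum, and the monokaryon supply is too thin for
di-mon mating competition to shape the population. With tetrads the
diploid endpoint (a $w_r$-maximising cluster) and the male-biased
mating-fitness drive of the standard dikaryon both emerge at the base
parameterisation. `spores_per_basidium` is config-exposed.

## Implementation notes

The updating engine is compiled (Rcpp). A mycelium is represented as a
clone record in a registry; sites carry a clone id. Mating takeovers
merge the affected clones under a fresh record via union-find in O(1),
which is what makes dense open-dikaryon lattices (where takeovers span
thousands of sites) tractable. Exact connected components are
recomputed at every generation boundary, so somatic fusion and
death-induced splits are recognised there; a mycelium severed
mid-generation acts as one individual for at most the remainder of that
generation. The exported R operations (`mycelium_of()`,
`list_candidates()`, `choose_male()`, `apply_mating()`, ...) are exact
reference implementations on the plain lattice structure; the test
suite cross-checks engine behaviour against them with frozen-lattice
transition-frequency oracles (total-variation distance below 0.01 at
$10^5$ single steps).

All randomness flows through R's RNG: `sim_params(seed = )` makes a
full trajectory reproducible bit-for-bit. Draw order within a step is
fixed (site, death, mutation, mating, sporulation).

## Defaults and their provenance

| parameter | default | meaning |
|---|---|---|
| `g` | 0.1 | basic mycelial growth rate |
| `r` | 1 | basic spore production rate |
| `d` | 0.3 | per-visit site death probability |
| `sigma` | 0.01 | mutation step s.d. |
| `beta` | 1 | trade-off exponent (linear budget) |
| `lam` | 1 | linkage (monogenic) |
| `theta` | 0.5 | dominance (codominant) |
| `m` | 30 | mating types |
| `disp_radius` | 3 | spore dispersal radius (Chebyshev) |
| `sigma_init` | 0.1 | founder fitness spread around (1/3,1/3,1/3) |
| `spores_per_basidium` | 4 | meiotic products per sporulation event |
| grid | 300 x 300 | arena (analyses here use 150-200 per side) |
| `init_occupied` | 2/3 of habitable sites | founder monokaryons |

`g, r, d, sigma` and the grid/initialisation follow the base
parameterisation of the study system; `theta`, `m`, `disp_radius` and
`sigma_init` are not fixed by it and were chosen once as the package's
defaults: codominance as the neutral midpoint of the dominance range,
30 mating types (the value used by the invasion competitions, and large
enough that ~97% of random encounters are compatible), a short local
dispersal kernel, and a founder cloud that covers the central region of
the fitness simplex without seeding corner specialists.

## What the simulations show (and what they do not)

Run at desk scale (150-200 sites per side, a few hundred generations),
the package reproduces the qualitative structure of the system:

* the **diploid** cycle is demographically the most robust and evolves
  towards spore-production maximisation under monogenic inheritance;
* the **standard dikaryon** shows a persistent drive for mating fitness
  concentrated in the male (fertilizing) nuclear role, a transient rise
  of mating fitness in the female role that is subsequently purged as
  parasite-carrying dikaryons under-produce spores, and a
  dominance/linkage dependence in the expected directions (more
  parasitism with higher dominance, purging only near the monogenic
  extreme);
* the **open dikaryon** saturates to an almost fully dikaryotic
  population and carries the strongest mating-fitness selection of the
  three cycles.

Several reported behaviours of the original study system are *not*
reproduced by this reconstruction at its base parameters, and we flag
them rather than tune them away. First, our open-dikaryon populations
do not reliably collapse to extinction at the base spore rate: mean
mating fitness oscillates under recurrent selection-purge cycles
instead of ratcheting irreversibly to one, and the surviving open
populations are not systematically smaller than standard-dikaryon ones
at the base rates. Second, under fully polygenic (blending)
inheritance the standard dikaryon reaches a stable population with
near-constant mean fitness rather than drifting to universal mating
specialisation; blending leaves too little heritable variance for the
mating channel in our formulation. Third, the purge of the female-role
mating-fitness rise completes here on a ~200-generation rather than
~75-generation timescale. All three sit on the knife edge between the
mating-selection channel and the spore/growth channels, and all
sharpen in the expected direction when dominance, spore supply or
mutational input increase. These gaps are visible in the acceptance
summaries rather than hidden behind re-tuned parameters.

The synthetic initial condition (a Gaussian cloud around the simplex
barycentre) emulates a population with standing variation but no
established specialists; real populations, and runs seeded from wider
clouds, contain rare mating specialists from the start and ignite the
parasite dynamics faster. Nothing in the generator emulates resource
heterogeneity, seasonality, or nuclear movement within a mycelium —
each site holds at most two nuclear types, as in the modelled system.

## A worked example

```{r example, fig.width = 7, fig.height = 3.5, eval = FALSE}
p <- sim_params(scenario = "standard", width = 150, height = 150,
                n_generations = 200, seed = 1)
sim <- run_simulation(p)
summary(sim)
plot(sim)
plot_ternary(sim$nuclei)
```

`run_simulation()` returns the per-generation metrics table (population
size, dikaryotic fraction, per-role mean fitness triples, parasite
fractions, DMF frequencies), per-generation event tallies, the final
lattice and its nucleus table. `run_panel()`, `run_dmf_competition()`
and `run_factor_scan()` script the standard experimental protocols on
top of it.
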