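test_that("the Moore neighbourhood wraps toroidally and is exhaustive", {
  lat <- new_lattice(3, 3)
  centre <- site_index(lat, 2, 2)
  expect_setequal(neighbors8(lat, centre), setdiff(1:9, centre))
  corner <- site_index(lat, 1, 1)
  nb <- neighbors8(lat, corner)
  expect_length(nb, 8L)
  expect_true(site_index(lat, 3, 3) %in% nb)  # opposite corner via wrap
  # on a 5x7 torus every site appears in exactly 8 neighbour lists
  lat2 <- new_lattice(7, 5)
  counts <- integer(35)
  for (i in 1:35) {
    nb <- neighbors8(lat2, i)
    expect_length(unique(nb), 8L)
    counts[nb] <- counts[nb] + 1L
  }
  expect_equal(counts, rep(8L, 35))
})

test_that("patch masks tile the torus with the advertised habitable count", {
  expect_true(all(build_patch_mask(8, 8, patch_size = 3, gap = 0)))
  expect_equal(sum(build_patch_mask(10, 10, patch_size = 3, gap = 2)), 36L)
  expect_equal(sum(build_patch_mask(6, 6, patch_size = 2, gap = 1)), 16L)
  expect_error(build_patch_mask(4, 4, patch_size = 4, gap = 1), "exceeds")
})

test_that("site placement, retrieval and clearing round-trip", {
  lat <- new_lattice(5, 5)
  a <- nuc(0.5, 0.3, 0.2, mt = 0L, lin = 1L)
  b <- nuc(0.1, 0.2, 0.7, mt = 1L, dmf = TRUE, lin = 2L)
  lat <- place_monokaryon(lat, 7, a)
  s <- get_site(lat, 7)
  expect_identical(s$tag, "monokaryon")
  expect_equal(s$nucleus1$fitness, a$fitness)
  lat <- place_dikaryon(lat, 8, a, b)
  s <- get_site(lat, 8)
  expect_identical(s$tag, "dikaryon")
  expect_identical(s$nucleus2$mating_type, 1L)
  expect_true(s$nucleus2$dmf)
  expect_error(place_dikaryon(lat, 9, a, nuc(0.2, 0.2, 0.6, mt = 0L)),
               "mating types")
  lat <- clear_site(lat, 8)
  expect_identical(get_site(lat, 8)$tag, "empty")
  hab <- matrix(TRUE, 5, 5); hab[3, 3] <- FALSE
  lat2 <- new_lattice(5, 5, hab)
  expect_error(place_monokaryon(lat2, site_index(lat2, 3, 3), a),
               "uninhabitable")
})

test_that("somatic identity compares lineage multisets", {
  lat <- new_lattice(5, 5)
  a <- nuc(0.5, 0.3, 0.2, mt = 0L, lin = 1L)
  b <- nuc(0.1, 0.2, 0.7, mt = 1L, lin = 2L)
  lat <- place_monokaryon(lat, 1, a)
  lat <- place_monokaryon(lat, 2, a)
  lat <- place_monokaryon(lat, 3, b)
  expect_true(same_genotype(lat, 1, 2))
  expect_false(same_genotype(lat, 1, 3))
  lat <- place_dikaryon(lat, 4, a, b)
  lat <- place_dikaryon(lat, 5, b, a)   # swapped roles, same multiset
  expect_true(same_genotype(lat, 4, 5))
  expect_false(same_genotype(lat, 1, 4))
  expect_error(same_genotype(lat, 1, 6), "empty")
})

test_that("mycelium queries return exact 8-connected components", {
  lat <- new_lattice(8, 8)
  a <- nuc(0.5, 0.3, 0.2, mt = 0L, lin = 1L)
  lat <- place_monokaryon(lat, site_index(lat, 2, 2), a)
  expect_identical(mycelium_of(lat, site_index(lat, 2, 2)),
                   site_index(lat, 2, 2))
  # a 2x3 block plus one diagonal-contact site: all 7 sites, 8-connectivity
  block <- c(site_index(lat, 4, 4), site_index(lat, 4, 5),
             site_index(lat, 4, 6), site_index(lat, 5, 4),
             site_index(lat, 5, 5), site_index(lat, 5, 6))
  diagonal <- site_index(lat, 6, 7)
  for (s in c(block, diagonal)) lat <- place_monokaryon(lat, s, a)
  comp <- mycelium_of(lat, block[1])
  expect_setequal(comp, c(block, diagonal))
  # equivalence-class property: every member yields the same set
  for (s in comp) expect_identical(mycelium_of(lat, s), comp)
  expect_error(mycelium_of(lat, site_index(lat, 1, 8)), "empty")
})

test_that("mycelia do not span uninhabitable strips", {
  hab <- build_patch_mask(7, 7, patch_size = 3, gap = 1)
  lat <- new_lattice(7, 7, hab)
  a <- nuc(0.5, 0.3, 0.2, mt = 0L, lin = 1L)
  left <- c(site_index(lat, 1, 3), site_index(lat, 2, 3))
  right <- c(site_index(lat, 1, 5), site_index(lat, 2, 5))
  for (s in c(left, right)) lat <- place_monokaryon(lat, s, a)
  expect_setequal(mycelium_of(lat, left[1]), left)
  expect_setequal(mycelium_of(lat, right[1]), right)
})

test_that("the engine's component query agrees with the reference one", {
  set.seed(11)
  p <- tiny_params(n_generations = 3L)
  sim <- run_simulation(p)
  lat <- sim$lattice
  occ <- which(lat$state > 0L)
  for (s in sample(occ, min(12, length(occ)))) {
    expect_identical(dikaryosim:::.cpp_mycelium_of(lat, s),
                     mycelium_of(lat, s))
  }
})

test_that("nuclei tables have one row per nucleus with role labels", {
  lat <- new_lattice(5, 5)
  a <- nuc(0.5, 0.3, 0.2, mt = 0L, lin = 1L)
  b <- nuc(0.1, 0.2, 0.7, mt = 1L, lin = 2L)
  lat <- place_monokaryon(lat, 2, a)
  lat <- place_dikaryon(lat, 10, a, b)
  tab <- nuclei_table(lat, generation = 4L)
  expect_identical(nrow(tab), 3L)
  expect_setequal(tab$role, c("mono", "female", "male"))
  expect_equal(sum(tab$role == "male"), 1L)
  expect_true(all(tab$generation == 4L))
})

test_that("inoculation respects habitat and founder count", {
  p <- tiny_params(patch_size = 3L, patch_gap = 1L, init_occupied = 50L)
  set.seed(2)
  lat <- init_lattice(p)
  expect_equal(sum(lat$state == 1L), 50L)
  expect_equal(sum(lat$state == 2L), 0L)
  expect_true(all(lat$state[!lat$habitable] == 0L))
  expect_identical(lat$next_lineage, 51L)
  # founders draw DMF classes with the configured proportion
  p2 <- tiny_params(dmf_types = 0:14, dmf_start_prop = 1, init_occupied = 60L)
  set.seed(3)
  lat2 <- init_lattice(p2)
  mono <- lat2$state == 1L
  expect_true(all(lat2$dmf1[mono] == 1L))
  expect_true(all(lat2$mt1[mono] %in% 0:14))
})
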