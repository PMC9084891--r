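test_that("expressed rates follow the dominance-weighted formulas", {
  p <- tiny_params(g = 0.1, r = 1, theta = 1)
  mono <- list(tag = "monokaryon", nucleus1 = nuc(0.5, 0.3, 0.2, 0L),
               nucleus2 = NULL)
  expect_equal(vegetative_rate(mono, p), 0.05)
  expect_equal(reproductive_rate(mono, p), 0)
  di <- list(tag = "dikaryon",
             nucleus1 = nuc(0.6, 0.5, 0.4, 0L) ,
             nucleus2 = NULL)
  di$nucleus1 <- nucleus(c(0.6, 0.2, 0.2), 0L)
  di$nucleus2 <- nucleus(c(0.2, 0.5, 0.3), 1L)
  # vegetative: w_v pair (0.6, 0.2); reproductive: w_r pair (0.2, 0.5)
  expect_equal(vegetative_rate(di, update_params(p, theta = 1)), 0.06)
  expect_equal(vegetative_rate(di, update_params(p, theta = 0.25)),
               0.1 * (0.6 * 0.25 + 0.2 * 0.75))
  expect_equal(reproductive_rate(di, update_params(p, theta = 0)), 0.2)
  expect_equal(reproductive_rate(di, update_params(p, theta = 0.5, r = 5)),
               5 * (0.5 * 0.5 + 0.2 * 0.5))
  expect_error(vegetative_rate(list(tag = "empty"), p), "empty")
})

test_that("a chosen occupied site always dies at d = 1", {
  lat <- new_lattice(5, 5)
  s <- site_index(lat, 3, 3)
  lat <- place_monokaryon(lat, s, nuc(0.5, 0.3, 0.2, 0L))
  p <- tiny_params(d = 1, sigma = 0)
  out <- elementary_step(lat, p, site = s)
  expect_identical(out$lattice$state[s], 0L)
})

test_that("an isolated monokaryon with no compatible mate is inert at d = 0", {
  lat <- new_lattice(5, 5)
  s <- site_index(lat, 3, 3)
  lat <- place_monokaryon(lat, s, nuc(0.5, 0.3, 0.2, 0L))
  p <- tiny_params(d = 0, sigma = 0)
  out <- elementary_step(lat, p, site = s)
  expect_identical(out$lattice$state, lat$state)
  expect_identical(nrow(out$spores), 0L)
})

test_that("colonization of an empty site is Bernoulli in the growth rate", {
  lat <- new_lattice(5, 5)
  src <- site_index(lat, 3, 3)
  tgt <- site_index(lat, 3, 4)
  lat <- place_monokaryon(lat, src, nuc(0.5, 0.3, 0.2, 0L))
  p <- tiny_params(d = 0, sigma = 0, g = 0.4)   # rate 0.4 * 0.5 = 0.2
  set.seed(14)
  hits <- replicate(5000, elementary_step(lat, p, site = tgt)$lattice$state[tgt])
  p_hat <- mean(hits == 1L)
  expect_lt(abs(p_hat - 0.2), 4 * sqrt(0.2 * 0.8 / 5000))
  # empty site with no occupied neighbours stays empty
  far <- site_index(lat, 1, 1)
  expect_identical(elementary_step(lat, p, site = far)$lattice$state[far], 0L)
})

test_that("sporulation draws tetrads at the reproductive rate and lands in the ball", {
  lat <- new_lattice(9, 9)
  s <- site_index(lat, 5, 5)
  lat <- place_dikaryon(lat, s,
                        nucleus(c(0.5, 0.4, 0.1), 0L),
                        nucleus(c(0.3, 0.4, 0.3), 1L))
  # theta irrelevant: both w_r = 0.4, rate = r * 0.4
  p <- tiny_params(d = 0, sigma = 0, r = 1, disp_radius = 1L,
                   spores_per_basidium = 4L)
  set.seed(15)
  counts <- integer(3000)
  sites <- integer(0)
  for (i in 1:3000) {
    sp <- elementary_step(lat, p, site = s)$spores
    counts[i] <- nrow(sp)
    sites <- c(sites, sp$site)
  }
  expect_true(all(counts %% 4L == 0L))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 4 * 0.4), 4 * se)
  expect_true(all(sites %in% neighbors8(lat, s)))
  # single-spore basidia recover the bare Poisson rate
  p1 <- update_params(p, spores_per_basidium = 1L)
  c1 <- replicate(3000, nrow(elementary_step(lat, p1, site = s)$spores))
  expect_lt(abs(mean(c1) - 0.4), 4 * sd(c1) / sqrt(3000))
  # a monokaryon never sporulates
  lat0 <- place_monokaryon(new_lattice(5, 5), 13, nuc(0.1, 0.8, 0.1, 0L))
  expect_identical(nrow(elementary_step(lat0, p, site = 13)$spores), 0L)
})

test_that("germination keeps one uniform survivor per empty site", {
  lat <- new_lattice(5, 5)
  spores <- data.frame(site = c(7L, 7L, 7L),
                       wv = c(0.5, 0.3, 0.2), wr = c(0.3, 0.4, 0.2),
                       wm = c(0.2, 0.3, 0.6), mt = 0:2,
                       dmf = 0L, lin = 11:13)
  set.seed(16)
  survivors <- replicate(6000, {
    out <- germinate(lat, spores)
    out$lin1[7]
  })
  expect_setequal(unique(survivors), 11:13)
  expect_gt(stats::chisq.test(table(survivors))$p.value, 1e-4)
  # occupied sites ignore spores; empty bank is a no-op
  lat2 <- place_monokaryon(lat, 7, nuc(0.5, 0.3, 0.2, 0L, lin = 1L))
  out2 <- germinate(lat2, spores)
  expect_identical(out2$lin1[7], 1L)
  expect_identical(germinate(lat, spores[0, ])$state, lat$state)
  # uninhabitable sites never germinate
  hab <- matrix(TRUE, 5, 5); hab[2, 2] <- FALSE
  lat3 <- new_lattice(5, 5, hab)
  out3 <- germinate(lat3, data.frame(site = site_index(lat3, 2, 2),
                                     wv = 0.4, wr = 0.3, wm = 0.3,
                                     mt = 0L, dmf = 0L, lin = 5L))
  expect_identical(out3$state[site_index(lat3, 2, 2)], 0L)
})

test_that("a compatible monokaryon pair is absorbed into one dikaryon", {
  lat <- new_lattice(3, 3)
  lat <- place_monokaryon(lat, 1, nuc(0.5, 0.3, 0.2, 0L, lin = 1L))
  lat <- place_monokaryon(lat, 2, nuc(0.2, 0.2, 0.6, 1L, lin = 2L))
  p <- tiny_params(d = 0, g = 0, r = 0, sigma = 0)
  set.seed(17)
  for (i in 1:60) {
    lat <- elementary_step(lat, p)$lattice
    if (all(lat$state[1:2] == 2L)) break
  }
  expect_true(all(lat$state[1:2] == 2L))
  expect_identical(lat$lin1[1], lat$lin1[2])
})

test_that("generations are reproducible and censuses conserve the habitat", {
  p <- tiny_params(n_generations = 4L, seed = 123L,
                   patch_size = 4L, patch_gap = 1L, init_occupied = 100L)
  simA <- run_simulation(p)
  simB <- run_simulation(p)
  expect_identical(simA$metrics, simB$metrics)
  expect_identical(simA$lattice, simB$lattice)
  m <- simA$metrics
  expect_true(all(m$n_mono + m$n_di == m$pop_size))
  expect_true(all(m$pop_size <= sum(simA$lattice$habitable)))
  expect_true(all(simA$lattice$state[!simA$lattice$habitable] == 0L))
})

test_that("with growth and spores disabled the population decays geometrically", {
  p <- tiny_params(width = 41L, height = 41L, g = 0, r = 0, d = 0.3,
                   n_generations = 6L, init_occupied = 1200L, seed = 4L)
  sim <- run_simulation(p)
  pops <- sim$metrics$pop_size
  ratios <- pops[-1] / pops[-length(pops)]
  # per-generation survival of a site visited Poisson(1) times with
  # per-visit death d: E[(1-d)^K] = exp(-d)
  expect_lt(abs(mean(ratios) - exp(-0.3)), 0.04)
})

test_that("a zero-generation run returns only the initial census", {
  p <- tiny_params(n_generations = 0L, seed = 5L)
  sim <- run_simulation(p)
  expect_identical(nrow(sim$metrics), 1L)
  expect_identical(sim$metrics$generation, 0L)
  expect_identical(sim$metrics$pop_size, p$init_occupied)
  expect_identical(sim$metrics$n_di, 0L)
})

test_that("extinction is recorded and ratios go NA, never zero", {
  p <- tiny_params(d = 1, g = 0, r = 0, n_generations = 40L, seed = 6L)
  sim <- run_simulation(p)
  expect_false(is.na(sim$extinct_gen))
  last <- sim$metrics[nrow(sim$metrics), ]
  expect_identical(last$pop_size, 0)
  expect_true(is.na(last$frac_dikaryotic))
  expect_true(is.na(last$mean_wm_role1))
  expect_true(is.na(last$frac_parasitic))
})
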