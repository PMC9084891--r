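# a 5x5 arena with a focal monokaryon at the centre and configurable
# neighbours; centre site is index site_index(lat, 3, 3)
focal_arena <- function() {
  lat <- new_lattice(5, 5)
  place_monokaryon(lat, site_index(lat, 3, 3),
                   nuc(0.5, 0.3, 0.2, mt = 0L, lin = 1L))
}

test_that("candidate listing honours compatibility and scenario", {
  lat <- focal_arena()
  f <- site_index(lat, 3, 3)
  # all neighbours share the focal mating type: nothing to mate with
  lat1 <- place_monokaryon(lat, site_index(lat, 2, 2),
                           nuc(0.2, 0.2, 0.6, mt = 0L, lin = 2L))
  expect_identical(nrow(list_candidates(lat1, f, "standard")), 0L)
  # compatible monokaryon plus a dikaryon: the dikaryon's nuclei are
  # excluded under the diploid scenario, included under standard
  lat2 <- place_monokaryon(lat, site_index(lat, 2, 3),
                           nuc(0.2, 0.2, 0.6, mt = 1L, lin = 2L))
  lat2 <- place_dikaryon(lat2, site_index(lat, 4, 3),
                         nuc(0.3, 0.3, 0.4, mt = 2L, lin = 3L),
                         nuc(0.1, 0.1, 0.8, mt = 3L, lin = 4L))
  expect_identical(nrow(list_candidates(lat2, f, "diploid")), 1L)
  cand <- list_candidates(lat2, f, "standard")
  expect_identical(nrow(cand), 3L)
  expect_setequal(cand$lineage_id, 2:4)
  # a focal-type nucleus inside a dikaryon is not a candidate
  lat3 <- place_dikaryon(lat, site_index(lat, 4, 4),
                         nuc(0.3, 0.3, 0.4, mt = 0L, lin = 3L),
                         nuc(0.1, 0.1, 0.8, mt = 5L, lin = 4L))
  cand3 <- list_candidates(lat3, f, "standard")
  expect_identical(cand3$lineage_id, 4L)
})

test_that("a mycelium competes once per contact site", {
  lat <- focal_arena()
  f <- site_index(lat, 3, 3)
  a <- nuc(0.2, 0.2, 0.6, mt = 1L, lin = 2L)
  lat <- place_monokaryon(lat, site_index(lat, 2, 2), a)
  lat <- place_monokaryon(lat, site_index(lat, 2, 3), a)  # same clone
  cand <- list_candidates(lat, f, "standard")
  expect_identical(nrow(cand), 2L)
  expect_true(all(cand$lineage_id == 2L))
})

test_that("DMF expression modes filter di-mon candidacy", {
  lat <- focal_arena()
  f <- site_index(lat, 3, 3)
  lat <- place_dikaryon(lat, site_index(lat, 2, 3),
                        nuc(0.3, 0.3, 0.4, mt = 1L, dmf = TRUE, lin = 2L),
                        nuc(0.1, 0.1, 0.8, mt = 2L, dmf = FALSE, lin = 3L))
  n_for <- function(mode)
    nrow(list_candidates(lat, f, "standard", dmf_mode = mode))
  expect_identical(n_for("off"), 2L)
  expect_identical(n_for("dominant"), 2L)   # either carrier enables both
  expect_identical(n_for("recessive"), 0L)  # both must carry
  cod <- list_candidates(lat, f, "standard", dmf_mode = "codominant")
  expect_identical(nrow(cod), 1L)
  expect_true(cod$dmf)
})

test_that("male choice is proportional to mating fitness", {
  cand <- data.frame(source_site = 1:2, source_kind = "monokaryon",
                     which = 1L, w_v = 0.1, w_r = 0.1,
                     w_m = c(0.8, 0.2), mating_type = 1:2, dmf = FALSE,
                     lineage_id = 1:2)
  set.seed(9)
  wins <- replicate(20000, choose_male(cand)$lineage_id)
  p_hat <- mean(wins == 1L)
  expect_lt(abs(p_hat - 0.8), 4 * sqrt(0.8 * 0.2 / 20000))
  # all-zero weights: uniform choice
  cand$w_m <- 0
  cand <- rbind(cand, cand[1, ])
  cand$lineage_id <- 1:3
  wins0 <- replicate(9000, choose_male(cand)$lineage_id)
  expect_gt(stats::chisq.test(table(wins0))$p.value, 1e-4)
  expect_error(choose_male(cand[0, ]), "no candidates")
})

test_that("di-di resolution samples compatible pairs by product weight", {
  hi <- nuc(0.05, 0.05, 0.9, mt = 0L, lin = 1L)   # high-w_m A-type
  lo <- nuc(0.45, 0.45, 0.1, mt = 0L, lin = 2L)   # low-w_m A-type
  b1 <- nuc(0.4, 0.4, 0.2, mt = 1L, lin = 3L)
  b2 <- nuc(0.3, 0.4, 0.3, mt = 1L, lin = 4L)
  set.seed(10)
  # the high-w_m A nucleus should dominate the winning pairs
  res <- replicate(2000, {
    out <- resolve_di_di(list(hi, b1), list(lo, b2))
    hi$lineage_id %in% c(out$nucleus1$lineage_id, out$nucleus2$lineage_id)
  })
  # exact marginal: mating types are (A, B, A, B), so the compatible
  # pairs are (hi,b1), (hi,b2), (b1,lo), (lo,b2); the focal pair (hi,b1)
  # can be sampled and is then retained unchanged, hi staying a winner
  wms <- c(0.9, 0.2, 0.1, 0.3)
  pairs <- rbind(c(1, 2), c(1, 4), c(2, 3), c(3, 4))
  w <- apply(pairs, 1, function(pr) wms[pr[1]] * wms[pr[2]])
  p_hi <- sum(w[c(1, 2)]) / sum(w)
  expect_lt(abs(mean(res) - p_hi), 4 * sqrt(p_hi * (1 - p_hi) / 2000) + 0.01)
  # winner containing a focal nucleus keeps it in the female role
  out <- resolve_di_di(list(hi, b1), list(lo, b2))
  if (out$changed &&
      out$nucleus1$lineage_id %in% c(1L, 3L) ||
      out$nucleus2$lineage_id %in% c(1L, 3L)) {
    expect_true(out$nucleus1$lineage_id %in% c(1L, 3L) ||
                !(out$nucleus2$lineage_id %in% c(1L, 3L)))
  }
  # incompatible foursome (all one mating type) is a no-op
  same <- lapply(1:4, function(i) nuc(0.3, 0.3, 0.4, mt = 0L, lin = i))
  out2 <- resolve_di_di(same[1:2], same[3:4])
  expect_false(out2$changed)
})

test_that("mating takeovers convert the affected mycelia and conserve occupancy", {
  lat <- new_lattice(6, 6)
  a <- nuc(0.5, 0.3, 0.2, mt = 0L, lin = 1L)
  b <- nuc(0.2, 0.2, 0.6, mt = 1L, lin = 2L)
  # two adjacent two-site monokaryon clones
  fa <- c(site_index(lat, 2, 2), site_index(lat, 2, 3))
  fb <- c(site_index(lat, 3, 3), site_index(lat, 4, 3))
  for (s in fa) lat <- place_monokaryon(lat, s, a)
  for (s in fb) lat <- place_monokaryon(lat, s, b)
  occupied_before <- sum(lat$state > 0L)
  cand <- list_candidates(lat, fa[1], "standard")
  win <- cand[cand$lineage_id == 2L, ][1, ]
  lat2 <- apply_mating(lat, fa[1], win)
  expect_equal(sum(lat2$state > 0L), occupied_before)
  expect_true(all(lat2$state[c(fa, fb)] == 2L))
  expect_true(all(lat2$lin1[c(fa, fb)] == 1L))  # focal keeps female role
  expect_true(all(lat2$lin2[c(fa, fb)] == 2L))
})

test_that("di-mon conversion of the donor is switchable", {
  lat <- new_lattice(6, 6)
  mono <- site_index(lat, 3, 3)
  donor <- c(site_index(lat, 3, 4), site_index(lat, 4, 4))
  lat <- place_monokaryon(lat, mono, nuc(0.5, 0.3, 0.2, mt = 0L, lin = 1L))
  dn1 <- nuc(0.3, 0.3, 0.4, mt = 1L, lin = 2L)
  dn2 <- nuc(0.1, 0.1, 0.8, mt = 2L, lin = 3L)
  for (s in donor) lat <- place_dikaryon(lat, s, dn1, dn2)
  cand <- list_candidates(lat, mono, "standard")
  win <- cand[cand$lineage_id == 3L, ][1, ]
  full <- apply_mating(lat, mono, win)
  expect_true(all(full$state[c(mono, donor)] == 2L))
  expect_true(all(full$lin1[c(mono, donor)] == 1L))
  expect_true(all(full$lin2[c(mono, donor)] == 3L))   # partner evicted
  strict <- apply_mating(lat, mono, win, dimon_converts_donor = FALSE)
  expect_identical(strict$lin1[donor[1]], 2L)          # donor untouched
  expect_identical(strict$lin2[donor[1]], 3L)
  expect_identical(strict$state[mono], 2L)
  expect_identical(strict$lin2[mono], 3L)
  expect_error(apply_mating(lat, mono, within(win, mating_type <- 0L)),
               "incompatible")
})

test_that("mating never yields a dikaryon of identical mating types", {
  set.seed(21)
  p <- tiny_params(n_generations = 6L, m = 4L)
  sim <- run_simulation(p)
  lat <- sim$lattice
  di <- lat$state == 2L
  expect_true(all(lat$mt1[di] != lat$mt2[di]))
})
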