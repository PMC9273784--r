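test_that("the contact cutoff is a strict inequality at 6 A", {
  expect_equal(compute_contacts(pair_at(5.99))$n_inter, 1L)
  expect_equal(compute_contacts(pair_at(6.00))$n_inter, 0L)
})

test_that("contacts match the brute-force all-pairs oracle", {
  # a single extended strand chain
  s <- build_segment("strand", 10L)
  conf1 <- conformation(list(list(chain_id = "A", ca_coords = s)))
  cs <- compute_contacts(conf1, cutoff = 6, min_seq_sep = 1L)
  oracle <- brute_contacts(conf1, 6, 1L)
  expect_equal(cs$n_intra, oracle$n_intra)
  expect_equal(cs$n_inter, 0L)

  # random snapshots from the generator, both seq-sep conventions
  gen <- sample_ensemble(ensemble_spec(n_snapshots = 4L, dimer_fraction = 0.5,
                                       seed = 61L))
  for (i in 1:4) {
    conf <- gen$ensemble[[i]]
    for (sep in c(1L, 3L)) {
      cs <- compute_contacts(conf, 6, sep)
      oracle <- brute_contacts(conf, 6, sep)
      expect_equal(cs$n_inter, oracle$n_inter)
      expect_equal(cs$n_intra, oracle$n_intra)
      expect_equal(cs$n_inter + cs$n_intra, nrow(cs$contacts))
      expect_true(all(cs$contacts$distance < 6))
    }
  }
})

test_that("a planted 18-residue interface contributes all 18 inter contacts", {
  conf <- planted_dimer(78L, 18L, seed = 63L)
  cs <- compute_contacts(conf, cutoff = 6)
  inter <- cs$contacts[cs$contacts$scope == "inter", ]
  planted <- paste(78:95, 78:95)
  expect_true(all(planted %in% paste(inter$res_i, inter$res_j)))
})

test_that("dimer classification switches exactly above 10 close pairs", {
  # interface of length 11 -> 11 same-index pairs below 5 A -> dimer
  conf11 <- planted_dimer(78L, 11L, seed = 65L)
  lab11 <- classify_dimer(conf11)
  expect_equal(lab11$n_close_pairs, brute_close_pairs(conf11, 5))
  expect_gte(lab11$n_close_pairs, 11L)
  expect_true(lab11$is_dimer)

  # interface of length 10 -> 10 close pairs -> not a dimer
  conf10 <- planted_dimer(78L, 10L, seed = 67L)
  lab10 <- classify_dimer(conf10)
  expect_equal(lab10$n_close_pairs, 10L)
  expect_false(lab10$is_dimer)

  apart <- two_chain_conf(cbind((1:20) * 3.8, 0, 0),
                          cbind((1:20) * 3.8, 25, 0))
  lab <- classify_dimer(apart)
  expect_false(lab$is_dimer)
  expect_equal(lab$n_close_pairs, 0L)

  single <- conformation(list(list(chain_id = "A",
                                   ca_coords = cbind(1:5 * 3.8, 0, 0))))
  expect_error(classify_dimer(single), "exactly 2 chains")
})

test_that("dimer classification reproduces the planted fraction exactly", {
  gen <- sample_ensemble(ensemble_spec(n_snapshots = 20L,
                                       dimer_fraction = 0.35, seed = 69L))
  cls <- vapply(seq_len(20L), function(i) {
    classify_dimer(gen$ensemble[[i]])$is_dimer
  }, logical(1))
  expect_equal(sum(cls), round(20 * 0.35))
})

test_that("mean intermolecular contacts agree with a hand count", {
  # residue 10 of chain A sits within 6 A of residues 20 and 21 of chain B;
  # every other pair is far away: profile value (2 + 0) / 2 = 1 at residue 10
  a <- matrix(rep(c(0, 0, 1e4), each = 30), 30, 3)
  a[, 3] <- a[, 3] + (1:30) * 50
  b <- a + matrix(rep(c(0, 1e4, 0), each = 30), 30, 3)
  a[10, ] <- c(0, 0, 0)
  b[20, ] <- c(3, 0, 0)
  b[21, ] <- c(-3, 0, 0)
  conf <- two_chain_conf(a, b)
  prof <- mean_intermolecular_contacts(ca_ensemble(list(conf)))
  expect_equal(prof[10], 1.0)
  expect_equal(prof[20], 0.5) # one contact on the B copy, none on A's
  expect_equal(prof[21], 0.5)
  expect_equal(sum(prof), 2.0)

  # chain-swap invariance
  swapped <- two_chain_conf(b, a)
  expect_equal(mean_intermolecular_contacts(ca_ensemble(list(swapped))), prof)
})

test_that("contact probability maps are symmetrised frequencies", {
  gen <- sample_ensemble(ensemble_spec(n_snapshots = 6L, dimer_fraction = 1,
                                       dfncs_fraction_of_dimers = 1,
                                       seed = 71L))
  maps <- contact_probability_maps(gen$ensemble)
  expect_true(all(maps$inter >= 0 & maps$inter <= 1))
  expect_equal(maps$inter, t(maps$inter))
  expect_equal(maps$intra, t(maps$intra))
  # the planted same-index interface appears in every snapshot
  expect_equal(unname(diag(maps$inter)[78:95]), rep(1, 18))
  # spot-check one cell against the brute-force frequency
  freq <- mean(vapply(seq_len(6L), function(i) {
    conf <- gen$ensemble[[i]]
    d1 <- euclid(conf$chains[[1]]$ca_coords[80, ],
                 conf$chains[[2]]$ca_coords[82, ]) < 6
    d2 <- euclid(conf$chains[[2]]$ca_coords[80, ],
                 conf$chains[[1]]$ca_coords[82, ]) < 6
    (d1 + d2) / 2
  }, 0))
  expect_equal(maps$inter[80, 82], freq)
})

test_that("effective landscapes follow the closed-form -ln(P/Pmax)", {
  # all samples in one bin
  one <- effective_landscape(rep(3, 10), rep(4, 10), 5L)
  expect_equal(sum(one$P), 1)
  occ <- is.finite(one$F)
  expect_equal(sum(occ), 1L)
  expect_equal(one$F[occ], 0)

  # two bins with counts 100 and 92: dF = ln(100/92)
  two <- effective_landscape(c(rep(1, 100), rep(50, 92)),
                             c(rep(1, 100), rep(50, 92)), 5L)
  f <- sort(two$F[is.finite(two$F)])
  expect_equal(f, c(0, log(100 / 92)))
  expect_equal(sum(two$P), 1)

  # uniform occupancy: F = 0 everywhere occupied
  unif <- effective_landscape(rep(c(0, 10, 20), each = 3),
                              rep(c(0, 10, 20), 3), 5L)
  expect_true(all(unif$F[is.finite(unif$F)] == 0))

  expect_error(effective_landscape(numeric(0), numeric(0)), ">= 1")
})

test_that("local minima recover two-basin depths and respect the window", {
  x <- c(rep(1, 100), rep(50, 60))
  y <- c(rep(1, 100), rep(50, 60))
  grid <- effective_landscape(x, y, 5L)
  mins <- find_minima(grid, depth_window = 1.0)
  expect_equal(nrow(mins), 2L)
  expect_equal(mins$F, c(0, log(100 / 60)), tolerance = 1e-12)

  # a shallow third basin outside the window is dropped
  x2 <- c(x, rep(100, 20))
  y2 <- c(y, rep(100, 20))
  mins2 <- find_minima(effective_landscape(x2, y2, 5L), depth_window = 1.0)
  expect_equal(nrow(mins2), 2L)
  mins3 <- find_minima(effective_landscape(x2, y2, 5L), depth_window = 2.0)
  expect_equal(nrow(mins3), 3L)
  expect_equal(mins3$F[3], log(100 / 20), tolerance = 1e-12)

  single <- find_minima(effective_landscape(rep(2, 5), rep(2, 5), 5L))
  expect_equal(nrow(single), 1L)
  expect_equal(single$F, 0)
})
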