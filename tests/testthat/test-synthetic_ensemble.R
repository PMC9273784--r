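test_that("ideal segments reproduce their closed-form geometry", {
  h <- build_segment("helix", 10L)
  bonds <- sqrt(rowSums(diff(h)^2))
  expect_true(all(abs(bonds - 3.83) < 0.01))
  geo <- backbone_geometry(h)
  oracle <- ideal_helix_angles()
  expect_equal(mean(geo$theta, na.rm = TRUE), oracle["theta"],
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(mean(geo$tau, na.rm = TRUE), oracle["tau"],
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_gt(oracle["tau"], 45)
  expect_lt(oracle["tau"], 55)

  s <- build_segment("strand", 12L)
  expect_equal(unname(sqrt(rowSums(diff(s)^2))), rep(3.8, 11), tolerance = 1e-9)
  gs <- backbone_geometry(s)
  expect_true(all(abs(gs$tau[!is.na(gs$tau)]) > 160))

  s2 <- build_segment("strand", 2L)
  expect_equal(euclid(s2[1, ], s2[2, ]), 3.8, tolerance = 1e-12)

  c1 <- build_segment("coil", 50L, seed = 1L)
  c2 <- build_segment("coil", 50L, seed = 1L)
  expect_identical(c1, c2)
  expect_equal(unname(sqrt(rowSums(diff(c1)^2))), rep(3.8, 49),
               tolerance = 1e-9)
  d <- as.matrix(dist(c1))
  nonbond <- abs(row(d) - col(d)) > 1L
  expect_gte(min(d[nonbond]), 4.0)

  expect_error(build_segment("helix", 0L), ">= 1")
})

test_that("assembled chains carry exact ground-truth labels and 3.8 A bonds", {
  ch <- assemble_chain(list(segment_spec("helix", 53L, 13L)), 140L, seed = 3L)
  expect_equal(sum(ch$labels == "H"), 13L)
  expect_equal(which(ch$labels == "H"), 53:65)
  expect_equal(sum(ch$labels == "C"), 127L)

  ch2 <- assemble_chain(list(segment_spec("helix", 53L, 13L),
                             segment_spec("strand", 36L, 7L)), 140L, seed = 4L)
  want <- rep("C", 140)
  want[53:65] <- "H"
  want[36:42] <- "E"
  expect_equal(ch2$labels, want)
  bonds <- sqrt(rowSums(diff(ch2$ca_coords)^2))
  expect_true(all(bonds > 3.79 & bonds < 3.84))

  expect_error(assemble_chain(list(segment_spec("helix", 135L, 10L)), 140L),
               "exceeds chain length")
  expect_error(assemble_chain(list(segment_spec("helix", 50L, 10L),
                                   segment_spec("strand", 55L, 10L)), 140L),
               "overlapping")
})

test_that("planted in-register interfaces give exactly the intended close pairs", {
  conf <- planted_dimer(78L, 18L, seed = 21L)
  a <- conf$chains[[1]]$ca_coords
  b <- conf$chains[[2]]$ca_coords
  same_idx <- vapply(1:140, function(r) euclid(a[r, ], b[r, ]) < 5, logical(1))
  expect_equal(which(same_idx), 78:95)
  expect_equal(vapply(78:95, function(r) euclid(a[r, ], b[r, ]), 0),
               rep(4.8, 18), tolerance = 0.1)

  shifted <- planted_dimer(78L, 10L, seed = 23L, kind = "shifted_parallel",
                           shift = 1L)
  a <- shifted$chains[[1]]$ca_coords
  b <- shifted$chains[[2]]$ca_coords
  expect_equal(sum(vapply(1:140, function(r) euclid(a[r, ], b[r, ]) < 5,
                          logical(1))), 0L)
  expect_equal(sum(vapply(78:87, function(r) euclid(a[r, ], b[r + 1L, ]) < 5,
                          logical(1))), 10L)

  apart <- plant_dimer(assemble_chain(list(), 140L, seed = 25L, chain_id = "A"),
                       assemble_chain(list(), 140L, seed = 26L, chain_id = "B"),
                       dimer_plant_spec("none"), seed = 27L)
  expect_equal(brute_close_pairs(apart, 5), 0L)
})

test_that("non-interface interchain pairs keep clear of the partner chain", {
  conf <- planted_dimer(78L, 18L, seed = 31L)
  d <- matrix(NA_real_, 140, 140)
  a <- conf$chains[[1]]$ca_coords
  b <- conf$chains[[2]]$ca_coords
  for (i in 1:140) for (j in 1:140) d[i, j] <- euclid(a[i, ], b[j, ])
  free <- setdiff(1:140, 78:95)
  expect_gt(min(d[free, free]), 6)
})

test_that("sampled ensembles honour the planted dimer and Dfncs partition", {
  spec <- ensemble_spec(n_snapshots = 30L, dimer_fraction = 0.23,
                        dfncs_fraction_of_dimers = 0.14, seed = 41L)
  gen <- sample_ensemble(spec)
  td <- unique(gen$truth[, c("snapshot", "is_dimer", "is_dfncs")])
  expect_equal(sum(td$is_dimer), round(30 * 0.23)) # 7
  expect_equal(sum(td$is_dfncs), round(round(30 * 0.23) * 0.14)) # 1
  # classification on the generated geometry reproduces the plant exactly
  cls <- vapply(seq_len(length(gen$ensemble)), function(i) {
    classify_dimer(gen$ensemble[[i]])$is_dimer
  }, logical(1))
  expect_equal(cls, td$is_dimer)
  dfc <- vapply(seq_len(length(gen$ensemble)), function(i) {
    classify_dfncs(gen$ensemble[[i]])$is_dfncs
  }, logical(1))
  expect_equal(dfc & cls, td$is_dfncs)
  # monomer snapshots are far apart
  mono <- td$snapshot[!td$is_dimer]
  seps <- vapply(mono, function(i) {
    conf <- gen$ensemble[[i]]
    min(dimerlens:::cross_dist(conf$chains[[1]]$ca_coords,
                               conf$chains[[2]]$ca_coords))
  }, 0)
  expect_true(all(seps > 10))
})

test_that("dimer_fraction 0 yields no dimers at all", {
  gen <- sample_ensemble(ensemble_spec(n_snapshots = 6L, dimer_fraction = 0,
                                       seed = 43L))
  cls <- vapply(seq_len(6L), function(i) {
    classify_dimer(gen$ensemble[[i]])$is_dimer
  }, logical(1))
  expect_false(any(cls))
})

test_that("seeded generation is bitwise reproducible", {
  spec <- ensemble_spec(n_snapshots = 8L, dimer_fraction = 0.5, seed = 47L)
  expect_identical(sample_ensemble(spec), sample_ensemble(spec))
})

test_that("planted ideal geometry is recovered by the SS assignment", {
  # helix: interior residues of the planted 53-65 helix come back H,
  # nothing outside the segment is ever H (100% precision)
  ch <- assemble_chain(list(segment_spec("helix", 53L, 13L)), 140L, seed = 51L)
  conf <- two_chain_conf(ch$ca_coords, ch$ca_coords + 300)
  ss <- assign_ss(conf)
  hres <- which(ss$labels$A == "H")
  expect_true(all(hres %in% 53:65))
  interior <- 55:62
  expect_true(all(interior %in% hres))
  expect_gte(length(hres) / 13, 0.75)

  # paired strands: interface residues come back E with full precision
  dim <- planted_dimer(78L, 18L, seed = 53L)
  ssd <- assign_ss(dim)
  eres <- which(ssd$labels$A == "E")
  expect_true(all(eres %in% 78:95))
  expect_true(all(80:93 %in% eres))
})

test_that("chain radii of gyration realise the requested mixture", {
  spec <- ensemble_spec(n_snapshots = 60L, dimer_fraction = 0,
                        rg_mixture = cbind(mean = c(28, 45), sd = c(1.5, 1.5),
                                           weight = c(0.5, 0.5)),
                        seed = 57L)
  gen <- sample_ensemble(spec)
  rgs <- unlist(lapply(seq_len(60L), function(i) {
    radius_of_gyration(gen$ensemble[[i]], "chain")
  }))
  lo <- rgs[rgs < 36.5]
  hi <- rgs[rgs >= 36.5]
  expect_equal(mean(lo), 28, tolerance = 0.06)
  expect_equal(mean(hi), 45, tolerance = 0.06)
  expect_equal(length(lo) / length(rgs), 0.5, tolerance = 0.15)
})
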