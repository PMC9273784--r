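test_that("backbone geometry matches the analytic helix and strand values", {
  h <- build_segment("helix", 12L)
  geo <- backbone_geometry(h)
  oracle <- ideal_helix_angles()
  inner <- 3:9
  expect_equal(geo$theta[inner], rep(unname(oracle["theta"]), length(inner)),
               tolerance = 1e-9)
  expect_equal(geo$tau[inner], rep(unname(oracle["tau"]), length(inner)),
               tolerance = 1e-9)
  # terminals are undefined
  expect_true(is.na(geo$theta[1]) && is.na(geo$theta[12]))
  expect_true(is.na(geo$tau[1]) && is.na(geo$tau[11]) && is.na(geo$tau[12]))

  s <- build_segment("strand", 10L)
  gs <- backbone_geometry(s)
  expect_true(all(abs(gs$tau[2:8]) > 160))
  expect_equal(gs$theta[5], 125, tolerance = 1e-9)

  expect_error(backbone_geometry(matrix(0, 3, 3)), "at least 4")
})

test_that("collinear triplets give NA flags, not exceptions", {
  straight <- cbind((1:6) * 3.8, 0, 0)
  geo <- backbone_geometry(straight)
  expect_true(all(is.na(geo$theta[2:5])))
  expect_true(all(is.na(geo$tau[2:4])))
})

test_that("helices need at least 4 residues and planted helices are recovered", {
  ch <- assemble_chain(list(segment_spec("helix", 53L, 13L)), 140L, seed = 81L)
  conf <- two_chain_conf(ch$ca_coords, ch$ca_coords + 400)
  ss <- assign_ss(conf)
  hres <- which(ss$labels$A == "H")
  expect_true(all(hres %in% 53:65))     # 100% precision
  expect_true(all(55:62 %in% hres))     # interior recall
  expect_identical(ss$labels$A, ss$labels$B)

  # a 3-residue helical stretch is below the minimum length: no H anywhere
  short <- assemble_chain(list(segment_spec("helix", 60L, 3L)), 140L,
                          seed = 83L)
  conf3 <- two_chain_conf(short$ca_coords, short$ca_coords + 400)
  expect_false(any(assign_ss(conf3)$labels$A == "H"))
})

test_that("unpaired extended runs are never sheets", {
  # two strands > 6 A apart with no partner anywhere
  a <- build_segment("strand", 10L)
  b <- build_segment("strand", 10L)
  b[, 2] <- b[, 2] + 12
  conf <- two_chain_conf(a, b)
  ss <- assign_ss(conf)
  expect_false(any(unlist(ss$labels) == "E"))
  expect_equal(nrow(ss$sheet_pairs), 0L)
})

test_that("interchain in-register interfaces pair as parallel inter sheets", {
  conf <- planted_dimer(78L, 18L, seed = 85L)
  ss <- assign_ss(conf)
  pr <- ss$sheet_pairs
  inter <- pr[pr$scope == "inter", ]
  expect_true(all(inter$orientation == "parallel"))
  expect_gte(nrow(inter), 14L)
  # register is exactly in-register for every reported pair
  expect_true(all(inter$res_a == inter$res_b))
})

test_that("intrachain hairpins pair as antiparallel with the mirrored register", {
  # strands at residues 6-12 and 17-23 of a 27-residue trace, register
  # j = 29 - i by construction
  s1 <- build_segment("strand", 7L)
  s2 <- s1[7:1, , drop = FALSE]
  s2[, 2] <- s2[, 2] + 4.8
  turn <- rbind(c(23, 1, 2.5), c(24.5, 4.0, 3.5), c(21.5, 6.5, 3.0),
                c(24.0, 8.0, 1.5))
  pre <- cbind(seq(-20, -4, length.out = 5), -6, 0)
  post <- cbind(seq(26, 40, length.out = 5), 12, 0)
  coords <- rbind(pre, s1, turn, s2, post)
  conf <- two_chain_conf(coords, coords + 300)
  ss <- assign_ss(conf)
  pr <- ss$sheet_pairs[ss$sheet_pairs$scope == "intra" &
                       ss$sheet_pairs$chain_a == "A", ]
  expect_gt(nrow(pr), 0L)
  expect_true(all(pr$orientation == "antiparallel"))
  expect_true(all(pr$res_a + pr$res_b == 29L))
})

test_that("a single isolated close pair is not a sheet", {
  # one extended residue pair in contact with no consecutive support
  mask <- list(c(rep(FALSE, 4), TRUE, rep(FALSE, 5)),
               c(rep(FALSE, 4), TRUE, rep(FALSE, 5)))
  a <- build_segment("strand", 10L)
  b <- a
  b[, 2] <- b[, 2] + 4.8
  conf <- two_chain_conf(a, b)
  pairs <- detect_sheet_pairings(conf, mask)
  expect_equal(nrow(pairs), 0L)
})

test_that("assignments are invariant under rigid motion", {
  conf <- planted_dimer(78L, 18L, seed = 87L)
  q <- qr.Q(qr(matrix(c(0.1, 0.5, -0.2, 0.7, 0.2, 0.4, -0.3, 0.6, 0.5), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  moved <- conformation(lapply(conf$chains, function(ch) {
    list(chain_id = ch$chain_id,
         ca_coords = sweep(ch$ca_coords %*% q, 2, c(-30, 12, 7)))
  }))
  ss1 <- assign_ss(conf)
  ss2 <- assign_ss(moved)
  expect_identical(ss1$labels, ss2$labels)
  expect_equal(ss1$sheet_pairs[, c("res_a", "res_b", "orientation", "scope")],
               ss2$sheet_pairs[, c("res_a", "res_b", "orientation", "scope")])
})

test_that("regional residue counts are exact bookkeeping", {
  ch <- assemble_chain(list(segment_spec("helix", 53L, 13L)), 140L, seed = 89L)
  conf <- two_chain_conf(ch$ca_coords, ch$ca_coords + 400)
  ss <- assign_ss(conf)
  counts <- count_ss_region(ss, c(1L, 95L))
  # both chains contribute the same recovered helix run
  expect_equal(counts$alpha, 2L * sum(ss$labels$A == "H"))
  expect_equal(counts$beta, 0L)
  expect_lte(counts$alpha + counts$beta, 190L)

  none <- assign_ss(two_chain_conf(build_segment("coil", 140L, seed = 91L),
                                   build_segment("coil", 140L, seed = 92L) + 400))
  c0 <- count_ss_region(none, c(1L, 95L))
  expect_lte(c0$alpha + c0$beta, 190L)
  expect_error(count_ss_region(ss, c(0L, 95L)), "invalid region")
})

test_that("B/HB splitting matches the planted helix fraction", {
  spec <- ensemble_spec(n_snapshots = 16L, dimer_fraction = 0,
                        helix_fraction = 0.5, seed = 93L)
  gen <- sample_ensemble(spec)
  counts <- do.call(rbind, lapply(seq_len(16L), function(i) {
    cc <- count_ss_region(assign_ss(gen$ensemble[[i]]), c(1L, 95L))
    data.frame(alpha = cc$alpha, beta = cc$beta)
  }))
  split <- split_B_HB(counts)
  planted_helix <- unique(gen$truth[gen$truth$planted_label == "H",
                                    "snapshot"])
  expect_equal(sum(split$state == "HB"), length(planted_helix))
  expect_equal(split$b_fraction, 1 - length(planted_helix) / 16)

  # all-helix ensembles leave B empty; all-coil leaves HB empty
  all_h <- split_B_HB(data.frame(alpha = c(5, 8), beta = c(0, 2)))
  expect_equal(sum(all_h$state == "B"), 0L)
  all_b <- split_B_HB(data.frame(alpha = c(0, 0), beta = c(3, 9)))
  expect_equal(sum(all_b$state == "HB"), 0L)
  expect_equal(sum(all_b$b_density), 1)
})

test_that("the cumulative DOS curve follows the closed form", {
  # single occupied bin at alpha = 0: step to 1 at c = 0
  single <- cumulative_dos_curve(data.frame(alpha = rep(0L, 5),
                                            beta = rep(10L, 5)),
                                 cutoffs = c(0, 1, 2))
  expect_equal(single$fraction, c(1, 1, 1))

  # two equally occupied bins, one on the alpha = 0 axis: both at F = 0
  tie <- cumulative_dos_curve(data.frame(alpha = c(0, 0, 4, 4),
                                         beta = c(5, 5, 7, 7)),
                              cutoffs = c(0, 0.5))
  expect_equal(tie$fraction, c(1, 1))

  # probabilities 0.8 (alpha = 0) and 0.2: jump at c = ln 4
  two <- cumulative_dos_curve(data.frame(alpha = c(rep(0, 80), rep(3, 20)),
                                         beta = c(rep(10, 80), rep(12, 20))),
                              cutoffs = c(0, log(4) - 1e-9, log(4) + 1e-9, 9))
  expect_equal(two$fraction, c(0.8, 0.8, 1, 1))
  expect_true(all(diff(two$fraction) >= 0))

  expect_error(cumulative_dos_curve(data.frame(alpha = c(2, 3),
                                               beta = c(1, 1))),
               "B reference state")
})

test_that("orientation percentages match a hand count on pure ensembles", {
  # every snapshot an in-register parallel dimer: the paired residues are
  # the 16 interface residues with full dihedral support on each chain,
  # i.e. 32 of 280 residues per snapshot
  confs <- lapply(c(95L, 97L), function(s) planted_dimer(78L, 18L, seed = s))
  sss <- lapply(confs, assign_ss)
  pct <- orientation_percentages(sss)
  paired <- unique(unlist(lapply(sss, function(a) {
    pr <- a$sheet_pairs
    pr[pr$orientation == "parallel", c("res_a")]
  })))
  expect_equal(pct$parallel_pct, 100 * 32 / 280, tolerance = 1e-9)
  expect_equal(pct$antiparallel_pct, 0)
  expect_true(all(vapply(sss, function(a) {
    all(a$sheet_pairs$orientation == "parallel")
  }, logical(1))))

  # chain-swap invariance and bounds
  swapped <- lapply(confs, function(conf) {
    assign_ss(two_chain_conf(conf$chains[[2]]$ca_coords,
                             conf$chains[[1]]$ca_coords))
  })
  pct2 <- orientation_percentages(swapped)
  expect_equal(pct2$parallel_pct, pct$parallel_pct)
  expect_gte(pct$parallel_pct, 0)
  expect_lte(pct$parallel_pct, 100)
  expect_error(orientation_percentages(list()), "empty")
})
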