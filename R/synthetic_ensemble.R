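# Synthetic two-chain Calpha ensembles with planted, labelled structure.
#
# Geometry targets: 3.8 A virtual bonds everywhere; ideal alpha-helix
# parametrization (radius 2.3 A, rise 1.5 A/residue, 100 deg/residue, giving
# pseudo bond angle ~90 deg and pseudo dihedral ~+50 deg); extended zig-zag
# strands (bond angle 125 deg, planar dihedral 180 deg); self-avoiding coils
# with a minimum 4.0 A non-bonded separation. In-register intermolecular
# parallel beta-sheet interfaces are planted at 4.8 A spacing, the same-index
# interchain distance seen in alpha-synuclein fibrils.

.BOND <- 3.8
.MIN_SEP <- 4.0
.INTER_CLEAR <- 6.0
.STRAND_THETA <- 125 # deg, pseudo bond angle of the zig-zag build

#' Segment specification for the synthetic generator
#'
#' @param kind `"helix"`, `"strand"` or `"coil"`.
#' @param start 1-based first residue of the segment.
#' @param length Number of residues (>= 1).
#' @return A `segment_spec` list.
#' @export
segment_spec <- function(kind = c("helix", "strand", "coil"), start, length) {
  kind <- match.arg(kind)
  start <- as.integer(start)
  length <- as.integer(length)
  if (length < 1L) stop("segment length must be >= 1")
  if (start < 1L) stop("segment start must be >= 1")
  structure(list(kind = kind, start = start, length = length),
            class = "segment_spec")
}

#' Dimer interface specification
#'
#' Describes the planted intermolecular beta-sheet interface: in-register
#' parallel (residue i of chain A faces residue i of chain B, as in fibrils),
#' register-shifted parallel, antiparallel, or none (free monomers).
#'
#' @param interface_kind One of `"in_register_parallel"`, `"shifted_parallel"`,
#'   `"antiparallel"`, `"none"`.
#' @param interface_start 1-based first interface residue.
#' @param interface_length Number of interface residues.
#' @param register_shift Signed register shift (0 for in-register); residue i
#'   of chain A faces residue i + `register_shift` of chain B.
#' @param interchain_spacing Interchain Calpha-Calpha spacing in Angstrom
#'   (default 4.8, the fibril value).
#' @return A `dimer_plant_spec` list.
#' @export
dimer_plant_spec <- function(interface_kind = c("in_register_parallel",
                                                "shifted_parallel",
                                                "antiparallel", "none"),
                             interface_start = 78L, interface_length = 18L,
                             register_shift = 0L, interchain_spacing = 4.8) {
  interface_kind <- match.arg(interface_kind)
  if (interchain_spacing <= 0) stop("interchain_spacing must be > 0")
  if (interface_kind == "in_register_parallel" && register_shift != 0L) {
    stop("in_register_parallel means register_shift = 0")
  }
  structure(list(interface_kind = interface_kind,
                 interface_start = as.integer(interface_start),
                 interface_length = as.integer(interface_length),
                 register_shift = as.integer(register_shift),
                 interchain_spacing = interchain_spacing),
            class = "dimer_plant_spec")
}

#' Build one ideal secondary-structure segment
#'
#' Helix: ideal alpha-helix Calpha parametrization (radius 2.3 A, rise
#' 1.5 A/residue, 100 degrees/residue). Strand: planar extended zig-zag with
#' 3.8 A virtual bonds. Coil: seeded self-avoiding random walk with 3.8 A
#' bonds and a minimum 4.0 A non-bonded separation.
#'
#' @param kind `"helix"`, `"strand"` or `"coil"`.
#' @param n Number of residues (>= 1).
#' @param seed Integer seed (used by the coil walk; helix and strand are
#'   deterministic closed forms).
#' @return An `n` x 3 coordinate matrix in Angstrom.
#' @export
build_segment <- function(kind = c("helix", "strand", "coil"), n, seed = 1L) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (n < 1L) stop("segment size must be >= 1")
  switch(kind,
    helix = helix_template(n),
    strand = strand_template(n),
    coil = with_seed(seed, {
      g <- grow_walk(n, knob = 0.3)
      if (is.null(g)) stop("coil walk failed for n = ", n)
      g
    }))
}

helix_template <- function(n, radius = 2.3, rise = 1.5, turn_deg = 100) {
  t <- seq_len(n) - 1L
  w <- turn_deg * pi / 180
  cbind(radius * cos(t * w), radius * sin(t * w), rise * t)
}

strand_template <- function(n) {
  a <- .BOND * sin(.STRAND_THETA / 2 * pi / 180)
  b <- .BOND * cos(.STRAND_THETA / 2 * pi / 180) / 2
  t <- seq_len(n) - 1L
  cbind(t * a, b * (-1)^t, 0)
}

# ---- internal growth machinery --------------------------------------------

step_direction <- function(prev_dir, knob, bias, bias_w, centroid, from) {
  d <- rnorm(3)
  d <- d / sqrt(sum(d * d))
  if (knob > 0) d <- d + knob * prev_dir
  if (knob < 0) {
    toc <- centroid - from
    nt <- sqrt(sum(toc * toc))
    if (nt > 1e-9) d <- d + (-knob) * toc / nt
  }
  if (!is.null(bias)) d <- d + bias_w * bias
  unit(d)
}

clash_free <- function(pt, own_pts, obstacles) {
  if (!is.null(own_pts) && nrow(own_pts) > 0) {
    d2 <- rowSums(sweep(own_pts, 2, pt)^2)
    if (min(d2) < .MIN_SEP^2) return(FALSE)
  }
  if (!is.null(obstacles) && nrow(obstacles) > 0) {
    d2 <- rowSums(sweep(obstacles, 2, pt)^2)
    if (min(d2) < .INTER_CLEAR^2) return(FALSE)
  }
  TRUE
}

# Free self-avoiding walk used by build_segment("coil", ...).
grow_walk <- function(n, knob = 0.3, bias = NULL, bias_w = 0.8,
                      max_tries = 50L) {
  p <- matrix(0, n, 3)
  if (n == 1L) return(p)
  dir <- unit(rnorm(3))
  for (i in 2:n) {
    done <- FALSE
    for (k in seq_len(max_tries)) {
      cen <- colMeans(p[seq_len(i - 1L), , drop = FALSE])
      d <- step_direction(dir, knob, bias, bias_w, cen, p[i - 1L, ])
      cand <- p[i - 1L, ] + .BOND * d
      if (clash_free(cand, p[seq_len(max(i - 2L, 0L)), , drop = FALSE], NULL)) {
        p[i, ] <- cand
        dir <- d
        done <- TRUE
        break
      }
    }
    if (!done) return(NULL)
  }
  p
}

# Place residues `order_idx` (a contiguous forward or backward run) of one
# chain. `coords`/`placed` carry the partially built chain; `seg_id` maps
# residues to structured segments with canonical `templates`. Grown points
# keep >= .MIN_SEP from non-bonded own-chain points and >= .INTER_CLEAR from
# `obstacles` (the partner chain). Returns updated coords or NULL on dead end.
place_run <- function(coords, placed, order_idx, seg_id, templates,
                      knob = 0.3, bias = NULL, bias_w = 0.8,
                      obstacles = NULL, max_tries = 60L) {
  if (length(order_idx) == 0L) {
    return(coords)
  }
  backward <- length(order_idx) > 1L && order_idx[2] < order_idx[1]
  first <- order_idx[1]
  pred <- first + if (backward) 1L else -1L
  prev_pt <- coords[pred, ]
  nb2 <- pred + if (backward) 1L else -1L
  prev_dir <- if (nb2 >= 1L && nb2 <= nrow(coords) && placed[nb2]) {
    unit(prev_pt - coords[nb2, ])
  } else {
    unit(rnorm(3))
  }
  own_except <- function(excl) {
    coords[placed & seq_len(nrow(coords)) != excl, , drop = FALSE]
  }
  k <- 1L
  while (k <= length(order_idx)) {
    i <- order_idx[k]
    sid <- seg_id[i]
    placed_pts <- coords[placed, , drop = FALSE]
    cen <- if (nrow(placed_pts) > 0) colMeans(placed_pts) else c(0, 0, 0)
    if (sid > 0L) {
      # remaining part of the segment, in run direction
      seg_res <- which(seg_id == sid)
      block_idx <- if (backward) i:min(seg_res) else i:max(seg_res)
      tmpl <- templates[[sid]]
      rows <- match(block_idx, seg_res)
      slice <- tmpl[rows, , drop = FALSE]
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        d <- step_direction(prev_dir, knob, bias, bias_w, cen, prev_pt)
        rot <- random_rotation()
        block <- sweep(slice, 2, slice[1, ]) %*% t(rot)
        block <- sweep(block, 2, -(prev_pt + .BOND * d))
        good <- clash_free(block[1, ], own_except(pred), obstacles)
        if (good && nrow(block) > 1L) {
          all_own <- coords[placed, , drop = FALSE]
          for (r in 2:nrow(block)) {
            if (!clash_free(block[r, ], all_own, obstacles)) {
              good <- FALSE
              break
            }
          }
        }
        if (good) {
          coords[block_idx, ] <- block
          placed[block_idx] <- TRUE
          prev_pt <- block[nrow(block), ]
          prev_dir <- if (nrow(block) > 1L) {
            unit(block[nrow(block), ] - block[nrow(block) - 1L, ])
          } else d
          pred <- block_idx[length(block_idx)]
          k <- k + length(block_idx)
          ok <- TRUE
          break
        }
      }
      if (!ok) return(NULL)
    } else {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        d <- step_direction(prev_dir, knob, bias, bias_w, cen, prev_pt)
        cand <- prev_pt + .BOND * d
        if (clash_free(cand, own_except(pred), obstacles)) {
          coords[i, ] <- cand
          placed[i] <- TRUE
          prev_pt <- cand
          prev_dir <- d
          pred <- i
          k <- k + 1L
          ok <- TRUE
          break
        }
      }
      if (!ok) return(NULL)
    }
  }
  coords
}

normalise_segments <- function(segments, n_total) {
  if (length(segments) == 0L) {
    return(list(seg_id = integer(n_total), templates = list(),
                labels = rep("C", n_total), segments = list()))
  }
  seg_id <- integer(n_total)
  labels <- rep("C", n_total)
  templates <- vector("list", length(segments))
  for (s in seq_along(segments)) {
    sp <- segments[[s]]
    idx <- sp$start:(sp$start + sp$length - 1L)
    if (max(idx) > n_total) {
      stop("segment [", sp$start, ", ", max(idx), "] exceeds chain length ",
           n_total)
    }
    if (any(seg_id[idx] != 0L)) stop("overlapping segments")
    if (sp$kind == "coil") next # walked like unlisted residues
    seg_id[idx] <- s
    labels[idx] <- if (sp$kind == "helix") "H" else "E"
    templates[[s]] <- if (sp$kind == "helix") helix_template(sp$length)
                      else strand_template(sp$length)
  }
  list(seg_id = seg_id, templates = templates, labels = labels,
       segments = segments)
}

# Build a whole chain (optionally around a pinned block) with bounded restarts.
build_chain_coords <- function(norm, n_total, knob = 0.3, bias = NULL,
                               fixed_idx = NULL, fixed_coords = NULL,
                               obstacles = NULL, max_restarts = 25L) {
  for (r in seq_len(max_restarts)) {
    coords <- matrix(NA_real_, n_total, 3)
    placed <- logical(n_total)
    if (is.null(fixed_idx)) {
      coords[1L, ] <- c(0, 0, 0)
      placed[1L] <- TRUE
      res <- place_run(coords, placed, if (n_total > 1L) 2:n_total else integer(0),
                       norm$seg_id, norm$templates, knob, bias,
                       obstacles = obstacles)
      if (!is.null(res)) return(res)
    } else {
      coords[fixed_idx, ] <- fixed_coords
      placed[fixed_idx] <- TRUE
      lo <- min(fixed_idx)
      hi <- max(fixed_idx)
      res <- coords
      if (lo > 1L) {
        res <- place_run(res, placed, (lo - 1L):1L, norm$seg_id,
                         norm$templates, knob, bias, obstacles = obstacles)
      }
      if (!is.null(res) && hi < n_total) {
        placed2 <- placed
        placed2[seq_len(lo - 1L)] <- lo > 1L
        res <- place_run(res, placed2, (hi + 1L):n_total, norm$seg_id,
                         norm$templates, knob, bias, obstacles = obstacles)
      }
      if (!is.null(res)) return(res)
    }
  }
  NULL
}

chain_rg <- function(coords) {
  cen <- colMeans(coords)
  sqrt(mean(rowSums(sweep(coords, 2, cen)^2)))
}

# Bisection on the compactness knob so the realized chain Rg approaches
# `target_rg` (common random numbers: each evaluation reseeds identically).
build_chain_target_rg <- function(norm, n_total, target_rg, sub_seed,
                                  bias = NULL, fixed_idx = NULL,
                                  fixed_coords = NULL, obstacles = NULL,
                                  tol = 0.8, max_iter = 8L) {
  eval_knob <- function(k) {
    with_seed(sub_seed, build_chain_coords(norm, n_total, knob = k,
                                           bias = bias, fixed_idx = fixed_idx,
                                           fixed_coords = fixed_coords,
                                           obstacles = obstacles))
  }
  lo <- -0.6
  hi <- 3.0
  best <- NULL
  best_err <- Inf
  k <- 0.3
  for (it in seq_len(max_iter)) {
    coords <- eval_knob(k)
    if (is.null(coords)) {
      k <- (k + 0.3) / 2 # retreat toward a forgiving knob
      next
    }
    rg <- chain_rg(coords)
    err <- abs(rg - target_rg)
    if (err < best_err) {
      best <- coords
      best_err <- err
    }
    if (err < tol) break
    if (rg < target_rg) lo <- k else hi <- k
    k <- (lo + hi) / 2
  }
  if (is.null(best)) stop("chain growth failed (self-avoidance dead end)")
  best
}

#' Assemble one chain from segment specifications
#'
#' Residues not covered by a segment become self-avoiding coil. Linker
#' geometry preserves 3.8 A virtual bonds; structured segments keep their
#' ideal internal geometry and are attached with seeded random orientations
#' under a 4.0 A self-avoidance constraint. The ground-truth per-residue
#' label vector (`H`/`E`/`C`; junctions between segments are coil by
#' construction) is returned alongside the coordinates.
#'
#' @param segments List of [segment_spec()] entries (non-overlapping).
#' @param n_total Chain length in residues (default 140).
#' @param seed Integer seed; generation is bitwise reproducible.
#' @param chain_id Chain identifier.
#' @param target_rg Optional target radius of gyration in Angstrom; realised
#'   by adjusting a compactness knob of the coil walk (extension bias or
#'   centroid attraction), never by rescaling coordinates.
#' @return A `chain_record` list: `chain_id`, `ca_coords` (n x 3), `labels`,
#'   `segments`, `n_total`, `seed`.
#' @export
assemble_chain <- function(segments = list(), n_total = 140L, seed = 1L,
                           chain_id = "A", target_rg = NULL) {
  n_total <- as.integer(n_total)
  norm <- normalise_segments(segments, n_total)
  coords <- if (is.null(target_rg)) {
    with_seed(seed, build_chain_coords(norm, n_total))
  } else {
    build_chain_target_rg(norm, n_total, target_rg, sub_seed = seed)
  }
  if (is.null(coords)) stop("chain growth failed (self-avoidance dead end)")
  structure(list(chain_id = chain_id, ca_coords = coords,
                 labels = norm$labels, segments = segments,
                 n_total = n_total, seed = as.integer(seed)),
            class = "chain_record")
}

# ---- dimer planting --------------------------------------------------------

# Interface correspondence: chain A residues a_idx face chain B residues
# b_idx; B's pinned coordinates sit `spacing` along the normal of A's
# interface plane, reversed for antiparallel interfaces.
interface_mapping <- function(spec, n_total) {
  a_idx <- spec$interface_start:(spec$interface_start + spec$interface_length - 1L)
  b_idx <- switch(spec$interface_kind,
    in_register_parallel = a_idx,
    shifted_parallel = a_idx + spec$register_shift,
    antiparallel = rev(a_idx),
    none = integer(0))
  if (length(b_idx) > 0L && (min(b_idx) < 1L || max(b_idx) > n_total)) {
    stop("interface does not fit in both chains")
  }
  list(a_idx = a_idx, b_idx = b_idx)
}

plane_normal <- function(coords) {
  cen <- sweep(coords, 2, colMeans(coords))
  sv <- svd(cen)
  unit(sv$v[, 3])
}

separate_chains <- function(coordsA, coordsB, min_dist) {
  d <- unit(colMeans(coordsB) - colMeans(coordsA))
  if (all(abs(d) < 1e-9)) d <- c(0, 0, 1)
  cur <- min(cross_dist(coordsA, coordsB))
  shift <- max(0, min_dist - cur) + 1
  repeat {
    cand <- sweep(coordsB, 2, -shift * d)
    if (min(cross_dist(coordsA, cand)) > min_dist) return(cand)
    shift <- shift + 5
  }
}

#' Plant a dimer interface between two chains
#'
#' Places chain B rigidly so that its interface strand faces chain A's at the
#' requested spacing and register: residue i of chain A ends up exactly
#' `interchain_spacing` Angstrom from residue `i + register_shift` of chain B
#' (antiparallel interfaces reverse the correspondence). Both chains must
#' carry strand labels across the interface window. If the placement leaves
#' non-interface interchain pairs closer than 6 A, the coil portions are
#' regrown (seeded, bounded retries) with tails biased away from the partner
#' chain; residues of the interface block itself are exempt from the 6 A
#' clearance since cross pairs adjacent in register necessarily sit near
#' `sqrt(spacing^2 + 3.4^2)` in any beta-sheet geometry.
#'
#' @param chainA,chainB `chain_record` objects from [assemble_chain()].
#' @param spec A [dimer_plant_spec()]. `interface_kind = "none"` places the
#'   chains far apart (minimum interchain distance 25 A).
#' @param seed Seed for the regrowth retries.
#' @param max_retries Bounded number of regrowth attempts before erroring.
#' @return A [conformation()] with chains A and B.
#' @export
plant_dimer <- function(chainA, chainB, spec, seed = 1L, max_retries = 20L) {
  n_total <- chainA$n_total
  if (chainB$n_total != n_total) stop("chains must have equal length")
  map <- interface_mapping(spec, n_total)

  if (spec$interface_kind == "none") {
    coordsB <- with_seed(seed, separate_chains(chainA$ca_coords,
                                               chainB$ca_coords, 25))
    return(conformation(list(
      list(chain_id = chainA$chain_id, ca_coords = chainA$ca_coords),
      list(chain_id = chainB$chain_id, ca_coords = coordsB)),
      source_tag = "plant_dimer"))
  }

  if (!all(chainA$labels[map$a_idx] == "E")) {
    stop("chain A must carry strand labels across the interface")
  }
  if (!all(chainB$labels[sort(map$b_idx)] == "E")) {
    stop("chain B must carry strand labels across the interface")
  }

  place_b <- function(coordsA, coordsB) {
    nrm <- plane_normal(coordsA[map$a_idx, , drop = FALSE])
    target <- sweep(coordsA[map$a_idx, , drop = FALSE], 2,
                    -spec$interchain_spacing * nrm)
    fit <- kabsch_fit(coordsB[map$b_idx, , drop = FALSE], target)
    apply_fit(coordsB, fit)
  }

  clearance_ok <- function(coordsA, coordsB) {
    d <- cross_dist(coordsA, coordsB)
    pair_d <- d[cbind(map$a_idx, map$b_idx)]
    if (any(abs(pair_d - spec$interchain_spacing) > 0.1)) return(FALSE)
    free_a <- setdiff(seq_len(n_total), map$a_idx)
    free_b <- setdiff(seq_len(n_total), sort(map$b_idx))
    ok_ff <- length(free_a) == 0L || length(free_b) == 0L ||
      min(d[free_a, free_b]) > .INTER_CLEAR
    # grown tail vs the partner's interface block must also keep clear
    ok_fa <- length(free_a) == 0L || min(d[free_a, sort(map$b_idx)]) > 5
    ok_fb <- length(free_b) == 0L || min(d[map$a_idx, free_b]) > 5
    ok_ff && ok_fa && ok_fb
  }

  coordsB <- place_b(chainA$ca_coords, chainB$ca_coords)
  if (clearance_ok(chainA$ca_coords, coordsB)) {
    return(conformation(list(
      list(chain_id = chainA$chain_id, ca_coords = chainA$ca_coords),
      list(chain_id = chainB$chain_id, ca_coords = coordsB)),
      source_tag = "plant_dimer"))
  }

  # regrow coils around a canonically pinned interface, tails biased apart
  normA <- normalise_segments(chainA$segments, n_total)
  normB <- normalise_segments(chainB$segments, n_total)
  tmplA <- strand_template(spec$interface_length)
  tmplB <- tmplA[match(sort(map$b_idx), map$b_idx), , drop = FALSE]
  tmplB[, 3] <- tmplB[, 3] + spec$interchain_spacing
  for (r in seq_len(max_retries)) {
    sub <- (as.integer(seed) * 1009L + r * 7919L) %% 2147483647L
    coordsA <- with_seed(sub, build_chain_coords(
      normA, n_total, bias = c(0, 0, -1),
      fixed_idx = map$a_idx, fixed_coords = tmplA))
    if (is.null(coordsA)) next
    coordsB2 <- with_seed(sub + 1L, build_chain_coords(
      normB, n_total, bias = c(0, 0, 1),
      fixed_idx = sort(map$b_idx), fixed_coords = tmplB,
      obstacles = coordsA))
    if (is.null(coordsB2)) next
    if (clearance_ok(coordsA, coordsB2)) {
      return(conformation(list(
        list(chain_id = chainA$chain_id, ca_coords = coordsA),
        list(chain_id = chainB$chain_id, ca_coords = coordsB2)),
        source_tag = "plant_dimer"))
    }
  }
  stop("plant_dimer: no clash-free placement after ", max_retries,
       " regrowth retries (interface ", spec$interface_kind, " at ",
       spec$interface_start, "+", spec$interface_length, ")")
}

# ---- ensemble sampling -----------------------------------------------------

#' Ensemble specification for the synthetic generator
#'
#' Defaults emulate the wild-type study conditions: 31% of snapshots are
#' dimers, 8.33% of dimers carry a planted run of fibril-like native contacts
#' (an 18-residue in-register parallel interface over residues 78-95), the
#' transient helix 53-65 is present in every snapshot, and per-chain radii of
#' gyration are drawn from a two-component mixture with means 33.5 and 42.2 A
#' (weights 0.6/0.4, sd 2.5 A).
#'
#' @param n_snapshots Number of snapshots (>= 1).
#' @param dimer_fraction Fraction of snapshots that are dimers, in `[0, 1]`.
#' @param dfncs_fraction_of_dimers Fraction of dimers carrying the planted
#'   native-contact interface, in `[0, 1]`.
#' @param segments Per-chain lists of [segment_spec()] (names `A`, `B`)
#'   planted in every snapshot whose helix flag is on.
#' @param helix_fraction Fraction of snapshots that carry the planted helix
#'   segments (1 = all; lower values generate mixed helix-free/helix-bearing
#'   ensembles for two-state statistics).
#' @param dfncs_interface Interface of Dfncs snapshots ([dimer_plant_spec()]).
#' @param disordered_interface Interface of non-Dfncs dimer snapshots; the
#'   default register-shifted parallel contact patch yields > 10 close pairs
#'   (a dimer) but no same-index contact.
#' @param rg_mixture Matrix with columns `mean`, `sd`, `weight` (Angstrom);
#'   weights must sum to 1.
#' @param seed Integer seed.
#' @return An `ensemble_spec` list.
#' @export
ensemble_spec <- function(n_snapshots = 200L,
                          dimer_fraction = 0.31,
                          dfncs_fraction_of_dimers = 0.0833,
                          segments = list(
                            A = list(segment_spec("helix", 53L, 13L)),
                            B = list(segment_spec("helix", 53L, 13L))),
                          helix_fraction = 1,
                          dfncs_interface = dimer_plant_spec(
                            "in_register_parallel", 78L, 18L, 0L, 4.8),
                          disordered_interface = dimer_plant_spec(
                            "shifted_parallel", 78L, 14L, 1L, 4.8),
                          rg_mixture = cbind(mean = c(33.5, 42.2),
                                             sd = c(2.5, 2.5),
                                             weight = c(0.6, 0.4)),
                          seed = 1L) {
  if (n_snapshots < 1L) stop("n_snapshots must be >= 1")
  stopifnot(dimer_fraction >= 0, dimer_fraction <= 1,
            dfncs_fraction_of_dimers >= 0, dfncs_fraction_of_dimers <= 1,
            helix_fraction >= 0, helix_fraction <= 1)
  w <- rg_mixture[, "weight"]
  if (abs(sum(w) - 1) > 1e-6) stop("rg mixture weights must sum to 1")
  structure(list(n_snapshots = as.integer(n_snapshots),
                 dimer_fraction = dimer_fraction,
                 dfncs_fraction_of_dimers = dfncs_fraction_of_dimers,
                 segments = segments, helix_fraction = helix_fraction,
                 dfncs_interface = dfncs_interface,
                 disordered_interface = disordered_interface,
                 rg_mixture = rg_mixture, seed = as.integer(seed)),
            class = "ensemble_spec")
}

strip_interface_overlap <- function(segs, iface) {
  idx <- iface$interface_start:(iface$interface_start + iface$interface_length - 1L)
  keep <- vapply(segs, function(s) {
    s_idx <- s$start:(s$start + s$length - 1L)
    length(intersect(s_idx, idx)) == 0L
  }, logical(1))
  segs[keep]
}

#' Sample a synthetic labelled ensemble
#'
#' Generates exactly `round(n * dimer_fraction)` dimer snapshots, of which
#' `round(. * dfncs_fraction_of_dimers)` carry the planted in-register
#' native-contact interface; the remaining dimers carry a register-shifted
#' contact patch (dimer by pair count, no same-index contact), and monomer
#' snapshots keep an interchain separation above 10 A. Per-chain compactness
#' is adjusted so chain radii of gyration realise the requested mixture.
#' Fully reproducible from `spec$seed`.
#'
#' @param spec An [ensemble_spec()].
#' @return A list with elements `ensemble` (a [ca_ensemble()]), `truth`
#'   (data frame: snapshot, chain, residue, planted_label, is_dimer,
#'   is_dfncs) and `spec`.
#' @export
sample_ensemble <- function(spec) {
  if (!inherits(spec, "ensemble_spec")) stop("spec must be an ensemble_spec")
  n <- spec$n_snapshots
  n_dimer <- round(n * spec$dimer_fraction)
  n_dfncs <- round(n_dimer * spec$dfncs_fraction_of_dimers)
  n_helix <- round(n * spec$helix_fraction)

  plan <- with_seed(spec$seed, {
    type <- rep("monomer", n)
    dim_pos <- if (n_dimer > 0) sample(n, n_dimer) else integer(0)
    type[dim_pos] <- "disordered"
    if (n_dfncs > 0) type[sample(dim_pos, n_dfncs)] <- "dfncs"
    helix_on <- rep(FALSE, n)
    if (n_helix > 0) helix_on[sample(n, n_helix)] <- TRUE
    comp <- sample(nrow(spec$rg_mixture), 2L * n, replace = TRUE,
                   prob = spec$rg_mixture[, "weight"])
    targets <- rnorm(2L * n, spec$rg_mixture[comp, "mean"],
                     spec$rg_mixture[comp, "sd"])
    list(type = type, helix_on = helix_on,
         targets = matrix(pmin(pmax(targets, 16), 80), ncol = 2))
  })

  n_res <- 140L
  confs <- vector("list", n)
  truth_rows <- vector("list", n)
  for (i in seq_len(n)) {
    sub <- (spec$seed * 1000003L + i * 97L) %% 2147483647L
    type <- plan$type[i]
    segsA <- if (plan$helix_on[i]) spec$segments$A else list()
    segsB <- if (plan$helix_on[i]) spec$segments$B else list()
    if (type == "monomer") {
      chA <- assemble_chain(segsA, n_res, seed = sub, chain_id = "A",
                            target_rg = plan$targets[i, 1])
      chB <- assemble_chain(segsB, n_res, seed = sub + 1L, chain_id = "B",
                            target_rg = plan$targets[i, 2])
      coordsB <- with_seed(sub + 2L,
                           separate_chains(chA$ca_coords, chB$ca_coords, 15))
      conf <- conformation(list(
        list(chain_id = "A", ca_coords = chA$ca_coords),
        list(chain_id = "B", ca_coords = coordsB)),
        snapshot_index = i, source_tag = "synthetic")
      labA <- chA$labels
      labB <- chB$labels
    } else {
      iface <- if (type == "dfncs") spec$dfncs_interface
               else spec$disordered_interface
      map <- interface_mapping(iface, n_res)
      segsA2 <- c(strip_interface_overlap(segsA, iface),
                  list(segment_spec("strand", iface$interface_start,
                                    iface$interface_length)))
      b_lo <- min(map$b_idx)
      segsB2 <- c(strip_interface_overlap(segsB, iface),
                  list(segment_spec("strand", b_lo, iface$interface_length)))
      conf <- plant_dimer_canonical(segsA2, segsB2, iface, n_res, sub,
                                    target_rg = plan$targets[i, ])
      conf$meta$snapshot_index <- i
      normA <- normalise_segments(segsA2, n_res)
      normB <- normalise_segments(segsB2, n_res)
      labA <- normA$labels
      labB <- normB$labels
    }
    confs[[i]] <- conf
    truth_rows[[i]] <- data.frame(
      snapshot = i,
      chain = rep(c("A", "B"), each = n_res),
      residue = rep(seq_len(n_res), 2L),
      planted_label = c(labA, labB),
      is_dimer = type != "monomer",
      is_dfncs = type == "dfncs",
      stringsAsFactors = FALSE)
  }
  list(ensemble = ca_ensemble(confs, provenance = "synthetic"),
       truth = do.call(rbind, truth_rows),
       spec = spec)
}

# Canonical dimer build used by sample_ensemble: interface pinned, tails
# grown outward with opposite normal biases and interchain clearance.
plant_dimer_canonical <- function(segsA, segsB, iface, n_total, seed,
                                  target_rg = NULL, max_retries = 25L) {
  map <- interface_mapping(iface, n_total)
  normA <- normalise_segments(segsA, n_total)
  normB <- normalise_segments(segsB, n_total)
  tmplA <- strand_template(iface$interface_length)
  b_sorted <- sort(map$b_idx)
  tmplB <- tmplA[match(b_sorted, map$b_idx), , drop = FALSE]
  tmplB[, 3] <- tmplB[, 3] + iface$interchain_spacing
  build_one <- function(norm, fixed_idx, fixed_coords, bias, obstacles,
                        sub, target) {
    if (is.null(target)) {
      with_seed(sub, build_chain_coords(norm, n_total, bias = bias,
                                        fixed_idx = fixed_idx,
                                        fixed_coords = fixed_coords,
                                        obstacles = obstacles))
    } else {
      tryCatch(build_chain_target_rg(norm, n_total, target, sub_seed = sub,
                                     bias = bias, fixed_idx = fixed_idx,
                                     fixed_coords = fixed_coords,
                                     obstacles = obstacles),
               error = function(e) NULL)
    }
  }
  for (r in seq_len(max_retries)) {
    sub <- (seed + r * 131L) %% 2147483647L
    coordsA <- build_one(normA, map$a_idx, tmplA, c(0, 0, -1), NULL, sub,
                         if (is.null(target_rg)) NULL else target_rg[1])
    if (is.null(coordsA)) next
    coordsB <- build_one(normB, b_sorted, tmplB, c(0, 0, 1), coordsA,
                         sub + 1L,
                         if (is.null(target_rg)) NULL else target_rg[2])
    if (is.null(coordsB)) next
    return(conformation(list(list(chain_id = "A", ca_coords = coordsA),
                             list(chain_id = "B", ca_coords = coordsB)),
                        source_tag = "synthetic"))
  }
  stop("dimer build failed after ", max_retries, " retries")
}

#' Write the ground-truth label table
#'
#' Sidecar tab-separated table (snapshot, chain, residue, planted_label,
#' is_dimer, is_dfncs) accompanying a written synthetic ensemble.
#'
#' @param truth The `truth` data frame from [sample_ensemble()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_label_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
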