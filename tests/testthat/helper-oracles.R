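# Independent oracles and small builders shared across the tests.
# The oracles use plain double loops over coordinates so they stay
# independent of the package's vectorised implementations.

euclid <- function(p, q) sqrt(sum((p - q)^2))

# Brute-force all-pairs contact count for a 1- or 2-chain conformation.
brute_contacts <- function(conf, cutoff = 6, min_seq_sep = 1L) {
  n_inter <- 0L
  n_intra <- 0L
  for (ci in seq_along(conf$chains)) {
    xyz <- conf$chains[[ci]]$ca_coords
    n <- nrow(xyz)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (j - i >= min_seq_sep && euclid(xyz[i, ], xyz[j, ]) < cutoff) {
          n_intra <- n_intra + 1L
        }
      }
    }
  }
  if (length(conf$chains) == 2L) {
    a <- conf$chains[[1]]$ca_coords
    b <- conf$chains[[2]]$ca_coords
    for (i in seq_len(nrow(a))) {
      for (j in seq_len(nrow(b))) {
        if (euclid(a[i, ], b[j, ]) < cutoff) n_inter <- n_inter + 1L
      }
    }
  }
  list(n_inter = n_inter, n_intra = n_intra)
}

# Brute-force count of interchain residue pairs below a cutoff.
brute_close_pairs <- function(conf, cutoff = 5) {
  a <- conf$chains[[1]]$ca_coords
  b <- conf$chains[[2]]$ca_coords
  n <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (euclid(a[i, ], b[j, ]) < cutoff) n <- n + 1L
    }
  }
  n
}

# Brute-force same-index contact vector.
brute_nfc <- function(conf, cutoff = 5) {
  a <- conf$chains[[1]]$ca_coords
  b <- conf$chains[[2]]$ca_coords
  vapply(seq_len(nrow(a)), function(r) euclid(a[r, ], b[r, ]) < cutoff,
         logical(1))
}

# Longest run of TRUE by direct scan.
brute_max_run <- function(mask) {
  best <- 0L
  cur <- 0L
  for (v in mask) {
    cur <- if (v) cur + 1L else 0L
    best <- max(best, cur)
  }
  best
}

# Closed-form pseudo-angles of the ideal helix parametrization, evaluated
# analytically from three/four consecutive points of the parametric curve.
ideal_helix_angles <- function(radius = 2.3, rise = 1.5, turn_deg = 100) {
  w <- turn_deg * pi / 180
  p <- function(t) c(radius * cos(t * w), radius * sin(t * w), rise * t)
  u <- p(0) - p(1)
  v <- p(2) - p(1)
  theta <- acos(sum(u * v) / sqrt(sum(u * u) * sum(v * v))) * 180 / pi
  b1 <- p(1) - p(0)
  b2 <- p(2) - p(1)
  b3 <- p(3) - p(2)
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2)
  n2 <- cr(b2, b3)
  tau <- atan2(sum(cr(n1, n2) * b2 / sqrt(sum(b2 * b2))), sum(n1 * n2)) *
    180 / pi
  c(theta = theta, tau = tau)
}

# Two-chain conformation with both chains given explicitly.
two_chain_conf <- function(a, b) {
  conformation(list(list(chain_id = "A", ca_coords = a),
                    list(chain_id = "B", ca_coords = b)))
}

# A pair of isolated two-residue chains whose single interchain distance of
# interest is `d` (all other pairs far away).
pair_at <- function(d) {
  a <- rbind(c(0, 0, 0), c(0, 0, 500))
  b <- rbind(c(d, 0, 0), c(d, 0, -500))
  two_chain_conf(a, b)
}

# A planted in-register parallel dimer with strand interface [start, start+len-1].
planted_dimer <- function(start = 78L, len = 18L, seed = 101L,
                          kind = "in_register_parallel", shift = 0L,
                          spacing = 4.8) {
  shiftB <- if (kind == "shifted_parallel") shift else 0L
  chA <- assemble_chain(list(segment_spec("strand", start, len)), 140L,
                        seed = seed, chain_id = "A")
  chB <- assemble_chain(list(segment_spec("strand", start + shiftB, len)),
                        140L, seed = seed + 1L, chain_id = "B")
  plant_dimer(chA, chB,
              dimer_plant_spec(kind, start, len, shift, spacing),
              seed = seed)
}
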