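# Secondary-structure assignment from Calpha geometry: pseudo bond angles
# (curvature) and pseudo dihedrals (torsion), helix/strand windows, sheet
# pairing with orientation, and the (alpha, beta) two-state statistics.

#' Secondary-structure assignment parameters
#'
#' Numeric windows calibrated on ideal geometry: the ideal helix
#' parametrization gives (theta, tau) = (90.4, +50.0) degrees and the
#' extended zig-zag strand (125, 180) degrees. A helix needs at least 4
#' consecutive residues; a paired strand at least 2 (so a minimal beta-sheet
#' has 4 residues).
#'
#' @param helix_theta,helix_tau Helix windows for the pseudo bond angle and
#'   pseudo dihedral, degrees.
#' @param strand_theta Strand window for the pseudo bond angle, degrees.
#' @param strand_tau_abs Window for |tau| of strand candidates, degrees.
#' @param min_helix_len Minimum helix run length (default 4).
#' @param min_strand_len Minimum paired-strand run length (default 2).
#' @param pairing_cutoff Calpha-Calpha cutoff for sheet pairing, Angstrom.
#' @param min_intra_pair_sep Minimum sequence separation for intrachain sheet
#'   pairing (default 4, so a tight hairpin's strands can pair but near
#'   neighbours cannot).
#' @return An `ss_params` list.
#' @export
ss_params <- function(helix_theta = c(80, 105), helix_tau = c(30, 70),
                      strand_theta = c(100, 155), strand_tau_abs = c(140, 180),
                      min_helix_len = 4L, min_strand_len = 2L,
                      pairing_cutoff = 5.5, min_intra_pair_sep = 4L) {
  stopifnot(min_helix_len >= 1L, min_strand_len >= 1L)
  structure(list(helix_theta = helix_theta, helix_tau = helix_tau,
                 strand_theta = strand_theta, strand_tau_abs = strand_tau_abs,
                 min_helix_len = as.integer(min_helix_len),
                 min_strand_len = as.integer(min_strand_len),
                 pairing_cutoff = pairing_cutoff,
                 min_intra_pair_sep = as.integer(min_intra_pair_sep)),
            class = "ss_params")
}

#' Pseudo bond angles and dihedrals of a Calpha trace
#'
#' theta_i is the bond angle at residue i from the triplet (i-1, i, i+1);
#' tau_i is the dihedral from the quadruplet (i-1, i, i+1, i+2). Terminal
#' residues (and near-collinear triplets) carry `NA`.
#'
#' @param coords N x 3 Calpha coordinate matrix, N >= 4.
#' @return Data frame with columns `theta` and `tau` in degrees
#'   (tau in (-180, 180]).
#' @export
backbone_geometry <- function(coords) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 4L) stop("backbone geometry needs at least 4 residues")
  b <- diff(coords) # bond vectors b_i = p_{i+1} - p_i, rows 1..n-1
  bn <- sqrt(rowSums(b * b))
  theta <- rep(NA_real_, n)
  cosang <- rowSums(-b[seq_len(n - 2L), , drop = FALSE] *
                    b[2:(n - 1L), , drop = FALSE]) /
    (bn[seq_len(n - 2L)] * bn[2:(n - 1L)])
  theta[2:(n - 1L)] <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  tau <- rep(NA_real_, n)
  if (n >= 4L) {
    i <- seq_len(n - 3L)
    b1 <- b[i, , drop = FALSE]
    b2 <- b[i + 1L, , drop = FALSE]
    b3 <- b[i + 2L, , drop = FALSE]
    n1 <- row_cross(b1, b2)
    n2 <- row_cross(b2, b3)
    x <- rowSums(n1 * n2)
    y <- rowSums(row_cross(n1, n2) * (b2 / bn[i + 1L]))
    val <- atan2(y, x) * 180 / pi
    deg <- sqrt(rowSums(n1 * n1)) < 1e-8 | sqrt(rowSums(n2 * n2)) < 1e-8
    val[deg] <- NA_real_
    tau[i + 1L] <- val
  }
  collin <- !is.na(theta) & (abs(theta - 180) < 1e-6 | theta < 1e-6)
  theta[collin] <- NA_real_
  data.frame(theta = theta, tau = tau)
}

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

in_window <- function(x, w) !is.na(x) & x >= w[1] & x <= w[2]

runs_at_least <- function(mask, min_len) {
  r <- rle(mask)
  keep <- r$values & r$lengths >= min_len
  inverse.rle(list(lengths = r$lengths, values = keep))
}

# Candidate masks per chain. A residue at a segment's C-terminal junction has
# theta but no tau of its own (tau_i needs residue i+2), so candidacy accepts
# the dihedral of residue i or i-1.
ss_candidates <- function(coords, params) {
  geo <- backbone_geometry(coords)
  tau_ok_h <- in_window(geo$tau, params$helix_tau)
  tau_prev_h <- c(FALSE, tau_ok_h[-length(tau_ok_h)])
  helix <- in_window(geo$theta, params$helix_theta) & (tau_ok_h | tau_prev_h)
  abs_tau <- abs(geo$tau)
  tau_ok_e <- in_window(abs_tau, params$strand_tau_abs)
  tau_prev_e <- c(FALSE, tau_ok_e[-length(tau_ok_e)])
  extended <- in_window(geo$theta, params$strand_theta) &
    (tau_ok_e | tau_prev_e) & !helix
  list(helix = helix, extended = extended, geometry = geo)
}

#' Assign secondary structure to a conformation
#'
#' Residues whose (theta, tau) fall in the helix window and form runs of at
#' least `min_helix_len` are helix (H). Extended candidates become sheet (E)
#' only when paired into beta-sheets (see [detect_sheet_pairings()]) with at
#' least `min_strand_len` consecutive pairs; everything else is coil (C).
#'
#' @param conf A [conformation()]; every chain needs >= 4 residues.
#' @param params An [ss_params()].
#' @return An `ss_assignment`: list with `labels` (list of per-chain H/E/C
#'   vectors) and `sheet_pairs` (data frame: chain_a, res_a, chain_b, res_b,
#'   orientation, scope).
#' @export
assign_ss <- function(conf, params = ss_params()) {
  nc <- n_chains(conf)
  cand <- lapply(seq_len(nc), function(ci) {
    ss_candidates(chain_coords(conf, ci), params)
  })
  labels <- lapply(seq_len(nc), function(ci) {
    n <- nrow(chain_coords(conf, ci))
    lab <- rep("C", n)
    lab[runs_at_least(cand[[ci]]$helix, params$min_helix_len)] <- "H"
    lab
  })
  ext_mask <- lapply(cand, `[[`, "extended")
  pairs <- detect_sheet_pairings(conf, ext_mask, params)
  if (nrow(pairs) > 0) {
    for (ci in seq_len(nc)) {
      cid <- conf$chains[[ci]]$chain_id
      in_sheet <- unique(c(pairs$res_a[pairs$chain_a == cid],
                           pairs$res_b[pairs$chain_b == cid]))
      labels[[ci]][in_sheet] <- "E"
    }
  }
  names(labels) <- vapply(conf$chains, `[[`, "", "chain_id")
  structure(list(labels = labels, sheet_pairs = pairs, params = params),
            class = "ss_assignment")
}

#' @export
print.ss_assignment <- function(x, ...) {
  for (cid in names(x$labels)) {
    tab <- table(factor(x$labels[[cid]], levels = c("H", "E", "C")))
    cat(sprintf("chain %s: H %d  E %d  C %d\n", cid, tab["H"], tab["E"],
                tab["C"]))
  }
  cat(nrow(x$sheet_pairs), "sheet pairs\n")
  invisible(x)
}

#' Detect beta-sheet pairings among extended candidates
#'
#' Residues i (chain X) and j (chain Y) are paired when both are extended
#' candidates, their Calpha distance is below the pairing cutoff, and the
#' pairing propagates over at least `min_strand_len` consecutive residues
#' with a consistent register: parallel when the partner index increases
#' with i, antiparallel when it decreases. Scope is `intra` when X = Y
#' (minimum sequence separation applies), `inter` otherwise.
#'
#' @param conf A [conformation()].
#' @param extended_mask List of per-chain logical vectors (candidate stage of
#'   [assign_ss()]).
#' @param params An [ss_params()].
#' @return Data frame: chain_a, res_a, chain_b, res_b, orientation, scope.
#' @export
detect_sheet_pairings <- function(conf, extended_mask, params = ss_params()) {
  nc <- n_chains(conf)
  out <- list()
  empty <- data.frame(chain_a = character(), res_a = integer(),
                      chain_b = character(), res_b = integer(),
                      orientation = character(), scope = character(),
                      stringsAsFactors = FALSE)
  for (ca in seq_len(nc)) {
    for (cb in ca:nc) {
      ma <- extended_mask[[ca]]
      mb <- extended_mask[[cb]]
      if (!any(ma) || !any(mb)) next
      d <- cross_dist(chain_coords(conf, ca), chain_coords(conf, cb))
      close <- d < params$pairing_cutoff
      close[!ma, ] <- FALSE
      close[, !mb] <- FALSE
      if (ca == cb) {
        sep <- abs(outer(seq_along(ma), seq_along(mb), "-"))
        close[sep < params$min_intra_pair_sep] <- FALSE
        close[lower.tri(close)] <- FALSE # each unordered pair once
      }
      idx <- which(close, arr.ind = TRUE)
      if (nrow(idx) == 0L) next
      has <- function(i, j) {
        i >= 1 & i <= nrow(close) & j >= 1 & j <= ncol(close) &
          close[cbind(pmin(pmax(i, 1), nrow(close)),
                      pmin(pmax(j, 1), ncol(close)))]
      }
      par_ok <- has(idx[, 1] + 1L, idx[, 2] + 1L) |
                has(idx[, 1] - 1L, idx[, 2] - 1L)
      anti_ok <- has(idx[, 1] + 1L, idx[, 2] - 1L) |
                 has(idx[, 1] - 1L, idx[, 2] + 1L)
      cida <- conf$chains[[ca]]$chain_id
      cidb <- conf$chains[[cb]]$chain_id
      scope <- if (ca == cb) "intra" else "inter"
      if (any(par_ok)) {
        out[[length(out) + 1L]] <- data.frame(
          chain_a = cida, res_a = idx[par_ok, 1], chain_b = cidb,
          res_b = idx[par_ok, 2], orientation = "parallel", scope = scope,
          stringsAsFactors = FALSE)
      }
      if (any(anti_ok)) {
        out[[length(out) + 1L]] <- data.frame(
          chain_a = cida, res_a = idx[anti_ok, 1], chain_b = cidb,
          res_b = idx[anti_ok, 2], orientation = "antiparallel", scope = scope,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Count helix and sheet residues in a region
#'
#' @param assignment An `ss_assignment` from [assign_ss()].
#' @param region Integer range `c(start, end)` of residues (default the
#'   N-terminal + NAC window 1-95 over which the two-state statistics are
#'   accumulated).
#' @return An `ss_counts` list: `alpha` (helix residues in the region, summed
#'   over chains), `beta` (sheet residues) and `region`.
#' @export
count_ss_region <- function(assignment, region = c(1L, 95L)) {
  n <- length(assignment$labels[[1]])
  if (region[1] < 1L || region[2] > n || region[1] > region[2]) {
    stop("invalid region [", region[1], ", ", region[2], "]")
  }
  idx <- region[1]:region[2]
  alpha <- sum(vapply(assignment$labels,
                      function(l) sum(l[idx] == "H"), 0L))
  beta <- sum(vapply(assignment$labels,
                     function(l) sum(l[idx] == "E"), 0L))
  structure(list(alpha = alpha, beta = beta, region = region),
            class = "ss_counts")
}

#' Split snapshots into helix-free (B) and helix-bearing (HB) states
#'
#' State B collects conformations with no residue in a helix (alpha = 0);
#' state HB collects the rest. Returns the one-dimensional distribution of
#' beta within B and the joint (alpha, beta) distribution within HB.
#'
#' @param counts Data frame with one row per snapshot and columns `alpha`,
#'   `beta` (e.g. from [count_ss_region()] applied per snapshot).
#' @return List with `state` (factor "B"/"HB" per snapshot), `b_fraction`,
#'   `b_density` (named table over beta) and `hb_density` (data frame alpha,
#'   beta, p).
#' @export
split_B_HB <- function(counts) {
  state <- factor(ifelse(counts$alpha == 0L, "B", "HB"), levels = c("B", "HB"))
  b <- counts[state == "B", , drop = FALSE]
  hb <- counts[state == "HB", , drop = FALSE]
  b_density <- if (nrow(b) > 0) table(b$beta) / nrow(b) else table(integer(0))
  hb_density <- if (nrow(hb) > 0) {
    agg <- as.data.frame(table(hb$alpha, hb$beta), stringsAsFactors = FALSE)
    agg <- agg[agg$Freq > 0, , drop = FALSE]
    data.frame(alpha = as.integer(agg$Var1), beta = as.integer(agg$Var2),
               p = agg$Freq / nrow(hb))
  } else {
    data.frame(alpha = integer(), beta = integer(), p = numeric())
  }
  list(state = state, b_fraction = mean(state == "B"),
       b_density = b_density, hb_density = hb_density)
}

#' Cumulative density-of-states curve over the (alpha, beta) landscape
#'
#' The effective free energy of a snapshot's (alpha, beta) bin is
#' -ln(P / Pmax) in kT units, where Pmax is the maximum probability on the
#' helix-free axis (alpha = 0, the B state). The curve gives the fraction of
#' snapshots whose bin lies within a free-energy cut-off c; its derivative is
#' the density of conformational states.
#'
#' @param counts Data frame with columns `alpha`, `beta` per snapshot.
#' @param cutoffs Numeric grid of cut-off values (kT).
#' @return Data frame with columns `cutoff` and `fraction` (non-decreasing,
#'   reaching 1 for large cut-offs).
#' @export
cumulative_dos_curve <- function(counts, cutoffs = seq(0, 8, by = 0.1)) {
  key <- paste(counts$alpha, counts$beta)
  tab <- table(key)
  p <- as.numeric(tab) / nrow(counts)
  names(p) <- names(tab)
  on_axis <- counts$alpha == 0L
  if (!any(on_axis)) {
    stop("no alpha = 0 snapshots: the B reference state is undefined")
  }
  pmax_b <- max(p[unique(key[on_axis])])
  f_snap <- -log(p[key] / pmax_b)
  data.frame(cutoff = cutoffs,
             fraction = vapply(cutoffs, function(cc) mean(f_snap <= cc), 0))
}

#' Percentages of residues in parallel and antiparallel beta-sheets
#'
#' The percentage of all residues (both chains, all snapshots) participating
#' in sheet pairings of each orientation, intra- and intermolecular pooled.
#' A residue paired in both orientations counts once per orientation.
#'
#' @param assignments List of `ss_assignment` objects (one per snapshot).
#' @return List with `parallel_pct`, `antiparallel_pct` and a `by_scope`
#'   data frame (orientation x scope percentages).
#' @export
orientation_percentages <- function(assignments) {
  if (length(assignments) < 1L) stop("empty ensemble")
  total <- 0L
  n_par <- 0L
  n_anti <- 0L
  scope_acc <- c(parallel.intra = 0L, parallel.inter = 0L,
                 antiparallel.intra = 0L, antiparallel.inter = 0L)
  for (a in assignments) {
    total <- total + sum(vapply(a$labels, length, 0L))
    pr <- a$sheet_pairs
    for (ori in c("parallel", "antiparallel")) {
      sel <- pr[pr$orientation == ori, , drop = FALSE]
      res <- unique(rbind(data.frame(chain = sel$chain_a, res = sel$res_a),
                          data.frame(chain = sel$chain_b, res = sel$res_b)))
      if (ori == "parallel") n_par <- n_par + nrow(res)
      else n_anti <- n_anti + nrow(res)
      for (sc in c("intra", "inter")) {
        ss <- sel[sel$scope == sc, , drop = FALSE]
        rs <- unique(rbind(data.frame(chain = ss$chain_a, res = ss$res_a),
                           data.frame(chain = ss$chain_b, res = ss$res_b)))
        scope_acc[paste(ori, sc, sep = ".")] <-
          scope_acc[paste(ori, sc, sep = ".")] + nrow(rs)
      }
    }
  }
  list(parallel_pct = 100 * n_par / total,
       antiparallel_pct = 100 * n_anti / total,
       by_scope = data.frame(
         orientation = rep(c("parallel", "antiparallel"), each = 2),
         scope = rep(c("intra", "inter"), 2),
         pct = 100 * as.numeric(scope_acc) / total))
}
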