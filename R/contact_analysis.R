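# Contact statistics, dimer classification, contact maps and effective
# free-energy landscapes over (n_inter, n_intra).

#' Compute Calpha contacts of a conformation
#'
#' A contact is a pair of Calpha atoms belonging to different residues at a
#' distance strictly smaller than `cutoff`. Intrachain pairs additionally
#' require a sequence separation of at least `min_seq_sep`; the default 1
#' follows the literal contact definition (bonded neighbours included), while
#' `min_seq_sep = 3` gives sheet-focused maps without the i+-1/i+-2 inflation
#' of n_intra.
#'
#' @param conf A [conformation()] with 1 or 2 chains.
#' @param cutoff Contact cutoff in Angstrom (default 6).
#' @param min_seq_sep Minimum intrachain sequence separation (default 1).
#' @return A `contact_set`: list with `contacts` (data frame: chain_i, res_i,
#'   chain_j, res_j, distance), `n_inter` and `n_intra`. Each unordered pair
#'   is counted once.
#' @export
compute_contacts <- function(conf, cutoff = 6, min_seq_sep = 1L) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  nc <- n_chains(conf)
  if (nc < 1L || nc > 2L) stop("compute_contacts expects 1 or 2 chains")
  rows <- list()
  for (ci in seq_len(nc)) {
    coords <- chain_coords(conf, ci)
    d <- cross_dist(coords, coords)
    n <- nrow(coords)
    sel <- which(upper.tri(d) & d < cutoff, arr.ind = TRUE)
    if (nrow(sel) > 0) {
      keep <- (sel[, 2] - sel[, 1]) >= min_seq_sep
      sel <- sel[keep, , drop = FALSE]
    }
    if (nrow(sel) > 0) {
      cid <- conf$chains[[ci]]$chain_id
      rows[[length(rows) + 1L]] <- data.frame(
        chain_i = cid, res_i = sel[, 1], chain_j = cid, res_j = sel[, 2],
        distance = d[sel], scope = "intra", stringsAsFactors = FALSE)
    }
  }
  if (nc == 2L) {
    d <- cross_dist(chain_coords(conf, 1), chain_coords(conf, 2))
    sel <- which(d < cutoff, arr.ind = TRUE)
    if (nrow(sel) > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        chain_i = conf$chains[[1]]$chain_id, res_i = sel[, 1],
        chain_j = conf$chains[[2]]$chain_id, res_j = sel[, 2],
        distance = d[sel], scope = "inter", stringsAsFactors = FALSE)
    }
  }
  contacts <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(chain_i = character(), res_i = integer(),
               chain_j = character(), res_j = integer(),
               distance = numeric(), scope = character(),
               stringsAsFactors = FALSE)
  structure(list(contacts = contacts,
                 n_inter = sum(contacts$scope == "inter"),
                 n_intra = sum(contacts$scope == "intra"),
                 cutoff = cutoff, min_seq_sep = as.integer(min_seq_sep)),
            class = "contact_set")
}

#' @export
print.contact_set <- function(x, ...) {
  cat("<contact_set> n_inter =", x$n_inter, " n_intra =", x$n_intra,
      " (cutoff", x$cutoff, "A)\n")
  invisible(x)
}

#' Classify a two-chain snapshot as dimer or free monomers
#'
#' A dimer is two chains with more than 10 residue pairs whose Calpha atoms
#' lie at an intermolecular distance smaller than 5 Angstrom (pair-level
#' count: each residue pair counts once, however many contacts it makes).
#'
#' @param conf A [conformation()] with exactly 2 chains.
#' @param cutoff Dimer contact cutoff in Angstrom (default 5).
#' @param min_pairs Pair-count threshold; `is_dimer` is true iff the number
#'   of close pairs exceeds it (default 10, i.e. at least 11 pairs).
#' @return A `dimer_label`: list with `is_dimer` and `n_close_pairs`.
#' @export
classify_dimer <- function(conf, cutoff = 5, min_pairs = 10L) {
  if (n_chains(conf) != 2L) stop("classify_dimer expects exactly 2 chains")
  d <- cross_dist(chain_coords(conf, 1), chain_coords(conf, 2))
  n_close <- sum(d < cutoff)
  structure(list(is_dimer = n_close > min_pairs,
                 n_close_pairs = as.integer(n_close)),
            class = "dimer_label")
}

#' Keep only dimer snapshots of an ensemble
#'
#' @param ensemble A [ca_ensemble()] of two-chain snapshots.
#' @param cutoff,min_pairs Passed to [classify_dimer()].
#' @return A [ca_ensemble()] of the dimer snapshots; errors if none qualify.
#' @export
filter_dimers <- function(ensemble, cutoff = 5, min_pairs = 10L) {
  keep <- vapply(seq_len(length(ensemble)), function(i) {
    classify_dimer(ensemble[[i]], cutoff, min_pairs)$is_dimer
  }, logical(1))
  if (!any(keep)) stop("no dimer snapshots in the ensemble")
  ensemble[which(keep)]
}

#' Per-residue mean intermolecular contacts
#'
#' For residue r, the mean over snapshots and over the two chains of the
#' number of residues on the other chain within `cutoff` of r. Computed for
#' the ensemble of dimers.
#'
#' @param ensemble A [ca_ensemble()] of two-chain (dimer) snapshots.
#' @param cutoff Contact cutoff in Angstrom (default 6).
#' @return Numeric vector, one value per residue.
#' @export
mean_intermolecular_contacts <- function(ensemble, cutoff = 6) {
  n_snap <- length(ensemble)
  if (n_snap < 1L) stop("empty ensemble")
  acc <- NULL
  for (i in seq_len(n_snap)) {
    conf <- ensemble[[i]]
    if (n_chains(conf) != 2L) stop("snapshot ", i, " does not have 2 chains")
    d <- cross_dist(chain_coords(conf, 1), chain_coords(conf, 2))
    per_res <- (rowSums(d < cutoff) + colSums(d < cutoff)) / 2
    if (is.null(acc)) acc <- per_res else acc <- acc + per_res
  }
  acc / n_snap
}

#' Contact probability maps
#'
#' Cell (i, j) holds the fraction of snapshots in which residue pair (i, j)
#' is in contact. The intermolecular map is symmetrised over chain exchange;
#' the intramolecular map pools both chains.
#'
#' @param ensemble A [ca_ensemble()] of two-chain (dimer) snapshots.
#' @param cutoff Contact cutoff in Angstrom (default 6).
#' @param min_seq_sep Minimum intrachain sequence separation (default 1).
#' @return List with matrices `inter` and `intra` (values in `[0, 1]`).
#' @export
contact_probability_maps <- function(ensemble, cutoff = 6, min_seq_sep = 1L) {
  n_snap <- length(ensemble)
  if (n_snap < 1L) stop("empty ensemble")
  inter <- NULL
  intra <- NULL
  for (i in seq_len(n_snap)) {
    conf <- ensemble[[i]]
    a <- chain_coords(conf, 1)
    b <- chain_coords(conf, 2)
    m <- (cross_dist(a, b) < cutoff) * 1
    m <- (m + t(m)) / 2 # chain-exchange symmetrisation
    da <- cross_dist(a, a) < cutoff
    db <- cross_dist(b, b) < cutoff
    sep_ok <- abs(outer(seq_len(nrow(a)), seq_len(nrow(a)), "-")) >= min_seq_sep
    mi <- ((da & sep_ok) + (db & sep_ok)) / 2
    if (is.null(inter)) {
      inter <- m
      intra <- mi
    } else {
      inter <- inter + m
      intra <- intra + mi
    }
  }
  list(inter = inter / n_snap, intra = intra / n_snap)
}

#' Effective free-energy landscape over a 2D order-parameter histogram
#'
#' Bins integer-valued sample pairs (e.g. n_inter, n_intra per snapshot),
#' converts bin probabilities P to a dimensionless effective free energy
#' F = -ln(P / Pmax) (in kT units), with F = 0 at the most probable bin and
#' +Inf in empty bins.
#'
#' @param x,y Integer-valued sample coordinates (equal length, >= 1 sample).
#' @param bin_width Histogram bin width on both axes (default 5).
#' @return A `landscape_grid`: list with `x_mid`, `y_mid` (bin centres),
#'   `P` (probabilities summing to 1) and `F`.
#' @export
effective_landscape <- function(x, y, bin_width = 5L) {
  if (length(x) < 1L || length(x) != length(y)) {
    stop("need >= 1 (x, y) sample of equal length")
  }
  bin_width <- max(1L, as.integer(bin_width))
  bx <- floor(x / bin_width)
  by <- floor(y / bin_width)
  ux <- seq(min(bx), max(bx))
  uy <- seq(min(by), max(by))
  counts <- matrix(0, length(ux), length(uy))
  for (k in seq_along(bx)) {
    i <- bx[k] - ux[1] + 1L
    j <- by[k] - uy[1] + 1L
    counts[i, j] <- counts[i, j] + 1
  }
  p <- counts / sum(counts)
  f <- -log(p / max(p)) # empty bins: -log(0) = +Inf sentinel
  structure(list(x_mid = (ux + 0.5) * bin_width, y_mid = (uy + 0.5) * bin_width,
                 P = p, F = f, bin_width = bin_width),
            class = "landscape_grid")
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat("<landscape_grid>", nrow(x$P), "x", ncol(x$P), "bins (width",
      x$bin_width, "); occupied:", sum(x$P > 0), "\n")
  invisible(x)
}

#' Local minima of an effective free-energy landscape
#'
#' Smooths the probability surface with a 3x3 binomial kernel (raw integer
#' histograms are noisy at typical sample sizes; the binomial kernel keeps
#' strict peaks and preserves depth differences between isolated basins
#' exactly), recomputes F and reports
#' occupied cells strictly below all 8 neighbours with F within `depth_window`
#' of the global minimum, sorted by F (ties broken by (x, y) order). The
#' depth of minimum i relative to minimum 1 is F_i - F_1 = -ln(P_i / P_1).
#'
#' @param grid A `landscape_grid` from [effective_landscape()].
#' @param depth_window Report minima with F <= this value (default 1.0).
#' @param smooth Apply the 3x3 kernel before detection (default TRUE).
#' @return Data frame with columns `x`, `y`, `F`.
#' @export
find_minima <- function(grid, depth_window = 1.0, smooth = TRUE) {
  p <- grid$P
  if (smooth) p <- smooth_3x3(p)
  f <- -log(p / max(p))
  nr <- nrow(f)
  nc <- ncol(f)
  hits <- list()
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!is.finite(f[i, j])) next
      ni <- max(1, i - 1):min(nr, i + 1)
      nj <- max(1, j - 1):min(nc, j + 1)
      nb <- f[ni, nj]
      if (sum(nb <= f[i, j]) == 1L) { # strictly below all neighbours
        hits[[length(hits) + 1L]] <- c(grid$x_mid[i], grid$y_mid[j], f[i, j])
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(x = numeric(), y = numeric(), F = numeric()))
  }
  out <- as.data.frame(do.call(rbind, hits))
  names(out) <- c("x", "y", "F")
  out <- out[order(out$F, out$x, out$y), , drop = FALSE]
  out <- out[out$F <= depth_window, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# 3x3 binomial kernel ([1 2 1] x [1 2 1] / 16) with zero padding outside the
# histogram range: denoises the raw integer histogram while keeping a strict
# maximum at an isolated peak, and the relative depth of isolated basins
# (-ln Pi/P1) is preserved exactly.
smooth_3x3 <- function(p) {
  nr <- nrow(p)
  nc <- ncol(p)
  out <- matrix(0, nr, nc)
  for (di in -1:1) {
    for (dj in -1:1) {
      si_lo <- max(1, 1 + di)
      si_hi <- min(nr, nr + di)
      sj_lo <- max(1, 1 + dj)
      sj_hi <- min(nc, nc + dj)
      if (si_lo > si_hi || sj_lo > sj_hi) next
      si <- si_lo:si_hi
      sj <- sj_lo:sj_hi
      w <- (2 - abs(di)) * (2 - abs(dj)) / 16
      out[si - di, sj - dj] <- out[si - di, sj - dj] + w * p[si, sj]
    }
  }
  out
}
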