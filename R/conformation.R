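# Core containers: a single Calpha-trace conformation and an ensemble thereof.

#' Construct a Calpha-trace conformation
#'
#' A conformation holds one or more chains of ordered Calpha coordinates (in
#' Angstrom). Residues are re-indexed 1..N per chain; any original author
#' numbering is kept alongside so that positions quoted on the 140-residue
#' sequence (A30, E46, A53, A90, ...) remain 1-based sequence positions.
#'
#' @param chains A list of chain records; each record is a list with elements
#'   `chain_id` (single character), `ca_coords` (N x 3 numeric matrix, Angstrom)
#'   and optionally `orig_resno` (integer vector of author residue numbers).
#' @param snapshot_index Integer snapshot label.
#' @param temperature_label Optional temperature in Kelvin.
#' @param source_tag Free-text provenance.
#' @return An object of class `conformation`.
#' @export
conformation <- function(chains, snapshot_index = 1L, temperature_label = NULL,
                         source_tag = "") {
  stopifnot(is.list(chains), length(chains) >= 1L)
  chains <- lapply(chains, function(ch) {
    coords <- as.matrix(ch$ca_coords)
    storage.mode(coords) <- "double"
    if (ncol(coords) != 3L) {
      stop("chain '", ch$chain_id, "': ca_coords must be an N x 3 matrix")
    }
    if (nrow(coords) < 2L) {
      stop("chain '", ch$chain_id, "': a chain needs at least 2 residues")
    }
    n <- nrow(coords)
    orig <- ch$orig_resno
    if (is.null(orig)) orig <- seq_len(n)
    if (length(orig) != n || any(diff(orig) <= 0L)) {
      stop("chain '", ch$chain_id,
           "': original residue numbers must be strictly increasing")
    }
    list(chain_id = as.character(ch$chain_id),
         residue_indices = seq_len(n),
         ca_coords = unname(coords),
         orig_resno = as.integer(orig))
  })
  structure(
    list(chains = chains,
         meta = list(snapshot_index = as.integer(snapshot_index),
                     temperature_label = temperature_label,
                     source_tag = source_tag)),
    class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat("<conformation> snapshot", x$meta$snapshot_index, "\n")
  for (ch in x$chains) {
    b <- bond_lengths(ch$ca_coords)
    cat(sprintf("  chain %s: %d residues, bond range [%.2f, %.2f] A\n",
                ch$chain_id, nrow(ch$ca_coords), min(b), max(b)))
  }
  invisible(x)
}

#' Validate the virtual-bond geometry of a conformation
#'
#' Consecutive Calpha-Calpha distances of a physically plausible trace fall in
#' 2.8-4.5 Angstrom. Out-of-range bonds are reported but do not invalidate the
#' object (validation flag, not a hard rejection).
#'
#' @param conf A [conformation()].
#' @param range Allowed bond range in Angstrom.
#' @return Logical: `TRUE` if every bond of every chain is within `range`;
#'   the per-chain bond ranges are attached as attribute `"bond_range"`.
#' @export
validate_geometry <- function(conf, range = c(2.8, 4.5)) {
  rng <- t(vapply(conf$chains, function(ch) {
    b <- bond_lengths(ch$ca_coords)
    c(min(b), max(b))
  }, numeric(2)))
  ok <- all(rng[, 1] >= range[1]) && all(rng[, 2] <= range[2])
  attr(ok, "bond_range") <- rng
  ok
}

n_chains <- function(conf) length(conf$chains)

chain_coords <- function(conf, i) conf$chains[[i]]$ca_coords

#' Construct an ensemble of conformations
#'
#' @param conformations A list of [conformation()] objects.
#' @param provenance Free-text description of the source.
#' @return An object of class `ca_ensemble`; supports `length()`, `[[` and
#'   `[` (subsetting returns another ensemble). Iteration order is the storage
#'   order and therefore deterministic for a fixed source.
#' @export
ca_ensemble <- function(conformations, provenance = "") {
  if (length(conformations) < 1L) stop("an ensemble needs at least 1 snapshot")
  structure(list(conformations = conformations, provenance = provenance),
            class = "ca_ensemble")
}

#' @export
length.ca_ensemble <- function(x) length(x$conformations)

#' @export
`[[.ca_ensemble` <- function(x, i) x$conformations[[i]]

#' @export
`[.ca_ensemble` <- function(x, i) {
  ca_ensemble(x$conformations[i], provenance = x$provenance)
}

#' @export
print.ca_ensemble <- function(x, ...) {
  cat("<ca_ensemble>", length(x), "snapshots;", x$provenance, "\n")
  invisible(x)
}

# ---- geometry helpers ------------------------------------------------------

bond_lengths <- function(coords) {
  d <- diff(coords)
  sqrt(rowSums(d * d))
}

# All-pairs Euclidean distances between two coordinate sets (rows).
cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a * a), rowSums(b * b), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# Kabsch: proper rotation R and translation t minimising ||R x + t - y||.
kabsch_fit <- function(x, y) {
  cx <- colMeans(x)
  cy <- colMeans(y)
  h <- crossprod(sweep(x, 2, cx), sweep(y, 2, cy))
  sv <- svd(h)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(rotation = rot, translation = cy - as.vector(rot %*% cx))
}

apply_fit <- function(coords, fit) {
  sweep(coords %*% t(fit$rotation), 2, -fit$translation)
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation.
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

unit <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-12) c(1, 0, 0) else v / n
}

# Evaluate a function with a temporary RNG state seeded from `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
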