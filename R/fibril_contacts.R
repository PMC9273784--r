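# Fibril-like native contacts: same-index intermolecular contacts, the
# pre-fibrillar dimer class (>= 5 consecutive native contacts), per-residue
# native-contact probabilities, AFM-style contour lengths, and reference
# geometry extracted from fibril structures.

#' Native fibril contacts of a two-chain snapshot
#'
#' Residue r carries a native fibril contact (Nfc) when the Calpha atoms of
#' residue r in chain A and residue r in chain B lie at a distance strictly
#' below `cutoff` — the same-index intermolecular contact geometry of
#' in-register parallel fibrils.
#'
#' @param conf A [conformation()] with exactly 2 chains of equal length.
#' @param cutoff Contact cutoff in Angstrom (default 5, chosen from the
#'   4.7-4.9 A same-index distances of measured fibril structures).
#' @return Logical vector over residues 1..N.
#' @export
native_fibril_contacts <- function(conf, cutoff = 5) {
  if (n_chains(conf) != 2L) stop("native contacts need exactly 2 chains")
  a <- chain_coords(conf, 1)
  b <- chain_coords(conf, 2)
  if (nrow(a) != nrow(b)) {
    stop("chains have unequal lengths (", nrow(a), " vs ", nrow(b), ")")
  }
  sqrt(rowSums((a - b)^2)) < cutoff
}

#' Classify a dimer as pre-fibrillar (Dfncs)
#'
#' A dimer with fibril-like native contacts (Dfncs) carries at least
#' `min_run` consecutive same-index intermolecular contacts below `cutoff`.
#' "Consecutive" means strictly adjacent residue indices, no gaps.
#'
#' @param conf A two-chain [conformation()] (a dimer).
#' @param cutoff Nfc cutoff in Angstrom (default 5).
#' @param min_run Minimum run length (default 5).
#' @return A `dfncs_label`: list with `is_dfncs` and `segments` (data frame:
#'   start, end, length of each maximal Nfc run).
#' @export
classify_dfncs <- function(conf, cutoff = 5, min_run = 5L) {
  nfc <- native_fibril_contacts(conf, cutoff)
  segments <- nfc_runs(nfc)
  structure(list(is_dfncs = nrow(segments) > 0 &&
                   max(segments$length) >= min_run,
                 segments = segments),
            class = "dfncs_label")
}

nfc_runs <- function(nfc) {
  r <- rle(nfc)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

#' Native-contact profile of an ensemble
#'
#' Per-residue probability of a native fibril contact over the snapshots,
#' plus the longest consecutive Nfc run found anywhere in the ensemble.
#'
#' @param ensemble A [ca_ensemble()] of two-chain (dimer) snapshots.
#' @param cutoff Nfc cutoff in Angstrom (default 5).
#' @return List with `profile` (numeric per residue) and `max_run` (list:
#'   length, start, end, snapshot).
#' @export
nfc_profile <- function(ensemble, cutoff = 5) {
  n_snap <- length(ensemble)
  if (n_snap < 1L) stop("empty ensemble")
  acc <- NULL
  best <- list(length = 0L, start = NA_integer_, end = NA_integer_,
               snapshot = NA_integer_)
  for (i in seq_len(n_snap)) {
    nfc <- native_fibril_contacts(ensemble[[i]], cutoff)
    acc <- if (is.null(acc)) as.numeric(nfc) else acc + nfc
    runs <- nfc_runs(nfc)
    if (nrow(runs) > 0) {
      j <- which.max(runs$length)
      if (runs$length[j] > best$length) {
        best <- list(length = runs$length[j], start = runs$start[j],
                     end = runs$end[j], snapshot = i)
      }
    }
  }
  list(profile = acc / n_snap, max_run = best)
}

#' AFM-style contour length of the unbound tails
#'
#' In rupture-force AFM experiments the contour length measures the
#' stretchable parts of the two monomers that are not involved in the dimer
#' interface: twice the backbone length from the C-terminus to the first
#' residue forming a native fibril contact, at 3.8 A per Calpha-Calpha
#' virtual bond.
#'
#' @param first_nfc_residue 1-based position of the first Nfc residue.
#' @param chain_length Chain length in residues (default 140).
#' @param bond Virtual bond length in Angstrom (default 3.8).
#' @return Contour length in Angstrom, rounded to the nearest Angstrom.
#' @export
contour_length_estimate <- function(first_nfc_residue, chain_length = 140L,
                                    bond = 3.8) {
  if (any(first_nfc_residue < 1L) || any(first_nfc_residue > chain_length)) {
    stop("first_nfc_residue out of range 1..", chain_length)
  }
  round(2 * (chain_length - first_nfc_residue + 1) * bond)
}

#' Reference sheet geometry of a fibril structure
#'
#' Chains are ordered along the fibril axis (principal axis of the chain
#' centroids) and paired with their stacking successor. Secondary structure
#' is assigned from the Calpha geometry, and the mean same-index interchain
#' Calpha distance is computed over residues participating in intermolecular
#' beta-sheets, together with the residue windows those sheets span.
#'
#' @param ref A multi-chain [conformation()] from [load_fibril_reference()].
#' @param params An [ss_params()].
#' @param cutoff Fallback pairing cutoff in Angstrom used to locate
#'   same-index partners when secondary structure finds no interchain sheet.
#' @return List with `mean_distance` (Angstrom), `windows` (data frame:
#'   start, end) and `n_pairs`.
#' @export
fibril_reference_sheets <- function(ref, params = ss_params(), cutoff = 5.5) {
  if (n_chains(ref) < 2L) stop("fibril geometry needs at least 2 chains")
  cents <- t(vapply(ref$chains, function(ch) colMeans(ch$ca_coords),
                    numeric(3)))
  axis <- if (nrow(cents) == 2L) unit(cents[2, ] - cents[1, ]) else
    unit(prcomp(cents)$rotation[, 1])
  ord <- order(cents %*% axis)
  ss <- assign_ss(ref, params)
  inter <- ss$sheet_pairs[ss$sheet_pairs$scope == "inter", , drop = FALSE]
  cid <- vapply(ref$chains, `[[`, "", "chain_id")
  sheet_res <- lapply(seq_along(cid), function(ci) {
    unique(c(inter$res_a[inter$chain_a == cid[ci]],
             inter$res_b[inter$chain_b == cid[ci]]))
  })
  dists <- numeric(0)
  res_used <- integer(0)
  for (k in seq_len(length(ord) - 1L)) {
    c1 <- ord[k]
    c2 <- ord[k + 1L]
    r1 <- ref$chains[[c1]]
    r2 <- ref$chains[[c2]]
    common <- intersect(r1$orig_resno, r2$orig_resno)
    shared_sheet <- intersect(
      r1$orig_resno[sheet_res[[c1]]] , r2$orig_resno[sheet_res[[c2]]])
    use <- intersect(common, shared_sheet)
    if (length(use) == 0L) {
      # fall back to same-index pairs within the contact cutoff
      i1 <- match(common, r1$orig_resno)
      i2 <- match(common, r2$orig_resno)
      dd <- sqrt(rowSums((r1$ca_coords[i1, , drop = FALSE] -
                          r2$ca_coords[i2, , drop = FALSE])^2))
      use <- common[dd < cutoff]
    }
    if (length(use) == 0L) next
    i1 <- match(use, r1$orig_resno)
    i2 <- match(use, r2$orig_resno)
    dists <- c(dists, sqrt(rowSums((r1$ca_coords[i1, , drop = FALSE] -
                                    r2$ca_coords[i2, , drop = FALSE])^2)))
    res_used <- c(res_used, use)
  }
  if (length(dists) == 0L) {
    stop("no same-index interchain sheet residues found in the reference")
  }
  res_used <- sort(unique(res_used))
  runs <- nfc_runs(seq(min(res_used), max(res_used)) %in% res_used)
  runs$start <- runs$start + min(res_used) - 1L
  runs$end <- runs$end + min(res_used) - 1L
  list(mean_distance = mean(dists),
       windows = runs[, c("start", "end")],
       n_pairs = length(dists))
}
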