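# Experiment-facing observables: radius of gyration and its Gaussian-mixture
# clustering (SAXS), residue-90 pair distances and an approximate FRET
# efficiency (single-molecule FRET), and Chou-Fasman beta-sheet propensity.

#' Radius of gyration of a conformation
#'
#' Root-mean-square Calpha distance from the Calpha centroid, unweighted.
#'
#' @param conf A [conformation()].
#' @param scope `"dimer"` pools all chains (e.g. 280 Calpha positions for a
#'   two-chain snapshot); `"chain"` returns one value per chain.
#' @return Rg in Angstrom (scalar for `"dimer"`, named vector for `"chain"`).
#' @export
radius_of_gyration <- function(conf, scope = c("dimer", "chain")) {
  scope <- match.arg(scope)
  if (scope == "dimer") {
    coords <- do.call(rbind, lapply(conf$chains, `[[`, "ca_coords"))
    chain_rg(coords)
  } else {
    setNames(vapply(conf$chains, function(ch) chain_rg(ch$ca_coords), 0),
             vapply(conf$chains, `[[`, "", "chain_id"))
  }
}

#' Gaussian-mixture clustering of radius-of-gyration samples
#'
#' Fits Gaussian mixtures with k = 1..`k_max` components by
#' expectation-maximisation and selects k by the Bayesian information
#' criterion. Components are reported sorted by weight.
#'
#' @param samples Rg samples in Angstrom (>= 50 values).
#' @param k_max Largest candidate component count (default 4).
#' @param seed Integer seed (the fit is deterministic given the seed).
#' @return A `gmm_fit`: list with `components` (data frame: mean, sd,
#'   weight), `ensemble_average`, `n_components` and `selection_score`
#'   (BIC per candidate k; larger is better in mclust's convention).
#' @export
fit_rg_mixture <- function(samples, k_max = 4L, seed = 1L) {
  if (length(samples) < 50L) {
    stop("need at least 50 samples for mixture clustering, got ",
         length(samples))
  }
  fit <- with_seed(seed, Mclust(samples, G = seq_len(k_max),
                                modelNames = c("E", "V"), verbose = FALSE))
  if (is.null(fit)) stop("mixture fit failed")
  means <- as.numeric(fit$parameters$mean)
  vars <- fit$parameters$variance$sigmasq
  if (length(vars) == 1L) vars <- rep(vars, fit$G)
  comp <- data.frame(mean = means, sd = sqrt(vars),
                     weight = as.numeric(fit$parameters$pro))
  comp <- comp[order(-comp$weight), , drop = FALSE]
  rownames(comp) <- NULL
  bic <- apply(fit$BIC, 1, max, na.rm = TRUE)
  structure(list(components = comp,
                 ensemble_average = sum(comp$weight * comp$mean),
                 n_components = fit$G,
                 fit_seed = as.integer(seed),
                 selection_score = bic),
            class = "gmm_fit")
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat("<gmm_fit>", x$n_components, "components; ensemble average",
      sprintf("%.1f A\n", x$ensemble_average))
  print(round(x$components, 3))
  invisible(x)
}

#' Interchain residue-pair distance distribution
#'
#' One distance per dimer snapshot between the Calpha atoms of `residue` in
#' the two chains (residue 90 is the FRET labelling position), reported
#' separately for disordered dimers and pre-fibrillar dimers (Dfncs).
#'
#' @param ensemble A [ca_ensemble()] of two-chain snapshots.
#' @param residue 1-based residue position (default 90).
#' @param nfc_cutoff,min_run Dfncs definition, see [classify_dfncs()].
#' @param dimer_cutoff,min_pairs Dimer definition, see [classify_dimer()].
#' @return List with numeric vectors `disordered` and `dfncs` plus the
#'   corresponding `density_disordered` / `density_dfncs` (NULL when a class
#'   is empty of snapshots).
#' @export
residue_pair_distance_distribution <- function(ensemble, residue = 90L,
                                               nfc_cutoff = 5, min_run = 5L,
                                               dimer_cutoff = 5,
                                               min_pairs = 10L) {
  n_res <- nrow(chain_coords(ensemble[[1]], 1))
  if (residue < 1L || residue > n_res) {
    stop("residue out of range 1..", n_res)
  }
  dimers <- filter_dimers(ensemble, dimer_cutoff, min_pairs)
  dist_one <- function(conf) {
    sqrt(sum((chain_coords(conf, 1)[residue, ] -
              chain_coords(conf, 2)[residue, ])^2))
  }
  is_df <- vapply(seq_len(length(dimers)), function(i) {
    classify_dfncs(dimers[[i]], nfc_cutoff, min_run)$is_dfncs
  }, logical(1))
  d_all <- vapply(seq_len(length(dimers)), function(i) dist_one(dimers[[i]]),
                  0)
  out <- list(disordered = d_all[!is_df], dfncs = d_all[is_df])
  out$density_disordered <- if (length(out$disordered) > 1L)
    density(out$disordered) else NULL
  out$density_dfncs <- if (length(out$dfncs) > 1L)
    density(out$dfncs) else NULL
  out
}

#' Approximate FRET efficiency from a Calpha-Calpha distance
#'
#' E = 1 / (1 + (d / R0)^6) with d the Calpha-Calpha distance increased by
#' `offset` (twice the estimated dye-centre to Calpha distance) and R0 the
#' Foerster distance of the dye pair. E = 0.5 exactly when d = R0, i.e. at a
#' Calpha distance of R0 - offset.
#'
#' @param ca_distance Calpha-Calpha distance(s) in Angstrom (>= 0).
#' @param r0 Foerster distance in Angstrom (default 60).
#' @param offset Dye shift in Angstrom (default 20; 7.5 and 15 are the
#'   common alternatives for shorter linkers).
#' @return A `fret_record` data frame: ca_distance, dye_distance,
#'   efficiency, r0, offset.
#' @export
fret_efficiency <- function(ca_distance, r0 = 60, offset = 20) {
  if (r0 <= 0) stop("r0 must be > 0")
  if (any(ca_distance < 0)) stop("ca_distance must be >= 0")
  d <- ca_distance + offset
  e <- 1 / (1 + (d / r0)^6)
  structure(data.frame(ca_distance = ca_distance, dye_distance = d,
                       efficiency = e, r0 = r0, offset = offset),
            class = c("fret_record", "data.frame"))
}

#' Chou-Fasman beta-sheet propensity profile
#'
#' Weighted sliding-window mean of the Chou-Fasman (1978) beta-sheet
#' conformational parameters: weights fall linearly from 1 at the window
#' centre to `edge_weight` at the edges and the mean is normalised by the
#' weight sum (the ProtScale convention). Termini use truncated windows.
#'
#' @param sequence Character string of one-letter amino-acid codes.
#' @param window Odd window size in residues (default 15).
#' @param edge_weight Relative weight at the window edges (default 0.10).
#' @return Numeric propensity per residue (dimensionless).
#' @export
chou_fasman_profile <- function(sequence, window = 15L, edge_weight = 0.10) {
  if (window %% 2L != 1L) stop("window must be odd")
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(aa), names(.CF_BETA))
  if (length(bad) > 0) {
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  }
  v <- unname(.CF_BETA[aa])
  n <- length(v)
  half <- (window - 1L) / 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- max(1L, i - half):min(n, i + half)
    w <- 1 - (1 - edge_weight) * abs(k - i) / half
    out[i] <- sum(w * v[k]) / sum(w)
  }
  out
}

#' Local maxima of a per-residue profile
#'
#' @param profile Numeric vector.
#' @return Integer positions i with profile(i) > profile(i-1) and
#'   profile(i) >= profile(i+1) (left edge of a plateau).
#' @export
profile_peaks <- function(profile) {
  n <- length(profile)
  if (n < 3L) return(integer(0))
  which(profile[2:(n - 1L)] > profile[1:(n - 2L)] &
        profile[2:(n - 1L)] >= profile[3:n]) + 1L
}

#' Worked population partition of a monomer solution
#'
#' Given a total number of chains, the fraction of conformers that are dimers
#' (dimers / (dimers + free monomers)) and the fraction of dimers that are
#' pre-fibrillar (Dfncs), returns the integer partition: solving
#' D = f (N - D) gives D = f N / (1 + f) dimers, of which round(g D) are
#' Dfncs, leaving N - 2D free monomers.
#'
#' @param n_chains Total number of monomer chains in solution.
#' @param dimer_fraction Fraction of conformers that are dimers.
#' @param dfncs_fraction Fraction of dimers that are Dfncs.
#' @return List with `dimers`, `dfncs`, `disordered_dimers`, `free_monomers`.
#' @export
partition_populations <- function(n_chains, dimer_fraction, dfncs_fraction) {
  d <- round(dimer_fraction * n_chains / (1 + dimer_fraction))
  dfncs <- round(dfncs_fraction * d)
  list(dimers = d, dfncs = dfncs, disordered_dimers = d - dfncs,
       free_monomers = n_chains - 2L * d)
}
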