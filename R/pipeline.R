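# End-to-end orchestration: read or generate an ensemble, classify dimers,
# compute contacts/landscapes, assign secondary structure, extract native
# fibril contacts, and write the observable tables plus a run manifest.

#' Run the full dimer-analysis pipeline
#'
#' Stages, in order: load or generate the ensemble; classify dimers; contact
#' statistics and the (n_inter, n_intra) effective free-energy landscape;
#' secondary-structure assignment with sheet orientations; native fibril
#' contacts and Dfncs classification; radius-of-gyration mixture clustering
#' and residue-90 distance / FRET-proxy distributions. All tables are written
#' as TSV into `config$outdir` together with a JSON manifest of parameters,
#' seeds and counts. Re-running with the same config reproduces every output
#' byte for byte.
#'
#' @param config A list with entries:
#'   * `input`: path to a PDB/XYZ ensemble, or an [ensemble_spec()] to
#'     generate synthetic data (required);
#'   * `format`: `"pdb"` or `"xyz"` when `input` is a path;
#'   * `outdir`: output directory (required);
#'   * `seed`: integer seed (required when `input` is a path; an
#'     [ensemble_spec()] carries its own);
#'   * optional cutoffs: `contact_cutoff` (6), `dimer_cutoff` (5),
#'     `min_seq_sep` (1), `nfc_cutoff` (5), `min_run` (5), `bin_width` (5),
#'     `fret_offset` (20), `r0` (60), `region` (c(1, 95)), `k_max` (4).
#' @return Invisibly, a list with the manifest and the main in-memory
#'   results (`landscape`, `minima`, `ss_profiles`, `nfc`, `gmm`, `fret`).
#' @export
run_pipeline <- function(config) {
  required <- c("input", "outdir")
  missing <- setdiff(required, names(config))
  if (length(missing) > 0) {
    stop("config is missing required keys: ", paste(missing, collapse = ", "))
  }
  cfg <- utils::modifyList(list(
    format = "pdb", contact_cutoff = 6, dimer_cutoff = 5, min_seq_sep = 1L,
    nfc_cutoff = 5, min_run = 5L, bin_width = 5L, fret_offset = 20, r0 = 60,
    region = c(1L, 95L), k_max = 4L, seed = NULL), config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  truth <- NULL
  ens <- stage("read", {
    if (inherits(cfg$input, "ensemble_spec")) {
      gen <- sample_ensemble(cfg$input)
      truth <- gen$truth
      if (is.null(cfg$seed)) cfg$seed <- cfg$input$seed
      gen$ensemble
    } else {
      if (is.null(cfg$seed)) stop("config needs a seed for file input")
      read_structures(cfg$input, cfg$format)
    }
  })

  n_snap <- length(ens)
  labels <- stage("classify_dimers", {
    lapply(seq_len(n_snap), function(i) {
      classify_dimer(ens[[i]], cfg$dimer_cutoff)
    })
  })
  is_dimer <- vapply(labels, `[[`, TRUE, "is_dimer")
  if (!any(is_dimer)) stop("pipeline: no dimer snapshots in the input")
  dimers <- ens[which(is_dimer)]
  n_dim <- length(dimers)

  contacts <- stage("contacts", {
    lapply(seq_len(n_dim), function(i) {
      cs <- compute_contacts(dimers[[i]], cfg$contact_cutoff, cfg$min_seq_sep)
      c(n_inter = cs$n_inter, n_intra = cs$n_intra)
    })
  })
  n_inter <- vapply(contacts, `[[`, 0, "n_inter")
  n_intra <- vapply(contacts, `[[`, 0, "n_intra")
  landscape <- stage("landscape",
                     effective_landscape(n_inter, n_intra, cfg$bin_width))
  minima <- find_minima(landscape)
  mean_contacts <- stage("mean_contacts",
                         mean_intermolecular_contacts(dimers,
                                                      cfg$contact_cutoff))
  maps <- stage("maps", contact_probability_maps(dimers, cfg$contact_cutoff,
                                                 cfg$min_seq_sep))

  ss <- stage("secondary_structure", {
    lapply(seq_len(n_dim), function(i) assign_ss(dimers[[i]]))
  })
  counts <- data.frame(
    alpha = vapply(ss, function(a) count_ss_region(a, cfg$region)$alpha, 0L),
    beta = vapply(ss, function(a) count_ss_region(a, cfg$region)$beta, 0L))
  orient <- stage("orientations", orientation_percentages(ss))

  nfc <- stage("native_contacts", nfc_profile(dimers, cfg$nfc_cutoff))
  dfncs <- vapply(seq_len(n_dim), function(i) {
    classify_dfncs(dimers[[i]], cfg$nfc_cutoff, cfg$min_run)$is_dfncs
  }, logical(1))

  n_res <- nrow(chain_coords(ens[[1]], 1))
  ss_profiles <- stage("ss_profiles", {
    acc <- matrix(0, n_res, 4,
                  dimnames = list(NULL, c("P_helix", "P_intra_sheet",
                                          "P_inter_sheet", "P_nfc")))
    for (i in seq_len(n_dim)) {
      a <- ss[[i]]
      helix <- (a$labels[[1]] == "H") + (a$labels[[2]] == "H")
      pr <- a$sheet_pairs
      per_scope <- function(sc) {
        sel <- pr[pr$scope == sc, , drop = FALSE]
        m <- numeric(n_res)
        for (cid in names(a$labels)) {
          res <- unique(c(sel$res_a[sel$chain_a == cid],
                          sel$res_b[sel$chain_b == cid]))
          m[res] <- m[res] + 1
        }
        m
      }
      nfc_i <- native_fibril_contacts(dimers[[i]], cfg$nfc_cutoff)
      acc[, "P_helix"] <- acc[, "P_helix"] + helix / 2
      acc[, "P_intra_sheet"] <- acc[, "P_intra_sheet"] + per_scope("intra") / 2
      acc[, "P_inter_sheet"] <- acc[, "P_inter_sheet"] + per_scope("inter") / 2
      acc[, "P_nfc"] <- acc[, "P_nfc"] + nfc_i
    }
    acc / n_dim
  })

  rg_dimer <- vapply(seq_len(n_dim), function(i) {
    radius_of_gyration(dimers[[i]], "dimer")
  }, 0)
  rg_chain <- unlist(lapply(seq_len(n_dim), function(i) {
    radius_of_gyration(dimers[[i]], "chain")
  }))
  gmm <- stage("rg_mixture", {
    if (n_dim >= 50L) fit_rg_mixture(rg_dimer, cfg$k_max, seed = cfg$seed)
    else NULL
  })
  a90 <- stage("residue_distances", {
    residue_pair_distance_distribution(ens, residue = min(90L, n_res),
                                       nfc_cutoff = cfg$nfc_cutoff,
                                       min_run = cfg$min_run,
                                       dimer_cutoff = cfg$dimer_cutoff)
  })
  fret <- stage("fret", {
    list(disordered = fret_efficiency(a90$disordered, cfg$r0, cfg$fret_offset),
         dfncs = if (length(a90$dfncs) > 0)
           fret_efficiency(a90$dfncs, cfg$r0, cfg$fret_offset) else NULL)
  })

  out <- function(name) file.path(cfg$outdir, name)
  wt <- function(x, name) {
    utils::write.table(x, out(name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(data.frame(snapshot = seq_len(n_snap), is_dimer = is_dimer,
                n_close_pairs = vapply(labels, `[[`, 0L, "n_close_pairs")),
     "dimer_labels.tsv")
  wt(data.frame(snapshot = which(is_dimer), n_inter = n_inter,
                n_intra = n_intra, alpha = counts$alpha, beta = counts$beta,
                is_dfncs = dfncs, rg_dimer = rg_dimer),
     "per_dimer.tsv")
  wt(data.frame(residue = seq_len(n_res), mean_inter_contacts = mean_contacts,
                nfc_probability = nfc$profile, ss_profiles),
     "residue_profiles.tsv")
  write.table(maps$inter, out("map_inter.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(maps$intra, out("map_intra.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  land_df <- expand.grid(x = landscape$x_mid, y = landscape$y_mid)
  land_df$P <- as.vector(landscape$P)
  land_df$F <- as.vector(landscape$F)
  wt(land_df[land_df$P > 0, ], "landscape.tsv")
  wt(minima, "landscape_minima.tsv")
  if (!is.null(truth)) wt(truth, "ground_truth.tsv")

  manifest <- list(
    parameters = cfg[setdiff(names(cfg), c("input", "outdir"))],
    seed = cfg$seed,
    counts = list(
      n_snapshots = n_snap,
      n_dimers = n_dim,
      dimer_fraction = n_dim / n_snap,
      n_dfncs = sum(dfncs),
      dfncs_fraction_of_dimers = sum(dfncs) / n_dim,
      dfncs_pct_of_dimers = 100 * sum(dfncs) / n_dim),
    orientation_percentages = orient[c("parallel_pct", "antiparallel_pct")],
    rg = list(
      mean_dimer = mean(rg_dimer), mean_chain = mean(rg_chain),
      gmm = if (!is.null(gmm)) list(
        n_components = gmm$n_components,
        components = gmm$components,
        ensemble_average = gmm$ensemble_average) else NULL),
    nfc_max_run = nfc$max_run)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(manifest = manifest, landscape = landscape, minima = minima,
                 mean_contacts = mean_contacts, maps = maps,
                 ss_counts = counts, orientation = orient,
                 ss_profiles = ss_profiles, nfc = nfc, gmm = gmm,
                 a90 = a90, fret = fret, truth = truth))
}
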