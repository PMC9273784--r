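# Reading and writing two-chain Calpha ensembles (multi-model PDB via bio3d,
# plus a minimal whitespace XYZ dialect for coarse-grained snapshots).

#' Read a Calpha ensemble from file
#'
#' For PDB input, `MODEL`/`ENDMDL` blocks delimit snapshots and chain
#' identifiers delimit chains; only CA atom records are consumed. Residues are
#' re-indexed 1..N per chain (original author numbering is retained in the
#' chain records). For the XYZ dialect, each snapshot is a header line with
#' one residue count per chain followed by `"chain_id x y z"` lines.
#'
#' @param path Path to the input file.
#' @param format `"pdb"` or `"xyz"`.
#' @return A [ca_ensemble()]; one [conformation()] per model, chains ordered
#'   by first appearance, coordinates in Angstrom.
#' @examples
#' conf <- sample_ensemble(ensemble_spec(n_snapshots = 2, seed = 1))$ensemble
#' f <- tempfile(fileext = ".pdb")
#' write_structures(conf, f)
#' length(read_structures(f))  # 2
#' @export
read_structures <- function(path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
    pdb = read_structures_pdb(path),
    xyz = read_structures_xyz(path))
}

read_structures_pdb <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop("could not parse PDB (zero models?): ",
                             conditionMessage(e)))
  sel <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
  if (length(sel$atom) == 0L) stop("no CA atom records in ", path)
  atoms <- pdb$atom[sel$atom, , drop = FALSE]
  ch <- atoms$chain
  ch[is.na(ch) | ch == ""] <- "A"
  chain_ids <- unique(ch)
  xyz <- pdb$xyz[, sel$xyz, drop = FALSE]
  n_models <- nrow(xyz)
  if (n_models < 1L) stop("zero models in ", path)

  # contiguity check: a residue whose CA is absent leaves a numbering gap
  for (cid in chain_ids) {
    resno <- atoms$resno[ch == cid]
    if (anyDuplicated(resno)) {
      stop("duplicate CA records in chain ", cid, " of ", path)
    }
    gaps <- which(diff(resno) != 1L)
    if (length(gaps) > 0L) {
      stop(sprintf("missing CA: model 1, chain %s, residue %d",
                   cid, resno[gaps[1]] + 1L))
    }
  }

  confs <- lapply(seq_len(n_models), function(m) {
    coords <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
    chains <- lapply(chain_ids, function(cid) {
      idx <- which(ch == cid)
      list(chain_id = cid,
           ca_coords = coords[idx, , drop = FALSE],
           orig_resno = atoms$resno[idx])
    })
    conformation(chains, snapshot_index = m, source_tag = path)
  })
  ca_ensemble(confs, provenance = paste0("pdb:", path))
}

read_structures_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  confs <- list()
  i <- 1L
  m <- 0L
  while (i <= length(lines)) {
    counts <- suppressWarnings(as.integer(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (anyNA(counts) || any(counts < 2L)) {
      stop("bad XYZ header at line ", i, " of ", path)
    }
    m <- m + 1L
    i <- i + 1L
    need <- sum(counts)
    if (i + need - 1L > length(lines)) {
      stop("truncated XYZ snapshot ", m, " in ", path)
    }
    body <- do.call(rbind, strsplit(trimws(lines[i:(i + need - 1L)]), "\\s+"))
    if (ncol(body) != 4L) stop("bad XYZ record in snapshot ", m, " of ", path)
    coords <- matrix(as.numeric(body[, 2:4]), ncol = 3)
    ids <- body[, 1]
    offset <- 0L
    chains <- lapply(seq_along(counts), function(k) {
      rows <- offset + seq_len(counts[k])
      offset <<- offset + counts[k]
      cid <- unique(ids[rows])
      if (length(cid) != 1L) {
        stop("inconsistent chain ids in snapshot ", m, " of ", path)
      }
      list(chain_id = cid, ca_coords = coords[rows, , drop = FALSE])
    })
    confs[[m]] <- conformation(chains, snapshot_index = m, source_tag = path)
    i <- i + need
  }
  if (m == 0L) stop("zero snapshots in ", path)
  ca_ensemble(confs, provenance = paste0("xyz:", path))
}

#' Write a Calpha ensemble to file
#'
#' PDB output writes one `MODEL` block per snapshot with CA-only ATOM records
#' (all snapshots must share the same chain topology); XYZ output writes the
#' dialect documented in [read_structures()].
#'
#' @param ensemble A [ca_ensemble()] or a single [conformation()].
#' @param path Output path.
#' @param format `"pdb"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_structures <- function(ensemble, path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  if (inherits(ensemble, "conformation")) ensemble <- ca_ensemble(list(ensemble))
  topo <- lapply(ensemble[[1]]$chains,
                 function(ch) c(ch$chain_id, nrow(ch$ca_coords)))
  for (i in seq_len(length(ensemble))) {
    ti <- lapply(ensemble[[i]]$chains,
                 function(ch) c(ch$chain_id, nrow(ch$ca_coords)))
    if (!identical(ti, topo)) {
      stop("all snapshots must share one chain topology for file output")
    }
  }
  if (format == "pdb") write_structures_pdb(ensemble, path)
  else write_structures_xyz(ensemble, path)
  invisible(path)
}

write_structures_pdb <- function(ensemble, path) {
  chains <- ensemble[[1]]$chains
  chain_vec <- unlist(lapply(chains, function(ch) rep(ch$chain_id, nrow(ch$ca_coords))))
  resno_vec <- unlist(lapply(chains, function(ch) ch$orig_resno))
  n_models <- length(ensemble)
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  out <- character(0)
  for (m in seq_len(n_models)) {
    xyz <- as.vector(t(do.call(rbind, lapply(ensemble[[m]]$chains,
                                             function(ch) ch$ca_coords))))
    n_atoms <- length(chain_vec)
    bio3d::write.pdb(file = tmp, xyz = xyz, chain = chain_vec,
                     resno = resno_vec, resid = rep("ALA", n_atoms),
                     elety = rep("CA", n_atoms))
    records <- grep("^(ATOM|TER)", readLines(tmp), value = TRUE)
    out <- c(out,
             if (n_models > 1L) sprintf("MODEL     %4d", m),
             records,
             if (n_models > 1L) "ENDMDL")
  }
  writeLines(c(out, "END"), path)
}

write_structures_xyz <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(length(ensemble))) {
    conf <- ensemble[[i]]
    writeLines(paste(vapply(conf$chains, function(ch) nrow(ch$ca_coords), 1L),
                     collapse = " "), con)
    for (ch in conf$chains) {
      writeLines(sprintf("%s %.3f %.3f %.3f", ch$chain_id,
                         ch$ca_coords[, 1], ch$ca_coords[, 2], ch$ca_coords[, 3]),
                 con)
    }
  }
}

#' Load a fibril reference structure
#'
#' Reads a multi-chain PDB (e.g. a deposited amyloid fibril entry) and returns
#' a single conformation holding all chains, suitable for
#' [fibril_reference_sheets()]. Multi-model (NMR-style) entries use one model,
#' the first by default, since the fibril is treated as a single geometry.
#'
#' @param path Path to a PDB file with at least 2 chains.
#' @param model Model number to use (default 1).
#' @return A [conformation()] with all fibril chains.
#' @export
load_fibril_reference <- function(path, model = 1L) {
  ens <- read_structures(path, format = "pdb")
  if (model < 1L || model > length(ens)) {
    stop("model ", model, " not present (file has ", length(ens), ")")
  }
  conf <- ens[[model]]
  if (n_chains(conf) < 2L) {
    stop("fibril analysis needs intermolecular geometry: ",
         "found a single chain in ", path)
  }
  conf
}

#' Read a protein sequence from FASTA
#'
#' @param path Path to a FASTA file; the first record is used.
#' @return A single character string of one-letter codes (upper case).
#' @export
read_sequence <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  s <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  toupper(as.character(s[[1]]))
}
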