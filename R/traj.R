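# Structural descriptors for protein-ssDNA trajectories: radius of
# gyration, per-atom / per-residue RMSF with optional least-squares
# (Kabsch) superposition, and the per-nucleotide surface-distance
# profile Delta_s = |r_P - c| - Rg(protein).

#' Construct a trajectory
#'
#' An ordered set of frames over a fixed atom roster. Atoms are
#' described once; coordinates are a `frames x atoms x 3` array (Å).
#'
#' @param atoms `data.frame` with columns `atom_name`, `residue_name`,
#'   `residue_index`, `chain` (conventionally `"protein"` or `"dna"`).
#' @param coords Numeric array `[frame, atom, xyz]` with finite values.
#' @return List of class `shm_trajectory`.
#' @export
trajectory <- function(atoms, coords) {
  atoms <- as.data.table(atoms)
  stopifnot(all(c("atom_name", "residue_name", "residue_index", "chain")
                %in% names(atoms)))
  if (length(dim(coords)) == 2L) {
    coords <- array(coords, dim = c(1L, nrow(coords), 3L))
  }
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2L] == nrow(atoms),
            dim(coords)[3L] == 3L, all(is.finite(coords)))
  structure(list(atoms = atoms[], coords = coords), class = "shm_trajectory")
}

n_frames <- function(traj) dim(traj$coords)[1L]

frame_coords <- function(traj, t) {
  matrix(traj$coords[t, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Select atom indices by chain / residue / atom name
#'
#' @param traj An `shm_trajectory`.
#' @param chain,atom_name,residue_index Optional filters (vectors).
#' @return Integer atom indices.
#' @export
select_atoms <- function(traj, chain = NULL, atom_name = NULL,
                         residue_index = NULL) {
  keep <- rep(TRUE, nrow(traj$atoms))
  if (!is.null(chain)) keep <- keep & traj$atoms$chain %in% chain
  if (!is.null(atom_name)) keep <- keep & traj$atoms$atom_name %in% atom_name
  if (!is.null(residue_index)) {
    keep <- keep & traj$atoms$residue_index %in% residue_index
  }
  which(keep)
}

#' Radius of gyration
#'
#' `sqrt(sum(w_i |r_i - rbar|^2) / sum(w_i))` with `rbar` the weighted
#' centroid. Weighting is uniform by default; `weights = "mass"` uses
#' standard atomic masses inferred from the first character of the
#' atom name (H, C, N, O, P, S).
#'
#' @param coords `n x 3` coordinate matrix (Å).
#' @param weights `"uniform"`, `"mass"`, or a numeric vector.
#' @param atom_names Required when `weights = "mass"`.
#' @return Rg in Å.
#' @export
radius_of_gyration <- function(coords, weights = "uniform", atom_names = NULL) {
  coords <- rbind(coords)
  if (nrow(coords) == 0L) stop("empty coordinate set", call. = FALSE)
  w <- if (is.numeric(weights)) {
    weights
  } else if (identical(weights, "mass")) {
    if (is.null(atom_names)) stop("atom_names needed for mass weighting",
                                  call. = FALSE)
    atomic_mass(atom_names)
  } else {
    rep(1, nrow(coords))
  }
  stopifnot(length(w) == nrow(coords), all(w >= 0), sum(w) > 0)
  ctr <- colSums(coords * w) / sum(w)
  d2 <- rowSums(sweep(coords, 2L, ctr)^2)
  sqrt(sum(w * d2) / sum(w))
}

atomic_mass <- function(atom_names) {
  el <- toupper(substr(atom_names, 1L, 1L))
  m <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06)
  out <- m[el]
  out[is.na(out)] <- 12.011
  unname(out)
}

#' Per-nucleotide surface distance Delta_s for one frame
#'
#' For each DNA phosphorus atom, the distance from the protein centre
#' minus the protein's radius of gyration (the protein approximated as
#' a sphere of radius Rg): an approximate height of the phosphate above
#' the protein surface. May be negative when the phosphorus lies inside
#' the effective sphere. The centre is the unweighted centroid of the
#' protein selection by default; `center_mode = "atom"` anchors it at a
#' single named atom instead (e.g. the C-alpha of a reference residue).
#'
#' @param protein_coords `n x 3` protein coordinates.
#' @param p_coords `m x 3` phosphorus coordinates (one per nucleotide;
#'   a 5'-terminal nucleotide without a phosphate simply contributes no
#'   row).
#' @param center_mode `"centroid"` (default) or `"atom"`.
#' @param center_atom Coordinate 3-vector used when
#'   `center_mode = "atom"`.
#' @param weights Passed to [radius_of_gyration()].
#' @return Numeric vector of Delta_s values (Å), one per phosphorus.
#' @export
delta_s <- function(protein_coords, p_coords,
                    center_mode = c("centroid", "atom"), center_atom = NULL,
                    weights = "uniform") {
  center_mode <- match.arg(center_mode)
  protein_coords <- rbind(protein_coords)
  p_coords <- rbind(p_coords)
  if (nrow(protein_coords) == 0L) stop("empty protein selection", call. = FALSE)
  rg <- radius_of_gyration(protein_coords, weights)
  ctr <- if (center_mode == "centroid") {
    colMeans(protein_coords)
  } else {
    if (is.null(center_atom)) stop("center_atom required", call. = FALSE)
    as.numeric(center_atom)
  }
  sqrt(rowSums(sweep(p_coords, 2L, ctr)^2)) - rg
}

#' Per-nucleotide Delta_s profile over a trajectory
#'
#' Mean and (population) standard deviation of Delta_s per nucleotide
#' across frames. Nucleotides lacking a phosphorus atom are reported
#' absent with a warning.
#'
#' @param traj An `shm_trajectory`.
#' @param protein_chain,dna_chain Chain labels.
#' @param p_name Phosphorus atom name (default `"P"`).
#' @param center_mode,center_atom_name See [delta_s()]; when
#'   `center_mode = "atom"`, `center_atom_name` selects the anchoring
#'   protein atom by `atom_name` + `residue_index`
#'   (e.g. `list(atom_name = "CA", residue_index = 79)`).
#' @return `data.table` with `residue_index`, `mean_delta_s`,
#'   `sd_delta_s`, `n_frames`.
#' @export
trajectory_distance_profile <- function(traj, protein_chain = "protein",
                                        dna_chain = "dna", p_name = "P",
                                        center_mode = c("centroid", "atom"),
                                        center_atom_name = NULL) {
  center_mode <- match.arg(center_mode)
  prot <- select_atoms(traj, chain = protein_chain)
  if (length(prot) == 0L) stop("empty protein selection", call. = FALSE)
  dna_res <- sort(unique(traj$atoms$residue_index[traj$atoms$chain %in% dna_chain]))
  pidx <- select_atoms(traj, chain = dna_chain, atom_name = p_name)
  pres <- traj$atoms$residue_index[pidx]
  missing <- setdiff(dna_res, pres)
  if (length(missing)) {
    warning("nucleotide(s) without a phosphorus atom omitted: ",
            paste(missing, collapse = ", "))
  }
  anchor_idx <- NULL
  if (center_mode == "atom") {
    stopifnot(is.list(center_atom_name))
    anchor_idx <- select_atoms(traj, chain = protein_chain,
                               atom_name = center_atom_name$atom_name,
                               residue_index = center_atom_name$residue_index)
    if (length(anchor_idx) != 1L) stop("anchor atom not unique", call. = FALSE)
  }
  nf <- n_frames(traj)
  vals <- matrix(NA_real_, nrow = nf, ncol = length(pidx))
  for (t in seq_len(nf)) {
    fc <- frame_coords(traj, t)
    vals[t, ] <- delta_s(fc[prot, , drop = FALSE], fc[pidx, , drop = FALSE],
                         center_mode = center_mode,
                         center_atom = if (!is.null(anchor_idx)) fc[anchor_idx, ])
  }
  data.table(residue_index = pres,
             mean_delta_s = colMeans(vals),
             sd_delta_s = apply(vals, 2L, function(v) {
               sqrt(mean((v - mean(v))^2))
             }),
             n_frames = nf)[order(residue_index)]
}

# Kabsch least-squares rigid superposition of P onto Q (n x 3 each)
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2L, cp); Q0 <- sweep(Q, 2L, cq)
  s <- svd(crossprod(P0, Q0))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotate = R, center_from = cp, center_to = cq)
}

apply_fit <- function(X, fit) {
  sweep(sweep(X, 2L, fit$center_from) %*% t(fit$rotate), 2L, fit$center_to, "+")
}

#' Root mean square fluctuation
#'
#' `RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2)` per atom, optionally
#' after a least-squares rigid superposition of every frame onto the
#' mean structure (Kabsch fit, iterated once: fit to the raw mean, then
#' recompute the mean and the deviations). Residue grouping averages
#' member-atom RMSF values. A degenerate superposition (all atoms at
#' one point) falls back to no superposition with a warning.
#'
#' @param traj An `shm_trajectory` with at least 2 frames.
#' @param superpose Remove rigid-body motion first (default `TRUE`).
#' @param grouping `"atom"` or `"residue"`.
#' @return `data.table`: per atom (`atom`, `atom_name`, `chain`,
#'   `residue_index`, `rmsf`) or per residue (`chain`, `residue_index`,
#'   `rmsf`).
#' @export
rmsf <- function(traj, superpose = TRUE, grouping = c("atom", "residue")) {
  grouping <- match.arg(grouping)
  nf <- n_frames(traj)
  stopifnot(nf >= 2L)
  na <- nrow(traj$atoms)
  frames <- lapply(seq_len(nf), function(t) frame_coords(traj, t))
  if (superpose) {
    mean_str <- Reduce(`+`, frames) / nf
    if (radius_of_gyration(mean_str) < 1e-12) {
      warning("degenerate superposition target; superposition skipped")
    } else {
      frames <- lapply(frames, function(f) apply_fit(f, kabsch(f, mean_str)))
      mean_str <- Reduce(`+`, frames) / nf
      frames <- lapply(frames, function(f) apply_fit(f, kabsch(f, mean_str)))
    }
  }
  mean_str <- Reduce(`+`, frames) / nf
  dev2 <- Reduce(`+`, lapply(frames, function(f) {
    rowSums((f - mean_str)^2)
  })) / nf
  per_atom <- data.table(atom = seq_len(na),
                         atom_name = traj$atoms$atom_name,
                         chain = traj$atoms$chain,
                         residue_index = traj$atoms$residue_index,
                         rmsf = sqrt(dev2))
  if (grouping == "atom") return(per_atom[])
  per_atom[, .(rmsf = mean(rmsf)), by = .(chain, residue_index)][]
}

#' Read a multi-model PDB file as a trajectory
#'
#' Parses `ATOM`/`HETATM` records between `MODEL`/`ENDMDL` pairs (a
#' file without MODEL records yields a single frame). Chains are
#' classified `"dna"` when the residue name is a nucleotide code
#' (`DA/DC/DG/DT/A/C/G/T/U`), `"protein"` otherwise.
#'
#' @param path PDB path.
#' @return An `shm_trajectory`.
#' @export
read_pdb_trajectory <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  model_starts <- grepl("^MODEL", lines)
  frame_id <- cumsum(model_starts)
  if (!any(model_starts)) frame_id <- rep(1L, length(lines))
  atom_lines <- grepl("^(ATOM  |HETATM)", lines)
  fid <- frame_id[atom_lines]
  al <- lines[atom_lines]
  parse_frame <- function(v) {
    data.table(
      atom_name = trimws(substr(v, 13L, 16L)),
      residue_name = trimws(substr(v, 18L, 20L)),
      residue_index = as.integer(trimws(substr(v, 23L, 26L))),
      chain_id = trimws(substr(v, 22L, 22L)),
      x = as.numeric(substr(v, 31L, 38L)),
      y = as.numeric(substr(v, 39L, 46L)),
      z = as.numeric(substr(v, 47L, 54L)))
  }
  frames <- split(al, fid)
  parsed <- lapply(frames, parse_frame)
  a1 <- parsed[[1L]]
  nuc <- c("DA", "DC", "DG", "DT", "DU", "A", "C", "G", "T", "U")
  atoms <- data.table(atom_name = a1$atom_name, residue_name = a1$residue_name,
                      residue_index = a1$residue_index,
                      chain = ifelse(a1$residue_name %in% nuc, "dna", "protein"))
  coords <- array(NA_real_, dim = c(length(parsed), nrow(a1), 3L))
  for (t in seq_along(parsed)) {
    stopifnot(nrow(parsed[[t]]) == nrow(a1))
    coords[t, , 1L] <- parsed[[t]]$x
    coords[t, , 2L] <- parsed[[t]]$y
    coords[t, , 3L] <- parsed[[t]]$z
  }
  trajectory(atoms, coords)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj An `shm_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  a <- traj$atoms
  chain_id <- ifelse(a$chain == "dna", "B", "A")
  for (t in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", t), con)
    fc <- frame_coords(traj, t)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(nrow(a)), substr(a$atom_name, 1L, 4L),
      substr(a$residue_name, 1L, 3L), chain_id, a$residue_index,
      fc[, 1L], fc[, 2L], fc[, 3L]), con)
    writeLines("ENDMDL", con)
  }
  invisible(path)
}

#' Read an XYZ trajectory
#'
#' Standard multi-frame XYZ: atom count line, comment line, then
#' `name x y z` rows per frame. Atom names become `atom_name`; residue
#' and chain metadata are not carried by XYZ and default to one protein
#' residue per atom.
#'
#' @param path XYZ path.
#' @return An `shm_trajectory`.
#' @export
read_xyz_trajectory <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  i <- 1L
  frames <- list()
  while (i <= length(lines)) {
    n <- as.integer(trimws(lines[i]))
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    frames[[length(frames) + 1L]] <- list(
      name = parts[, 1L],
      xyz = matrix(as.numeric(parts[, 2:4]), ncol = 3L))
    i <- i + 2L + n
  }
  a1 <- frames[[1L]]
  atoms <- data.table(atom_name = a1$name, residue_name = "UNK",
                      residue_index = seq_along(a1$name), chain = "protein")
  coords <- array(NA_real_, dim = c(length(frames), length(a1$name), 3L))
  for (t in seq_along(frames)) coords[t, , ] <- frames[[t]]$xyz
  trajectory(atoms, coords)
}

#' Summarise externally computed per-frame energy tables
#'
#' Interaction energies themselves are out of scope (they require
#' force-field evaluation); this helper only ingests a table of
#' per-frame energies and reports mean and standard deviation per
#' group, the summary used for energy histograms.
#'
#' @param energies `data.frame` with columns `group` and `energy`.
#' @return `data.table` with `group`, `n`, `mean`, `sd`.
#' @export
energy_summary <- function(energies) {
  e <- as.data.table(energies)
  stopifnot(all(c("group", "energy") %in% names(e)))
  e[, .(n = .N, mean = mean(energy), sd = sd(energy)), by = group][]
}
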