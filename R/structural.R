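#' Structural post-processing
#'
#' Kabsch least-squares superposition, pose and trajectory RMSD on a
#' backbone selection (atom names C, CA, N by default), per-residue RMSF,
#' ligand-contact residue occupancy at a distance cutoff, and MM/PBSA
#' binding-energy combination. Coordinates are in Angstrom throughout;
#' energies in kcal/mol.
#'
#' @name structural_analysis
NULL

#' Construct a toy/parsed trajectory
#'
#' @param atoms data.frame with columns \code{atom} (atom name),
#'   \code{resid} (residue number), \code{resname} and \code{elem}.
#' @param coords numeric array \code{n_atoms x 3 x n_frames} (Angstrom).
#' @param dt_ns time per frame in ns (metadata only).
#' @return Object of class \code{trajectory3d}.
#' @export
trajectory3d <- function(atoms, coords, dt_ns = 1) {
  stopifnot(is.data.frame(atoms),
            all(c("atom", "resid", "resname", "elem") %in% names(atoms)),
            length(dim(coords)) == 3L, dim(coords)[2] == 3L,
            dim(coords)[1] == nrow(atoms), nrow(atoms) > 0L,
            all(is.finite(coords)))
  structure(list(atoms = atoms, coords = coords, dt_ns = dt_ns),
            class = "trajectory3d")
}

#' @export
print.trajectory3d <- function(x, ...) {
  cat("Trajectory:", dim(x$coords)[3], "frames,", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$resid)), "residues,", x$dt_ns, "ns/frame\n")
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[3]
frame_xyz <- function(traj, i) traj$coords[, , i, drop = TRUE]

# Resolve a selection (NULL = all atoms; integer indices; logical mask;
# character atom names) to integer indices against an atom table.
sel_idx <- function(atoms, selection) {
  if (is.null(selection)) return(seq_len(nrow(atoms)))
  if (is.numeric(selection)) return(as.integer(selection))
  if (is.logical(selection)) return(which(selection))
  which(atoms$atom %in% selection)
}

#' Kabsch superposition
#'
#' Least-squares rigid-body fit of \code{mobile} onto \code{reference}
#' over the selected atoms: a proper rotation (det = +1, never a
#' reflection) plus translation, and the post-fit RMSD.
#'
#' @param mobile,reference numeric \code{n x 3} coordinate matrices with
#'   consistent atom ordering.
#' @param selection row indices to fit on (default: all rows).
#' @return List with \code{rotation} (3x3, applied as \code{xyz \%*\% R}),
#'   \code{translation}, \code{rmsd} (over the selection after fitting)
#'   and \code{transform}, a function mapping an \code{n x 3} matrix into
#'   the fitted frame.
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3L, ncol(reference) == 3L)
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (length(selection) < 3L) stop("need at least 3 atoms to superpose")
  P <- mobile[selection, , drop = FALSE]
  Q <- reference[selection, , drop = FALSE]
  if (nrow(P) != nrow(Q)) stop("selections differ in atom count")
  cp <- colMeans(P); cq <- colMeans(Q)
  A <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  sv <- svd(A)
  if (sv$d[2] - sv$d[3] < 1e-10 * max(sv$d[1], 1))
    warning("near-degenerate (collinear) selection; rotation poorly conditioned")
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  transform <- function(xyz)
    sweep(sweep(as.matrix(xyz), 2, cp) %*% R, 2, cq, `+`)
  fitted <- transform(mobile)
  list(rotation = R, translation = cq - as.vector(cp %*% R),
       rmsd = rmsd_xyz(fitted[selection, , drop = FALSE], Q),
       transform = transform)
}

# plain coordinate RMSD of two matched n x 3 matrices
rmsd_xyz <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  sqrt(mean(rowSums((a - b)^2)))
}

#' Root-mean-square deviation between two coordinate sets
#'
#' With \code{superpose = FALSE} (the convention for docking-pose RMSD
#' against a crystallographic pose, compared in the same site frame) the
#' deviation is computed on the coordinates as given, using identity atom
#' correspondence by input order; with \code{superpose = TRUE} a Kabsch
#' fit on the selection is applied first.
#'
#' @param a,b \code{n x 3} coordinate matrices.
#' @param selection row indices (default all).
#' @param superpose logical; least-squares fit before measuring?
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, selection = NULL, superpose = FALSE) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) stop("coordinate sets differ in atom count")
  if (is.null(selection)) selection <- seq_len(nrow(a))
  if (superpose) {
    fit <- kabsch_superpose(a, b, selection)
    return(fit$rmsd)
  }
  rmsd_xyz(a[selection, , drop = FALSE], b[selection, , drop = FALSE])
}

#' Per-frame superposed RMSD series
#'
#' Each frame is Kabsch-fitted to the reference on the selection and the
#' post-fit RMSD recorded; the classic RMSD-vs-time trace.
#'
#' @param traj a \code{trajectory3d}.
#' @param reference reference coordinates (\code{n x 3}); defaults to the
#'   first frame.
#' @param selection atom selection (default backbone names C, CA, N).
#' @return data.frame with columns \code{time_ns} and \code{rmsd}.
#' @export
rmsd_series <- function(traj, reference = NULL,
                        selection = c("C", "CA", "N")) {
  stopifnot(inherits(traj, "trajectory3d"))
  nf <- n_frames(traj)
  if (nf == 0L) stop("empty trajectory")
  if (is.null(reference)) reference <- frame_xyz(traj, 1)
  idx <- sel_idx(traj$atoms, selection)
  if (length(idx) == 0L) stop("empty selection")
  r <- vapply(seq_len(nf), function(i)
    kabsch_superpose(frame_xyz(traj, i), reference, idx)$rmsd, 0)
  data.frame(time_ns = (seq_len(nf) - 1) * traj$dt_ns, rmsd = r)
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are iteratively aligned (Kabsch, on the selection) to their
#' time-mean structure -- the mean is recomputed after each pass -- and the
#' RMSF of each selected atom about its mean position is averaged within
#' each residue.
#'
#' @param traj a \code{trajectory3d} with at least 2 frames.
#' @param selection atom selection (default backbone names C, CA, N).
#' @param align logical; rigid-body align frames to the running mean first
#'   (disable for pre-aligned toy data).
#' @param passes alignment passes (default 2).
#' @return data.frame with columns \code{resid}, \code{resname},
#'   \code{rmsf}.
#' @export
rmsf <- function(traj, selection = c("C", "CA", "N"), align = TRUE,
                 passes = 2) {
  stopifnot(inherits(traj, "trajectory3d"))
  nf <- n_frames(traj)
  if (nf < 2L) stop("need at least 2 frames for RMSF")
  idx <- sel_idx(traj$atoms, selection)
  if (length(idx) == 0L) stop("empty selection")
  frames <- lapply(seq_len(nf), function(i) frame_xyz(traj, i))
  if (align) {
    ref <- frames[[1]]
    for (p in seq_len(passes)) {
      frames <- lapply(frames, function(f)
        kabsch_superpose(f, ref, idx)$transform(f))
      ref <- Reduce(`+`, frames) / nf
    }
  }
  mean_xyz <- Reduce(`+`, frames) / nf
  msd <- Reduce(`+`, lapply(frames, function(f) rowSums((f - mean_xyz)^2))) / nf
  atom_rmsf <- sqrt(msd)[idx]
  resid <- traj$atoms$resid[idx]
  out <- do.call(rbind, lapply(split(seq_along(idx), resid), function(ix)
    data.frame(resid = resid[ix[1]],
               resname = traj$atoms$resname[idx[ix[1]]],
               rmsf = mean(atom_rmsf[ix]))))
  out <- out[order(out$resid), ]
  rownames(out) <- NULL
  out
}

#' Ligand-contact residue occupancy
#'
#' A residue is in contact in a frame when any of its heavy atoms lies
#' within \code{cutoff} of any ligand heavy atom; the occupancy is the
#' fraction of (selected) frames in contact. Frame windows support
#' stage-wise analyses (e.g. early vs late segments of a simulation).
#'
#' @param traj a \code{trajectory3d} containing both the protein and the
#'   ligand.
#' @param ligand_resname residue name identifying the ligand (default
#'   \code{"LIG"}).
#' @param cutoff contact distance in Angstrom (default 4).
#' @param frames optional integer vector of frame indices to restrict to.
#' @return data.frame with columns \code{resid}, \code{resname},
#'   \code{occupancy}, restricted to residues with occupancy > 0.
#' @export
contact_residues <- function(traj, ligand_resname = "LIG", cutoff = 4.0,
                             frames = NULL) {
  stopifnot(inherits(traj, "trajectory3d"), cutoff > 0)
  lig <- which(traj$atoms$resname == ligand_resname & traj$atoms$elem != "H")
  prot <- which(traj$atoms$resname != ligand_resname & traj$atoms$elem != "H")
  if (length(lig) == 0L) stop("no ligand atoms match resname ", ligand_resname)
  if (length(prot) == 0L) stop("no protein atoms")
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  resid <- traj$atoms$resid[prot]
  res_split <- split(prot, resid)
  hits <- stats::setNames(numeric(length(res_split)), names(res_split))
  for (f in frames) {
    xyz <- frame_xyz(traj, f)
    lx <- xyz[lig, , drop = FALSE]
    for (r in names(res_split)) {
      px <- xyz[res_split[[r]], , drop = FALSE]
      d2 <- outer(rowSums(px^2), rowSums(lx^2), `+`) - 2 * px %*% t(lx)
      if (min(d2) <= cutoff^2) hits[r] <- hits[r] + 1
    }
  }
  occ <- hits / length(frames)
  keep <- occ > 0
  res_ids <- as.integer(names(res_split))[keep]
  data.frame(resid = res_ids,
             resname = traj$atoms$resname[match(res_ids, traj$atoms$resid)],
             occupancy = unname(occ[keep]))
}

#' Combine MM/PBSA energy components into a binding free energy
#'
#' Per frame, each component difference is
#' \code{complex - receptor - ligand}; the molecular-mechanics term is
#' \code{dE_MM = dE_internal + dE_elec + dE_vdw}, the solvation term
#' \code{dG_solv = dG_PB + dG_SA} (Poisson-Boltzmann polar plus
#' surface-area non-polar), the enthalpic estimate
#' \code{dH = dE_MM + dG_solv}, and the binding free energy
#' \code{dG_bind = dH + (-TdS)} when an entropy term is supplied
#' (otherwise \code{dG_bind} is the enthalpy-only estimate, flagged).
#'
#' @param table data.frame with columns \code{frame}, \code{system}
#'   (\code{"complex"}, \code{"receptor"}, \code{"ligand"}),
#'   \code{E_internal}, \code{E_elec}, \code{E_vdw}, \code{G_PB},
#'   \code{G_SA}, and optionally \code{minus_TdS} (taken from the complex
#'   rows), all in kcal/mol.
#' @param minus_TdS optional scalar \code{-TdS} (kcal/mol), used when the
#'   table has no per-frame column.
#' @return List of class \code{mmpbsa_summary}: \code{per_frame} deltas,
#'   \code{summary} (mean and sd per component over frames),
#'   \code{dG_bind}, \code{dG_sd} and \code{entropy_included}.
#' @export
mmpbsa_combine <- function(table, minus_TdS = NULL) {
  comp_cols <- c("E_internal", "E_elec", "E_vdw", "G_PB", "G_SA")
  stopifnot(is.data.frame(table),
            all(c("frame", "system", comp_cols) %in% names(table)))
  if (!all(is.finite(as.matrix(table[comp_cols]))))
    stop("energy components must be finite")
  systems <- c("complex", "receptor", "ligand")
  frames <- sort(unique(table$frame))
  sub <- lapply(systems, function(s) {
    d <- table[table$system == s, ]
    if (nrow(d) != length(frames) || !setequal(d$frame, frames))
      stop("incomplete complex/receptor/ligand triples across frames")
    d[match(frames, d$frame), ]
  })
  names(sub) <- systems
  delta <- as.data.frame(lapply(comp_cols, function(cc)
    sub$complex[[cc]] - sub$receptor[[cc]] - sub$ligand[[cc]]))
  names(delta) <- paste0("d", comp_cols)
  delta$dE_MM <- delta$dE_internal + delta$dE_elec + delta$dE_vdw
  delta$dG_solv <- delta$dG_PB + delta$dG_SA
  delta$dH <- delta$dE_MM + delta$dG_solv
  tds <- NULL
  if ("minus_TdS" %in% names(table)) {
    tds <- sub$complex$minus_TdS
    if (all(is.na(tds))) tds <- NULL
  }
  if (is.null(tds) && !is.null(minus_TdS)) tds <- rep(minus_TdS, length(frames))
  entropy_included <- !is.null(tds)
  delta$minus_TdS <- if (entropy_included) tds else 0
  delta$dG_bind <- delta$dH + delta$minus_TdS
  delta <- cbind(frame = frames, delta)
  keep <- setdiff(names(delta), "frame")
  summ <- data.frame(
    component = keep,
    mean = vapply(delta[keep], mean, 0),
    sd = vapply(delta[keep], stats::sd, 0), row.names = NULL)
  structure(list(per_frame = delta, summary = summ,
                 dG_bind = mean(delta$dG_bind),
                 dG_sd = stats::sd(delta$dG_bind),
                 entropy_included = entropy_included),
            class = "mmpbsa_summary")
}

#' @export
print.mmpbsa_summary <- function(x, ...) {
  cat(sprintf("MM/PBSA over %d frames: dG_bind = %.2f +/- %.2f kcal/mol%s\n",
              nrow(x$per_frame), x$dG_bind, x$dG_sd,
              if (x$entropy_included) "" else " (enthalpy-only: no -TdS term)"))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Read a (multi-MODEL) PDB file as a trajectory
#'
#' @param file PDB path; each MODEL becomes a frame.
#' @param dt_ns time per frame in ns.
#' @return A \code{trajectory3d}.
#' @export
read_pdb_trajectory <- function(file, dt_ns = 1) {
  pdb <- bio3d::read.pdb(file, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(!nzchar(trimws(elem))))
    elem <- substr(trimws(at$elety), 1, 1) # infer from atom name
  atoms <- data.frame(atom = trimws(at$elety), resid = at$resno,
                      resname = trimws(at$resid), elem = trimws(elem))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz); na <- nrow(atoms)
  coords <- array(NA_real_, c(na, 3, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  trajectory3d(atoms, coords, dt_ns)
}

#' Write a trajectory as a multi-MODEL PDB file
#'
#' @param traj a \code{trajectory3d}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
write_pdb_trajectory <- function(traj, file) {
  stopifnot(inherits(traj, "trajectory3d"))
  at <- traj$atoms
  con <- file(file, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_xyz(traj, f)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(at)), substr(at$atom, 1, 4), substr(at$resname, 1, 3),
      at$resid, xyz[, 1], xyz[, 2], xyz[, 3], substr(at$elem, 1, 2)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}
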