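#' Synthetic inputs with planted ground truth
#'
#' Generators for every input the pipeline consumes: scaffold-decorated
#' compound libraries, correlated three-program docking score tables,
#' dose-response and inhibition-rate datasets with multiplicative noise,
#' toy backbone trajectories with per-residue fluctuation profiles and a
#' scheduled ligand, and per-frame MM/PBSA component tables. Each
#' generator is deterministic for a given seed and attaches its ground
#' truth as the \code{"truth"} attribute (also written as a sibling JSON
#' when a file is requested), so downstream modules can be tested against
#' planted values.
#'
#' Kinetics defaults are the study conditions of the screen this package
#' accompanies: a competitive inhibitor with Vmax = 36.06 mM/min,
#' Km = 25.71 mM, Ki = 0.0234 mM measured on substrate concentrations
#' 0.10-0.50 mM and inhibitor concentrations 0-0.060 mM, and a
#' dose-response curve with IC50 = 0.044 mM; noise is multiplicative
#' Gaussian with a 2\% coefficient of variation, in triplicate.
#'
#' @name synthetic_data
NULL

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.write_with_truth <- function(df, file) {
  utils::write.csv(df, file, row.names = FALSE)
  truth <- attr(df, "truth")
  if (!is.null(truth))
    jsonlite::write_json(truth, sub("\\.csv$", "", file) |> paste0("_truth.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(df)
}

# scaffold pool (SMILES) and saturated decoration chains used by gen_library;
# chains are sized so decorated compounds fall inside the 160-1000 g/mol window
.scaffold_pool <- c("c1ccccc1", "c1ccncc1", "C1CCCCC1", "c1ccc2ccccc2c1",
                    "c1ccsc1", "c1cncnc1", "C1CCNCC1", "C1CCOC1")
.chain_pool <- c("CCCCCCCC", "CCCCCCCCCC", "CCCCCCCCCCCC", "ClCCCCCCCC",
                 "BrCCCCCCCC", "OCCCCCCCC", "CC(C)CCCCCCC", "CCCCCCCCCCCCCC")

#' Generate a scaffold-structured compound library
#'
#' Compounds are built by decorating ring scaffolds with saturated
#' alkyl/halide side chains, so every compound's chemotype is known by
#' construction. Optional fractions of planted curation violations are
#' appended: molecular weights outside 160-1000 g/mol, exact duplicates
#' (same structure, less potent annotation, new id) and activities above
#' 100 uM.
#'
#' @param n_scaffolds number of distinct scaffolds (<= 8 from the built-in
#'   pool unless \code{scaffolds} is given).
#' @param decorations_per_scaffold compounds per scaffold (<= 8 distinct
#'   chains).
#' @param scaffolds optional character vector of scaffold SMILES replacing
#'   the built-in pool.
#' @param duplicate_fraction,mw_violation_fraction,high_activity_fraction
#'   fractions (of the base compounds) of planted violations of each
#'   curation criterion.
#' @param source_class annotation for all records.
#' @param seed RNG seed (activities, duplicate choice).
#' @param file optional CSV path; ground truth goes to a sibling
#'   \code{*_truth.json}.
#' @return data.frame with columns \code{id}, \code{smiles},
#'   \code{activity_um}, \code{activity_type}, \code{source_class}; the
#'   \code{"truth"} attribute maps each id to its planted scaffold key
#'   (canonical SMILES), violation type and duplicate parent.
#' @export
gen_library <- function(n_scaffolds = 4, decorations_per_scaffold = 5,
                        scaffolds = NULL,
                        duplicate_fraction = 0, mw_violation_fraction = 0,
                        high_activity_fraction = 0,
                        source_class = "PTP1B", seed = 1, file = NULL) {
  pool <- if (is.null(scaffolds)) .scaffold_pool else scaffolds
  if (n_scaffolds > length(pool)) stop("not enough scaffolds in the pool")
  if (decorations_per_scaffold > length(.chain_pool))
    stop("at most ", length(.chain_pool), " decorations per scaffold")
  df <- with_seed(seed, {
    scaf <- pool[seq_len(n_scaffolds)]
    base <- expand.grid(chain = .chain_pool[seq_len(decorations_per_scaffold)],
                        scaffold = scaf, stringsAsFactors = FALSE)
    n <- nrow(base)
    out <- data.frame(
      id = sprintf("CPD%04d", seq_len(n)),
      smiles = paste0(base$chain, base$scaffold),
      activity_um = round(stats::rlnorm(n, log(5), 0.8), 3),
      activity_type = "IC50", source_class = source_class)
    out$activity_um <- pmin(out$activity_um, 80) # base compounds are actives
    truth <- data.frame(id = out$id, scaffold_smiles = base$scaffold,
                        planted = "ok", duplicate_of = NA_character_)
    nxt <- n
    add <- function(ids, smiles, act, planted, dup = NA_character_) {
      out <<- rbind(out, data.frame(id = ids, smiles = smiles,
                                    activity_um = act, activity_type = "IC50",
                                    source_class = source_class))
      truth <<- rbind(truth, data.frame(id = ids, scaffold_smiles = NA,
                                        planted = planted, duplicate_of = dup))
    }
    n_dup <- round(duplicate_fraction * n)
    if (n_dup > 0) {
      pick <- sample.int(n, n_dup, replace = FALSE)
      ids <- sprintf("DUP%04d", seq_len(n_dup))
      add(ids, out$smiles[pick], out$activity_um[pick] * 2, "duplicate",
          out$id[pick])
      truth$scaffold_smiles[match(ids, truth$id)] <- truth$scaffold_smiles[pick]
    }
    n_mw <- round(mw_violation_fraction * n)
    if (n_mw > 0) {
      low <- sprintf("MWL%04d", seq_len(ceiling(n_mw / 2)))
      # toluene-sized (below window) and C70-chain (above window) violators
      add(low, rep("Cc1ccccc1", length(low)),
          round(stats::runif(length(low), 1, 80), 3), "mw_low")
      truth$scaffold_smiles[match(low, truth$id)] <- "c1ccccc1"
      n_hi <- n_mw - length(low)
      if (n_hi > 0) {
        hi <- sprintf("MWH%04d", seq_len(n_hi))
        add(hi, paste0(strrep("C", 70), pool[1]),
            round(stats::runif(n_hi, 1, 80), 3), "mw_high")
        truth$scaffold_smiles[match(hi, truth$id)] <- pool[1]
      }
    }
    n_act <- round(high_activity_fraction * n)
    if (n_act > 0) {
      ids <- sprintf("ACT%04d", seq_len(n_act))
      # same chemotypes, but planted above the 100 uM activity threshold;
      # an isopropyl-capped plain alkyl chain keeps them distinct from the
      # base compounds (halide chains cannot take the cap)
      plain <- c("CCCCCCCC", "CCCCCCCCCC", "CCCCCCCCCCCC")
      smi <- paste0("CC(C)", plain[(seq_len(n_act) - 1) %% 3 + 1],
                    pool[(seq_len(n_act) - 1) %% n_scaffolds + 1])
      add(ids, smi, round(stats::runif(n_act, 150, 500), 3), "high_activity")
      truth$scaffold_smiles[match(ids, truth$id)] <-
        pool[(seq_len(n_act) - 1) %% n_scaffolds + 1]
    }
    truth$scaffold_key <- ifelse(is.na(truth$scaffold_smiles), NA_character_,
                                 ob_canonical_smiles(ifelse(is.na(truth$scaffold_smiles),
                                                            "C", truth$scaffold_smiles)))
    attr(out, "truth") <- truth
    out
  })
  if (!is.null(file)) .write_with_truth(df, file)
  df
}

#' Generate correlated docking score tables for three programs
#'
#' Each compound has a latent binding affinity; per-program scores are
#' affine images of the latent plus independent Gaussian noise, with the
#' shared-latent weight calibrated so that the expected Spearman rank
#' correlation between any two programs equals \code{rank_correlation}.
#' Vina and AutoDock scores are emitted on a negative kcal/mol-like scale
#' (lower is better), GOLD as a positive fitness (higher is better).
#'
#' @param n_compounds number of compounds.
#' @param rank_correlation target inter-program Spearman correlation in
#'   [0, 1].
#' @param program_means,program_sds named numeric (names \code{vina},
#'   \code{autodock42}, \code{gold}): score location and scale per program.
#' @param seed RNG seed.
#' @param file_prefix optional path prefix; writes
#'   \code{<prefix>_vina.csv} etc. plus a truth JSON.
#' @return Named list of three \code{\link{score_table}}s with a
#'   \code{"truth"} attribute holding the latent affinities (larger =
#'   better binder).
#' @export
gen_docking_scores <- function(n_compounds = 1075, rank_correlation = 0.85,
                               program_means = c(vina = -7, autodock42 = -8.5,
                                                 gold = 40),
                               program_sds = c(vina = 1, autodock42 = 1.2,
                                               gold = 12),
                               seed = 1, file_prefix = NULL) {
  stopifnot(rank_correlation >= 0, rank_correlation <= 1)
  res <- with_seed(seed, {
    ids <- sprintf("CPD%05d", seq_len(n_compounds))
    z <- stats::rnorm(n_compounds) # latent affinity, larger = better
    rho <- 2 * sin(pi * rank_correlation / 6) # Pearson giving that Spearman
    w <- sqrt(rho)
    mix <- function() w * z + sqrt(1 - w^2) * stats::rnorm(n_compounds)
    tabs <- list(
      vina = score_table(ids, program_means[["vina"]] -
                           program_sds[["vina"]] * mix(), "vina"),
      autodock42 = score_table(ids, program_means[["autodock42"]] -
                                 program_sds[["autodock42"]] * mix(), "autodock42"),
      gold = score_table(ids, program_means[["gold"]] +
                           program_sds[["gold"]] * mix(), "gold"))
    attr(tabs, "truth") <- data.frame(id = ids, latent_affinity = z)
    tabs
  })
  if (!is.null(file_prefix)) {
    for (p in names(res))
      utils::write.csv(cbind(res[[p]], program = p),
                       paste0(file_prefix, "_", p, ".csv"), row.names = FALSE)
    jsonlite::write_json(attr(res, "truth"), paste0(file_prefix, "_truth.json"),
                         pretty = TRUE, digits = NA)
  }
  res
}

#' Generate dose-response (percent inhibition) data
#'
#' Responses follow the sigmoidal dose-response model times multiplicative
#' Gaussian noise \code{(1 + eps)}, \code{eps ~ N(0, noise_cv)}.
#'
#' @param A100 maximum inhibition (percent).
#' @param IC50 half-maximal concentration (mM).
#' @param s cooperativity exponent.
#' @param conc_mM inhibitor concentrations; default 8 log-spaced points
#'   spanning 0.005-0.5 mM.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param n_replicates replicates per concentration.
#' @param seed RNG seed.
#' @param file optional CSV path (truth JSON written alongside).
#' @return data.frame with columns \code{inhibitor_mM}, \code{response},
#'   \code{replicate}; generating parameters in the \code{"truth"}
#'   attribute.
#' @export
gen_dose_response <- function(A100 = 100, IC50 = 0.044, s = 1,
                              conc_mM = NULL, noise_cv = 0.02,
                              n_replicates = 3, seed = 1, file = NULL) {
  if (is.null(conc_mM))
    conc_mM <- exp(seq(log(0.005), log(0.5), length.out = 8))
  df <- with_seed(seed, {
    g <- expand.grid(inhibitor_mM = conc_mM, replicate = seq_len(n_replicates))
    mu <- dose_response_model(g$inhibitor_mM, A100, IC50, s)
    g$response <- mu * (1 + stats::rnorm(nrow(g), 0, noise_cv))
    g <- g[c("inhibitor_mM", "response", "replicate")]
    attr(g, "truth") <- list(A100 = A100, IC50 = IC50, s = s,
                             noise_cv = noise_cv)
    g
  })
  if (!is.null(file)) .write_with_truth(df, file)
  df
}

#' Generate inhibition-rate data on a substrate x inhibitor grid
#'
#' Velocities follow the selected inhibition rate law times multiplicative
#' Gaussian noise; the full factorial substrate x inhibitor x replicate
#' design is emitted. Grid defaults are the bench assay's concentrations.
#'
#' @param Vmax,Km,Ki generating kinetic parameters (mM/min, mM, mM).
#' @param mechanism \code{"competitive"}, \code{"uncompetitive"},
#'   \code{"noncompetitive"} or \code{"mixed"}.
#' @param Kiprime second inhibition constant for \code{"mixed"} (defaults
#'   to \code{Ki}).
#' @param substrate_mM,inhibitor_mM concentration grids.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param n_replicates replicates per grid point.
#' @param seed RNG seed.
#' @param file optional CSV path (truth JSON written alongside).
#' @return data.frame with columns \code{substrate_mM},
#'   \code{inhibitor_mM}, \code{velocity}, \code{replicate}; generating
#'   parameters in the \code{"truth"} attribute.
#' @export
gen_rate_data <- function(Vmax = 36.06, Km = 25.71, Ki = 0.0234,
                          mechanism = c("competitive", "uncompetitive",
                                        "noncompetitive", "mixed"),
                          Kiprime = NULL,
                          substrate_mM = c(0.10, 0.20, 0.30, 0.40, 0.50),
                          inhibitor_mM = c(0, 0.005, 0.040, 0.060),
                          noise_cv = 0.02, n_replicates = 3, seed = 1,
                          file = NULL) {
  mechanism <- match.arg(mechanism)
  if (is.null(Kiprime)) Kiprime <- Ki
  rate <- switch(mechanism,
    competitive = function(S, I) competitive_rate(S, I, Vmax, Km, Ki),
    uncompetitive = function(S, I) uncompetitive_rate(S, I, Vmax, Km, Ki),
    noncompetitive = function(S, I) noncompetitive_rate(S, I, Vmax, Km, Ki),
    mixed = function(S, I) mixed_rate(S, I, Vmax, Km, Ki, Kiprime))
  df <- with_seed(seed, {
    g <- expand.grid(substrate_mM = substrate_mM, inhibitor_mM = inhibitor_mM,
                     replicate = seq_len(n_replicates))
    mu <- rate(g$substrate_mM, g$inhibitor_mM)
    g$velocity <- mu * (1 + stats::rnorm(nrow(g), 0, noise_cv))
    g <- g[c("substrate_mM", "inhibitor_mM", "velocity", "replicate")]
    attr(g, "truth") <- list(Vmax = Vmax, Km = Km, Ki = Ki,
                             Kiprime = if (mechanism == "mixed") Kiprime else NULL,
                             mechanism = mechanism, noise_cv = noise_cv)
    g
  })
  if (!is.null(file)) .write_with_truth(df, file)
  df
}

#' Generate a toy backbone trajectory with planted fluctuations
#'
#' A linear backbone (N, CA, C per residue) in which each residue is
#' displaced along z by a periodic waveform of planted amplitude:
#' \code{"square"} alternates +amp/-amp (RMSF about the time mean exactly
#' \code{amp} for an even frame count), \code{"sine"} runs whole cycles
#' (RMSF \code{amp/sqrt(2)}). Optionally a single-atom probe residue
#' (\code{PRB}) is placed away from the chain with a one-atom ligand
#' (\code{LIG}) at a scheduled distance from it, giving exact planted
#' contact occupancies.
#'
#' @param n_frames number of frames (even counts make square-wave RMSF
#'   exact).
#' @param n_residues number of backbone residues.
#' @param amplitudes per-residue displacement amplitudes in Angstrom
#'   (length \code{n_residues}; default all zero).
#' @param waveform \code{"square"} or \code{"sine"}.
#' @param cycles whole waveform cycles across the trajectory (sine).
#' @param jitter_sd isotropic Gaussian positional noise, Angstrom.
#' @param ligand_distances optional numeric vector (length
#'   \code{n_frames}) of ligand-to-probe distances in Angstrom.
#' @param dt_ns ns per frame.
#' @param seed RNG seed (used by jitter only).
#' @return A \code{\link{trajectory3d}}; the \code{"truth"} attribute
#'   holds expected per-residue RMSF and, when a ligand is scheduled, the
#'   probe residue id and the distance schedule.
#' @export
gen_trajectory <- function(n_frames = 100, n_residues = 20,
                           amplitudes = NULL,
                           waveform = c("square", "sine"), cycles = 5,
                           jitter_sd = 0, ligand_distances = NULL,
                           dt_ns = 1, seed = 1) {
  waveform <- match.arg(waveform)
  if (is.null(amplitudes)) amplitudes <- rep(0, n_residues)
  stopifnot(length(amplitudes) == n_residues, n_frames >= 2)
  atoms <- do.call(rbind, lapply(seq_len(n_residues), function(i)
    data.frame(atom = c("N", "CA", "C"), resid = i, resname = "GLY",
               elem = c("N", "C", "C"))))
  base <- do.call(rbind, lapply(seq_len(n_residues), function(i) {
    ca <- c(3.8 * (i - 1), 0, 0)
    rbind(ca + c(-1.2, 0.8, 0.3), ca, ca + c(1.2, 0.8, -0.3))
  }))
  probe_resid <- NULL
  if (!is.null(ligand_distances)) {
    stopifnot(length(ligand_distances) == n_frames,
              all(ligand_distances >= 0))
    probe_resid <- n_residues + 1L
    probe_xyz <- c(3.8 * (n_residues + 2), 0, 0) # >10 A beyond the chain
    atoms <- rbind(atoms,
                   data.frame(atom = "CA", resid = probe_resid,
                              resname = "PRB", elem = "C"),
                   data.frame(atom = "C1", resid = n_residues + 2L,
                              resname = "LIG", elem = "C"))
    base <- rbind(base, probe_xyz, probe_xyz) # ligand placed per frame
  }
  wave <- switch(waveform,
    square = rep_len(c(1, -1), n_frames),
    sine = sin(2 * pi * cycles * (seq_len(n_frames) - 1) / n_frames))
  coords <- with_seed(seed, {
    arr <- array(NA_real_, c(nrow(atoms), 3, n_frames))
    for (f in seq_len(n_frames)) {
      xyz <- base
      for (i in seq_len(n_residues)) {
        rows <- (3 * i - 2):(3 * i)
        xyz[rows, 3] <- xyz[rows, 3] + amplitudes[i] * wave[f]
      }
      if (!is.null(probe_resid))
        xyz[nrow(xyz), ] <- xyz[nrow(xyz) - 1, ] + c(0, ligand_distances[f], 0)
      if (jitter_sd > 0)
        xyz <- xyz + stats::rnorm(length(xyz), 0, jitter_sd)
      arr[, , f] <- xyz
    }
    arr
  })
  traj <- trajectory3d(atoms, coords, dt_ns)
  rms_wave <- sqrt(mean((wave - mean(wave))^2))
  attr(traj, "truth") <- list(
    expected_rmsf = data.frame(resid = seq_len(n_residues),
                               rmsf = abs(amplitudes) * rms_wave),
    probe_resid = probe_resid,
    ligand_distances = ligand_distances,
    waveform = waveform)
  traj
}

#' Generate a per-frame MM/PBSA component table
#'
#' Gaussian per-frame energies for complex, receptor and ligand around
#' configurable means; the planted binding free energy is the sum of the
#' configured component-mean differences (plus \code{-TdS} if given).
#' Default means plant component differences
#' dE_internal = 0, dE_elec = -20, dE_vdw = -30, dG_PB = +15, dG_SA = -5
#' kcal/mol (enthalpy -40).
#'
#' @param n_frames number of frames.
#' @param means 3 x 5 numeric matrix of component means, rows
#'   \code{complex}, \code{receptor}, \code{ligand}, columns
#'   \code{E_internal}, \code{E_elec}, \code{E_vdw}, \code{G_PB},
#'   \code{G_SA}.
#' @param sds matching matrix of per-frame standard deviations (scalar
#'   recycled).
#' @param minus_TdS optional scalar entropy term (kcal/mol), added to the
#'   planted dG.
#' @param seed RNG seed.
#' @param file optional CSV path (truth JSON written alongside).
#' @return Long-format data.frame as consumed by
#'   \code{\link{mmpbsa_combine}}, with planted \code{dG_bind} and
#'   component deltas in the \code{"truth"} attribute.
#' @export
gen_energy_components <- function(n_frames = 200, means = NULL, sds = 2,
                                  minus_TdS = NULL, seed = 1, file = NULL) {
  comp_cols <- c("E_internal", "E_elec", "E_vdw", "G_PB", "G_SA")
  systems <- c("complex", "receptor", "ligand")
  if (is.null(means)) {
    means <- rbind(complex = c(5000, -8000, -900, 7030, 90),
                   receptor = c(4995, -7980, -870, 6990, 92),
                   ligand = c(5, 0, 0, 25, 3))
    colnames(means) <- comp_cols
  }
  means <- as.matrix(means)
  stopifnot(nrow(means) == 3, ncol(means) == 5)
  sds <- matrix(rep_len(as.numeric(sds), 15), 3, 5)
  df <- with_seed(seed, {
    rows <- do.call(rbind, lapply(seq_along(systems), function(si) {
      m <- matrix(stats::rnorm(n_frames * 5, mean = rep(means[si, ], each = n_frames),
                               sd = rep(sds[si, ], each = n_frames)),
                  n_frames, 5, dimnames = list(NULL, comp_cols))
      cbind(data.frame(frame = seq_len(n_frames), system = systems[si]),
            as.data.frame(m))
    }))
    if (!is.null(minus_TdS)) rows$minus_TdS <-
      ifelse(rows$system == "complex", minus_TdS, NA_real_)
    d <- means[1, ] - means[2, ] - means[3, ]
    attr(rows, "truth") <- list(
      delta_means = as.list(d),
      dH = sum(d),
      minus_TdS = minus_TdS,
      dG_bind = sum(d) + if (is.null(minus_TdS)) 0 else minus_TdS)
    rows
  })
  if (!is.null(file)) .write_with_truth(df, file)
  df
}
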