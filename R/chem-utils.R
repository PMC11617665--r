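# Internal OpenBabel-backed chemistry helpers shared by the curation and
# scaffold modules. All heavy lifting (SMILES/SDF parsing, canonicalization,
# desalting, neutralization, property computation) is delegated to
# ChemmineR/ChemmineOB; these wrappers only batch calls and map results back
# to caller-supplied identifiers.

# Convert SMILES to canonical SMILES, tolerating unparsable entries.
# Returns a character vector aligned with `smiles`; NA where parsing failed.
# desalt keeps the largest contiguous fragment; neutralize removes formal
# charges where valence-legal.
ob_canonical_smiles <- function(smiles, desalt = TRUE, neutralize = TRUE,
                                strip_stereo = FALSE) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  tokens <- sprintf("rk%07d", seq_along(smiles))
  # internal tokens avoid collisions with whitespace/odd characters in ids
  src <- paste0(paste(smiles, tokens), collapse = "\n")
  ops <- c("e", if (desalt) "r", if (neutralize) "neutralize",
           if (strip_stereo) "i")
  opts <- data.frame(names = ops, args = rep("", length(ops)))
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", src, options = opts)),
    error = function(e) "")
  res <- rep(NA_character_, length(smiles))
  if (nzchar(out)) {
    lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    got_tok <- vapply(parts, function(p) if (length(p) >= 2L) trimws(p[2]) else NA_character_, "")
    got_smi <- vapply(parts, function(p) p[1], "")
    idx <- match(got_tok, tokens)
    ok <- !is.na(idx)
    res[idx[ok]] <- got_smi[ok]
  }
  res
}

# Average molecular weight (g/mol, implicit hydrogens included) of each
# SMILES; NA where parsing failed. Computed on the structure as given, so
# pass desalted SMILES to get the parent weight.
ob_molecular_weight <- function(smiles) {
  stopifnot(is.character(smiles))
  mw <- rep(NA_real_, length(smiles))
  ok <- which(!is.na(smiles) & nzchar(smiles))
  if (length(ok) == 0L) return(mw)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles[ok],
                                                           sprintf("rk%07d", ok)))),
    error = function(e) NULL)
  if (is.null(sdf)) return(mw)
  props <- tryCatch(suppressWarnings(ChemmineR::propOB(sdf)),
                    error = function(e) NULL)
  if (is.null(props) || is.null(props$MW)) return(mw)
  # propOB returns one row per molecule in input order
  if (length(props$MW) == length(ok)) mw[ok] <- as.numeric(props$MW)
  mw
}

# Parse one or more SMILES into ChemmineR SDF objects (kekulized bond
# orders), returning a list aligned with input; NULL where parsing failed.
ob_smiles_to_sdf <- function(smiles) {
  out <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    if (is.na(smiles[i]) || !nzchar(smiles[i])) next
    sdf <- tryCatch(
      suppressWarnings(ChemmineR::smiles2sdf(smiles[i])),
      error = function(e) NULL)
    if (!is.null(sdf) && length(sdf) >= 1L) out[[i]] <- sdf[[1]]
  }
  out
}

# Molecular graph from a ChemmineR SDF component: element symbols,
# coordinates and an edge table with bond orders (kekulized; order 4 from
# aromatic V2000 files is treated as order 1 for pruning connectivity and
# written back as-is).
mol_graph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_[0-9]+$", "", rownames(ab))
  n <- nrow(ab)
  xyz <- cbind(x = ab[, 1], y = ab[, 2],
               z = if (ncol(ab) >= 3) ab[, 3] else rep(0, n))
  if (is.null(bb) || nrow(bb) == 0L) {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
  }
  list(elem = elem, xyz = xyz, bonds = bonds, n = n)
}

# Minimal V2000 MOL block for an induced subgraph of a molecular graph.
# Used to hand a pruned scaffold back to OpenBabel for canonicalization.
# Formal charges are not rewritten: scaffolds are produced downstream of
# neutralization and compared at the constitution level.
molblock_subgraph <- function(graph, keep, title = "scaffold") {
  keep <- sort(unique(keep))
  idx <- match(seq_len(graph$n), keep) # old -> new numbering
  b <- graph$bonds
  sel <- !is.na(idx[b$a1]) & !is.na(idx[b$a2])
  b <- b[sel, , drop = FALSE]
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        graph$xyz[keep, 1], graph$xyz[keep, 2],
                        graph$xyz[keep, 3], graph$elem[keep])
  bond_lines <- if (nrow(b)) {
    sprintf("%3d%3d%3d  0", idx[b$a1], idx[b$a2], b$order)
  } else character(0)
  paste0(title, "\n  repurposekit\n\n",
         sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                 length(keep), nrow(b)), "\n",
         paste(c(atom_lines, bond_lines), collapse = "\n"),
         "\nM  END\n$$$$\n")
}

# Canonical SMILES of one or more MOL blocks (already ending in $$$$).
# Returns NA where conversion failed; aligned via embedded titles.
ob_canonical_from_molblocks <- function(molblocks) {
  if (length(molblocks) == 0L) return(character(0))
  tokens <- sprintf("rk%07d", seq_along(molblocks))
  tagged <- vapply(seq_along(molblocks), function(i)
    sub("^[^\n]*\n", paste0(tokens[i], "\n"), molblocks[i]), "")
  opts <- data.frame(names = "e", args = "")
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN",
                                               paste0(tagged, collapse = ""),
                                               options = opts)),
    error = function(e) "")
  res <- rep(NA_character_, length(molblocks))
  if (nzchar(out)) {
    lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    got_tok <- vapply(parts, function(p) if (length(p) >= 2L) trimws(p[2]) else NA_character_, "")
    got_smi <- vapply(parts, function(p) p[1], "")
    idx <- match(got_tok, tokens)
    ok <- !is.na(idx)
    res[idx[ok]] <- got_smi[ok]
  }
  res
}
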