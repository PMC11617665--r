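#' Bemis-Murcko chemotype extraction with exocyclic-group retention
#'
#' The chemotype (scaffold) of a molecule is obtained by deleting all side
#' chains while preserving bond orders, atom types and the connectors
#' (linkers) between ring systems. Atoms double-bonded to a ring or linker
#' atom -- carbonyl, thiocarbonyl, imine, sulfone/sulfoxide oxygens and any
#' other exocyclic double bond -- are considered part of the cyclic system
#' and retained together with their double bond (but not their own
#' substituents). Acyclic molecules have no scaffold.
#'
#' Concretely the kept atom set is: ring atoms (atoms on at least one
#' cycle), linker atoms (atoms surviving iterative removal of terminal
#' non-ring atoms, i.e. atoms on acyclic paths connecting ring atoms), and
#' atoms joined by a bond of order >= 2 to a kept ring/linker atom.
#' Scaffold keys are canonical SMILES of the pruned structure and compare at
#' the constitution level (no stereochemistry).
#'
#' @name scaffold
NULL

# Ring atoms = endpoints of edges that lie on a cycle (non-bridge edges).
ring_atom_mask <- function(graph) {
  mask <- rep(FALSE, graph$n)
  b <- graph$bonds
  if (nrow(b) == 0L) return(mask)
  g <- igraph::graph_from_edgelist(cbind(b$a1, b$a2), directed = FALSE)
  if (igraph::vcount(g) < graph$n)
    g <- igraph::add_vertices(g, graph$n - igraph::vcount(g))
  br <- igraph::bridges(g)
  cyc_edges <- setdiff(seq_len(nrow(b)), as.integer(br))
  if (length(cyc_edges)) {
    mask[b$a1[cyc_edges]] <- TRUE
    mask[b$a2[cyc_edges]] <- TRUE
  }
  mask
}

# Indices of atoms forming the scaffold, or NULL when the molecule is
# acyclic. See the algorithm summary in ?scaffold.
scaffold_atom_set <- function(graph) {
  ring <- ring_atom_mask(graph)
  if (!any(ring)) return(NULL)
  b <- graph$bonds
  adj <- vector("list", graph$n)
  for (k in seq_len(nrow(b))) {
    adj[[b$a1[k]]] <- c(adj[[b$a1[k]]], b$a2[k])
    adj[[b$a2[k]]] <- c(adj[[b$a2[k]]], b$a1[k])
  }
  alive <- rep(TRUE, graph$n)
  deg <- lengths(adj)
  repeat {
    term <- which(alive & !ring & deg <= 1L)
    if (length(term) == 0L) break
    alive[term] <- FALSE
    for (v in term) for (u in adj[[v]]) if (alive[u]) deg[u] <- deg[u] - 1L
  }
  framework <- which(alive) # rings plus linkers
  # exocyclic retention: partners of framework atoms across double/triple-
  # order bonds written as order 2 in kekulized input (C=O, C=S, C=N, S=O)
  exo <- b$order >= 2L &
    ((b$a1 %in% framework & !(b$a2 %in% framework)) |
     (b$a2 %in% framework & !(b$a1 %in% framework)))
  partners <- setdiff(unique(c(b$a1[exo], b$a2[exo])), framework)
  sort(c(framework, partners))
}

#' Extract the chemotype scaffold of a molecule
#'
#' @param mol a SMILES string, or a \code{ChemmineR} \code{SDF} object.
#' @return \code{NULL} for acyclic molecules; otherwise a list of class
#'   \code{murcko_scaffold} with elements \code{key} (canonical SMILES of
#'   the scaffold), \code{n_rings} (number of independent rings) and
#'   \code{n_atoms} (heavy atoms in the scaffold).
#' @examples
#' \dontrun{
#' extract_scaffold("Cc1ccccc1")$key  # toluene -> benzene
#' }
#' @export
extract_scaffold <- function(mol) {
  if (is.character(mol)) {
    stopifnot(length(mol) == 1L)
    sdf <- ob_smiles_to_sdf(mol)[[1]]
    if (is.null(sdf)) stop("unparsable structure: ", mol)
  } else if (methods::is(mol, "SDF")) {
    sdf <- mol
  } else stop("mol must be a SMILES string or a ChemmineR SDF object")
  graph <- mol_graph(sdf)
  keep <- scaffold_atom_set(graph)
  if (is.null(keep)) return(NULL)
  key <- ob_canonical_from_molblocks(molblock_subgraph(graph, keep))
  if (is.na(key)) stop("scaffold canonicalization failed")
  b <- graph$bonds
  nb <- sum(b$a1 %in% keep & b$a2 %in% keep)
  comp <- .n_components(keep, b)
  structure(list(key = key, n_rings = nb - length(keep) + comp,
                 n_atoms = length(keep)),
            class = "murcko_scaffold")
}

.n_components <- function(keep, bonds) {
  idx <- match(seq_len(max(keep)), keep)
  sel <- bonds$a1 %in% keep & bonds$a2 %in% keep
  g <- igraph::graph_from_edgelist(
    cbind(idx[bonds$a1[sel]], idx[bonds$a2[sel]]), directed = FALSE)
  if (igraph::vcount(g) < length(keep))
    g <- igraph::add_vertices(g, length(keep) - igraph::vcount(g))
  igraph::components(g)$no
}

# Batched scaffold keys for a vector of SMILES; one OpenBabel call for all
# cyclic molecules. Returns NA for acyclic or unparsable entries.
scaffold_keys <- function(smiles) {
  sdfs <- ob_smiles_to_sdf(smiles)
  blocks <- character(0)
  owner <- integer(0)
  keys <- rep(NA_character_, length(smiles))
  for (i in seq_along(sdfs)) {
    if (is.null(sdfs[[i]])) next
    graph <- mol_graph(sdfs[[i]])
    keep <- scaffold_atom_set(graph)
    if (is.null(keep)) next
    blocks <- c(blocks, molblock_subgraph(graph, keep))
    owner <- c(owner, i)
  }
  if (length(blocks)) keys[owner] <- ob_canonical_from_molblocks(blocks)
  keys
}

#' Classify a library into chemotypes
#'
#' @param lib a \code{curated_library}, or a data.frame with columns
#'   \code{id} and \code{smiles}.
#' @return A \code{chemotype_table}: list with \code{entries} (named list,
#'   scaffold key -> member compound ids), \code{n_chemotypes},
#'   \code{acyclic_ids} (compounds with no ring) and \code{key_by_id}
#'   (named character vector, id -> key).
#' @export
classify_chemotypes <- function(lib) {
  rec <- if (inherits(lib, "curated_library")) lib$records else lib
  if (is.null(rec$id) || is.null(rec$smiles))
    stop("need columns 'id' and 'smiles'")
  if (nrow(rec) == 0L) {
    return(structure(list(entries = list(), n_chemotypes = 0L,
                          acyclic_ids = character(0),
                          key_by_id = character(0)),
                     class = "chemotype_table"))
  }
  keys <- scaffold_keys(rec$smiles)
  failed <- is.na(keys) & is.na(ob_canonical_smiles(rec$smiles))
  if (any(failed))
    warning(sum(failed), " structures could not be parsed and were skipped")
  acyclic <- is.na(keys) & !failed
  entries <- split(rec$id[!is.na(keys)], keys[!is.na(keys)])
  # preserve first-appearance order of scaffold keys
  first <- order(vapply(entries, function(ids) match(ids[1], rec$id), 0L))
  entries <- entries[first]
  structure(list(entries = entries,
                 n_chemotypes = length(entries),
                 acyclic_ids = as.character(rec$id[acyclic]),
                 key_by_id = stats::setNames(keys, rec$id)),
            class = "chemotype_table")
}

#' @export
print.chemotype_table <- function(x, ...) {
  cat("Chemotype table:", x$n_chemotypes, "chemotypes,",
      length(x$key_by_id), "compounds,",
      length(x$acyclic_ids), "acyclic\n")
  if (x$n_chemotypes) {
    sizes <- lengths(x$entries)
    top <- utils::head(sort(sizes, decreasing = TRUE), 5L)
    cat("Largest chemotypes:\n")
    for (k in names(top)) cat("  ", k, ": ", top[[k]], " members\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.chemotype_table <- function(x, ...) {
  data.frame(scaffold_smiles = names(x$entries),
             n_members = lengths(x$entries),
             member_ids = vapply(x$entries, paste, "", collapse = ";"),
             row.names = NULL)
}

#' Select search compounds sharing a chemotype with a reference set
#'
#' Returns, in stable input order, the search-library compound ids whose
#' scaffold key occurs among the reference chemotypes. Acyclic compounds
#' are never selected.
#'
#' @param reference,search \code{chemotype_table}s built with identical
#'   scaffold settings.
#' @return Character vector of selected search compound ids.
#' @export
chemotype_overlap <- function(reference, search) {
  stopifnot(inherits(reference, "chemotype_table"),
            inherits(search, "chemotype_table"))
  keys <- search$key_by_id
  sel <- !is.na(keys) & keys %in% names(reference$entries)
  as.character(names(keys)[sel])
}
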