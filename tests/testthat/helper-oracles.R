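# Independent oracles used across the suite. These deliberately use
# different algorithms from the package implementation: brute-force
# connectivity checks and one-atom-per-pass deletion for scaffolds, and
# Horn's closed-form quaternion method for superposition RMSD.

# --- scaffold pruning oracle -------------------------------------------------

.bfs_connected <- function(n, edges, from, to) {
  # edges: data.frame a1,a2 (subset); plain queue BFS
  if (from == to) return(TRUE)
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    adj[[edges$a1[k]]] <- c(adj[[edges$a1[k]]], edges$a2[k])
    adj[[edges$a2[k]]] <- c(adj[[edges$a2[k]]], edges$a1[k])
  }
  seen <- rep(FALSE, n); seen[from] <- TRUE; queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (u in adj[[v]]) if (!seen[u]) {
      if (u == to) return(TRUE)
      seen[u] <- TRUE; queue <- c(queue, u)
    }
  }
  FALSE
}

# atoms on at least one cycle: an edge lies on a cycle iff its endpoints
# stay connected after removing that one edge
oracle_ring_atoms <- function(graph) {
  b <- graph$bonds
  ring <- logical(graph$n)
  for (k in seq_len(nrow(b))) {
    if (.bfs_connected(graph$n, b[-k, , drop = FALSE], b$a1[k], b$a2[k])) {
      ring[b$a1[k]] <- TRUE
      ring[b$a2[k]] <- TRUE
    }
  }
  which(ring)
}

# non-ring atom v is a linker iff some pair of ring atoms connected in the
# molecule becomes disconnected when v is deleted
oracle_linker_atoms <- function(graph, ring_atoms) {
  b <- graph$bonds
  linkers <- integer(0)
  for (v in setdiff(seq_len(graph$n), ring_atoms)) {
    sub <- b[b$a1 != v & b$a2 != v, , drop = FALSE]
    for (i in seq_along(ring_atoms)) {
      broke <- FALSE
      for (j in seq_len(i - 1L)) {
        r1 <- ring_atoms[i]; r2 <- ring_atoms[j]
        if (.bfs_connected(graph$n, b, r1, r2) &&
            !.bfs_connected(graph$n, sub, r1, r2)) {
          linkers <- c(linkers, v); broke <- TRUE; break
        }
      }
      if (broke) break
    }
  }
  linkers
}

# one eligible terminal atom deleted per pass, until none remains
oracle_scaffold_atoms <- function(graph) {
  ring <- oracle_ring_atoms(graph)
  if (length(ring) == 0L) return(NULL)
  protected <- c(ring, oracle_linker_atoms(graph, ring))
  b <- graph$bonds
  alive <- rep(TRUE, graph$n)
  repeat {
    deleted <- FALSE
    for (v in which(alive)) {
      inc <- which(alive[b$a1] & alive[b$a2] & (b$a1 == v | b$a2 == v))
      if (length(inc) != 1L) next            # not terminal
      if (v %in% protected) next             # ring or linker atom
      partner <- setdiff(c(b$a1[inc], b$a2[inc]), v)
      if (b$order[inc] >= 2L && partner %in% protected) next # retained exocyclic
      alive[v] <- FALSE
      deleted <- TRUE
      break
    }
    if (!deleted) break
  }
  which(alive)
}

# --- quaternion superposition oracle (Horn 1987) -----------------------------

oracle_superpose_rmsd <- function(P, Q) {
  P <- sweep(P, 2, colMeans(P))
  Q <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(P, Q)
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  K <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,     Szx-Sxz,     Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz, Sxy+Syx,     Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,    -Sxx+Syy-Szz, Syz+Szy,
    Sxy-Syx,     Szx+Sxz,     Syz+Szy,    -Sxx-Syy+Szz), 4, 4, byrow = TRUE)
  lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lmax) / nrow(P)
  sqrt(max(msd, 0))
}

# --- enumerated small-molecule set for scaffold equivalence ------------------

# >= 200 molecules of <= 12 heavy atoms: ring cores x side-chain decorations
oracle_molecule_set <- function() {
  cores <- c("c1ccccc1", "c1ccncc1", "C1CCCC1", "C1=CCCCC1", "c1ccoc1",
             "c1ccsc1", "c1cc[nH]c1", "C1CC1", "C1CC2CCC1C2", "C1CCNCC1",
             "c1cncnc1", "C1CCOC1", "C1=CC(=O)CC1")
  decs <- c("", "C", "CC", "CCC", "CCCC", "CC(C)", "OC", "OCC", "NC",
            "ClC", "O=C(C)", "N#C", "O=S(=O)(C)", "OC(=O)", "C=C", "CN(C)")
  as.vector(outer(decs, cores, paste0))
}
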