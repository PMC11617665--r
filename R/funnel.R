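#' Consensus docking-score funnel
#'
#' Arithmetic of a staged consensus virtual screen over externally produced
#' docking score tables: orientation-aware 0-1 normalization (best compound
#' maps to 1, worst to 0), quartile partition with best-quartile (Q1)
#' gating, multi-program consensus ranking by the mean of normalized
#' scores, and top-N hit listing.
#'
#' @name screening_funnel
NULL

.programs <- c(vina = "lower_is_better", autodock42 = "lower_is_better",
               gold = "higher_is_better")

#' Construct a docking score table
#'
#' @param ids compound identifiers.
#' @param scores numeric scores, same length (kcal/mol for vina/autodock42,
#'   dimensionless ChemPLP fitness for gold).
#' @param program \code{"vina"}, \code{"autodock42"} or \code{"gold"}.
#' @param orientation score direction; defaults to the program's convention
#'   (binding energies: lower is better; GOLD fitness: higher is better).
#' @return A \code{score_table} data.frame with columns \code{id},
#'   \code{score}.
#' @export
score_table <- function(ids, scores,
                        program = c("vina", "autodock42", "gold"),
                        orientation = NULL) {
  program <- match.arg(program)
  stopifnot(length(ids) == length(scores))
  if (anyDuplicated(ids)) stop("duplicate compound ids in score table")
  if (is.null(orientation)) orientation <- .programs[[program]]
  orientation <- match.arg(orientation, c("lower_is_better", "higher_is_better"))
  structure(data.frame(id = as.character(ids), score = as.numeric(scores)),
            program = program, orientation = orientation,
            class = c("score_table", "data.frame"))
}

#' Min-max normalize docking scores to [0, 1]
#'
#' Scores are oriented so that larger means better and then min-max scaled:
#' the best compound maps to 1, the worst to 0. For lower-is-better scores
#' (binding energies) this is \code{(max - s) / (max - min)}; for
#' higher-is-better, \code{(s - min) / (max - min)}.
#'
#' @param table a \code{score_table}.
#' @return Named numeric vector of normalized scores in [0, 1].
#' @export
normalize_scores <- function(table) {
  stopifnot(inherits(table, "score_table"))
  s <- table$score
  rng <- range(s)
  if (diff(rng) == 0) stop("degenerate score range: all scores identical")
  norm <- if (attr(table, "orientation") == "lower_is_better") {
    (rng[2] - s) / diff(rng)
  } else {
    (s - rng[1]) / diff(rng)
  }
  stats::setNames(norm, table$id)
}

#' Partition compounds into quartiles, best first
#'
#' Compounds are sorted best-first (ties broken by id) and the first
#' \code{floor(N/4)} form Q1; Q2 and Q3 take \code{floor(N/4)} each and Q4
#' the remainder. With N = 1075 this puts 268 compounds in Q1.
#'
#' @param scores named numeric vector (names are compound ids) or a
#'   \code{score_table}.
#' @param orientation score direction; taken from the table if one is given.
#' @return Named factor of labels \code{Q1}-\code{Q4}, in input order.
#' @export
quartile_partition <- function(scores,
                               orientation = c("lower_is_better",
                                               "higher_is_better")) {
  if (inherits(scores, "score_table")) {
    orientation <- attr(scores, "orientation")
    scores <- stats::setNames(scores$score, scores$id)
  } else {
    orientation <- match.arg(orientation)
  }
  n <- length(scores)
  if (n < 4L) stop("need at least 4 compounds to form quartiles")
  ids <- names(scores)
  ord <- if (orientation == "lower_is_better") {
    order(scores, ids)
  } else {
    order(-scores, ids)
  }
  k <- n %/% 4L
  lab <- rep(c("Q1", "Q2", "Q3", "Q4"), c(k, k, k, n - 3L * k))
  out <- factor(character(n), levels = c("Q1", "Q2", "Q3", "Q4"))
  out[ord] <- lab
  stats::setNames(out, ids)
}

#' Consensus ranking across docking programs
#'
#' Each table is min-max normalized over its own compound set, the tables
#' are intersected on compound ids (compounds missing from any table are
#' dropped with a warning), and the consensus score is the unweighted mean
#' of the per-program normalized scores. Rank 1 is the highest consensus;
#' ties are broken by the first program's normalized score, then by id.
#'
#' @param tables list of \code{score_table}s (typically vina, autodock42,
#'   gold).
#' @return A \code{consensus_ranking} data.frame, ordered by rank, with the
#'   per-program normalized scores, \code{consensus} and \code{rank}.
#' @export
consensus_rank <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1L,
            all(vapply(tables, inherits, TRUE, "score_table")))
  progs <- vapply(tables, attr, "", "program")
  if (anyDuplicated(progs)) stop("each program may appear only once")
  norms <- lapply(tables, normalize_scores)
  common <- Reduce(intersect, lapply(norms, names))
  if (length(common) == 0L) stop("no compounds shared by all score tables")
  n_all <- length(unique(unlist(lapply(norms, names))))
  if (length(common) < n_all)
    warning(n_all - length(common),
            " compounds missing from at least one table were dropped")
  mat <- vapply(norms, function(x) x[common], numeric(length(common)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  colnames(mat) <- progs
  consensus <- rowMeans(mat)
  ord <- order(-consensus, -mat[, 1L], common)
  out <- data.frame(id = common, mat, consensus = consensus,
                    row.names = NULL, check.names = FALSE)
  names(out)[1L + seq_along(progs)] <- paste0("norm_", progs)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("consensus_ranking", "data.frame"))
}

#' Top-N compounds of a consensus ranking
#'
#' @param ranking a \code{consensus_ranking}.
#' @param n number of hits to return (default 50).
#' @return Character vector of the first \code{n} compound ids by rank.
#' @export
select_top_n <- function(ranking, n = 50) {
  stopifnot(inherits(ranking, "consensus_ranking"))
  if (n > nrow(ranking)) stop("n exceeds the number of ranked compounds")
  ranking$id[seq_len(n)]
}
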