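## Graph construction: the medication co-occurrence matrix, the binary DDI
## matrix, their lambda-combined graph, and per-visit complete bipartite
## graphs between entity types. All adjacency matrices are dense base-R
## matrices (vocabularies here are small), symmetric with a zero diagonal.

#' Medication co-occurrence adjacency
#'
#' Counts, for every unordered medication pair, the number of visits in which
#' the two medications were prescribed together. Starts from a zero matrix;
#' each visit contributes 1 to every pair of its (distinct) medications.
#' The diagonal stays zero.
#'
#' @param med_history List of character vectors, one medication code set per
#'   visit (typically the visits before the prediction step).
#' @param vocab A `csrec_vocab`; all codes must be known.
#' @return Symmetric `n_med` x `n_med` integer matrix with zero diagonal,
#'   with medication codes as dimnames.
#' @export
build_cooccurrence <- function(med_history, vocab) {
  stopifnot(inherits(vocab, "csrec_vocab"))
  n <- vocab$n_med
  A <- matrix(0, n, n, dimnames = list(vocab$med, vocab$med))
  for (meds in med_history) {
    idx <- match(unique(meds), vocab$med)
    if (anyNA(idx)) stop("unknown medication code: ",
                         paste(unique(meds)[is.na(idx)], collapse = ", "))
    if (length(idx) >= 2L) {
      pairs <- utils::combn(idx, 2L)
      for (k in seq_len(ncol(pairs))) {
        i <- pairs[1L, k]; j <- pairs[2L, k]
        A[i, j] <- A[i, j] + 1
        A[j, i] <- A[j, i] + 1
      }
    }
  }
  A
}

#' Binary drug-drug interaction adjacency
#'
#' Marks each supplied contraindicated pair with a symmetric 1. Pairs naming a
#' code outside the vocabulary are skipped with a warning (the DDI list is
#' usually broader than the cohort's medication vocabulary); self-pairs are
#' rejected with a warning. Duplicate pairs collapse to a single 1.
#'
#' @param pairs Two-column character matrix or data frame of medication code
#'   pairs, or a list of length-2 character vectors.
#' @param vocab A `csrec_vocab`.
#' @return Symmetric `n_med` x `n_med` 0/1 matrix with zero diagonal.
#' @export
build_ddi_matrix <- function(pairs, vocab) {
  stopifnot(inherits(vocab, "csrec_vocab"))
  n <- vocab$n_med
  A <- matrix(0, n, n, dimnames = list(vocab$med, vocab$med))
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs)
  if (is.matrix(pairs)) pairs <- split(pairs, row(pairs))
  for (p in pairs) {
    p <- as.character(p)
    i <- match(p[1L], vocab$med); j <- match(p[2L], vocab$med)
    if (is.na(i) || is.na(j)) {
      warning("DDI pair (", p[1L], ", ", p[2L],
              ") references unknown code; skipped", call. = FALSE)
      next
    }
    if (i == j) {
      warning("DDI self-pair (", p[1L], ") rejected", call. = FALSE)
      next
    }
    A[i, j] <- 1; A[j, i] <- 1
  }
  A
}

#' Read / write drug-drug interaction pairs as CSV
#'
#' Two-column UTF-8 CSV with header `code_a,code_b`.
#'
#' @param path CSV file path.
#' @return `read_ddi_csv`: a two-column character matrix of pairs.
#' @export
read_ddi_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  if (ncol(df) < 2L) stop("DDI CSV must have two columns (code_a,code_b)")
  as.matrix(df[, 1:2])
}

#' @rdname read_ddi_csv
#' @param pairs Two-column character matrix of medication code pairs.
#' @export
write_ddi_csv <- function(pairs, path) {
  df <- as.data.frame(pairs)
  names(df) <- c("code_a", "code_b")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Combine co-occurrence and DDI graphs into the medication graph
#'
#' Entrywise `A_mm - lambda * A_ddi`, with negative results clipped to zero.
#' The strictly positive entries define the edge set of the medication graph
#' consumed by the attention layer; clipping removes edges whose co-occurrence
#' support is outweighed by the interaction penalty (negative edge weights are
#' undefined in the attention layer that consumes the graph).
#'
#' @param a_mm Symmetric non-negative co-occurrence matrix.
#' @param a_ddi Symmetric 0/1 interaction matrix of the same size.
#' @param lambda Non-negative interaction penalty weight.
#' @return A list of class `csrec_medgraph` with `weights` (clipped matrix)
#'   and `lambda`.
#' @export
combine_medication_graph <- function(a_mm, a_ddi, lambda = 1) {
  if (!all(dim(a_mm) == dim(a_ddi)))
    stop("dimension mismatch: a_mm is ", nrow(a_mm), "x", ncol(a_mm),
         ", a_ddi is ", nrow(a_ddi), "x", ncol(a_ddi))
  stopifnot(lambda >= 0)
  w <- pmax(a_mm - lambda * a_ddi, 0)
  structure(list(weights = w, lambda = lambda), class = "csrec_medgraph")
}

#' Per-visit complete bipartite graph between two entity types
#'
#' Edges are the full cartesian product of the active code indices on the two
#' sides: `dp` pairs the visit's diagnoses with its procedures; `md` and `mp`
#' pair the medication history side with the visit's diagnoses or procedures.
#' For `md`/`mp` the caller supplies the previous visit's medication vector in
#' `visit$v_m` (the current visit's medications are the prediction target, not
#' an input). Either side empty gives an empty edge set.
#'
#' @param visit A `csrec_multihot` triple (for `md`/`mp`, with `v_m` holding
#'   the previous visit's medications).
#' @param pair One of `"dp"`, `"md"`, `"mp"`.
#' @return A list of class `csrec_bipartite` with `pair`, `left`, `right`
#'   (active 1-based index vectors) and `edges`, a 2-column integer matrix.
#' @export
build_visit_bipartite <- function(visit, pair = c("dp", "md", "mp")) {
  pair <- match.arg(pair)
  sides <- switch(pair,
                  dp = list(visit$v_d, visit$v_p),
                  md = list(visit$v_m, visit$v_d),
                  mp = list(visit$v_m, visit$v_p))
  left <- which(sides[[1L]] != 0L)
  right <- which(sides[[2L]] != 0L)
  edges <- if (length(left) && length(right))
    cbind(rep(left, each = length(right)), rep(right, times = length(left)))
  else matrix(integer(), 0L, 2L)
  structure(list(pair = pair, left = left, right = right, edges = edges),
            class = "csrec_bipartite")
}

#' Export an adjacency matrix as MatrixMarket sparse text
#'
#' Debugging helper; requires the `Matrix` package.
#'
#' @param a Adjacency matrix.
#' @param path Output path.
#' @export
export_adjacency <- function(a, path) {
  if (!requireNamespace("Matrix", quietly = TRUE))
    stop("export_adjacency requires the Matrix package")
  Matrix::writeMM(Matrix::Matrix(a, sparse = TRUE), path)
  invisible(path)
}
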