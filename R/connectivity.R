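#' Validate a connectivity matrix
#'
#' Checks the structural invariants every subject-level connectome must
#' satisfy before any downstream computation: a square numeric matrix,
#' exactly symmetric (streamline counts are integers, so symmetry is tested
#' with exact equality), zero diagonal, and no negative entries. Node
#' identity is carried by `dimnames`; unlabeled matrices are given
#' `"R001"`-style labels.
#'
#' @param weights Square numeric matrix of nonnegative streamline counts.
#' @param node_labels Optional character vector of region labels; defaults to
#'   existing row names, then to zero-padded `"R###"` labels.
#' @returns The validated matrix with row and column names set, invisibly
#'   usable anywhere a connectivity matrix is expected.
#' @export
as_connectivity_matrix <- function(weights, node_labels = NULL) {
  if (!is.matrix(weights) || !is.numeric(weights)) {
    rlang::abort("`weights` must be a numeric matrix.")
  }
  n <- nrow(weights)
  if (ncol(weights) != n) {
    rlang::abort(sprintf("matrix must be square, got %d x %d.", n, ncol(weights)))
  }
  if (is.null(node_labels)) {
    node_labels <- rownames(weights) %||% sprintf("R%03d", seq_len(n))
  }
  if (length(node_labels) != n) {
    rlang::abort(sprintf(
      "%d node labels supplied for a %d-node matrix.", length(node_labels), n
    ))
  }
  neg <- which(weights < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    rlang::abort(sprintf(
      "negative weight at [%d, %d]: %g.", neg[1, 1], neg[1, 2], weights[neg[1, , drop = FALSE]]
    ))
  }
  asym <- which(weights != t(weights), arr.ind = TRUE)
  if (nrow(asym) > 0) {
    i <- asym[1, 1]; j <- asym[1, 2]
    rlang::abort(sprintf(
      "matrix is not symmetric: [%d, %d] = %g but [%d, %d] = %g.",
      i, j, weights[i, j], j, i, weights[j, i]
    ))
  }
  if (any(diag(weights) != 0)) {
    i <- which(diag(weights) != 0)[1]
    rlang::abort(sprintf("diagonal must be zero; node %d has self-weight %g.", i, diag(weights)[i]))
  }
  dimnames(weights) <- list(node_labels, node_labels)
  weights
}

#' Remove spurious edges below a streamline-count floor
#'
#' Edges supported by fewer than `min_streamlines` streamlines are treated as
#' tractography noise and removed (set to zero); surviving edges keep their
#' raw counts, since class-wise connectivity strength is defined on them. The
#' comparison is inclusive: a count equal to the floor is retained. The
#' default floor of 3 is the conventional existence rule for
#' deterministic-tractography connectomes.
#'
#' @param weights Connectivity matrix (validated on entry).
#' @param min_streamlines Minimum count for an edge to exist; integer >= 1.
#' @returns The thresholded matrix. Idempotent: a second application at the
#'   same floor changes nothing.
#' @examples
#' m <- matrix(0, 3, 3)
#' m[1, 2] <- m[2, 1] <- 2
#' m[1, 3] <- m[3, 1] <- 3
#' threshold_matrix(m, 3) # the count-2 edge is gone, the count-3 edge stays
#' @export
threshold_matrix <- function(weights, min_streamlines = 3) {
  weights <- as_connectivity_matrix(weights)
  if (length(min_streamlines) != 1 || is.na(min_streamlines) || min_streamlines < 1) {
    rlang::abort("`min_streamlines` must be a single value >= 1.")
  }
  weights[weights < min_streamlines] <- 0
  weights
}

#' Binary node degree
#'
#' Degree of a node is the number of edges attached to it: nonzero
#' off-diagonal entries in its row. Weights are ignored — this is the degree
#' the rich-club coefficient and hub definition are built on.
#'
#' @param net Connectivity or binary adjacency matrix.
#' @returns Named integer vector of length N.
#' @export
node_degree <- function(net) {
  net <- as_connectivity_matrix(net)
  deg <- as.integer(rowSums(net != 0))
  names(deg) <- rownames(net)
  deg
}

#' Binarize a weighted network
#'
#' @param weights Connectivity matrix.
#' @returns 0/1 adjacency matrix with the same labels.
#' @export
binarize <- function(weights) {
  weights <- as_connectivity_matrix(weights)
  adj <- (weights != 0) * 1
  dimnames(adj) <- dimnames(weights)
  adj
}

#' Group-averaged binary network by edge prevalence
#'
#' An edge is kept when it is present (nonzero) in at least a `prevalence`
#' fraction of the group's subjects; the comparison is inclusive, so with 5
#' subjects and prevalence 0.60 an edge seen in exactly 3 is kept. The
#' default 0.60 is the conventional prevalence rule for defining a group
#' backbone on which hubs are identified.
#'
#' @param mats List of subject connectivity matrices over identical node
#'   labels (order included).
#' @param prevalence Fraction in (0, 1].
#' @returns Binary adjacency matrix with attribute `prevalence`.
#' @export
group_average_network <- function(mats, prevalence = 0.6) {
  if (length(mats) < 1) rlang::abort("need at least one matrix.")
  if (length(prevalence) != 1 || prevalence <= 0 || prevalence > 1) {
    rlang::abort("`prevalence` must be a single fraction in (0, 1].")
  }
  mats <- lapply(mats, as_connectivity_matrix)
  ref <- rownames(mats[[1]])
  for (s in seq_along(mats)) {
    lab <- rownames(mats[[s]])
    if (!identical(lab, ref)) {
      bad <- which(lab != ref)[1]
      rlang::abort(sprintf(
        "node labels of matrix %d differ from matrix 1 (first mismatch at position %d: '%s' vs '%s').",
        s, bad, lab[bad], ref[bad]
      ))
    }
  }
  count <- Reduce(`+`, lapply(mats, function(m) m != 0))
  adj <- (count / length(mats) >= prevalence) * 1
  dimnames(adj) <- list(ref, ref)
  attr(adj, "prevalence") <- prevalence
  adj
}
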