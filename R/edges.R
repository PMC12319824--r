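#' Edge indexing for undirected connectomes
#'
#' Every module in the package shares one fixed bijection between the
#' \code{E = N(N-1)/2} undirected region pairs of an \code{N}-region
#' parcellation and edge indices \code{1..E}: the upper triangle of the
#' \code{N x N} matrix, traversed row-major, diagonal excluded. Edge
#' \code{k} corresponds to the pair \code{(i, j)} with \code{i < j},
#' pairs ordered first by \code{i}, then by \code{j}. Model files record
#' this convention as the string \code{"upper-triangle-row-major"}.
#'
#' @param n_regions number of regions in the parcellation (>= 2).
#' @return \code{n_edges}: the edge count \code{N(N-1)/2}.
#' @examples
#' n_edges(268)       # 35778 features for a 268-node atlas
#' edge_pairs(4)      # (1,2) (1,3) (1,4) (2,3) (2,4) (3,4)
#' @export
n_edges <- function(n_regions) {
  stopifnot(is.numeric(n_regions), length(n_regions) == 1L, n_regions >= 2)
  as.integer(n_regions * (n_regions - 1) / 2)
}

#' @rdname n_edges
#' @return \code{edge_pairs}: an \code{E x 2} integer matrix with columns
#'   \code{i}, \code{j} (1-based region indices, \code{i < j}) in edge order.
#' @export
edge_pairs <- function(n_regions) {
  stopifnot(n_regions >= 2)
  n <- as.integer(n_regions)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  cbind(i = i, j = j)
}

#' @rdname n_edges
#' @param i,j region indices with \code{i < j} (vectors allowed).
#' @return \code{edge_index}: the edge index \code{k} of pair \code{(i, j)}.
#' @export
edge_index <- function(i, j, n_regions) {
  stopifnot(all(i >= 1), all(j <= n_regions), all(i < j))
  as.integer((i - 1) * n_regions - i * (i - 1) / 2 + (j - i))
}

# Vectorize a symmetric matrix into edge order; inverse of edge_matrix().
vectorize_edges <- function(mat) {
  n <- nrow(mat)
  stopifnot(ncol(mat) == n)
  mat[edge_pairs(n)]
}

# Rebuild a symmetric N x N matrix (diagonal `diag_value`) from an edge vector.
edge_matrix <- function(edges, n_regions, diag_value = 0) {
  stopifnot(length(edges) == n_edges(n_regions))
  m <- matrix(diag_value, n_regions, n_regions)
  p <- edge_pairs(n_regions)
  m[p] <- edges
  m[p[, c(2, 1)]] <- edges
  m
}

edge_convention <- function() "upper-triangle-row-major"
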