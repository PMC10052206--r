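# Scalar complexity and its bounds: C = f(S o E) with f the spectral matrix
# norm (largest singular value), plus per-variable profiles and the
# dependency map.

spectral_norm <- function(A) {
  if (length(A) == 1) return(abs(A[1]))
  max(svd(A, nu = 0, nv = 0)$d)
}

as_matrix_pair_input <- function(mp) {
  if (inherits(mp, "qct_matrix_pair")) return(mp)
  .check(is.list(mp) && !is.null(mp$S) && !is.null(mp$E),
         "mp must be a qct_matrix_pair or a list with S and E")
  mp
}

check_sym <- function(A, name) {
  .check(is.matrix(A) && nrow(A) == ncol(A), paste(name, "must be square"))
  .check(all(is.finite(A)), paste(name, "contains non-finite values"))
  .check(max(abs(A - t(A))) <= 1e-9, paste(name, "must be symmetric"))
}

#' System complexity of one window
#'
#' `C = f(S o E)`: the spectral norm (largest singular value) of the Hadamard
#' product of the structure matrix `S` and the entropy matrix `E`, in bits.
#' For the symmetric, entrywise non-negative matrices produced by
#' [build_matrices()] this equals the largest eigenvalue, so `C` grows both
#' with the density of the dependency network and with the disorder carried
#' on its links.
#'
#' @param mp A `qct_matrix_pair`, or any list with symmetric numeric `S`, `E`.
#' @return Complexity in bits.
#' @export
#' @examples
#' complexity(list(S = diag(3), E = diag(c(1, 2, 3))))  # 3
complexity <- function(mp) {
  mp <- as_matrix_pair_input(mp)
  check_sym(mp$S, "S"); check_sym(mp$E, "E")
  spectral_norm(mp$S * mp$E)
}

#' Lower and upper complexity bounds
#'
#' The complexity statistic is bounded: on a given dependency topology `S`,
#' the smallest value is reached when every link carries perfectly dependent
#' (structure-dominated) variables and the largest when every link is at
#' maximal disorder. For matrices estimated from data the entropy-extremal
#' matrices are recorded by [build_matrices()] on the same rows and mesh
#' (joint entropy of a structured pair is bracketed by its larger marginal
#' and its marginal sum), which guarantees `C_min <= C <= C_critical` on
#' every window. For a bare topology, supply the mesh side `b` and the
#' idealized rank-grid entropies are used: all connected entries at
#' `log2(b)` for the lower bound; diagonal `log2(b)` and connected
#' off-diagonal entries `2 * log2(b)` for the upper bound.
#'
#' @param mp A `qct_matrix_pair` (uses its `Emin`/`Emax`), or a list with at
#'   least `S` when `b` is given.
#' @param b Pixels per side of the idealized mesh (only used when `mp`
#'   carries no `Emin`/`Emax`).
#' @return Named numeric vector `c(c_min, c_critical)` in bits.
#' @export
#' @examples
#' complexity_bounds(list(S = matrix(1, 2, 2)), b = 4)  # c(4, 6)
complexity_bounds <- function(mp, b = NULL) {
  mp <- as_matrix_pair_input2(mp, b)
  check_sym(mp$S, "S")
  if (!is.null(mp$Emin) && !is.null(mp$Emax)) {
    emin <- mp$Emin; emax <- mp$Emax
  } else {
    .check(!is.null(b) && b >= 2, "supply b >= 2 when mp has no Emin/Emax")
    h <- log2(b)
    emin <- matrix(h, nrow(mp$S), ncol(mp$S))
    emax <- matrix(2 * h, nrow(mp$S), ncol(mp$S))
    diag(emax) <- h
  }
  c(c_min = spectral_norm(mp$S * emin),
    c_critical = spectral_norm(mp$S * emax))
}

as_matrix_pair_input2 <- function(mp, b) {
  if (inherits(mp, "qct_matrix_pair")) return(mp)
  .check(is.list(mp) && !is.null(mp$S), "mp must carry at least S")
  mp
}

#' Per-variable complexity profile
#'
#' Contribution of each state-vector component to the total complexity,
#' expressed in percentages. The default (`method = "leave_one_out"`) scores
#' variable `k` by how much the complexity drops when its row and column are
#' removed from `S o E`, clipped at zero and renormalized to sum to 100.
#' `method = "eigenvector"` instead uses the squared loadings of the leading
#' eigenvector, provided as a sensitivity alternative.
#'
#' @param mp A `qct_matrix_pair` (or list with `S`, `E`).
#' @param method `"leave_one_out"` (default) or `"eigenvector"`.
#' @return Named numeric vector of percentages summing to 100.
#' @export
complexity_profile <- function(mp, method = c("leave_one_out", "eigenvector")) {
  method <- match.arg(method)
  mp <- as_matrix_pair_input(mp)
  check_sym(mp$S, "S"); check_sym(mp$E, "E")
  A <- mp$S * mp$E
  N <- ncol(A)
  vars <- colnames(A)
  if (is.null(vars)) vars <- paste0("V", seq_len(N))
  if (N == 1) return(setNames(100, vars))
  if (method == "leave_one_out") {
    C <- spectral_norm(A)
    raw <- vapply(seq_len(N), function(k) {
      max(0, C - spectral_norm(A[-k, -k, drop = FALSE]))
    }, numeric(1))
  } else {
    es <- eigen(A, symmetric = TRUE)
    lead <- which.max(abs(es$values))
    raw <- es$vectors[, lead]^2
  }
  if (sum(raw) <= 0) raw <- rep(1, N)
  setNames(100 * raw / sum(raw), vars)
}

#' Complexity map of a window
#'
#' The dependency network at one time step: one node per state-vector
#' variable, one undirected edge per structured pair, weighted by the pair's
#' joint entropy (with its mutual information attached).
#'
#' @param mp A `qct_matrix_pair`.
#' @return An object of class `qct_map`: list with `nodes` (character) and
#'   `edges` (data frame `from`, `to`, `weight`, `mi`).
#' @export
complexity_map <- function(mp) {
  mp <- as_matrix_pair_input(mp)
  check_sym(mp$S, "S")
  N <- ncol(mp$S)
  vars <- colnames(mp$S)
  if (is.null(vars)) vars <- paste0("V", seq_len(N))
  idx <- which(upper.tri(mp$S) & mp$S == 1, arr.ind = TRUE)
  edges <- data.frame(
    from = vars[idx[, 1]],
    to = vars[idx[, 2]],
    weight = if (nrow(idx)) mp$E[idx] else numeric(0),
    mi = if (!is.null(mp$mi) && nrow(idx)) mp$mi[idx] else rep(NA_real_, nrow(idx)),
    stringsAsFactors = FALSE)
  structure(list(nodes = vars, edges = edges), class = "qct_map")
}

#' @export
print.qct_map <- function(x, ...) {
  cat(sprintf("Complexity map: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) {
    top <- x$edges[order(-x$edges$weight), , drop = FALSE]
    print(utils::head(top, 10), row.names = FALSE)
  }
  invisible(x)
}

#' Convert a complexity map to an igraph graph
#'
#' @param map A `qct_map`.
#' @return An undirected `igraph` graph with edge attributes `weight`, `mi`.
#' @export
map_to_igraph <- function(map) {
  .check(inherits(map, "qct_map"), "map must be a qct_map")
  igraph::graph_from_data_frame(map$edges, directed = FALSE,
                                vertices = data.frame(name = map$nodes))
}

#' Export a complexity map
#'
#' `write_map_json()` writes the node/edge list as JSON;
#' `write_map_graphml()` writes GraphML (via igraph).
#'
#' @param map A `qct_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_map_json <- function(map, path) {
  .check(inherits(map, "qct_map"), "map must be a qct_map")
  jsonlite::write_json(list(nodes = map$nodes, edges = map$edges),
                       path, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_map_json
#' @export
write_map_graphml <- function(map, path) {
  igraph::write_graph(map_to_igraph(map), path, format = "graphml")
  invisible(path)
}
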