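# Generalized-correlation detection: mutual information of the rank-binned
# pixel image, tested against a permutation-surrogate null, and assembly of
# the window-level structure (S) and entropy (E) matrices.

# marginal/joint entropies and MI (bits) from bin assignments
mi_from_bins <- function(bx, by, b) {
  n <- length(bx)
  hx <- entropy_counts(tabulate(bx, nbins = b), n)
  hy <- entropy_counts(tabulate(by, nbins = b), n)
  hxy <- entropy_counts(tabulate((bx - 1L) * b + by, nbins = b * b), n)
  list(hx = hx, hy = hy, hxy = hxy, mi = hx + hy - hxy)
}

# TRUE when `a` precedes `b` in lexicographic order (strictly)
lex_less <- function(a, b) {
  d <- a - b
  i <- which(d != 0)
  length(i) > 0 && d[i[1]] < 0
}

is_degenerate <- function(x) {
  x <- x[!is.na(x)]
  length(x) == 0 || all(x == x[1])
}

#' Test two variables for generalized correlation
#'
#' Pixelates the pair's scatter plot on the rank grid, computes the mutual
#' information `MI = H(x) + H(y) - H(x, y)` of the image, and compares it with
#' the MI of `n_surrogates` independent row permutations of one variable
#' (which destroy any dependence while preserving both margins). The pair is
#' declared structured when the exact permutation p-value
#' `(1 + #{MI_surr >= MI}) / (n_surrogates + 1)` is at most `alpha`.
#'
#' The surrogate stream is a deterministic function of `rng_seed` and of a
#' canonical ordering of the two bin vectors, so that
#' `pair_dependency(x, y)` and `pair_dependency(y, x)` are bit-identical and
#' R's global random-number state is never touched.
#'
#' @param x,y Numeric vectors of equal length; incomplete pairs are dropped.
#' @param alpha Significance level of the surrogate test (default 0.05).
#' @param n_surrogates Number of permutation surrogates (default 200).
#' @param rng_seed Integer seed for the surrogate stream.
#' @param window_index,pair_index Integers mixed into the surrogate seed so
#'   that every (window, pair) in a sliding analysis has its own stream.
#' @return An object of class `qct_dependency`: `h_i`, `h_j`, `h_ij`, `mi`
#'   (bits), `p_value`, `null_quantile` (the critical surrogate order
#'   statistic), `structured`, `n_valid` and `b`.
#' @export
#' @examples
#' d <- pair_dependency(1:100, (1:100)^2, rng_seed = 1)
#' d$mi          # log2(10): a pure-diagonal image
#' d$structured
pair_dependency <- function(x, y, alpha = 0.05, n_surrogates = 200,
                            rng_seed = 1, window_index = 0, pair_index = 0) {
  .check(length(x) == length(y), "x and y must have equal length")
  .check(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  .check(n_surrogates >= 1, "n_surrogates must be >= 1")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  .check(n >= 4, "insufficient samples: need >= 4 pairwise-complete pairs")

  dx <- is_degenerate(x); dy <- is_degenerate(y)
  b <- mesh_side(n)
  if (dx || dy) {
    # a constant axis carries no information: zero entropy, never structured
    hx <- if (dx) 0 else entropy_counts(tabulate(rank_bins(x, b), b), n)
    hy <- if (dy) 0 else entropy_counts(tabulate(rank_bins(y, b), b), n)
    return(structure(list(h_i = hx, h_j = hy, h_ij = max(hx, hy), mi = 0,
                          p_value = 1, null_quantile = NA_real_,
                          structured = FALSE, n_valid = n, b = b),
                     class = "qct_dependency"))
  }

  bx <- rank_bins(x, b)
  by <- rank_bins(y, b)
  ent <- mi_from_bins(bx, by, b)

  # canonical orientation: always permute the lexicographically larger margin
  if (lex_less(by, bx)) {
    surr <- .surrogate_mi(by, bx, b, n_surrogates, ent$hy, ent$hx,
                          rng_seed, window_index, pair_index)
  } else {
    surr <- .surrogate_mi(bx, by, b, n_surrogates, ent$hx, ent$hy,
                          rng_seed, window_index, pair_index)
  }
  p <- (1 + sum(surr >= ent$mi - 1e-12)) / (n_surrogates + 1)
  m <- max(1L, floor(alpha * (n_surrogates + 1)))
  thr <- sort(surr, decreasing = TRUE)[m]
  structure(list(h_i = ent$hx, h_j = ent$hy, h_ij = ent$hxy, mi = ent$mi,
                 p_value = p, null_quantile = thr,
                 structured = p <= alpha, n_valid = n, b = b),
            class = "qct_dependency")
}

#' @export
print.qct_dependency <- function(x, ...) {
  cat(sprintf("Pair dependency: MI %.4f bits (H_i %.3f, H_j %.3f, H_ij %.3f), p = %.4f -> %s\n",
              x$mi, x$h_i, x$h_j, x$h_ij, x$p_value,
              if (x$structured) "structured" else "chaotic"))
  invisible(x)
}

#' Pairwise-complete row policy for a window with gaps
#'
#' Returns, for each unordered variable pair, the number of pairwise-complete
#' rows in the window and whether the pair must be forced unstructured
#' because fewer than `min_valid_fraction` of the window's rows survive
#' deletion. The policy never aborts a window.
#'
#' @param mask Logical `M x N` matrix, `TRUE` marking missing cells.
#' @param min_valid_fraction Minimum fraction of rows a pair needs (default 0.5).
#' @return List with `n_valid` (N x N matrix of pairwise-complete counts) and
#'   `forced` (logical N x N matrix, `TRUE` where the pair is forced
#'   unstructured).
#' @export
gap_policy <- function(mask, min_valid_fraction = 0.5) {
  .check(is.matrix(mask) && is.logical(mask), "mask must be a logical matrix")
  .check(min_valid_fraction >= 0 && min_valid_fraction <= 1,
         "min_valid_fraction must be in [0, 1]")
  ok <- !mask
  n_valid <- crossprod(ok)                     # pairwise-complete counts
  min_rows <- max(4, ceiling(min_valid_fraction * nrow(mask)))
  forced <- n_valid < min_rows
  storage.mode(n_valid) <- "integer"
  list(n_valid = n_valid, forced = forced, min_rows = min_rows)
}

#' Build the structure and entropy matrices for one data window
#'
#' Runs the generalized-correlation test on every unordered variable pair of
#' an `M x N` window (pairwise-complete rows only) and assembles the
#' symmetric adjacency matrix `S` (1 = structured, unit diagonal) and entropy
#' matrix `E` (diagonal: marginal entropies; off-diagonal: joint entropy of
#' the pair where structured, 0 elsewhere). Also records the entropy-extremal
#' matrices `Emin`/`Emax` used for the complexity bounds: on the same rows and
#' mesh, a structured pair's joint entropy can be no smaller than the larger
#' marginal (perfect dependence) and no larger than the marginal sum
#' (independence).
#'
#' Variables with fewer than 4 valid rows are dropped for the window (zero
#' diagonal entropy, all pairs unstructured); pairs below the gap-policy
#' minimum are forced unstructured. Both are reported in the returned object.
#'
#' @param data Numeric `M x N` matrix (or `qct_state_matrix`).
#' @param mask Optional logical missingness matrix (defaults to `is.na(data)`).
#' @param alpha,n_surrogates Surrogate-test parameters.
#' @param min_valid_fraction Gap-policy threshold, see [gap_policy()].
#' @param seed Integer seed; each pair's surrogate stream is derived from
#'   `(seed, window_index, pair index)`.
#' @param window_index Index mixed into the surrogate seeds.
#' @return An object of class `qct_matrix_pair`: `S`, `E`, `Emin`, `Emax`,
#'   `mi` (full MI matrix), `n_valid`, `b` (window mesh side), `variables`,
#'   `dropped`, `forced_pairs`.
#' @export
build_matrices <- function(data, mask = NULL, alpha = 0.05, n_surrogates = 200,
                           min_valid_fraction = 0.5, seed = 1, window_index = 0) {
  if (inherits(data, "qct_state_matrix")) {
    mask <- data$mask
    data <- data$data
  }
  .check(is.matrix(data) && is.numeric(data), "data must be a numeric matrix")
  if (is.null(mask)) mask <- is.na(data)
  N <- ncol(data)
  .check(N >= 2, "need at least 2 variables")
  vars <- colnames(data)
  if (is.null(vars)) vars <- paste0("V", seq_len(N))
  M <- nrow(data)
  data[mask] <- NA_real_

  gp <- gap_policy(mask, min_valid_fraction)

  S <- diag(1, N)
  E <- Emin <- Emax <- MI <- matrix(0, N, N)
  dimnames(S) <- dimnames(E) <- dimnames(Emin) <- dimnames(Emax) <-
    dimnames(MI) <- list(vars, vars)

  # per-variable marginal entropies on each variable's own valid rows
  dropped <- character(0)
  hdiag <- numeric(N)
  for (i in seq_len(N)) {
    xi <- data[!mask[, i], i]
    if (length(xi) < 4 || is_degenerate(xi)) {
      hdiag[i] <- 0
      if (length(xi) < 4) dropped <- c(dropped, vars[i])
    } else {
      bi <- mesh_side(length(xi))
      hdiag[i] <- entropy_counts(tabulate(rank_bins(xi, bi), bi), length(xi))
    }
  }
  diag(E) <- diag(Emin) <- diag(Emax) <- hdiag

  forced_pairs <- character(0)
  pair_index <- 0L
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      pair_index <- pair_index + 1L
      if (vars[i] %in% dropped || vars[j] %in% dropped) next
      if (gp$forced[i, j]) {
        forced_pairs <- c(forced_pairs, paste(vars[i], vars[j], sep = "-"))
        next
      }
      dep <- pair_dependency(data[, i], data[, j], alpha = alpha,
                             n_surrogates = n_surrogates, rng_seed = seed,
                             window_index = window_index,
                             pair_index = pair_index)
      MI[i, j] <- MI[j, i] <- dep$mi
      if (dep$structured) {
        S[i, j] <- S[j, i] <- 1
        E[i, j] <- E[j, i] <- dep$h_ij
        Emin[i, j] <- Emin[j, i] <- max(dep$h_i, dep$h_j)
        Emax[i, j] <- Emax[j, i] <- dep$h_i + dep$h_j
      }
    }
  }
  structure(list(S = S, E = E, Emin = Emin, Emax = Emax, mi = MI,
                 n_valid = gp$n_valid, b = if (M >= 4) mesh_side(M) else NA_integer_,
                 variables = vars, dropped = dropped,
                 forced_pairs = forced_pairs),
            class = "qct_matrix_pair")
}

#' @export
print.qct_matrix_pair <- function(x, ...) {
  n_edges <- (sum(x$S) - ncol(x$S)) / 2
  cat(sprintf("Matrix pair: %d variables, %d structured pair(s), mesh side %s\n",
              ncol(x$S), n_edges, x$b))
  if (length(x$dropped)) cat("  dropped:", paste(x$dropped, collapse = ", "), "\n")
  if (length(x$forced_pairs))
    cat("  forced unstructured:", paste(x$forced_pairs, collapse = ", "), "\n")
  invisible(x)
}

#' Dump a window's matrices to JSON
#'
#' Writes the structure matrix, entropy matrix, per-pair mutual information
#' and variable names of one window as a JSON diagnostic record.
#'
#' @param mp A `qct_matrix_pair` from [build_matrices()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_pair_json <- function(mp, path) {
  .check(inherits(mp, "qct_matrix_pair"), "mp must be a qct_matrix_pair")
  jsonlite::write_json(
    list(variables = mp$variables, S = mp$S, E = mp$E, mi = mp$mi,
         b = mp$b, dropped = mp$dropped, forced_pairs = mp$forced_pairs),
    path, digits = NA, auto_unbox = FALSE, matrix = "rowmajor")
  invisible(path)
}
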