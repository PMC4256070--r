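#' @title Gaussian and anisotropic elastic network models
#'
#' @description
#' The structure is reduced to Calpha nodes connected by Hookean springs of
#' uniform force constant gamma.  The Gaussian network model (GNM) encodes the
#' contact topology in the N x N Kirchhoff (graph Laplacian) matrix; the
#' anisotropic network model (ANM) encodes directions as well, through the
#' 3N x 3N Hessian of the harmonic pair potential.  Fluctuation amplitudes
#' are expressed in units of kB*T/gamma, taken as 1 A^2 by default.
#' @name elastic_network
NULL

.enm_new <- function(kind, matrix, cutoff, scale, residues, connected) {
  structure(list(kind = kind, matrix = matrix, cutoff = cutoff,
                 spring_constant_scale = scale, residues = residues,
                 connected = connected),
            class = "elastic_network")
}

#' @export
print.elastic_network <- function(x, ...) {
  cat(sprintf("elastic_network (%s): %d residues, cutoff %.1f A, kBT/gamma = %g A^2%s\n",
              x$kind, nrow(x$residues), x$cutoff, x$spring_constant_scale,
              if (x$connected) "" else " [disconnected graph]"))
  invisible(x)
}

.graph_connected <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nb <- which(adj[v, ] & !seen)
    seen[nb] <- TRUE
    stack <- c(stack, nb)
  }
  all(seen)
}

#' Build the GNM Kirchhoff matrix
#'
#' Off-diagonal entries are -1 for residue pairs with Calpha distance
#' `<= cutoff`, 0 otherwise; diagonal entries are node degrees (so every row
#' sums to zero).  A disconnected contact graph triggers a warning (extra
#' zero modes are then expected), not an error.
#'
#' @param s a [coarse_structure()].
#' @param cutoff contact cutoff in Angstrom (the commonly used GNM value is
#'   10).
#' @param kt_over_gamma kB*T/gamma in A^2; scales absolute fluctuations only.
#' @return An `elastic_network` of kind "GNM".
#' @export
build_kirchhoff <- function(s, cutoff = 10, kt_over_gamma = 1) {
  stopifnot(n_residues(s) >= 2L)
  X <- coords(s)
  d <- as.matrix(stats::dist(X))
  A <- (d <= cutoff)
  diag(A) <- FALSE
  G <- -1 * A
  diag(G) <- rowSums(A)
  connected <- .graph_connected(A)
  if (!connected)
    warning("GNM contact graph is disconnected; expect more than one zero mode")
  .enm_new("GNM", G, cutoff, kt_over_gamma,
           s$residues[, c("chain", "resno", "icode")], connected)
}

#' Build the ANM Hessian
#'
#' Standard anisotropic network model: for each contacting pair the 3 x 3
#' off-diagonal super-element is `-(d d^T) / |d|^2` (d the equilibrium
#' inter-node vector), and diagonal super-elements are the negated sums of
#' the off-diagonal ones, so block rows sum to the zero block.
#'
#' @param s a [coarse_structure()].
#' @param cutoff contact cutoff in Angstrom (the commonly used ANM value is
#'   15).
#' @param kt_over_gamma kB*T/gamma in A^2.
#' @return An `elastic_network` of kind "ANM" with a 3N x 3N matrix.
#' @export
build_hessian <- function(s, cutoff = 15, kt_over_gamma = 1) {
  n <- n_residues(s)
  stopifnot(n >= 2L)
  X <- coords(s)
  # collinearity check: rank of centered coordinates
  sv <- svd(scale(X, scale = FALSE), nu = 0, nv = 0)$d
  if (sv[2] < 1e-8 * sv[1])
    warning("collinear geometry: rigid-body null space exceeds 6 modes")
  d <- as.matrix(stats::dist(X))
  A <- (d <= cutoff)
  diag(A) <- FALSE
  connected <- .graph_connected(A)
  if (!connected)
    warning("ANM contact graph is disconnected; expect more than six zero modes")
  H <- matrix(0, 3 * n, 3 * n)
  idx <- which(A & upper.tri(A), arr.ind = TRUE)
  for (p in seq_len(nrow(idx))) {
    i <- idx[p, 1L]; j <- idx[p, 2L]
    dv <- X[j, ] - X[i, ]
    B <- tcrossprod(dv) / sum(dv^2)
    ri <- (3 * i - 2):(3 * i); rj <- (3 * j - 2):(3 * j)
    H[ri, rj] <- -B
    H[rj, ri] <- -B
    H[ri, ri] <- H[ri, ri] + B
    H[rj, rj] <- H[rj, rj] + B
  }
  .enm_new("ANM", H, cutoff, kt_over_gamma,
           s$residues[, c("chain", "resno", "icode")], connected)
}

# ---------------------------------------------------------------------------
# spectral decomposition
# ---------------------------------------------------------------------------

#' Eigen-decompose an elastic network
#'
#' Eigenvalues are returned in ascending order with deterministically signed
#' eigenvectors (largest-magnitude component positive).  Modes with
#' `lambda <= zero_tolerance` are flagged as zero modes; non-zero modes are
#' numbered from 1 starting at the slowest, matching the usual mode-numbering
#' convention ("mode 1" = slowest internal motion).
#'
#' @param net an `elastic_network`.
#' @param zero_tolerance absolute eigenvalue threshold for zero modes;
#'   `NULL` (default) uses `1e-8 * max(lambda)`.
#' @return An object of class `spectral_decomposition`: eigenvalues,
#'   eigenvectors (columns), `zero_mode_count`, `zero_tolerance`, degenerate
#'   mode grouping, plus the network metadata.
#' @export
decompose <- function(net, zero_tolerance = NULL) {
  stopifnot(inherits(net, "elastic_network"))
  if (any(!is.finite(net$matrix))) stop("non-finite entries in network matrix")
  e <- eigen(net$matrix, symmetric = TRUE)
  vals <- rev(e$values)
  vecs <- e$vectors[, rev(seq_along(e$values)), drop = FALSE]
  if (is.null(zero_tolerance)) zero_tolerance <- 1e-8 * max(abs(vals))
  if (any(vals < -zero_tolerance))
    stop("negative eigenvalue below tolerance: network matrix is not PSD")
  vals[vals < 0] <- 0
  # deterministic sign: largest |component| positive
  for (k in seq_len(ncol(vecs))) {
    m <- which.max(abs(vecs[, k]))
    if (vecs[m, k] < 0) vecs[, k] <- -vecs[, k]
  }
  nzero <- sum(vals <= zero_tolerance)
  nz_idx <- which(vals > zero_tolerance)
  # group non-zero modes that share an eigenvalue (relative gap < 1e-6)
  groups <- integer(length(nz_idx))
  g <- 0L
  for (k in seq_along(nz_idx)) {
    if (k == 1L || (vals[nz_idx[k]] - vals[nz_idx[k - 1L]]) /
          vals[nz_idx[k]] >= 1e-6) g <- g + 1L
    groups[k] <- g
  }
  structure(list(values = vals, vectors = vecs,
                 zero_mode_count = nzero, zero_tolerance = zero_tolerance,
                 nonzero_index = nz_idx, degenerate_group = groups,
                 kind = net$kind, scale = net$spring_constant_scale,
                 residues = net$residues),
            class = "spectral_decomposition")
}

#' @export
print.spectral_decomposition <- function(x, ...) {
  cat(sprintf("spectral_decomposition (%s): %d modes, %d zero mode(s)\n",
              x$kind, length(x$values), x$zero_mode_count))
  nz <- x$nonzero_index
  k <- min(6L, length(nz))
  cat("  slowest non-zero eigenvalues:",
      paste(signif(x$values[nz[seq_len(k)]], 4), collapse = ", "), "\n")
  invisible(x)
}

# map "mode k" (1 = slowest non-zero) to a column of the eigensystem
.mode_col <- function(d, k) {
  if (any(k < 1L) || any(k > length(d$nonzero_index)))
    stop("mode index out of range (non-zero modes: 1..",
         length(d$nonzero_index), ")")
  d$nonzero_index[k]
}

#' Non-zero mode count of a decomposition
#' @param d a `spectral_decomposition`.
#' @return integer.
#' @export
n_modes <- function(d) length(d$nonzero_index)

#' Eigenvalue(s) of non-zero mode(s)
#' @param d a `spectral_decomposition`.
#' @param k mode indices (1 = slowest non-zero mode).
#' @return numeric vector.
#' @export
mode_eigenvalue <- function(d, k) d$values[.mode_col(d, k)]

#' Degenerate-group labels of the non-zero modes
#'
#' Modes sharing an eigenvalue to relative precision 1e-6 belong to one
#' group; a C4-symmetric assembly shows paired groups among its slow modes.
#'
#' @param d a `spectral_decomposition`.
#' @return integer vector, one label per non-zero mode.
#' @export
degenerate_groups <- function(d) d$degenerate_group

# ---------------------------------------------------------------------------
# correlations and fluctuations
# ---------------------------------------------------------------------------

#' GNM residue fluctuation cross-correlations
#'
#' Returns the N x N matrix of `<dRi . dRj>` as the sum over the selected
#' non-zero modes of `3 (kBT/gamma) lambda_k^-1 u_k u_k^T`.  With all modes
#' this equals `3 (kBT/gamma)` times the Moore-Penrose pseudoinverse of the
#' Kirchhoff matrix; the diagonal is the per-residue mean-square fluctuation.
#'
#' @param d a GNM `spectral_decomposition`.
#' @param mode_subset "all" or a vector of non-zero mode indices (1 =
#'   slowest).
#' @return N x N numeric matrix.
#' @export
gnm_correlation <- function(d, mode_subset = "all") {
  stopifnot(d$kind == "GNM")
  ks <- if (identical(mode_subset, "all")) seq_len(n_modes(d)) else as.integer(mode_subset)
  cols <- .mode_col(d, ks)
  U <- d$vectors[, cols, drop = FALSE]
  w <- 1 / d$values[cols]
  3 * d$scale * (U %*% (w * t(U)))
}

#' ANM residue fluctuation cross-correlations
#'
#' Entry (i, j) is the trace of the 3 x 3 (i, j) super-element of the
#' (mode-restricted) pseudoinverse of the Hessian, scaled by kBT/gamma:
#' `sum_k lambda_k^-1 (u_k[i] . u_k[j])` with `u_k[i]` the 3-vector block of
#' residue i.
#'
#' @param d an ANM `spectral_decomposition`.
#' @param mode_subset "all" or non-zero mode indices.
#' @return N x N numeric matrix (N = residue count).
#' @export
anm_correlation <- function(d, mode_subset = "all") {
  stopifnot(d$kind == "ANM")
  ks <- if (identical(mode_subset, "all")) seq_len(n_modes(d)) else as.integer(mode_subset)
  cols <- .mode_col(d, ks)
  n <- nrow(d$vectors) / 3L
  out <- matrix(0, n, n)
  for (c0 in cols) {
    V <- matrix(d$vectors[, c0], nrow = 3L)   # 3 x N residue blocks
    out <- out + crossprod(V) / d$values[c0]
  }
  d$scale * out
}

#' Per-residue mean-square fluctuations
#' @param d a `spectral_decomposition` (GNM or ANM).
#' @param mode_subset "all" or non-zero mode indices.
#' @return numeric N-vector in A^2.
#' @export
mean_square_fluctuation <- function(d, mode_subset = "all") {
  m <- if (d$kind == "GNM") gnm_correlation(d, mode_subset) else
    anm_correlation(d, mode_subset)
  diag(m)
}

#' Normalize a cross-correlation matrix to [-1, 1]
#'
#' `C_ij = raw_ij / sqrt(raw_ii raw_jj)`.  Residues with (numerically) zero
#' mean-square fluctuation cannot be normalized; their rows/columns are set
#' to NA with a warning.
#'
#' @param raw N x N raw correlation matrix with positive diagonal.
#' @return N x N matrix with unit diagonal.
#' @export
normalized_cross_correlation <- function(raw) {
  msf <- diag(raw)
  bad <- msf <= 0 | !is.finite(msf)
  if (any(bad)) {
    warning(sum(bad), " residue(s) with zero mean-square fluctuation excluded from normalization")
    msf[bad] <- NA_real_
  }
  s <- 1 / sqrt(msf)
  out <- raw * tcrossprod(s)
  diag(out) <- ifelse(bad, NA_real_, 1)
  out
}

#' Relative contribution of a mode to the overall motion
#'
#' The contribution of non-zero mode k is `100 lambda_k^-1 / sum_j
#' lambda_j^-1` over all non-zero modes (inverse-eigenvalue weighting:
#' slower modes contribute more, and contributions sum to 100).  The
#' alternative `convention = "literal"` weights by the eigenvalues
#' themselves (`100 lambda_k / sum lambda_j`) and is provided for
#' comparison only.
#'
#' @param d a `spectral_decomposition`.
#' @param k non-zero mode index or vector of indices.
#' @param convention "inverse" (default) or "literal".
#' @return percentage(s).
#' @export
mode_contribution <- function(d, k, convention = c("inverse", "literal")) {
  convention <- match.arg(convention)
  lam <- d$values[d$nonzero_index]
  lk <- mode_eigenvalue(d, k)
  if (convention == "inverse") 100 * (1 / lk) / sum(1 / lam)
  else 100 * lk / sum(lam)
}
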