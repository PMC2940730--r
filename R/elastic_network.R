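# Gaussian and anisotropic elastic network models: Kirchhoff/Hessian
# construction, mode decomposition, mobility profiles and mode-deformation
# overlap.

contact_map <- function(coords, cutoff) {
  d2 <- as.matrix(stats::dist(coords))^2
  adj <- d2 <= cutoff^2
  diag(adj) <- FALSE
  adj
}

# connected components of an adjacency matrix (BFS)
components_of <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

check_connected <- function(adj, what) {
  comp <- components_of(adj)
  k <- max(comp)
  if (k > 1L) {
    sizes <- table(comp)
    stopf("%s network is disconnected at this cutoff: %d components (sizes %s)",
          what, k, paste(sizes, collapse = ", "))
  }
  if (any(rowSums(adj) == 0L)) stopf("%s network has an isolated node", what)
  invisible(TRUE)
}

new_mode_spectrum <- function(flavor, eigenvalues, eigenvectors, n_zero, n,
                              cutoff, trace) {
  structure(list(
    flavor = flavor,
    eigenvalues = eigenvalues,
    eigenvectors = eigenvectors,
    n_zero = n_zero,
    n_modes = length(eigenvalues),
    n = n,
    cutoff = cutoff,
    trace = trace
  ), class = "mode_spectrum")
}

#' @export
print.mode_spectrum <- function(x, ...) {
  cat(sprintf("%s mode spectrum: n = %d residues, %d modes (%d zero modes discarded), cutoff %.1f A\n",
              x$flavor, x$n, x$n_modes, x$n_zero, x$cutoff))
  cat(sprintf("softest eigenvalues: %s\n",
              paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = ", ")))
  invisible(x)
}

#' Build a Gaussian network model (GNM)
#'
#' Constructs the Kirchhoff (connectivity/Laplacian) matrix from the
#' C-alpha contact topology at the given cutoff: off-diagonal entries are
#' `-gamma` for residue pairs in contact, diagonals make row sums zero.
#' Eigendecomposition yields `n - 1` internal modes after discarding the
#' single zero mode.
#'
#' @param trace A `calpha_trace` (or an n x 3 coordinate matrix).
#' @param cutoff Contact distance cutoff in Angstrom (default 7.3, the
#'   conventional GNM value).
#' @param gamma Uniform spring constant (default 1; mobilities and overlaps
#'   are invariant to it).
#' @return A `mode_spectrum` with ascending nonzero eigenvalues and
#'   unit-norm n-dimensional eigenvectors (columns).
#' @export
build_gnm <- function(trace, cutoff = 7.3, gamma = 1) {
  coords <- if (inherits(trace, "calpha_trace")) trace_coords(trace) else as.matrix(trace)
  n <- nrow(coords)
  if (n < 3L) stopf("GNM needs at least 3 residues")
  if (cutoff <= 0) stopf("cutoff must be positive")
  adj <- contact_map(coords, cutoff)
  check_connected(adj, "GNM")
  K <- kirchhoff_matrix(coords, cutoff, gamma)
  e <- eigen(K, symmetric = TRUE)
  val <- rev(e$values)
  vec <- e$vectors[, rev(seq_len(n)), drop = FALSE]
  tol <- 1e-8 * max(val)
  zero <- which(val < tol)
  if (length(zero) != 1L) {
    stopf("expected exactly 1 zero mode, found %d (disconnected or degenerate network)",
          length(zero))
  }
  keep <- setdiff(seq_len(n), zero)
  warn_degenerate(val[keep], "GNM")
  new_mode_spectrum("GNM", val[keep], vec[, keep, drop = FALSE],
                    n_zero = 1L, n = n, cutoff = cutoff,
                    trace = if (inherits(trace, "calpha_trace")) trace else NULL)
}

warn_degenerate <- function(val, what) {
  if (length(val) > 1L) {
    gaps <- diff(val) / pmax(val[-length(val)], 1e-12)
    if (any(gaps[seq_len(min(9L, length(gaps)))] < 1e-6)) {
      warnf("%s spectrum has (near-)degenerate soft eigenvalues; mode order within a degenerate pair follows the solver, report overlap of such pairs jointly via cumulative_overlap",
            what)
    }
  }
}

#' Build an anisotropic network model (ANM)
#'
#' Constructs the 3n x 3n Hessian whose off-diagonal 3 x 3 super-elements
#' are `-gamma / |r_ij|^2 * r_ij r_ij^T` for residue pairs within the
#' cutoff, diagonal super-elements the negative sum over partners.
#' Exactly 6 zero modes (rigid-body translations/rotations) are discarded,
#' leaving `3n - 6` internal modes.
#'
#' @inheritParams build_gnm
#' @param cutoff Contact cutoff in Angstrom (default 13.0, the conventional
#'   ANM value).
#' @return A `mode_spectrum` with unit-norm 3n-dimensional eigenvectors.
#' @export
build_anm <- function(trace, cutoff = 13.0, gamma = 1) {
  coords <- if (inherits(trace, "calpha_trace")) trace_coords(trace) else as.matrix(trace)
  n <- nrow(coords)
  if (n < 3L) stopf("ANM needs at least 3 residues")
  if (cutoff <= 0) stopf("cutoff must be positive")
  adj <- contact_map(coords, cutoff)
  check_connected(adj, "ANM")
  H <- anm_hessian(coords, cutoff, gamma)
  e <- eigen(H, symmetric = TRUE)
  m <- 3L * n
  val <- rev(e$values)
  vec <- e$vectors[, rev(seq_len(m)), drop = FALSE]
  tol <- 1e-8 * max(val)
  zero <- which(val < tol)
  if (length(zero) > 6L) {
    stopf("ANM has %d near-zero modes (> 6): geometrically degenerate input",
          length(zero))
  }
  if (length(zero) < 6L) {
    stopf("ANM has %d near-zero modes (< 6): unexpected spectrum", length(zero))
  }
  keep <- setdiff(seq_len(m), zero)
  warn_degenerate(val[keep], "ANM")
  new_mode_spectrum("ANM", val[keep], vec[, keep, drop = FALSE],
                    n_zero = 6L, n = n, cutoff = cutoff,
                    trace = if (inherits(trace, "calpha_trace")) trace else NULL)
}

#' Kirchhoff (connectivity) matrix of a GNM
#'
#' @param coords n x 3 coordinate matrix or `calpha_trace`.
#' @param cutoff Contact cutoff in Angstrom.
#' @param gamma Spring constant.
#' @return n x n Laplacian matrix with zero row sums.
#' @export
kirchhoff_matrix <- function(coords, cutoff = 7.3, gamma = 1) {
  if (inherits(coords, "calpha_trace")) coords <- trace_coords(coords)
  adj <- contact_map(as.matrix(coords), cutoff)
  K <- -gamma * adj
  diag(K) <- gamma * rowSums(adj)
  K
}

#' Hessian matrix of an ANM
#'
#' Off-diagonal 3 x 3 super-elements `-gamma / |r_ij|^2 r_ij r_ij^T` for
#' contacting pairs; diagonal super-elements the negative sum over
#' partners, so the matrix annihilates rigid-body motions.
#'
#' @inheritParams kirchhoff_matrix
#' @param cutoff Contact cutoff in Angstrom.
#' @return 3n x 3n symmetric matrix.
#' @export
anm_hessian <- function(coords, cutoff = 13.0, gamma = 1) {
  if (inherits(coords, "calpha_trace")) coords <- trace_coords(coords)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  adj <- contact_map(coords, cutoff)
  H <- matrix(0, 3L * n, 3L * n)
  for (i in seq_len(n)) {
    bi <- (3L * (i - 1L) + 1L):(3L * i)
    for (j in which(adj[i, ])) {
      if (j <= i) next
      rij <- coords[j, ] - coords[i, ]
      d2 <- sum(rij^2)
      blk <- -gamma * tcrossprod(rij) / d2
      bj <- (3L * (j - 1L) + 1L):(3L * j)
      H[bi, bj] <- blk
      H[bj, bi] <- blk
    }
  }
  for (i in seq_len(n)) {
    bi <- (3L * (i - 1L) + 1L):(3L * i)
    acc <- matrix(0, 3L, 3L)
    for (j in which(adj[i, ])) {
      bj <- (3L * (j - 1L) + 1L):(3L * j)
      acc <- acc - H[bi, bj]
    }
    H[bi, bi] <- acc
  }
  H
}

# per-residue squared amplitude of one eigenvector
residue_sq <- function(spec, k) {
  v <- spec$eigenvectors[, k]
  if (spec$flavor == "ANM") {
    m <- matrix(v^2, ncol = 3L, byrow = TRUE)
    rowSums(m)
  } else {
    v^2
  }
}

#' Mobility profile over the softest modes
#'
#' Per-residue mean-square displacement driven by the `m` softest modes,
#' each mode weighted by the reciprocal of its eigenvalue:
#' `M_i = sum_k lambda_k^-1 [u^(k)]_i^2 / sum_k lambda_k^-1`.
#' For the ANM the three Cartesian components of a residue are summed.
#' The profile is normalized so that `sum_i M_i = 1` (the area under the
#' curve is 1), making profiles of different structures comparable.
#'
#' @param spec A `mode_spectrum`.
#' @param m Number of softest modes (default 10).
#' @return Object of class `mobility_profile`: list with `values`
#'   (length n), `m`, `normalized = TRUE`.
#' @export
mobility_profile <- function(spec, m = 10L) {
  stopifnot(inherits(spec, "mode_spectrum"))
  if (m < 1L || m > spec$n_modes) {
    stopf("m must be in [1, %d]", spec$n_modes)
  }
  w <- 1 / spec$eigenvalues[seq_len(m)]
  acc <- numeric(spec$n)
  for (k in seq_len(m)) acc <- acc + w[k] * residue_sq(spec, k)
  vals <- acc / sum(w)
  vals <- vals / sum(vals)
  structure(list(values = vals, m = m, normalized = TRUE),
            class = "mobility_profile")
}

as_numeric_d <- function(d) {
  if (inherits(d, "deformation_vector")) d$d else as.numeric(d)
}

# restrict ANM eigenvector columns to a residue subset (3 components each),
# without renormalizing; see package vignette for the rationale
restrict_modes <- function(spec, subset) {
  if (is.null(subset)) return(spec$eigenvectors)
  idx <- as.vector(t(outer(3L * (subset - 1L), 1:3, "+")))
  spec$eigenvectors[idx, , drop = FALSE]
}

#' Overlap (correlation cosine) between one mode and a deformation
#'
#' `|v^(k) . d| / |d|` for a unit-norm eigenvector. When the spectrum was
#' built on a larger structure than the deformation covers, pass `subset`
#' (residue indices into the spectrum's trace, in the order of the
#' deformation's residues); the eigenvector components are restricted to
#' that subset and deliberately not renormalized, so that cumulative
#' overlap over all modes of the full structure still reaches 1 only when
#' the deformation lies in the subspace spanned on those residues.
#'
#' @param spec A `mode_spectrum` (ANM for 3n deformations).
#' @param k Mode index (1 = softest nonzero mode).
#' @param d A `deformation_vector` or numeric vector.
#' @param subset Optional residue indices into the spectrum's structure.
#' @return Correlation cosine in `[0, 1]`.
#' @export
mode_overlap <- function(spec, k, d, subset = NULL) {
  stopifnot(inherits(spec, "mode_spectrum"))
  dv <- as_numeric_d(d)
  nd <- sqrt(sum(dv^2))
  if (nd == 0) stopf("deformation vector has zero norm")
  V <- restrict_modes(spec, subset)
  if (nrow(V) != length(dv)) {
    stopf("dimension mismatch: modes have %d components, deformation %d",
          nrow(V), length(dv))
  }
  if (k < 1L || k > spec$n_modes) stopf("mode index out of range")
  abs(sum(V[, k] * dv)) / nd
}

#' Cumulative overlap of the m softest modes with a deformation
#'
#' `CO(m) = sqrt( sum_{k=1..m} (v^(k) . d / |d|)^2 )`; nondecreasing in
#' `m` and equal to 1 when all `3n - 6` modes are included (the modes form
#' an orthonormal basis of the internal-motion space).
#'
#' @inheritParams mode_overlap
#' @param m Number of softest modes to accumulate.
#' @return `CO(m)` in `[0, 1]`.
#' @export
cumulative_overlap <- function(spec, m, d, subset = NULL) {
  stopifnot(inherits(spec, "mode_spectrum"))
  dv <- as_numeric_d(d)
  nd <- sqrt(sum(dv^2))
  if (nd == 0) stopf("deformation vector has zero norm")
  V <- restrict_modes(spec, subset)
  if (nrow(V) != length(dv)) {
    stopf("dimension mismatch: modes have %d components, deformation %d",
          nrow(V), length(dv))
  }
  if (m < 1L || m > spec$n_modes) stopf("m out of range")
  proj <- crossprod(V[, seq_len(m), drop = FALSE], dv) / nd
  min(sqrt(sum(proj^2)), 1)
}

#' Per-mode overlap and cumulative overlap table
#'
#' Convenience wrapper producing the per-mode correlation cosines and the
#' running cumulative overlap for the `m_max` softest modes, the quantities
#' plotted in mode/deformation comparison figures.
#'
#' @inheritParams mode_overlap
#' @param m_max Number of softest modes to tabulate (default 20).
#' @return Data frame with columns `mode`, `overlap`, `cumulative_overlap`.
#' @export
overlap_table <- function(spec, d, m_max = 20L, subset = NULL) {
  m_max <- min(m_max, spec$n_modes)
  ov <- vapply(seq_len(m_max), function(k) mode_overlap(spec, k, d, subset),
               numeric(1))
  data.frame(mode = seq_len(m_max), overlap = ov,
             cumulative_overlap = sqrt(cumsum(ov^2)))
}
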