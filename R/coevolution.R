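# Mutual-information co-evolution analysis over MSA columns, with the gap
# as the 21st symbol.

encode_msa <- function(msa) {
  m <- match(msa$mat, AA_GAP)
  m[is.na(m)] <- 21L
  matrix(m, nrow = nrow(msa$mat))
}

plugin_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Mutual-information matrix of an alignment
#'
#' Treats each column as a discrete random variable over 21 symbols (20
#' amino acids plus gap) and computes, from plug-in (empirical)
#' probabilities with no pseudocounts and no sequence weighting,
#' `I(i, j) = sum_{x,y} P(x_i, y_j) log( P(x_i, y_j) / (P(x_i) P(y_j)) )`.
#' The diagonal holds the column entropies `H(i)`. Natural logarithm
#' (nats) by default.
#'
#' @param msa An `msa_view` with at least 2 rows.
#' @param base `"nat"` (default) or `"bit"` logarithm units.
#' @param correction `"none"` (default) or `"miller_madow"` small-sample
#'   bias correction (adds `(m_xy - m_x - m_y + 1) / (2n)` with `m_*` the
#'   observed support sizes).
#' @return Object of class `mi_matrix`: an N x N symmetric numeric matrix
#'   with attributes `base` and `ref_numbering`.
#' @export
mi_matrix <- function(msa, base = c("nat", "bit"),
                      correction = c("none", "miller_madow")) {
  stopifnot(inherits(msa, "msa_view"))
  base <- match.arg(base)
  correction <- match.arg(correction)
  if (length(msa$ids) < 2L) stopf("need at least 2 sequences")
  E <- encode_msa(msa)
  n_rows <- nrow(E); nc <- ncol(E)
  scale <- if (base == "bit") 1 / log(2) else 1

  marg <- lapply(seq_len(nc), function(i) tabulate(E[, i], 21L))
  H <- vapply(marg, plugin_entropy, numeric(1))
  I <- matrix(0, nc, nc)
  diag(I) <- H
  if (nc >= 2L) {
    for (i in seq_len(nc - 1L)) {
      xi <- E[, i]
      hi <- H[i]
      mi_support <- sum(marg[[i]] > 0)
      for (j in (i + 1L):nc) {
        joint <- tabulate(xi + 21L * (E[, j] - 1L), 21L * 21L)
        hij <- plugin_entropy(joint)
        val <- hi + H[j] - hij
        if (correction == "miller_madow") {
          mj <- sum(marg[[j]] > 0)
          val <- val + (sum(joint > 0) - mi_support - mj + 1) / (2 * n_rows)
        }
        val <- max(val, 0)
        I[i, j] <- val
        I[j, i] <- val
      }
    }
  }
  I <- I * scale
  attr(I, "base") <- base
  attr(I, "ref_numbering") <- msa$ref_numbering
  class(I) <- c("mi_matrix", class(I))
  I
}

#' Per-column average mutual information
#'
#' Mean of each row of the MI matrix, diagonal (the column's own entropy)
#' excluded by default. High-average columns single out residues engaged
#' in many co-evolutionary relationships.
#'
#' @param I An `mi_matrix`.
#' @param exclude_diag Exclude the diagonal (default `TRUE`).
#' @return Numeric vector of length N.
#' @export
residue_average_mi <- function(I, exclude_diag = TRUE) {
  n <- nrow(I)
  if (n < 2L) stopf("MI matrix must be at least 2 x 2")
  M <- unclass(I)
  if (exclude_diag) {
    (rowSums(M) - diag(M)) / (n - 1L)
  } else {
    rowSums(M) / n
  }
}

#' Block-averaged mutual information
#'
#' Mean MI between and within labeled column sets (e.g. secondary-structure
#' elements or subdomains). Between blocks A and B the mean runs over all
#' `(i in A, j in B)` pairs; within a block over unordered pairs `i < j`.
#'
#' @param I An `mi_matrix`.
#' @param blocks Named list of disjoint column index vectors.
#' @return A symmetric `length(blocks)` x `length(blocks)` matrix of means.
#' @export
block_average_mi <- function(I, blocks) {
  if (any(lengths(blocks) == 0L)) stopf("empty block")
  all_idx <- unlist(blocks)
  if (anyDuplicated(all_idx)) stopf("blocks overlap")
  nb <- length(blocks)
  M <- unclass(I)
  out <- matrix(NA_real_, nb, nb, dimnames = list(names(blocks), names(blocks)))
  for (a in seq_len(nb)) {
    for (b in a:nb) {
      ia <- blocks[[a]]; ib <- blocks[[b]]
      if (a == b) {
        if (length(ia) < 2L) { out[a, b] <- NA_real_; next }
        sub <- M[ia, ia, drop = FALSE]
        out[a, b] <- mean(sub[upper.tri(sub)])
      } else {
        out[a, b] <- mean(M[ia, ib])
        out[b, a] <- out[a, b]
      }
    }
  }
  out
}

#' Top co-evolving column pairs
#'
#' Ranks off-diagonal pairs by MI (descending) after removing pairs closer
#' than `min_separation` along the sequence (`|i - j| > min_separation`,
#' i.e. separated by at least `min_separation` residues). In fraction mode
#' the number of reported pairs is `floor(fraction * N(N-1)/2)` (the top
#' 1% of a 380-column alignment is 720 pairs).
#'
#' @param I An `mi_matrix`.
#' @param fraction Fraction of all `N(N-1)/2` pairs to report (default
#'   0.01); ignored when `threshold` is given.
#' @param threshold Report all pairs with MI above this value instead.
#' @param min_separation Minimum sequence separation (default 2).
#' @return Data frame with columns `col_i`, `col_j`, `res_i`, `res_j`
#'   (reference numbering when available), `mi`, sorted by decreasing MI.
#' @export
top_coevolving_pairs <- function(I, fraction = 0.01, threshold = NULL,
                                 min_separation = 2L) {
  n <- nrow(I)
  M <- unclass(I)
  ut <- which(upper.tri(M), arr.ind = TRUE)
  sep_ok <- abs(ut[, 1L] - ut[, 2L]) > min_separation
  ut <- ut[sep_ok, , drop = FALSE]
  vals <- M[ut]
  ord <- order(-vals, ut[, 1L], ut[, 2L])
  ut <- ut[ord, , drop = FALSE]; vals <- vals[ord]
  if (is.null(threshold)) {
    if (fraction <= 0 || fraction > 1) stopf("fraction must be in (0, 1]")
    n_top <- max(1L, floor(fraction * n * (n - 1) / 2))
    keep <- seq_len(min(n_top, length(vals)))
  } else {
    keep <- which(vals > threshold)
  }
  ref <- attr(I, "ref_numbering") %||% seq_len(n)
  data.frame(
    col_i = ut[keep, 1L], col_j = ut[keep, 2L],
    res_i = ref[ut[keep, 1L]], res_j = ref[ut[keep, 2L]],
    mi = vals[keep]
  )
}

#' Write an MI matrix as TSV
#' @param I An `mi_matrix`.
#' @param path Output path.
#' @export
write_mi_tsv <- function(I, path) {
  M <- unclass(I)
  attr(M, "base") <- NULL
  attr(M, "ref_numbering") <- NULL
  utils::write.table(M, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
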