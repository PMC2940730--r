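# Relaxed Evolutionary Trace: p-distance tree, level partitions,
# class-consensus with the 90% rule and gap tolerance, per-residue ranks.

#' Pairwise p-distance matrix of an alignment
#'
#' Fraction of mismatched columns among the columns where both sequences
#' are non-gap. Sequence pairs sharing no non-gap column get distance 1.
#'
#' @param msa An `msa_view`.
#' @return A symmetric numeric matrix with sequence ids as dimnames.
#' @export
p_distance <- function(msa) {
  stopifnot(inherits(msa, "msa_view"))
  mat <- msa$mat
  n <- nrow(mat)
  ng <- mat != "-"
  # shared non-gap column counts via crossprod of the indicator matrix
  NG <- tcrossprod(ng * 1)
  # matched non-gap symbol counts, one indicator crossprod per symbol
  M <- matrix(0, n, n)
  for (s in AA1) {
    z <- (mat == s) * 1
    M <- M + tcrossprod(z)
  }
  D <- 1 - M / pmax(NG, 1)
  D[NG == 0] <- 1
  diag(D) <- 0
  dimnames(D) <- list(msa$ids, msa$ids)
  D
}

#' Build a distance tree over alignment rows
#'
#' Default: agglomerative average-linkage (UPGMA) clustering of the
#' p-distance matrix, yielding an ultrametric dendrogram. Alternatively
#' neighbor-joining (midpoint-rooted). Tie-breaking is deterministic
#' (sequence order).
#'
#' @param msa An `msa_view`.
#' @param method `"upgma"` (default) or `"nj"`.
#' @return Object of class `phylo_dendrogram`: list with `labels`,
#'   `method`, and either `hclust` (UPGMA) or `phylo` (NJ, an [ape]
#'   object).
#' @export
build_distance_tree <- function(msa, method = c("upgma", "nj")) {
  method <- match.arg(method)
  if (length(msa$ids) < 2L) stopf("need at least 2 sequences")
  if (anyDuplicated(msa$ids)) stopf("duplicate sequence ids")
  D <- p_distance(msa)
  if (method == "upgma") {
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    structure(list(labels = msa$ids, method = method, hclust = hc),
              class = "phylo_dendrogram")
  } else {
    tr <- ape::nj(stats::as.dist(D))
    # midpoint-root so that top-down level cuts are defined
    tr <- midpoint_root(tr)
    structure(list(labels = msa$ids, method = method, phylo = tr),
              class = "phylo_dendrogram")
  }
}

midpoint_root <- function(tr) {
  if (!requireNamespace("phangorn", quietly = TRUE)) {
    stopf("neighbor-joining trees require the phangorn package for midpoint rooting")
  }
  phangorn::midpoint(tr)
}

#' Partition a tree at a level
#'
#' Level `l` cuts the dendrogram into exactly `l` classes by undoing the
#' `l - 1` highest merges; level 1 is the whole family as a single class.
#' For a non-ultrametric (NJ) tree the cut proceeds top-down, always
#' splitting the class whose root split is closest to the tree root.
#'
#' @param tree A `phylo_dendrogram`.
#' @param level Integer `l >= 1`.
#' @return Object of class `level_partition`: list of character vectors of
#'   sequence ids, with attribute `level`.
#' @export
partition_at_level <- function(tree, level) {
  stopifnot(inherits(tree, "phylo_dendrogram"))
  n <- length(tree$labels)
  if (level < 1L || level > n) stopf("level must be in [1, %d]", n)
  if (!is.null(tree$hclust)) {
    cl <- stats::cutree(tree$hclust, k = level)
    classes <- split(names(cl), cl)
  } else {
    classes <- cut_phylo_topdown(tree$phylo, level)
  }
  names(classes) <- NULL
  structure(classes, class = "level_partition", level = level)
}

# greedy top-down cut of a rooted phylo into k leaf classes
cut_phylo_topdown <- function(tr, k) {
  ntips <- length(tr$tip.label)
  root <- ntips + 1L
  depths <- ape::node.depth.edgelength(tr)   # distance from root
  kids <- split(tr$edge[, 2L], tr$edge[, 1L])
  clusters <- list(root)
  repeat {
    if (length(clusters) >= k) break
    internal <- vapply(clusters, function(nd) nd > ntips, logical(1))
    if (!any(internal)) break
    cand <- unlist(clusters[internal])
    pick <- cand[which.min(depths[cand])]
    idx <- which(vapply(clusters, function(nd) nd == pick, logical(1)))[1L]
    clusters <- c(clusters[-idx], as.list(kids[[as.character(pick)]]))
  }
  lapply(clusters, function(nd) tr$tip.label[tips_under(tr, nd, ntips, kids)])
}

tips_under <- function(tr, nd, ntips, kids) {
  if (nd <= ntips) return(nd)
  out <- integer(0)
  stack <- nd
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    if (v <= ntips) out <- c(out, v)
    else stack <- c(stack, kids[[as.character(v)]])
  }
  out
}

#' Class consensus under the relaxed (90%) conservation rule
#'
#' A symbol is the class consensus at a column if at least
#' `threshold` of the class's non-gap rows carry it. Gaps are excluded from
#' the denominator, but a class with fewer than `min_nongap_frac` non-gap
#' rows at the column is treated as not conserved there (prevents vacuous
#' conservation of nearly-all-gap classes). Singleton classes are
#' vacuously conserved at their own symbol.
#'
#' @param msa An `msa_view`.
#' @param class_rows Character vector of sequence ids, or integer row
#'   indices, forming the class.
#' @param column Column index.
#' @param threshold Conservation fraction (default 0.90).
#' @param min_nongap_frac Minimum non-gap fraction (default 0.5).
#' @return The conserved symbol, or `NA_character_` if the class is not
#'   conserved at the column.
#' @export
class_consensus_conserved <- function(msa, class_rows, column,
                                      threshold = 0.90,
                                      min_nongap_frac = 0.5) {
  rows <- if (is.character(class_rows)) match(class_rows, msa$ids) else class_rows
  if (length(rows) == 0L) stopf("empty class")
  col <- msa$mat[rows, column]
  if (length(rows) == 1L) return(unname(col))
  nongap <- col[col != "-"]
  if (length(nongap) == 0L) return(NA_character_)
  if (length(nongap) < min_nongap_frac * length(col)) return(NA_character_)
  tab <- table(nongap)
  top <- which.max(tab)
  if (tab[top] >= threshold * length(nongap)) names(tab)[top] else NA_character_
}

#' Evolutionary Trace ranks over all columns
#'
#' For each column, the ET rank is the smallest level `l` at which every
#' class of the level-`l` partition is conserved (90% rule with gap
#' tolerance). At that level the column is `"conserved"` when all classes
#' share a single symbol, otherwise it is a class-specific trace residue
#' (`"X"`). Columns never class-conserved up to level `L` receive rank
#' `L + 1`.
#'
#' @param msa An `msa_view`.
#' @param tree A `phylo_dendrogram` over the alignment rows (default:
#'   built by [build_distance_tree()]).
#' @param L Number of levels (default 20).
#' @param threshold Conservation fraction (default 0.90).
#' @param min_nongap_frac See [class_consensus_conserved()].
#' @return Object of class `et_result`: list with `ranks` (integer per
#'   column), `trace_flags` (L x n_cols character matrix with values
#'   `"conserved"`, `"X"`, `""`), `L`, `threshold`, `ref_numbering`.
#' @export
compute_et_ranks <- function(msa, tree = NULL, L = 20L, threshold = 0.90,
                             min_nongap_frac = 0.5) {
  stopifnot(inherits(msa, "msa_view"))
  if (L < 1L) stopf("L must be >= 1")
  L <- min(L, length(msa$ids))
  if (is.null(tree)) tree <- build_distance_tree(msa)
  nc <- msa$n_cols
  ranks <- rep.int(L + 1L, nc)
  flags <- matrix("", nrow = L, ncol = nc)

  for (lev in seq_len(L)) {
    part <- partition_at_level(tree, lev)
    # per class: conserved symbol per column (vectorized over columns)
    cls_sym <- lapply(part, function(ids) {
      class_conserved_columns(msa, ids, threshold, min_nongap_frac)
    })
    sym_mat <- do.call(rbind, cls_sym)          # classes x columns
    all_cons <- colSums(is.na(sym_mat)) == 0L
    shared <- apply(sym_mat, 2L, function(s) {
      u <- unique(s[!is.na(s) & s != "-"])
      length(u) == 1L
    })
    flags[lev, all_cons & shared] <- "conserved"
    flags[lev, all_cons & !shared] <- "X"
    newly <- all_cons & ranks == (L + 1L)
    ranks[newly] <- lev
  }
  structure(list(ranks = ranks, trace_flags = flags, L = L,
                 threshold = threshold,
                 ref_numbering = msa$ref_numbering),
            class = "et_result")
}

# vectorized class consensus over all columns for one class
class_conserved_columns <- function(msa, ids, threshold, min_nongap_frac) {
  rows <- match(ids, msa$ids)
  sub <- msa$mat[rows, , drop = FALSE]
  if (length(rows) == 1L) return(as.character(sub[1L, ]))
  counts <- vapply(AA1, function(s) colSums(sub == s), numeric(ncol(sub)))
  if (ncol(sub) == 1L) counts <- matrix(counts, nrow = 1L,
                                        dimnames = list(NULL, AA1))
  nongap <- rowSums(counts)
  best <- max.col(counts, ties.method = "first")
  best_count <- counts[cbind(seq_len(nrow(counts)), best)]
  out <- ifelse(nongap > 0 &
                  nongap >= min_nongap_frac * length(rows) &
                  best_count >= threshold * nongap,
                AA1[best], NA_character_)
  out
}

#' Write an ET result as TSV
#'
#' Columns: column index, reference residue number (if set), rank, and the
#' per-level flag string (one character per level: the conserved symbol
#' marker `C`, trace `X`, or `.`).
#' @param et An `et_result`.
#' @param path Output path.
#' @export
write_et_tsv <- function(et, path) {
  flag_str <- apply(et$trace_flags, 2L, function(f) {
    paste(ifelse(f == "conserved", "C", ifelse(f == "X", "X", ".")),
          collapse = "")
  })
  out <- data.frame(
    column = seq_along(et$ranks),
    residue = et$ref_numbering %||% seq_along(et$ranks),
    rank = et$ranks,
    levels = flag_str
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a tree in Newick format
#' @param tree A `phylo_dendrogram`.
#' @param path Output path.
#' @export
write_tree_newick <- function(tree, path) {
  ph <- if (!is.null(tree$hclust)) ape::as.phylo(tree$hclust) else tree$phylo
  ape::write.tree(ph, file = path)
  invisible(path)
}
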