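# Seeded synthetic-data generators: two-lobe hinge-protein conformer pairs
# (for the dynamics stages) and tree-structured MSAs with planted
# conservation, class-specific and co-evolving columns (for the sequence
# stages).

#' Specification of a synthetic hinge protein
#'
#' Two compact lobes (beads on a 3.8 Angstrom grid, the C-alpha virtual
#' bond length) joined by a narrow hinge ribbon. The hinge ribbon lies in
#' the x-z plane, so that in-plane bending (rotation of one lobe about the
#' z axis through the hinge) is the softest deformation direction --
#' emulating the open/closed interlobe motion of a two-lobe enzyme.
#'
#' @param n_per_lobe Beads per lobe (default 60).
#' @param gap Gap between each lobe surface and the hinge, along x
#'   (default 7.0 Angstrom, which keeps the two lobes out of direct
#'   contact at the default ANM cutoff while the hinge stays connected at
#'   the default GNM cutoff).
#' @param hinge_width Hinge ribbon width in beads along z (default 3).
#' @param opening_angle Rotation of the second lobe about the hinge z axis
#'   in the open form, degrees (default 20).
#' @param jitter Isotropic Gaussian coordinate noise, Angstrom (default
#'   0.3), applied to the closed form and inherited rigidly by the open
#'   form.
#' @return List of class `hinge_spec`.
#' @export
hinge_spec <- function(n_per_lobe = 60L, gap = 7.0, hinge_width = 3L,
                       opening_angle = 20, jitter = 0.3) {
  stopifnot(n_per_lobe >= 8L, gap > 0, hinge_width >= 1L, jitter >= 0)
  structure(list(n_per_lobe = as.integer(n_per_lobe), gap = gap,
                 hinge_width = as.integer(hinge_width),
                 opening_angle = opening_angle, jitter = jitter),
            class = "hinge_spec")
}

# beads on a cubic grid (spacing 3.8 A) filling a sphere, deterministic
lobe_beads <- function(n, spacing = 3.8) {
  k <- ceiling((n * 3 / (4 * pi))^(1 / 3)) + 1L
  g <- seq(-k, k) * spacing
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  ord <- order(rowSums(pts^2), pts[, 1L], pts[, 2L], pts[, 3L])
  pts[ord[seq_len(n)], , drop = FALSE]
}

#' Generate closed/open conformers of a synthetic hinge protein
#'
#' The closed form places the two lobes on the x axis, joined by a hinge
#' ribbon at the origin. The open form rigidly rotates the second lobe
#' (and nothing else) by `opening_angle` about the z axis through the
#' hinge. The planted deformation is the exact C-alpha coordinate
#' difference after Kabsch superposition of the open form onto the closed
#' form, i.e. precisely what [deformation_vector()] measures.
#'
#' @param spec A [hinge_spec()].
#' @param seed Integer seed (jitter is the only randomness).
#' @param out_dir Optional directory; when given, `closed.pdb` and
#'   `open.pdb` are written via [write_pdb_trace()].
#' @return List with `closed`, `open` (`calpha_trace` objects, identical
#'   residue sets), and `deformation` (the planted `deformation_vector`).
#' @export
make_hinge_conformers <- function(spec = hinge_spec(), seed = 1L,
                                  out_dir = NULL) {
  stopifnot(inherits(spec, "hinge_spec"))
  set.seed(as.integer(seed))
  sp <- 3.8
  lobe <- lobe_beads(spec$n_per_lobe, sp)
  r_lobe <- max(abs(lobe[, 1L]))
  cx <- r_lobe + spec$gap                    # lobe centre offset from hinge
  lobe1 <- sweep(lobe, 2, c(-cx, 0, 0), "+")
  lobe2 <- sweep(lobe, 2, c(cx, 0, 0), "+")
  zw <- (seq_len(spec$hinge_width) - (spec$hinge_width + 1) / 2) * sp
  hinge <- as.matrix(expand.grid(x = c(-sp, 0, sp), y = 0, z = zw))
  coords <- rbind(lobe1, hinge, lobe2)
  coords <- coords + matrix(stats::rnorm(length(coords), 0, spec$jitter),
                            ncol = 3L)
  n <- nrow(coords)
  lobe2_idx <- (nrow(lobe1) + nrow(hinge) + 1L):n

  theta <- spec$opening_angle * pi / 180
  Rz <- matrix(c(cos(theta), sin(theta), 0,
                 -sin(theta), cos(theta), 0,
                 0, 0, 1), 3L, 3L)
  open_coords <- coords
  open_coords[lobe2_idx, ] <- coords[lobe2_idx, , drop = FALSE] %*% Rz

  as_trace <- function(xyz, id) {
    out <- data.frame(
      chain_id = "A",
      residue_number = seq_len(n),
      insertion_code = "",
      residue_name = "GLY",
      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
      stringsAsFactors = FALSE
    )
    class(out) <- c("calpha_trace", class(out))
    attr(out, "structure_id") <- id
    out
  }
  closed <- as_trace(coords, "hinge_closed")
  open <- as_trace(open_coords, "hinge_open")
  # planted deformation: identical residue sets, identity map
  map <- structure(list(pairs = cbind(index_a = seq_len(n),
                                      index_b = seq_len(n)),
                        n_common = n), class = "residue_map")
  d <- deformation_vector(closed, open, map)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_pdb_trace(closed, file.path(out_dir, "closed.pdb"))
    write_pdb_trace(open, file.path(out_dir, "open.pdb"))
  }
  list(closed = closed, open = open, deformation = d)
}

#' Specification of a simulated family alignment
#'
#' A family of `clades` subfamilies, each a balanced binary tree, evolved
#' from a random root sequence by an independent-site substitution process
#' (uniform over the 19 alternative amino acids; realistic
#' exchangeabilities are irrelevant to the column-pattern statistics the
#' downstream analyses consume). Planted structure:
#' * `conserved_columns` never substitute (emulating nucleotide-binding
#'   positions);
#' * `trace_columns` substitute only on the clade-founding branches, to a
#'   clade-specific symbol (class-specific trace residues);
#' * `coevolving_pairs` substitute jointly: a substitution event at the
#'   pair resets both columns consistently (via a fixed random bijection)
#'   with probability `coupling`, otherwise only one side changes;
#' * gaps are injected per cell at `gap_rate`.
#'
#' @param n_seqs Number of leaf sequences (default 200).
#' @param n_cols Alignment width (default 100).
#' @param clades Number of subfamilies (default 4).
#' @param sub_rate Per-branch, per-site substitution probability
#'   (default 0.03).
#' @param conserved_columns Integer columns (default `c(10, 30, 50, 70,
#'   90)`).
#' @param trace_columns Integer columns that carry the clade signal
#'   (default `c(5, 45, 85)`).
#' @param coevolving_pairs 2-column matrix of column pairs, sequence
#'   separation at least 3 (default 5 pairs).
#' @param coupling Probability that a pair substitution is joint
#'   (default 0.9).
#' @param coev_rate Per-branch event probability for a co-evolving pair
#'   (default `3 * sub_rate`: recognition sites evolve faster than the
#'   average position).
#' @param founder_branches Length of each clade-founding branch, in units
#'   of ordinary branches (default 5): subfamilies diverge from each other
#'   well before they diversify internally, which is what makes them
#'   recoverable as tree classes.
#' @param gap_rate Per-cell gap injection probability (default 0.01).
#' @return List of class `msa_sim_spec`.
#' @export
msa_sim_spec <- function(n_seqs = 200L, n_cols = 100L, clades = 4L,
                         sub_rate = 0.03,
                         conserved_columns = c(10L, 30L, 50L, 70L, 90L),
                         trace_columns = c(5L, 45L, 85L),
                         coevolving_pairs = cbind(c(15L, 25L, 40L, 55L, 80L),
                                                  c(20L, 33L, 60L, 77L, 95L)),
                         coupling = 0.9, coev_rate = 3 * sub_rate,
                         founder_branches = 5L, gap_rate = 0.01) {
  coevolving_pairs <- as.matrix(coevolving_pairs)
  planted <- c(conserved_columns, trace_columns, as.vector(coevolving_pairs))
  if (anyDuplicated(planted)) {
    stopf("planted column sets must be disjoint")
  }
  if (any(planted > n_cols)) stopf("planted column beyond n_cols")
  if (any(abs(coevolving_pairs[, 1L] - coevolving_pairs[, 2L]) < 3L)) {
    stopf("co-evolving pairs must be separated by at least 3 columns")
  }
  stopifnot(coupling >= 0, coupling <= 1, gap_rate >= 0, gap_rate < 1)
  structure(list(n_seqs = as.integer(n_seqs), n_cols = as.integer(n_cols),
                 clades = as.integer(clades), sub_rate = sub_rate,
                 conserved_columns = as.integer(conserved_columns),
                 trace_columns = as.integer(trace_columns),
                 coevolving_pairs = coevolving_pairs,
                 coupling = coupling, coev_rate = coev_rate,
                 founder_branches = as.integer(founder_branches),
                 gap_rate = gap_rate),
            class = "msa_sim_spec")
}

#' Simulate a family alignment with planted evolutionary structure
#'
#' @param spec An [msa_sim_spec()].
#' @param seed Integer seed; the generator is fully seed-deterministic.
#' @param out_dir Optional directory: writes `msa.fasta` and a
#'   `truth.tsv` column-annotation table.
#' @return List with `msa` (an `msa_view`) and `truth`: list holding
#'   `conserved` (columns), `trace` (named list column -> clade symbols),
#'   `coevolving_pairs`, `clade` (named clade index per sequence), and
#'   `root` (the root sequence).
#' @export
simulate_msa <- function(spec = msa_sim_spec(), seed = 1L, out_dir = NULL) {
  stopifnot(inherits(spec, "msa_sim_spec"))
  set.seed(as.integer(seed))
  nc <- spec$n_cols
  conserved <- spec$conserved_columns
  tracec <- spec$trace_columns
  pairs <- spec$coevolving_pairs
  normal <- setdiff(seq_len(nc), c(conserved, tracec, as.vector(pairs)))

  root <- sample(AA1, nc, replace = TRUE)
  # clade-specific symbols: distinct per clade at each trace column
  clade_syms <- lapply(tracec, function(i) sample(AA1, spec$clades))
  names(clade_syms) <- as.character(tracec)
  # fixed random bijection per co-evolving pair
  bijections <- lapply(seq_len(nrow(pairs)), function(p) {
    b <- sample(AA1)
    names(b) <- AA1
    b
  })

  mutate_normal <- function(s, cols, rate) {
    hit <- cols[stats::runif(length(cols)) < rate]
    for (i in hit) {
      s[i] <- sample(setdiff(AA1, s[i]), 1L)
    }
    s
  }
  mutate_pairs <- function(s) {
    for (p in seq_len(nrow(pairs))) {
      if (stats::runif(1) < spec$coev_rate) {
        i <- pairs[p, 1L]; j <- pairs[p, 2L]
        if (stats::runif(1) < spec$coupling) {
          a <- sample(AA1, 1L)
          s[i] <- a
          s[j] <- bijections[[p]][[a]]
        } else {
          k <- if (stats::runif(1) < 0.5) i else j
          s[k] <- sample(setdiff(AA1, s[k]), 1L)
        }
      }
    }
    s
  }
  evolve_branch <- function(s) mutate_pairs(mutate_normal(s, normal, spec$sub_rate))

  leaves_per_clade <- spec$n_seqs %/% spec$clades
  extra <- spec$n_seqs - leaves_per_clade * spec$clades
  seqs <- list(); clade_of <- integer(0)
  for (cl in seq_len(spec$clades)) {
    founder <- root
    for (tc in seq_along(tracec)) {
      founder[tracec[tc]] <- clade_syms[[tc]][cl]
    }
    for (fb in seq_len(spec$founder_branches)) {
      founder <- evolve_branch(founder)
    }
    n_leaves <- leaves_per_clade + (cl <= extra)
    depth <- max(1L, ceiling(log2(max(n_leaves, 2L))))
    # balanced binary descent; prune to n_leaves leaves
    level <- list(founder)
    for (d in seq_len(depth)) {
      level <- unlist(lapply(level, function(s) {
        list(evolve_branch(s), evolve_branch(s))
      }), recursive = FALSE)
    }
    level <- level[seq_len(n_leaves)]
    seqs <- c(seqs, level)
    clade_of <- c(clade_of, rep.int(cl, n_leaves))
  }

  mat <- do.call(rbind, seqs)
  if (spec$gap_rate > 0) {
    gap_hits <- matrix(stats::runif(length(mat)) < spec$gap_rate,
                       nrow = nrow(mat))
    mat[gap_hits] <- "-"
    # conserved columns stay recoverable: gap tolerance in downstream
    # analyses excludes gaps from the conservation denominator
  }
  ids <- sprintf("clade%d_seq%03d", clade_of, seq_len(nrow(mat)))
  msa <- msa_view(ids, apply(mat, 1L, paste, collapse = ""))
  names(clade_of) <- ids

  truth <- list(conserved = conserved,
                trace = clade_syms,
                coevolving_pairs = pairs,
                clade = clade_of,
                root = paste(root, collapse = ""))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_msa_fasta(msa, file.path(out_dir, "msa.fasta"))
    ann <- rep("normal", nc)
    ann[conserved] <- "conserved"
    ann[tracec] <- "trace"
    ann[as.vector(pairs)] <- "coevolving"
    utils::write.table(
      data.frame(column = seq_len(nc), annotation = ann),
      file.path(out_dir, "truth.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(msa = msa, truth = truth)
}
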