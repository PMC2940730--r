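# PDB reading, C-alpha trace extraction, residue mapping between conformers,
# Kabsch superposition and deformation vectors.

#' Read a PDB-format structure file
#'
#' Parses the fixed-column ATOM/HETATM records of a PDB file (plain or
#' gzip-compressed) into an atom table. HETATM records are retained and
#' flagged (`hetatm` column) so that bound ligands such as ADP remain
#' available for inspection. Alternate locations are resolved by keeping, for
#' each atom, the altloc with the highest occupancy (ties broken in favour of
#' altloc `"A"`, then alphabetically).
#'
#' @param path Path to a PDB file (`.pdb` or `.pdb.gz`).
#' @param model Model number to read. For single-model files (no MODEL
#'   records) the whole file is model 1.
#' @return A data frame of class `pdb_atoms` with one row per atom and
#'   columns `record`, `serial`, `atom_name`, `altloc`, `residue_name`,
#'   `chain_id`, `residue_number`, `insertion_code`, `x`, `y`, `z`,
#'   `occupancy`, `element`, `hetatm`.
#' @examples
#' pdb <- system.file("extdata", "toy_dimer.pdb", package = "chaperonemodes")
#' atoms <- read_pdb(pdb)
#' table(atoms$chain_id)
#' @export
read_pdb <- function(path, model = 1L) {
  if (!is_string(path) || !file.exists(path)) {
    stopf("PDB file not found: %s", path)
  }
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)

  rec <- substr(lines, 1, 6)
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) > 0L) {
    model_ids <- suppressWarnings(as.integer(substr(lines[model_starts], 11, 14)))
    hit <- which(model_ids == model)
    if (length(hit) == 0L) {
      stopf("model %d not present in %s (models: %s)", model, path,
            paste(model_ids, collapse = ", "))
    }
    from <- model_starts[hit[1L]]
    ends <- which(rec == "ENDMDL")
    to <- ends[ends > from]
    to <- if (length(to)) to[1L] else length(lines)
    lines <- lines[from:to]
    rec <- substr(lines, 1, 6)
  } else if (model != 1L) {
    stopf("file %s has a single model; model %d requested", path, model)
  }

  keep <- rec == "ATOM  " | rec == "HETATM"
  lines <- lines[keep]
  if (length(lines) == 0L) stopf("no ATOM/HETATM records in %s", path)

  num <- function(s) {
    out <- suppressWarnings(as.numeric(s))
    if (anyNA(out[trimws(s) != ""])) {
      stopf("unparseable numeric field in %s (first bad: '%s')",
            path, s[which(is.na(out) & trimws(s) != "")[1L]])
    }
    out
  }
  xyz_x <- num(substr(lines, 31, 38))
  xyz_y <- num(substr(lines, 39, 46))
  xyz_z <- num(substr(lines, 47, 54))
  if (anyNA(xyz_x) || anyNA(xyz_y) || anyNA(xyz_z)) {
    stopf("missing coordinate field in %s", path)
  }
  occ <- num(substr(lines, 55, 60))
  occ[is.na(occ)] <- 1.0
  elem <- trimws(substr(lines, 77, 78))
  atom_name <- trimws(substr(lines, 13, 16))
  # infer element from the atom name when columns 77-78 are blank
  blank <- elem == ""
  if (any(blank)) {
    guess <- sub("^[0-9]*", "", atom_name[blank])
    two <- substr(guess, 1, 2) %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE")
    elem[blank] <- ifelse(two, substr(guess, 1, 2), substr(guess, 1, 1))
  }

  atoms <- data.frame(
    record = trimws(substr(lines, 1, 6)),
    serial = suppressWarnings(as.integer(substr(lines, 7, 11))),
    atom_name = atom_name,
    altloc = substr(lines, 17, 17),
    residue_name = trimws(substr(lines, 18, 20)),
    chain_id = substr(lines, 22, 22),
    residue_number = suppressWarnings(as.integer(substr(lines, 23, 26))),
    insertion_code = trimws(substr(lines, 27, 27)),
    x = xyz_x, y = xyz_y, z = xyz_z,
    occupancy = occ,
    element = toupper(elem),
    stringsAsFactors = FALSE
  )
  atoms$hetatm <- atoms$record == "HETATM"
  if (any(atoms$residue_name == "")) stopf("empty residue name in %s", path)

  # altloc resolution: highest occupancy wins; ties prefer 'A', then order
  alt <- atoms$altloc != " " & atoms$altloc != ""
  if (any(alt)) {
    key <- paste(atoms$chain_id, atoms$residue_number, atoms$insertion_code,
                 atoms$residue_name, atoms$atom_name, sep = "\r")
    pref <- order(key, -atoms$occupancy, atoms$altloc != "A", atoms$altloc)
    dup <- duplicated(key[pref])
    drop_idx <- pref[dup]
    if (length(drop_idx)) atoms <- atoms[-drop_idx, , drop = FALSE]
    atoms <- atoms[order(atoms$serial), , drop = FALSE]
    rownames(atoms) <- NULL
  }
  class(atoms) <- c("pdb_atoms", class(atoms))
  attr(atoms, "path") <- path
  atoms
}

#' Extract a C-alpha trace from an atom table
#'
#' Keeps one record per residue possessing a CA atom, ordered by
#' (chain, residue number, insertion code). Residues in the selection that
#' lack a CA atom are dropped with a warning. HETATM residues are excluded.
#'
#' @param atoms A `pdb_atoms` data frame from [read_pdb()].
#' @param chain Optional chain identifier(s) to keep (e.g. `"A"`).
#' @param residue_range Optional length-2 integer vector `c(first, last)`
#'   restricting author residue numbers (inclusive).
#' @param structure_id Identifier stored with the trace.
#' @return A data frame of class `calpha_trace` with columns `chain_id`,
#'   `residue_number`, `insertion_code`, `residue_name`, `x`, `y`, `z`.
#' @export
extract_calpha_trace <- function(atoms, chain = NULL, residue_range = NULL,
                                 structure_id = "") {
  sel <- !atoms$hetatm
  if (!is.null(chain)) sel <- sel & atoms$chain_id %in% chain
  if (!is.null(residue_range)) {
    stopifnot(length(residue_range) == 2L)
    sel <- sel & atoms$residue_number >= residue_range[1L] &
      atoms$residue_number <= residue_range[2L]
  }
  a <- atoms[sel, , drop = FALSE]
  if (nrow(a) == 0L) stopf("empty selection (chain %s)",
                           paste(chain, collapse = ","))
  key <- paste(a$chain_id, a$residue_number, a$insertion_code, sep = "\r")
  ca <- a[a$atom_name == "CA" & a$element != "CA", , drop = FALSE]  # not calcium
  if (nrow(ca) == 0L) ca <- a[a$atom_name == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stopf("no CA atoms in selection")
  n_res <- length(unique(key))
  if (n_res > nrow(ca)) {
    warnf("%d residue(s) in selection lack a CA atom and were omitted",
          n_res - nrow(ca))
  }
  ord <- order(ca$chain_id, ca$residue_number, ca$insertion_code)
  ca <- ca[ord, , drop = FALSE]
  out <- data.frame(
    chain_id = ca$chain_id,
    residue_number = ca$residue_number,
    insertion_code = ca$insertion_code,
    residue_name = ca$residue_name,
    x = ca$x, y = ca$y, z = ca$z,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  dup <- duplicated(paste(out$chain_id, out$residue_number,
                          out$insertion_code, sep = "\r"))
  if (any(dup)) out <- out[!dup, , drop = FALSE]
  class(out) <- c("calpha_trace", class(out))
  attr(out, "structure_id") <- structure_id
  out
}

#' Coordinates of a C-alpha trace as an n x 3 matrix
#' @param trace A `calpha_trace`.
#' @return Numeric matrix with one row per residue.
#' @export
trace_coords <- function(trace) {
  m <- cbind(trace$x, trace$y, trace$z)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Map common residues between two C-alpha traces
#'
#' Pairs residues by global alignment of the one-letter sequences of the two
#' traces (match +1, mismatch -1, gap -2), not by raw author numbering, so
#' that bound and unbound structures with different resolved residues can be
#' compared. Aligned identical or substituted positions are paired; positions
#' opposite a gap are unpaired.
#'
#' @param a,b `calpha_trace` objects.
#' @param min_pairs Minimum acceptable number of pairs; fewer is an error
#'   (it usually signals a wrong chain selection).
#' @return A list of class `residue_map` with `pairs` (2-column integer
#'   matrix of indices into `a` and `b`) and `n_common`.
#' @export
map_common_residues <- function(a, b, min_pairs = 30L) {
  stopifnot(inherits(a, "calpha_trace"), inherits(b, "calpha_trace"))
  if (nrow(a) == 0L || nrow(b) == 0L) stopf("empty trace")
  sa <- paste(three_to_one(a$residue_name), collapse = "")
  sb <- paste(three_to_one(b$residue_name), collapse = "")
  alphabet <- unique(c(chars(sa), chars(sb)))
  sub <- matrix(-1, length(alphabet), length(alphabet),
                dimnames = list(alphabet, alphabet))
  diag(sub) <- 1
  aln <- Biostrings::pairwiseAlignment(
    sa, sb, type = "global", substitutionMatrix = sub,
    gapOpening = 0, gapExtension = 2
  )
  pa <- chars(as.character(Biostrings::alignedPattern(aln)))
  pb <- chars(as.character(Biostrings::alignedSubject(aln)))
  ia <- cumsum(pa != "-")
  ib <- cumsum(pb != "-")
  both <- pa != "-" & pb != "-"
  pairs <- cbind(index_a = ia[both], index_b = ib[both])
  if (nrow(pairs) < min_pairs) {
    stopf("only %d residue pairs mapped (< %d): check chain selection",
          nrow(pairs), min_pairs)
  }
  structure(list(pairs = pairs, n_common = nrow(pairs)),
            class = "residue_map")
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' paired coordinate sets, via singular value decomposition of the covariance
#' matrix; the determinant sign is corrected so the rotation is proper
#' (det = +1, no reflection).
#'
#' @param mobile,reference n x 3 coordinate matrices over the same n paired
#'   points (n >= 3, non-collinear).
#' @return List with `rotation` (3 x 3, applied to centered mobile
#'   coordinates), `translation` (length-3), and `rmsd` (Angstrom) after
#'   superposition. The fitted coordinates are
#'   `mobile %*% t(rotation) + translation` (rows are points).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3L, ncol(reference) == 3L,
            nrow(mobile) == nrow(reference))
  n <- nrow(mobile)
  if (n < 3L) stopf("need at least 3 paired points for superposition")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)
  H <- crossprod(P, Q)           # 3x3 covariance
  sv <- svd(H)
  if (sv$d[2L] < 1e-10 * max(sv$d[1L], 1e-12)) {
    stopf("degenerate (collinear or coincident) point set")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)    # x_fit = R %*% x_centered (column vectors)
  fitted <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  translation <- as.numeric(cr - R %*% cm)
  list(rotation = R, translation = translation, rmsd = rmsd)
}

#' Apply a superposition transform to coordinates
#' @param coords n x 3 matrix.
#' @param transform Result of [kabsch_superpose()].
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(coords, transform) {
  sweep(as.matrix(coords) %*% t(transform$rotation), 2,
        transform$translation, "+")
}

#' Deformation vector between two conformers
#'
#' Superposes the bound conformer onto the free one over the mapped residues
#' (Kabsch), then concatenates the per-residue C-alpha displacement
#' `x_bound - x_free` into a 3n vector. Rigid-body translation/rotation is
#' thereby removed and only internal deformation remains.
#'
#' @param free,bound `calpha_trace` objects.
#' @param map A `residue_map` from [map_common_residues()]; if `NULL` it is
#'   computed (with `min_pairs = 3`).
#' @return List of class `deformation_vector` with `d` (length 3n), `norm`
#'   (Angstrom), `residue_keys` (the n mapped residues of the free trace),
#'   `map`, and the superposition `rmsd`.
#' @export
deformation_vector <- function(free, bound, map = NULL) {
  if (is.null(map)) map <- map_common_residues(free, bound, min_pairs = 3L)
  ia <- map$pairs[, 1L]; ib <- map$pairs[, 2L]
  xf <- trace_coords(free)[ia, , drop = FALSE]
  xb <- trace_coords(bound)[ib, , drop = FALSE]
  tf <- kabsch_superpose(xb, xf)
  xb_fit <- apply_transform(xb, tf)
  delta <- xb_fit - xf
  d <- as.numeric(t(delta))      # per residue: x, y, z
  structure(list(
    d = d,
    norm = sqrt(sum(d^2)),
    residue_keys = free[ia, c("chain_id", "residue_number",
                              "insertion_code", "residue_name")],
    map = map,
    rmsd = tf$rmsd
  ), class = "deformation_vector")
}

#' Write a deformation vector as TSV
#'
#' Columns: chain, resnum, resname, dx, dy, dz.
#' @param def A `deformation_vector`.
#' @param path Output file path.
#' @export
write_deformation_tsv <- function(def, path) {
  m <- matrix(def$d, ncol = 3L, byrow = TRUE)
  out <- data.frame(
    chain = def$residue_keys$chain_id,
    resnum = def$residue_keys$residue_number,
    resname = def$residue_keys$residue_name,
    dx = m[, 1L], dy = m[, 2L], dz = m[, 3L]
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a C-alpha trace as a minimal PDB file
#'
#' CA-only fixed-column writer (3-decimal coordinates) so that generated
#' fixtures round-trip through [read_pdb()].
#' @param trace A `calpha_trace`.
#' @param path Output path.
#' @export
write_pdb_trace <- function(trace, path) {
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(trace)),
    substr(ifelse(trace$residue_name == "", "GLY", trace$residue_name), 1, 3),
    trace$chain_id, trace$residue_number,
    ifelse(trace$insertion_code == "", " ", trace$insertion_code),
    trace$x, trace$y, trace$z
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}
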