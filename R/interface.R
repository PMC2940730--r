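# Protein-protein interface characterization: close atom-atom contacts,
# Shrake-Rupley solvent-accessible surface area, buried-surface reports and
# interfacial salt bridges.

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

atom_radii <- function(atoms) {
  r <- VDW_RADII[atoms$element]
  unk <- is.na(r)
  if (any(unk)) {
    warnf("unknown element(s) %s: default radius 1.70 A used",
          paste(unique(atoms$element[unk]), collapse = ", "))
    r[unk] <- 1.70
  }
  unname(r)
}

res_key <- function(atoms) {
  paste(atoms$chain_id, atoms$residue_number, atoms$insertion_code, sep = ":")
}

select_group <- function(atoms, chains, include_het = FALSE) {
  sel <- atoms$chain_id %in% chains & atoms$element != "H"
  if (!include_het) sel <- sel & !atoms$hetatm
  atoms[sel, , drop = FALSE]
}

#' Inter-group atom-atom contacts
#'
#' Lists all residue pairs of two chain groups having at least one
#' heavy-atom pair closer than the cutoff (strict inequality), with the
#' minimum interatomic distance per residue pair. The 4 Angstrom default
#' is the convention for defining interface contacts.
#'
#' @param atoms A `pdb_atoms` table of the complex.
#' @param group_a,group_b Disjoint chain-id vectors.
#' @param cutoff Distance cutoff in Angstrom (default 4.0).
#' @param include_het Include HETATM residues (default `FALSE`: ligands
#'   such as nucleotides are not part of the protein-protein interface).
#' @return Object of class `contact_report`: list with `pairs` (data frame
#'   `chain_a`, `resnum_a`, `resname_a`, `chain_b`, `resnum_b`,
#'   `resname_b`, `min_distance`), `residues_a`, `residues_b` (data frames
#'   of contacting residues per group), and `cutoff`.
#' @export
interface_contacts <- function(atoms, group_a, group_b, cutoff = 4.0,
                               include_het = FALSE) {
  if (length(intersect(group_a, group_b)) > 0L) {
    stopf("chain groups overlap: %s",
          paste(intersect(group_a, group_b), collapse = ","))
  }
  A <- select_group(atoms, group_a, include_het)
  B <- select_group(atoms, group_b, include_het)
  if (nrow(A) == 0L || nrow(B) == 0L) stopf("empty chain group")
  xa <- cbind(A$x, A$y, A$z); xb <- cbind(B$x, B$y, B$z)
  # all inter-group distances (groups are at most a few thousand atoms)
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  d2[d2 < 0] <- 0
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0L) {
    pairs <- data.frame(chain_a = character(0), resnum_a = integer(0),
                        resname_a = character(0), chain_b = character(0),
                        resnum_b = integer(0), resname_b = character(0),
                        min_distance = numeric(0))
  } else {
    ra <- hit[, 1L]; rb <- hit[, 2L]
    key <- paste(res_key(A)[ra], res_key(B)[rb], sep = "|")
    dmin <- tapply(sqrt(d2[hit]), key, min)
    first <- !duplicated(key)
    pairs <- data.frame(
      chain_a = A$chain_id[ra][first],
      resnum_a = A$residue_number[ra][first],
      resname_a = A$residue_name[ra][first],
      chain_b = B$chain_id[rb][first],
      resnum_b = B$residue_number[rb][first],
      resname_b = B$residue_name[rb][first],
      min_distance = as.numeric(dmin[key[first]])
    )
    pairs <- pairs[order(pairs$chain_a, pairs$resnum_a,
                         pairs$chain_b, pairs$resnum_b), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  uniq <- function(ch, rn, rs) {
    df <- unique(data.frame(chain = ch, resnum = rn, resname = rs))
    df <- df[order(df$chain, df$resnum), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  structure(list(
    pairs = pairs,
    residues_a = uniq(pairs$chain_a, pairs$resnum_a, pairs$resname_a),
    residues_b = uniq(pairs$chain_b, pairs$resnum_b, pairs$resname_b),
    cutoff = cutoff
  ), class = "contact_report")
}

# deterministic quasi-uniform points on the unit sphere (Fibonacci lattice)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Numerical SASA by sampling points on each atom's solvent-expanded
#' sphere (van der Waals radius + probe radius) and counting those not
#' buried inside any neighbouring atom's expanded sphere. Standard element
#' radii: C 1.70, N 1.55, O 1.52, S 1.80 Angstrom; unknown elements fall
#' back to 1.70 with a warning. Hydrogens are ignored.
#'
#' @param atoms A `pdb_atoms` table (or any data frame with `x`, `y`, `z`,
#'   `element`, `chain_id`, `residue_number`, `insertion_code`,
#'   `residue_name` columns).
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param n_points Sphere sample points per atom (default 960).
#' @return List with `atom_sasa` (numeric, one per atom, Angstrom^2) and
#'   `residue_sasa` (data frame `chain`, `resnum`, `resname`, `sasa`).
#' @export
shrake_rupley_sasa <- function(atoms, probe = 1.4, n_points = 960L) {
  atoms <- atoms[atoms$element != "H", , drop = FALSE]
  n <- nrow(atoms)
  if (n == 0L) stopf("no heavy atoms")
  r <- atom_radii(atoms) + probe
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  pts <- sphere_points(n_points)
  # neighbour candidates: centre distance below the sum of expanded radii
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
  d2[d2 < 0] <- 0
  rsum2 <- outer(r, r, "+")^2
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < rsum2[i, ] & seq_len(n) != i)
    area_i <- 4 * pi * r[i]^2
    if (length(nb) == 0L) { sasa[i] <- area_i; next }
    p <- sweep(pts * r[i], 2, xyz[i, ], "+")       # points on sphere i
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj2 <- (p[exposed, 1L] - xyz[j, 1L])^2 +
        (p[exposed, 2L] - xyz[j, 2L])^2 +
        (p[exposed, 3L] - xyz[j, 3L])^2
      exposed[exposed] <- dj2 >= r[j]^2
    }
    sasa[i] <- area_i * sum(exposed) / n_points
  }
  key <- res_key(atoms)
  per_res <- tapply(sasa, key, sum)
  first <- !duplicated(key)
  residue_sasa <- data.frame(
    chain = atoms$chain_id[first],
    resnum = atoms$residue_number[first],
    resname = atoms$residue_name[first],
    sasa = as.numeric(per_res[key[first]])
  )
  rownames(residue_sasa) <- NULL
  list(atom_sasa = sasa, residue_sasa = residue_sasa)
}

#' Per-residue change in solvent accessibility upon binding
#'
#' SASA of the target chains computed in isolation (apo) and within the
#' complex (bound); `delta = SASA_bound - SASA_apo`, so interface burial
#' gives negative values. Only residues with `delta < 0` are reported.
#'
#' @param complex_atoms `pdb_atoms` of the complex.
#' @param target_chains Chain ids whose residues are reported.
#' @param apo_atoms Optional `pdb_atoms` of a separate apo structure; by
#'   default the target chains extracted from the complex serve as apo.
#'   When given, residues are matched by sequence alignment of the
#'   C-alpha traces.
#' @param probe,n_points Passed to [shrake_rupley_sasa()].
#' @param include_het Include HETATM residues in the environments
#'   (default `FALSE`).
#' @return Object of class `sasa_report`: data frame `chain`, `resnum`,
#'   `resname`, `sasa_apo`, `sasa_bound`, `delta` restricted to
#'   `delta < 0`, with the full table in attribute `all`.
#' @export
delta_sasa_report <- function(complex_atoms, target_chains, apo_atoms = NULL,
                              probe = 1.4, n_points = 960L,
                              include_het = FALSE) {
  tgt <- select_group(complex_atoms, target_chains, include_het)
  if (nrow(tgt) == 0L) stopf("no atoms on target chains")
  env <- complex_atoms[complex_atoms$element != "H", , drop = FALSE]
  if (!include_het) env <- env[!env$hetatm, , drop = FALSE]

  bound <- shrake_rupley_sasa(env, probe, n_points)
  in_tgt <- res_key(env) %in% res_key(tgt)
  bound_res <- bound$residue_sasa[bound$residue_sasa$chain %in% target_chains, ,
                                  drop = FALSE]

  if (is.null(apo_atoms)) {
    apo <- shrake_rupley_sasa(tgt, probe, n_points)$residue_sasa
  } else {
    apo_sel <- apo_atoms[apo_atoms$element != "H" & !apo_atoms$hetatm, ,
                         drop = FALSE]
    apo <- shrake_rupley_sasa(apo_sel, probe, n_points)$residue_sasa
    # map apo residues onto complex target residues by trace alignment
    ta <- extract_calpha_trace(apo_atoms)
    tb <- extract_calpha_trace(complex_atoms, chain = target_chains)
    mp <- map_common_residues(ta, tb, min_pairs = 3L)
    ka <- paste(ta$chain_id[mp$pairs[, 1L]], ta$residue_number[mp$pairs[, 1L]],
                sep = ":")
    akey <- paste(apo$chain, apo$resnum, sep = ":")
    apo <- apo[match(ka, akey), , drop = FALSE]
    # re-key apo residues in the complex's numbering
    apo$chain <- tb$chain_id[mp$pairs[, 2L]]
    apo$resnum <- tb$residue_number[mp$pairs[, 2L]]
    apo <- apo[!is.na(apo$sasa), , drop = FALSE]
  }

  bkey <- paste(bound_res$chain, bound_res$resnum, sep = ":")
  akey <- paste(apo$chain, apo$resnum, sep = ":")
  common <- intersect(bkey, akey)
  bi <- match(common, bkey); ai <- match(common, akey)
  all_tab <- data.frame(
    chain = bound_res$chain[bi],
    resnum = bound_res$resnum[bi],
    resname = bound_res$resname[bi],
    sasa_apo = apo$sasa[ai],
    sasa_bound = bound_res$sasa[bi]
  )
  all_tab$delta <- all_tab$sasa_bound - all_tab$sasa_apo
  all_tab <- all_tab[order(all_tab$chain, all_tab$resnum), , drop = FALSE]
  rownames(all_tab) <- NULL
  out <- all_tab[all_tab$delta < -1e-9, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, all = all_tab, class = c("sasa_report", class(out)))
}

BASIC_SIDE_N <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                     HIS = c("ND1", "NE2"))
ACIDIC_SIDE_O <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

#' Interfacial salt bridges
#'
#' Pairs where a side-chain nitrogen of Lys/Arg/His in one chain group
#' lies within the cutoff of a side-chain carboxylate oxygen of Asp/Glu in
#' the other group (either orientation). Backbone atoms never qualify.
#'
#' @inheritParams interface_contacts
#' @return Data frame `chain_a`, `resnum_a`, `resname_a`, `atom_a`,
#'   `chain_b`, `resnum_b`, `resname_b`, `atom_b`, `distance`.
#' @export
salt_bridges <- function(atoms, group_a, group_b, cutoff = 4.0) {
  if (length(intersect(group_a, group_b)) > 0L) stopf("chain groups overlap")
  pick <- function(sub, spec) {
    keep <- rep(FALSE, nrow(sub))
    for (rn in names(spec)) {
      keep <- keep | (sub$residue_name == rn & sub$atom_name %in% spec[[rn]])
    }
    sub[keep & !sub$hetatm, , drop = FALSE]
  }
  one_direction <- function(ga, gb) {
    basic <- pick(atoms[atoms$chain_id %in% ga, , drop = FALSE], BASIC_SIDE_N)
    acid <- pick(atoms[atoms$chain_id %in% gb, , drop = FALSE], ACIDIC_SIDE_O)
    if (nrow(basic) == 0L || nrow(acid) == 0L) return(NULL)
    xa <- cbind(basic$x, basic$y, basic$z)
    xb <- cbind(acid$x, acid$y, acid$z)
    d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
    hit <- which(d2 < cutoff^2, arr.ind = TRUE)
    if (nrow(hit) == 0L) return(NULL)
    data.frame(
      chain_a = basic$chain_id[hit[, 1L]],
      resnum_a = basic$residue_number[hit[, 1L]],
      resname_a = basic$residue_name[hit[, 1L]],
      atom_a = basic$atom_name[hit[, 1L]],
      chain_b = acid$chain_id[hit[, 2L]],
      resnum_b = acid$residue_number[hit[, 2L]],
      resname_b = acid$residue_name[hit[, 2L]],
      atom_b = acid$atom_name[hit[, 2L]],
      distance = sqrt(pmax(d2[hit], 0))
    )
  }
  fwd <- one_direction(group_a, group_b)
  rev_ <- one_direction(group_b, group_a)
  if (!is.null(rev_)) {
    # report with group_a first for a stable orientation
    rev_ <- data.frame(
      chain_a = rev_$chain_b, resnum_a = rev_$resnum_b,
      resname_a = rev_$resname_b, atom_a = rev_$atom_b,
      chain_b = rev_$chain_a, resnum_b = rev_$resnum_a,
      resname_b = rev_$resname_a, atom_b = rev_$atom_a,
      distance = rev_$distance
    )
    # note: orientation flip may not map chain_a into group_a if acidic
    # residues sit on group_a; the flip above restores that convention
    rev_ <- rev_[rev_$chain_a %in% group_a, , drop = FALSE]
  }
  out <- rbind(fwd, rev_)
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(chain_a = character(0), resnum_a = integer(0),
                      resname_a = character(0), atom_a = character(0),
                      chain_b = character(0), resnum_b = integer(0),
                      resname_b = character(0), atom_b = character(0),
                      distance = numeric(0)))
  }
  out <- unique(out)
  out <- out[order(out$chain_a, out$resnum_a, out$resnum_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a contact report as TSV
#' @param report A `contact_report`.
#' @param path Output path.
#' @export
write_contacts_tsv <- function(report, path) {
  utils::write.table(report$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
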