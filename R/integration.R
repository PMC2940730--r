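# Integration of dynamics and evolution outputs: subdomain annotation,
# bound-vs-unbound mobility change, mobility-vs-conservation coupling, and
# the end-to-end pipeline.

#' Hsc70 ATPase-domain annotation
#'
#' Subdomain ranges, nucleotide-binding residues and the secondary
#' structure elements of the NEF-binding surface, all in the author
#' numbering of the unbound bovine Hsc70 ATPase domain (PDB 1HPM), the
#' canonical coordinate system for every report.
#'
#' @return List with `subdomains` (named list of 2-column start/end
#'   matrices: IA = 1-39 and 116-188, IB = 40-115, IIA = 189-228 and
#'   307-385, IIB = 229-306), `nucleotide_binding` (integer residue set),
#'   and `secondary_structure` (data frame `element`, `start`, `end`,
#'   `subdomain`).
#' @export
hsc70_annotation <- function() {
  list(
    subdomains = list(
      IA = rbind(c(1L, 39L), c(116L, 188L)),
      IB = rbind(c(40L, 115L)),
      IIA = rbind(c(189L, 228L), c(307L, 385L)),
      IIB = rbind(c(229L, 306L))
    ),
    nucleotide_binding = c(12:15, 201:203, 230L, 231L, 268L, 271L, 272L,
                           275L, 338:340, 342L, 343L, 366L),
    secondary_structure = data.frame(
      element = c("helix8", "helix9", "sheetE_strand1", "sheetE_strand2"),
      start = c(230L, 257L, 279L, 293L),
      end = c(249L, 275L, 284L, 298L),
      subdomain = c("IIB", "IIB", "IIB", "IIB")
    )
  )
}

#' Assign subdomain labels to residues
#'
#' @param residue_numbers Integer residue numbers (1HPM numbering), or a
#'   `calpha_trace` whose `residue_number` column is used.
#' @param annotation Annotation list (default [hsc70_annotation()]).
#' @return Character vector of labels (`"IA"`, `"IB"`, `"IIA"`, `"IIB"` or
#'   `"unassigned"`).
#' @export
assign_subdomains <- function(residue_numbers, annotation = hsc70_annotation()) {
  if (inherits(residue_numbers, "calpha_trace")) {
    residue_numbers <- residue_numbers$residue_number
  }
  out <- rep("unassigned", length(residue_numbers))
  for (sd in names(annotation$subdomains)) {
    rngs <- annotation$subdomains[[sd]]
    for (r in seq_len(nrow(rngs))) {
      hit <- residue_numbers >= rngs[r, 1L] & residue_numbers <= rngs[r, 2L]
      out[hit] <- sd
    }
  }
  out
}

#' Mobility change upon binding
#'
#' Difference of two mobility profiles over their common residues. Both
#' profiles are renormalized to unit sum over the common set, so the
#' differences sum to zero: mobility lost by one region is gained
#' elsewhere.
#'
#' @param bound_profile,free_profile `mobility_profile` objects or numeric
#'   vectors.
#' @param map Optional `residue_map` pairing free indices (column 1) with
#'   bound indices (column 2); default assumes identical residue sets.
#' @return Numeric vector `delta = M_bound - M_free` over the common
#'   residues (ordered as the free profile's mapped residues).
#' @export
mobility_change <- function(bound_profile, free_profile, map = NULL) {
  vb <- if (inherits(bound_profile, "mobility_profile")) bound_profile$values else as.numeric(bound_profile)
  vf <- if (inherits(free_profile, "mobility_profile")) free_profile$values else as.numeric(free_profile)
  if (is.null(map)) {
    if (length(vb) != length(vf)) {
      stopf("profiles differ in length (%d vs %d) and no map given",
            length(vb), length(vf))
    }
    ib <- seq_along(vb); if_ <- seq_along(vf)
  } else {
    if_ <- map$pairs[, 1L]; ib <- map$pairs[, 2L]
  }
  b <- vb[ib] / sum(vb[ib])
  f <- vf[if_] / sum(vf[if_])
  b - f
}

#' Average mobility per conservation rank
#'
#' Groups residues by ET rank, reports the mean mobility, its standard
#' error (sd / sqrt(count)) and the residue count per rank, fits a
#' second-order polynomial to mean-vs-rank by least squares, and gives the
#' Pearson correlation between fitted and observed means. A decreasing
#' curve quantifies the coupling between conservation and restricted
#' mobility.
#'
#' @param profile A `mobility_profile` (or numeric vector), one value per
#'   residue/column.
#' @param ranks An `et_result` or integer vector of the same length.
#' @return Object of class `rank_mobility_curve`: list with `table`
#'   (data frame `rank`, `mean`, `se`, `n`), `fit` (named quadratic
#'   coefficients), `correlation`.
#' @export
mobility_vs_rank <- function(profile, ranks) {
  v <- if (inherits(profile, "mobility_profile")) profile$values else as.numeric(profile)
  r <- if (inherits(ranks, "et_result")) ranks$ranks else as.integer(ranks)
  if (length(v) != length(r)) {
    stopf("profile (%d) and ranks (%d) differ in length", length(v), length(r))
  }
  spl <- split(v, r)
  tab <- data.frame(
    rank = as.integer(names(spl)),
    mean = vapply(spl, mean, numeric(1)),
    se = vapply(spl, function(x) {
      if (length(x) < 2L) 0 else stats::sd(x) / sqrt(length(x))
    }, numeric(1)),
    n = lengths(spl)
  )
  rownames(tab) <- NULL
  tab <- tab[order(tab$rank), , drop = FALSE]
  if (nrow(tab) >= 3L) {
    fit <- stats::lm(mean ~ rank + I(rank^2), data = tab)
    coefs <- stats::coef(fit)
    names(coefs) <- c("intercept", "rank", "rank2")
    fitted_means <- stats::fitted(fit)
    correlation <- if (stats::sd(tab$mean) > 0 && stats::sd(fitted_means) > 0) {
      stats::cor(tab$mean, fitted_means)
    } else 0
  } else {
    coefs <- c(intercept = mean(tab$mean), rank = 0, rank2 = 0)
    correlation <- NA_real_
  }
  structure(list(table = tab, fit = coefs, correlation = correlation),
            class = "rank_mobility_curve")
}

#' Read a flat key-value pipeline configuration
#'
#' One `key = value` pair per line; `#` comments and blank lines ignored;
#' comma-separated values become vectors; numeric-looking values are
#' converted.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stopf("bad config line: '%s'", ln)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    vals <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    nums <- suppressWarnings(as.numeric(vals))
    out[[key]] <- if (!anyNA(nums)) nums else vals
  }
  out
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the structural route (traces, elastic network models, mobility
#' profiles and change, mode-deformation overlap, interface reports) and/or
#' the sequence route (refinement, distance tree, ET ranks, MI analysis),
#' then the combined mobility-conservation product when both are present.
#' Deterministic given the config; every filter count is logged. All
#' outputs are TSV files under `config$out_dir`.
#'
#' @param config Named list (see Details) or path to a flat key-value file
#'   for [read_pipeline_config()]. Recognized keys: `free_pdb`,
#'   `free_chain`, `bound_pdb`, `bound_chain`, `nef_chains`, `msa_fasta`,
#'   `out_dir`, `gnm_cutoff` (7.3), `anm_cutoff` (13), `modes` (10),
#'   `et_levels` (20), `identity_min` (0.4), `max_gaps` (10),
#'   `mi_top_fraction` (0.01), `contact_cutoff` (4), `seed` (1),
#'   `ref_start` (6).
#' @return Invisible list of in-memory results (`free_trace`, `spectra`,
#'   `profiles`, `overlaps`, `contacts`, `msa`, `et`, `mi`, ...); the same
#'   content is written as TSV.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- function(key, default = NULL) config[[key]] %||% default
  out_dir <- cfg("out_dir", tempfile("chaperonemodes_run_"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  set.seed(as.integer(cfg("seed", 1)))
  results <- list(out_dir = out_dir)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  # ---- structural route -------------------------------------------------
  if (!is.null(cfg("free_pdb"))) {
    free_atoms <- stage("structure_io", read_pdb(cfg("free_pdb")))
    free_trace <- extract_calpha_trace(free_atoms,
                                       chain = cfg("free_chain"),
                                       structure_id = basename(cfg("free_pdb")))
    logf("free structure: %d residues", nrow(free_trace))
    gnm_free <- stage("elastic_network",
                      build_gnm(free_trace, cutoff = cfg("gnm_cutoff", 7.3)))
    anm_free <- stage("elastic_network",
                      build_anm(free_trace, cutoff = cfg("anm_cutoff", 13)))
    m <- as.integer(cfg("modes", 10))
    prof_free <- mobility_profile(gnm_free, m = m)
    utils::write.table(
      data.frame(resnum = free_trace$residue_number,
                 subdomain = assign_subdomains(free_trace),
                 mobility = prof_free$values),
      file.path(out_dir, "mobility_free.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    results$free_trace <- free_trace
    results$gnm_free <- gnm_free
    results$anm_free <- anm_free
    results$profile_free <- prof_free

    if (!is.null(cfg("bound_pdb"))) {
      bound_atoms <- stage("structure_io", read_pdb(cfg("bound_pdb")))
      bound_trace <- extract_calpha_trace(bound_atoms,
                                          chain = cfg("bound_chain"),
                                          structure_id = basename(cfg("bound_pdb")))
      map <- stage("structure_io",
                   map_common_residues(free_trace, bound_trace,
                                       min_pairs = as.integer(cfg("min_pairs", 30))))
      logf("mapped %d common residues", map$n_common)
      d <- deformation_vector(free_trace, bound_trace, map)
      logf("deformation |d| = %.2f A (superposition rmsd %.2f A)",
           d$norm, d$rmsd)
      write_deformation_tsv(d, file.path(out_dir, "deformation.tsv"))
      ov <- overlap_table(anm_free, d, m_max = as.integer(cfg("overlap_modes", 20)),
                          subset = map$pairs[, 1L])
      utils::write.table(ov, file.path(out_dir, "overlap_free.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      gnm_bound <- build_gnm(bound_trace, cutoff = cfg("gnm_cutoff", 7.3))
      prof_bound <- mobility_profile(gnm_bound, m = min(m, gnm_bound$n_modes))
      delta <- mobility_change(prof_bound, prof_free, map)
      utils::write.table(
        data.frame(resnum = free_trace$residue_number[map$pairs[, 1L]],
                   delta = delta),
        file.path(out_dir, "mobility_change.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      results$map <- map
      results$deformation <- d
      results$overlaps <- ov
      results$profile_bound <- prof_bound
      results$mobility_change <- delta

      nef <- cfg("nef_chains")
      if (!is.null(nef)) {
        contacts <- stage("interface",
                          interface_contacts(bound_atoms,
                                             group_a = cfg("bound_chain"),
                                             group_b = nef,
                                             cutoff = cfg("contact_cutoff", 4)))
        logf("interface: %d residue-residue contacts", nrow(contacts$pairs))
        write_contacts_tsv(contacts, file.path(out_dir, "contacts.tsv"))
        bridges <- salt_bridges(bound_atoms, cfg("bound_chain"), nef,
                                cutoff = cfg("contact_cutoff", 4))
        utils::write.table(bridges, file.path(out_dir, "salt_bridges.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        dsasa <- delta_sasa_report(bound_atoms,
                                   target_chains = cfg("bound_chain"),
                                   n_points = as.integer(cfg("sasa_points", 240)))
        utils::write.table(as.data.frame(dsasa),
                           file.path(out_dir, "delta_sasa.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        results$contacts <- contacts
        results$salt_bridges <- bridges
        results$delta_sasa <- dsasa
      }
    }
  }

  # ---- sequence route ---------------------------------------------------
  if (!is.null(cfg("msa_fasta"))) {
    raw <- stage("msa_pipeline", read_msa_fasta(cfg("msa_fasta")))
    logf("raw MSA: %d sequences x %d columns", length(raw$ids), raw$n_cols)
    ref <- stage("msa_pipeline",
                 refine_msa(raw, identity_min = cfg("identity_min", 0.4),
                            max_gaps = as.integer(cfg("max_gaps", 10))))
    for (i in seq_len(nrow(ref$report))) {
      logf("refine %s: %d -> %d sequences, %d columns",
           ref$report$step[i], ref$report$sequences_in[i],
           ref$report$sequences_out[i], ref$report$columns_out[i])
    }
    write_refinement_tsv(ref$report, file.path(out_dir, "refinement.tsv"))
    msa <- set_reference_numbering(ref$msa, start = as.integer(cfg("ref_start", 6)))
    tree <- stage("evolutionary_trace", build_distance_tree(msa))
    write_tree_newick(tree, file.path(out_dir, "tree.nwk"))
    et <- compute_et_ranks(msa, tree, L = as.integer(cfg("et_levels", 20)))
    write_et_tsv(et, file.path(out_dir, "et_ranks.tsv"))
    logf("ET: %d rank-1 column(s)", sum(et$ranks == 1L))
    I <- stage("coevolution", mi_matrix(msa))
    write_mi_tsv(I, file.path(out_dir, "mi_matrix.tsv"))
    pairs <- top_coevolving_pairs(I, fraction = cfg("mi_top_fraction", 0.01))
    utils::write.table(pairs, file.path(out_dir, "mi_top_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    avg <- residue_average_mi(I)
    utils::write.table(
      data.frame(column = seq_along(avg),
                 residue = msa$ref_numbering %||% seq_along(avg),
                 avg_mi = avg),
      file.path(out_dir, "mi_residue_average.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    results$msa <- msa
    results$tree <- tree
    results$et <- et
    results$mi <- I
    results$mi_top_pairs <- pairs

    # ---- combined product ----------------------------------------------
    if (!is.null(results$profile_free)) {
      trace_res <- results$free_trace$residue_number
      idx <- match(msa$ref_numbering, trace_res)
      ok <- !is.na(idx)
      logf("mobility-vs-rank: %d columns matched to structure (%d dropped)",
           sum(ok), sum(!ok))
      curve <- mobility_vs_rank(results$profile_free$values[idx[ok]],
                                et$ranks[ok])
      utils::write.table(curve$table,
                         file.path(out_dir, "mobility_vs_rank.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      results$rank_mobility <- curve
    }
  }

  logf("pipeline complete: outputs in %s", out_dir)
  invisible(results)
}
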