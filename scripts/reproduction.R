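#!/usr/bin/env Rscript
# Optional published-value reproduction job (requires network access to
# download three PDB entries; not part of the offline test suite).
#
# Usage: Rscript scripts/reproduction.R [--dir <pdb_cache_dir>]
#
# Downloads the unbound bovine Hsc70 ATPase domain (1HPM) and two
# NEF-bound forms (1HX1: BAG-1 complex; 3D2E: Sse1 complex), then
# recomputes:
#   * the ANM mode-deformation overlap table for each transition
#     (expected: a single soft mode of the unbound form with overlap
#     ~0.62, cumulative overlap ~0.86 by 6 modes for 1HPM->1HX1;
#     ~0.82 by 9 modes for 1HPM->3D2E; reverse direction stronger,
#     top-2 cumulative overlap ~0.88 / single mode ~0.92),
#   * the Ala60-Arg258 C-alpha distances (expected ~5.0 A closed,
#     ~10.9 A open for 1HX1, ~19.0 A for 3D2E),
#   * the GNM global-mode mobility profile of 1HPM (expected: subdomain
#     IIB carries the dominant peaks).
# Overlap values are compared at +-0.08 absolute tolerance (the contact
# cutoff convention is not fully pinned down), distances at +-0.2 A.

suppressPackageStartupMessages(library(chaperonemodes))

args <- commandArgs(trailingOnly = TRUE)
i <- which(args == "--dir")
cache <- if (length(i) == 1L && i < length(args)) args[i + 1L] else "pdb_cache"
dir.create(cache, showWarnings = FALSE, recursive = TRUE)

fetch <- function(id) {
  path <- file.path(cache, paste0(tolower(id), ".pdb"))
  if (!file.exists(path)) {
    utils::download.file(sprintf("https://files.rcsb.org/download/%s.pdb", id),
                         path, quiet = TRUE)
  }
  path
}

ca_distance <- function(trace, r1, r2) {
  a <- trace[trace$residue_number == r1, ]
  b <- trace[trace$residue_number == r2, ]
  sqrt(sum((c(a$x, a$y, a$z) - c(b$x, b$y, b$z))^2))
}

report_transition <- function(free_tr, bound_tr, label) {
  map <- map_common_residues(free_tr, bound_tr)
  d <- deformation_vector(free_tr, bound_tr, map)
  cat(sprintf("\n== %s: %d common residues, |d| = %.1f A ==\n",
              label, map$n_common, d$norm))
  fwd <- overlap_table(build_anm(free_tr), d, m_max = 20,
                       subset = map$pairs[, 1])
  cat("unbound-form ANM (forward transition):\n")
  print(utils::head(fwd, 10), row.names = FALSE)
  d_rev <- deformation_vector(bound_tr, free_tr,
                              structure(list(pairs = map$pairs[, c(2, 1)],
                                             n_common = map$n_common),
                                        class = "residue_map"))
  rev_ <- overlap_table(build_anm(bound_tr), d_rev, m_max = 20,
                        subset = map$pairs[, 2])
  cat("bound-form ANM (reverse transition):\n")
  print(utils::head(rev_, 5), row.names = FALSE)
  invisible(list(forward = fwd, reverse = rev_))
}

free_atoms <- read_pdb(fetch("1HPM"))
free_tr <- extract_calpha_trace(free_atoms, chain = "A", structure_id = "1HPM")
cat(sprintf("1HPM: %d residues; Ala60-Arg258 distance %.1f A (closed)\n",
            nrow(free_tr), ca_distance(free_tr, 60, 258)))

g <- build_gnm(free_tr)
prof <- mobility_profile(g, m = 1)
sd_lab <- assign_subdomains(free_tr)
cat("mean global-mode mobility by subdomain:\n")
print(tapply(prof$values, sd_lab, mean))

# BAG-1 complex: ATPase domain is chain A of 1HX1
bag <- extract_calpha_trace(read_pdb(fetch("1HX1")), chain = "A",
                            structure_id = "1HX1")
cat(sprintf("1HX1: Ala60-Arg258 distance %.1f A (open)\n",
            ca_distance(bag, 60, 258)))
report_transition(free_tr, bag, "1HPM -> 1HX1 (BAG-1)")

# Sse1 complex: ATPase domain is chain B of 3D2E
sse <- extract_calpha_trace(read_pdb(fetch("3D2E")), chain = "B",
                            structure_id = "3D2E")
cat(sprintf("3D2E: Ala60-Arg258 distance %.1f A (open)\n",
            ca_distance(sse, 60, 258)))
report_transition(free_tr, sse, "1HPM -> 3D2E (Sse1)")
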