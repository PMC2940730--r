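test_that("read_pdb parses single records literally", {
  p <- write_pdb_fixture(pdb_line(x = 1.234, y = -5.678, z = 9.1))
  atoms <- read_pdb(p)
  expect_equal(nrow(atoms), 1L)
  expect_equal(atoms$x, 1.234)
  expect_equal(atoms$y, -5.678)
  expect_equal(atoms$z, 9.1)
  expect_equal(atoms$chain_id, "A")
  expect_equal(atoms$residue_name, "ALA")
  expect_false(atoms$hetatm)
})

test_that("read_pdb handles multi-chain fixtures, HETATM flags and altlocs", {
  lines <- character(0)
  serial <- 0
  for (ch in c("A", "B")) {
    for (rn in 1:3) {
      for (at in c("N", "CA", "C", "O")) {
        serial <- serial + 1
        lines <- c(lines, pdb_line(serial = serial, name = at, chain = ch,
                                   resnum = rn, x = serial,
                                   element = substr(at, 1, 1)))
      }
    }
  }
  lines <- c(lines, pdb_line(record = "HETATM", serial = serial + 1,
                             name = "PB", resname = "ADP", chain = "A",
                             resnum = 500, element = "P"))
  atoms <- read_pdb(write_pdb_fixture(lines))
  expect_equal(nrow(atoms), 25L)
  expect_equal(as.vector(table(atoms$chain_id)[c("A", "B")]), c(13L, 12L))
  expect_equal(atoms$residue_name[atoms$hetatm], "ADP")

  # altloc: keep highest occupancy, tie prefers 'A'
  alt <- c(
    pdb_line(serial = 1, altloc = "A", x = 1, occ = 0.4),
    pdb_line(serial = 2, altloc = "B", x = 2, occ = 0.6),
    pdb_line(serial = 3, name = "CB", altloc = "A", x = 3, occ = 0.5),
    pdb_line(serial = 4, name = "CB", altloc = "B", x = 4, occ = 0.5)
  )
  a2 <- read_pdb(write_pdb_fixture(alt))
  expect_equal(nrow(a2), 2L)
  expect_equal(a2$x[a2$atom_name == "CA"], 2)  # occupancy 0.6 wins
  expect_equal(a2$x[a2$atom_name == "CB"], 3)  # tie -> altloc A
})

test_that("read_pdb error paths: missing file, absent model", {
  expect_error(read_pdb(tempfile()), "not found")
  p <- write_pdb_fixture(c("MODEL     1", pdb_line(), "ENDMDL"))
  expect_error(read_pdb(p, model = 3), "model 3 not present")
  expect_equal(nrow(read_pdb(p, model = 1)), 1L)
})

test_that("extract_calpha_trace keeps CA-bearing residues in order", {
  lines <- c(
    pdb_line(serial = 1, name = "N", resnum = 1, element = "N"),
    pdb_line(serial = 2, name = "CA", resnum = 1, x = 1),
    pdb_line(serial = 3, name = "CA", resnum = 2, x = 2),
    pdb_line(serial = 4, name = "CA", resnum = 3, x = 3)
  )
  tr <- extract_calpha_trace(read_pdb(write_pdb_fixture(lines)))
  expect_equal(nrow(tr), 3L)
  expect_equal(tr$x, c(1, 2, 3))

  # residue 2 lacking its CA is omitted with a warning
  lines2 <- lines[-3]
  lines2 <- append(lines2, pdb_line(serial = 9, name = "CB", resnum = 2), 2)
  expect_warning(tr2 <- extract_calpha_trace(read_pdb(write_pdb_fixture(lines2))),
                 "lack a CA")
  expect_equal(tr2$residue_number, c(1L, 3L))

  expect_error(extract_calpha_trace(read_pdb(write_pdb_fixture(lines)),
                                    chain = "Z"),
               "empty selection")
})

test_that("map_common_residues pairs identical and deletion-bearing traces", {
  set.seed(11)
  resnames <- sample(names(chaperonemodes:::AA3TO1)[1:20], 40, replace = TRUE)
  a <- toy_trace(matrix(rnorm(120), ncol = 3), resnames = resnames)
  m <- map_common_residues(a, a)
  expect_equal(m$n_common, 40L)
  expect_equal(m$pairs[, 1], m$pairs[, 2], ignore_attr = TRUE)

  drop <- c(5, 12, 20, 27, 33)
  b <- a[-drop, ]
  class(b) <- class(a)
  m2 <- map_common_residues(a, b)
  expect_equal(m2$n_common, 35L)
  expect_false(any(m2$pairs[, 1] %in% drop))
  # strictly increasing in both coordinates
  expect_true(all(diff(m2$pairs[, 1]) > 0))
  expect_true(all(diff(m2$pairs[, 2]) > 0))

  expect_error(map_common_residues(a, b, min_pairs = 100), "check chain")
})

test_that("kabsch_superpose recovers planted transforms and is symmetric", {
  set.seed(42)
  for (rep in 1:5) {
    ref <- matrix(rnorm(45), ncol = 3)
    R <- random_rotation()
    t <- rnorm(3, sd = 10)
    mob <- sweep(ref %*% t(R), 2, t, "+")
    tf <- kabsch_superpose(mob, ref)
    expect_lt(tf$rmsd, 1e-8)
    expect_equal(det(tf$rotation), 1, tolerance = 1e-8)
    # inverse transform recovered
    expect_equal(tf$rotation, t(R), tolerance = 1e-8)
    expect_equal(apply_transform(mob, tf), ref, tolerance = 1e-8,
                 ignore_attr = TRUE)
    # rmsd is symmetric in the two roles
    expect_equal(kabsch_superpose(ref, mob)$rmsd, tf$rmsd, tolerance = 1e-10)
  }

  ref <- matrix(rnorm(30), ncol = 3)
  expect_equal(kabsch_superpose(ref, ref)$rmsd, 0, tolerance = 1e-10)
  expect_equal(kabsch_superpose(ref, ref)$rotation, diag(3), tolerance = 1e-8)
  collinear <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(collinear, collinear), "degenerate")
})

test_that("superposed rmsd never exceeds raw rmsd, and matches the quaternion oracle", {
  set.seed(7)
  for (rep in 1:10) {
    a <- matrix(rnorm(36), ncol = 3)
    b <- a + matrix(rnorm(36, sd = runif(1, 0.1, 3)), ncol = 3)
    raw <- sqrt(mean(rowSums((a - b)^2)))
    tf <- kabsch_superpose(a, b)
    expect_lte(tf$rmsd, raw + 1e-12)
    expect_equal(tf$rmsd, horn_rmsd(a, b), tolerance = 1e-8)
  }
})

test_that("deformation_vector is zero for identity and antisymmetric in norm", {
  set.seed(3)
  a <- toy_trace(matrix(rnorm(90, sd = 5), ncol = 3))
  m <- map_common_residues(a, a, min_pairs = 3)
  d0 <- deformation_vector(a, a, m)
  expect_equal(d0$norm, 0, tolerance = 1e-10)

  b <- a
  b$x <- b$x + rnorm(30); b$y <- b$y + rnorm(30)
  dab <- deformation_vector(a, b, m)
  mba <- structure(list(pairs = m$pairs[, c(2, 1)], n_common = m$n_common),
                   class = "residue_map")
  dba <- deformation_vector(b, a, mba)
  expect_equal(dab$norm, dba$norm, tolerance = 1e-6)
  expect_equal(length(dab$d), 90L)
})

test_that("deformation norm matches a direct-subtraction oracle when no rigid motion is present", {
  # displace one residue of a large cloud: superposition is pinned by the
  # other residues, so |d| approaches the direct displacement
  set.seed(8)
  a <- toy_trace(matrix(rnorm(600, sd = 20), ncol = 3))
  b <- a
  b$x[7] <- b$x[7] + 2
  m <- map_common_residues(a, a, min_pairs = 3)
  d <- deformation_vector(a, b, m)
  direct <- sqrt(sum((trace_coords(b) - trace_coords(a))^2))
  expect_equal(direct, 2)
  expect_lte(d$norm, direct + 1e-9)      # Kabsch can only reduce it
  expect_gt(d$norm, 0.95 * direct)       # and barely does for 1/200 residues
})

test_that("PDB writer round-trips coordinates to 3 decimals", {
  set.seed(5)
  tr <- toy_trace(matrix(rnorm(60, sd = 30), ncol = 3),
                  resnames = c("ALA", "GLY", "LYS"))
  p <- tempfile(fileext = ".pdb")
  write_pdb_trace(tr, p)
  back <- extract_calpha_trace(read_pdb(p))
  expect_equal(back$x, round(tr$x, 3))
  expect_equal(back$y, round(tr$y, 3))
  expect_equal(back$z, round(tr$z, 3))
  expect_equal(back$residue_name, tr$residue_name)
})
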