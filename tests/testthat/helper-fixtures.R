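# Fixture builders and independent oracles used across the suite.

# build a calpha_trace from a coordinate matrix
toy_trace <- function(coords, resnames = "GLY", chain = "A",
                      resnum = seq_len(nrow(coords))) {
  coords <- as.matrix(coords)
  out <- data.frame(
    chain_id = chain,
    residue_number = resnum,
    insertion_code = "",
    residue_name = rep_len(resnames, nrow(coords)),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    stringsAsFactors = FALSE
  )
  class(out) <- c("calpha_trace", class(out))
  out
}

# fixed-column PDB ATOM/HETATM line
pdb_line <- function(record = "ATOM", serial = 1, name = "CA", altloc = " ",
                     resname = "ALA", chain = "A", resnum = 1, icode = " ",
                     x = 0, y = 0, z = 0, occ = 1, element = "C") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial,
          if (nchar(name) < 4) paste0(" ", name) else name,
          altloc, resname, chain, resnum, icode, x, y, z, occ, 0, element)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# a minimal atoms data frame accepted by the interface functions
toy_atoms <- function(x, y, z, element = "C", chain = "A",
                      resnum = seq_along(x), resname = "ALA",
                      atom_name = "CA", hetatm = FALSE) {
  data.frame(
    record = ifelse(hetatm, "HETATM", "ATOM"),
    serial = seq_along(x),
    atom_name = rep_len(atom_name, length(x)),
    altloc = " ",
    residue_name = rep_len(resname, length(x)),
    chain_id = rep_len(chain, length(x)),
    residue_number = rep_len(resnum, length(x)),
    insertion_code = "",
    x = x, y = y, z = z,
    occupancy = 1,
    element = rep_len(element, length(x)),
    hetatm = rep_len(hetatm, length(x)),
    stringsAsFactors = FALSE
  )
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Independent superposition oracle: Horn's closed-form quaternion method
# (a different algorithm from the SVD-based Kabsch under test)
horn_rmsd <- function(mobile, reference) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(reference, 2, colMeans(reference))
  S <- crossprod(P, Q)
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],        -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],        -S[1,1]-S[2,2]+S[3,3]
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE)$values)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lam) / nrow(P)
  sqrt(max(msd, 0))
}

# Independent Smith-Waterman oracle: Gotoh affine-gap DP where a gap of
# length L costs gap_open + L * gap_ext (the Biostrings convention)
sw_oracle <- function(a, b, submat, gap_open, gap_ext) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[a[i - 1], b[j - 1]]
      Ix[i, j] <- max(M[i - 1, j] - gap_open - gap_ext, Ix[i - 1, j] - gap_ext)
      Iy[i, j] <- max(M[i, j - 1] - gap_open - gap_ext, Iy[i, j - 1] - gap_ext)
      M[i, j] <- max(0, M[i - 1, j - 1] + s, Ix[i - 1, j - 1] + s,
                     Iy[i - 1, j - 1] + s)
      best <- max(best, M[i, j])
    }
  }
  best
}

# O(n^2) all-pairs contact oracle
contacts_oracle <- function(A, B, cutoff) {
  hits <- list()
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      d <- sqrt((A$x[i] - B$x[j])^2 + (A$y[i] - B$y[j])^2 + (A$z[i] - B$z[j])^2)
      if (d < cutoff) {
        key <- paste(A$residue_number[i], B$residue_number[j])
        hits[[key]] <- min(hits[[key]] %||% Inf, d)
      }
    }
  }
  hits
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small connected bead cloud for toy ANMs (deterministic given seed)
toy_cloud <- function(n = 10, seed = 99, box = 8) {
  set.seed(seed)
  toy_trace(matrix(runif(3 * n, 0, box), ncol = 3))
}
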