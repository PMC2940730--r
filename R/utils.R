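# Shared constants and small helpers.

# 20 standard amino acids, one-letter, alphabetical
AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# alignment alphabet: 20 amino acids + gap as the 21st symbol
AA_GAP <- c(AA1, "-")

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M", SEC = "U", PYL = "O"
)

three_to_one <- function(resnames) {
  out <- AA3TO1[toupper(resnames)]
  out[is.na(out)] <- "X"
  unname(out)
}

#' @noRd
is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# split a single aligned sequence string into a character vector of symbols
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
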