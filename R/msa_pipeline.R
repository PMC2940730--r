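# Multiple-sequence-alignment container, FASTA/Stockholm I/O, consensus,
# Smith-Waterman screening and the three-step refinement.

#' Construct an MSA view
#'
#' Rows are aligned sequences over the alphabet of the 20 amino acids plus
#' the gap character `-`; columns may carry a reference residue numbering.
#' Unknown symbols (e.g. `X`, `.`) are normalized: `.` and lower case are
#' mapped to `-`/upper case, anything outside the alphabet becomes a gap
#' with a warning.
#'
#' @param ids Character vector of sequence identifiers.
#' @param sequences Character vector of equal-length aligned sequences.
#' @param ref_numbering Optional integer vector (one per column) of
#'   reference residue numbers.
#' @return Object of class `msa_view`: list with `ids`, `mat` (character
#'   matrix, rows x columns), `n_cols`, `ref_numbering`.
#' @export
msa_view <- function(ids, sequences, ref_numbering = NULL) {
  stopifnot(length(ids) == length(sequences))
  if (anyDuplicated(ids)) stopf("duplicate sequence ids")
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L) stopf("rows differ in length")
  mat <- do.call(rbind, strsplit(toupper(sequences), "", fixed = TRUE))
  mat[mat == "."] <- "-"
  bad <- !(mat %in% AA_GAP)
  if (any(bad)) {
    warnf("%d symbol(s) outside the 21-letter alphabet replaced by gaps",
          sum(bad))
    mat[bad] <- "-"
  }
  rownames(mat) <- ids
  if (!is.null(ref_numbering)) stopifnot(length(ref_numbering) == ncol(mat))
  structure(list(ids = ids, mat = mat, n_cols = ncol(mat),
                 ref_numbering = ref_numbering),
            class = "msa_view")
}

#' @export
print.msa_view <- function(x, ...) {
  cat(sprintf("MSA: %d sequences x %d columns\n", length(x$ids), x$n_cols))
  invisible(x)
}

msa_strings <- function(msa) apply(msa$mat, 1L, paste, collapse = "")

#' Read an aligned FASTA file into an `msa_view`
#' @param path FASTA file path.
#' @return An `msa_view`.
#' @export
read_msa_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  msa_view(names(ss), as.character(ss))
}

#' Write an `msa_view` as aligned FASTA
#' @param msa An `msa_view`.
#' @param path Output path.
#' @export
write_msa_fasta <- function(msa, path) {
  con <- file(path, "wt"); on.exit(close(con))
  seqs <- msa_strings(msa)
  writeLines(paste0(">", msa$ids, "\n", seqs), con)
  invisible(path)
}

#' Read a Stockholm-format alignment into an `msa_view`
#'
#' Minimal single- or multi-block Stockholm reader: `#` annotation lines
#' are ignored, sequence lines of repeated names are concatenated across
#' blocks, `//` terminates.
#' @param path Stockholm file path.
#' @return An `msa_view`.
#' @export
read_msa_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^# STOCKHOLM", lines[1L])) {
    stopf("not a Stockholm file: %s", path)
  }
  acc <- list()
  for (ln in lines[-1L]) {
    if (grepl("^//", ln) ) break
    if (ln == "" || grepl("^#", ln)) next
    parts <- strsplit(trimws(ln), "[[:space:]]+")[[1L]]
    if (length(parts) != 2L) next
    acc[[parts[1L]]] <- paste0(acc[[parts[1L]]] %||% "", parts[2L])
  }
  if (!length(acc)) stopf("no sequences in %s", path)
  msa_view(names(acc), unlist(acc, use.names = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an `msa_view` in Stockholm format
#' @param msa An `msa_view`.
#' @param path Output path.
#' @export
write_msa_stockholm <- function(msa, path) {
  w <- max(nchar(msa$ids)) + 2L
  lines <- c("# STOCKHOLM 1.0",
             sprintf(paste0("%-", w, "s%s"), msa$ids, msa_strings(msa)),
             "//")
  writeLines(lines, path)
  invisible(path)
}

#' Majority-rule consensus sequence of an alignment
#'
#' Per column, the most frequent non-gap symbol; ties are broken
#' alphabetically; an all-gap column yields a gap.
#'
#' @param msa An `msa_view`.
#' @param count_gaps If `TRUE`, the gap is counted as a symbol, so columns
#'   where gaps dominate return `-` (used internally to flag insertion
#'   columns); ties still prefer the alphabetically first amino acid.
#' @return A single consensus string.
#' @export
consensus_sequence <- function(msa, count_gaps = FALSE) {
  stopifnot(inherits(msa, "msa_view"))
  if (length(msa$ids) == 0L) stopf("empty alignment")
  alphabet <- if (count_gaps) c(AA1, "X", "-") else c(AA1, "X")
  counts <- vapply(alphabet, function(s) colSums(msa$mat == s),
                   numeric(msa$n_cols))
  if (msa$n_cols == 1L) counts <- matrix(counts, nrow = 1L,
                                         dimnames = list(NULL, alphabet))
  pick <- apply(counts, 1L, function(cc) {
    if (all(cc == 0)) return("-")
    alphabet[which.max(cc)]   # which.max takes the first (alphabetical) on ties
  })
  paste(pick, collapse = "")
}

#' Smith-Waterman local alignment of two sequences
#'
#' Optimal local alignment under a substitution matrix with affine gap
#' penalties (defaults: BLOSUM62, gap opening 11, extension 1). Identity is
#' the fraction of identical positions over the local alignment length,
#' internal gaps included.
#'
#' @param query,target Ungapped amino-acid sequences (strings).
#' @param substitution_matrix Matrix name known to Biostrings (e.g.
#'   `"BLOSUM62"`) or a numeric matrix.
#' @param gap_opening,gap_extension Gap penalties (positive numbers).
#' @param identity_on Denominator of the identity fraction: the local
#'   `"alignment"` length including internal gaps (default), the full
#'   `"target"` length, or the `"shorter"` of the two input sequences.
#' @return List of class `alignment_result`: `score`, `identity`,
#'   `aligned_query`, `aligned_target`, `pairs` (2-column matrix of aligned
#'   ungapped positions).
#' @export
smith_waterman <- function(query, target, substitution_matrix = "BLOSUM62",
                           gap_opening = 11, gap_extension = 1,
                           identity_on = c("alignment", "target", "shorter")) {
  identity_on <- match.arg(identity_on)
  if (!nzchar(query) || !nzchar(target)) stopf("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(target),
    type = "local", substitutionMatrix = substitution_matrix,
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  score <- as.numeric(Biostrings::score(aln))
  if (score <= 0) {
    return(structure(list(score = 0, identity = 0, aligned_query = "",
                          aligned_target = "",
                          pairs = matrix(integer(0), ncol = 2L)),
                     class = "alignment_result"))
  }
  aq <- as.character(Biostrings::alignedPattern(aln))
  at <- as.character(Biostrings::alignedSubject(aln))
  ca <- chars(aq); cb <- chars(at)
  len <- switch(identity_on,
                alignment = length(ca),
                target = nchar(target),
                shorter = min(nchar(query), nchar(target)))
  ident <- sum(ca == cb & ca != "-") / len
  qa <- cumsum(ca != "-") + Biostrings::start(Biostrings::pattern(aln)) - 1L
  ta <- cumsum(cb != "-") + Biostrings::start(Biostrings::subject(aln)) - 1L
  both <- ca != "-" & cb != "-"
  structure(list(score = score, identity = ident,
                 aligned_query = aq, aligned_target = at,
                 pairs = cbind(query_pos = qa[both], target_pos = ta[both])),
            class = "alignment_result")
}

#' Three-step refinement of a raw family alignment
#'
#' Reproduces the refinement used to distil a family alignment down to the
#' columns of a reference domain consensus:
#' (i) each sequence (degapped) is aligned to the consensus by
#' Smith-Waterman and dropped if its identity falls below `identity_min`;
#' (ii) columns that are insertions with respect to the consensus are
#' deleted, leaving exactly `nchar(consensus)` columns;
#' (iii) remaining sequences with more than `max_gaps` gap characters are
#' removed.
#'
#' Insertion columns are those where the alignment's gapped majority row
#' (gap counted as a symbol) carries a gap; alternatively a gapped
#' consensus row of length `n_cols` can be passed and its gap positions are
#' used directly.
#'
#' @param raw An `msa_view`.
#' @param consensus Consensus string (ungapped, or gapped of length
#'   `n_cols`). Default: computed from `raw` by [consensus_sequence()].
#' @param identity_min Identity threshold for step (i) (default 0.40).
#' @param max_gaps Maximum tolerated gaps per retained sequence (default 10).
#' @param iterate If `TRUE`, the consensus is re-estimated from the
#'   retained set and the screen repeated until the set is stable.
#' @param ... Passed to [smith_waterman()] (scoring scheme).
#' @return List with `msa` (refined `msa_view`) and `report` (data frame:
#'   step, sequences_in, sequences_out, columns_out).
#' @export
refine_msa <- function(raw, consensus = NULL, identity_min = 0.40,
                       max_gaps = 10L, iterate = FALSE, ...) {
  stopifnot(inherits(raw, "msa_view"))
  gapped_cons <- NULL
  if (is.null(consensus)) {
    gapped_cons <- consensus_sequence(raw, count_gaps = TRUE)
    consensus <- gsub("-", "", gapped_cons, fixed = TRUE)
  } else if (nchar(consensus) == raw$n_cols && grepl("-", consensus, fixed = TRUE)) {
    gapped_cons <- consensus
    consensus <- gsub("-", "", consensus, fixed = TRUE)
  }
  if (nchar(consensus) > raw$n_cols) {
    stopf("consensus longer than the alignment (%d > %d)",
          nchar(consensus), raw$n_cols)
  }

  repeat {
    n0 <- length(raw$ids)
    # (i) identity screen against the consensus
    idents <- vapply(msa_strings(raw), function(s) {
      s <- gsub("-", "", s, fixed = TRUE)
      if (!nzchar(s)) return(0)
      smith_waterman(s, consensus, ...)$identity
    }, numeric(1))
    keep1 <- idents >= identity_min
    msa1 <- subset_msa(raw, rows = which(keep1))
    if (length(msa1$ids) == 0L) stopf("identity screen removed every sequence")

    # (ii) delete insertion columns relative to the consensus
    gc <- gapped_cons %||% consensus_sequence(msa1, count_gaps = TRUE)
    ins <- which(chars(gc) == "-")
    msa2 <- subset_msa(msa1, cols = setdiff(seq_len(msa1$n_cols), ins))
    if (msa2$n_cols != nchar(consensus)) {
      warnf("column projection left %d columns; consensus has %d",
            msa2$n_cols, nchar(consensus))
    }

    # (iii) gap-count screen
    gap_counts <- rowSums(msa2$mat == "-")
    keep3 <- gap_counts <= max_gaps
    msa3 <- subset_msa(msa2, rows = which(keep3))
    if (length(msa3$ids) == 0L) stopf("gap screen removed every sequence")

    report <- data.frame(
      step = c("identity_screen", "column_projection", "gap_screen"),
      sequences_in = c(n0, length(msa1$ids), length(msa2$ids)),
      sequences_out = c(length(msa1$ids), length(msa2$ids), length(msa3$ids)),
      columns_out = c(msa1$n_cols, msa2$n_cols, msa3$n_cols)
    )
    if (!iterate || identical(sort(msa3$ids), sort(raw$ids))) {
      return(list(msa = msa3, report = report))
    }
    # re-estimate the consensus from the survivors and rescreen the survivors
    raw <- msa3
    gapped_cons <- NULL
    consensus <- gsub("-", "", consensus_sequence(raw, count_gaps = TRUE),
                      fixed = TRUE)
  }
}

#' Subset an MSA by rows and/or columns
#' @param msa An `msa_view`.
#' @param rows,cols Integer indices to keep (default: all).
#' @return An `msa_view`.
#' @export
subset_msa <- function(msa, rows = NULL, cols = NULL) {
  rows <- rows %||% seq_along(msa$ids)
  cols <- cols %||% seq_len(msa$n_cols)
  mat <- msa$mat[rows, cols, drop = FALSE]
  structure(list(ids = msa$ids[rows], mat = mat, n_cols = ncol(mat),
                 ref_numbering = msa$ref_numbering[cols]),
            class = "msa_view")
}

#' Attach reference residue numbering to MSA columns
#'
#' After refinement the columns correspond to consecutive residues of the
#' reference domain; by convention column 1 maps to Hsc70 residue 6 for the
#' 380-column Hsp70 ATPase-domain alignment.
#'
#' @param msa An `msa_view`.
#' @param start First reference residue number (default 6).
#' @return The `msa_view` with `ref_numbering` set.
#' @export
set_reference_numbering <- function(msa, start = 6L) {
  msa$ref_numbering <- seq.int(start, length.out = msa$n_cols)
  msa
}

#' Write a refinement report as TSV
#' @param report Report data frame from [refine_msa()].
#' @param path Output path.
#' @export
write_refinement_tsv <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
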