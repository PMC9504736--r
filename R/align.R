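#' Extract the one-letter sequence of a pocket
#'
#' 3-letter codes are mapped to one-letter codes; unknown residues become
#' `X`. Residue numbers absent from the coordinates are omitted (with a
#' warning), so the sequence length equals the number of resolved residues.
#'
#' @param pocket a `pocket_model`.
#' @return object of class `pocket_sequence`: list with `seq` (string),
#'   `resnums` (author numbers per position), `chain` and `offset` (first
#'   author number).
#' @export
pocket_sequence <- function(pocket) {
  stopifnot(nrow(pocket$residues) > 0)
  if (length(pocket$missing)) {
    warning("pocket is missing residue number(s): ",
            paste(pocket$missing, collapse = ", "),
            "; they are omitted from the sequence")
  }
  one <- .aa_321[toupper(pocket$residues$resname)]
  one[is.na(one)] <- "X"
  structure(
    list(seq = paste(one, collapse = ""),
         resnums = pocket$residues$resnum,
         chain = pocket$chain, offset = pocket$start),
    class = "pocket_sequence"
  )
}

#' @export
print.pocket_sequence <- function(x, ...) {
  cat("pocket_sequence (", nchar(x$seq), " aa, chain ", x$chain,
      ", from ", x$offset, "):\n", sep = "")
  cat(strwrap(x$seq, 60), sep = "\n")
  invisible(x)
}

as_seq_string <- function(x) {
  if (inherits(x, "pocket_sequence")) x$seq
  else if (is.character(x) && length(x) == 1L) x
  else stop("expected a pocket_sequence or a single string")
}

#' Global pairwise alignment of two pocket sequences
#'
#' Needleman-Wunsch global alignment with affine gap penalties (a gap of
#' length L costs `gap_open + L * gap_extend`), computed with
#' [Biostrings::pairwiseAlignment()]. Defaults (BLOSUM62, open 10,
#' extend 0.5) are the conventional protein settings. The result carries a
#' Clustal-style conservation line and the percent identity.
#'
#' @param a,b `pocket_sequence` objects or plain strings.
#' @param matrix substitution matrix name (a Biostrings data set, e.g.
#'   `"BLOSUM62"`) or a numeric matrix.
#' @param gap_open,gap_extend affine gap penalties (positive).
#' @param denominator identity denominator mode, see [identity_percent()].
#' @return object of class `pocket_alignment`: list with `aligned_a`,
#'   `aligned_b` (equal-length gapped strings), `conservation`, `score`,
#'   `identity` and the parameters used.
#' @examples
#' al <- align_sequences("ACDE", "ACE")
#' al$aligned_a
#' @export
align_sequences <- function(a, b, matrix = "BLOSUM62",
                            gap_open = 10, gap_extend = 0.5,
                            denominator = c("shorter_sequence_length",
                                            "alignment_length")) {
  denominator <- match.arg(denominator)
  sa <- as_seq_string(a)
  sb <- as_seq_string(b)
  stopifnot(nchar(sa) > 0, nchar(sb) > 0)
  if (is.character(matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    matrix <- get(matrix, envir = e)
  }
  pa <- Biostrings::pairwiseAlignment(
    pattern = sa, subject = sb, type = "global",
    substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  ga <- as.character(Biostrings::alignedPattern(pa))
  gb <- as.character(Biostrings::alignedSubject(pa))
  out <- structure(
    list(aligned_a = ga, aligned_b = gb,
         conservation = conservation_line(ga, gb),
         score = Biostrings::score(pa),
         identity = NA_real_,
         params = list(gap_open = gap_open, gap_extend = gap_extend,
                       denominator = denominator),
         n_a = nchar(sa), n_b = nchar(sb)),
    class = "pocket_alignment"
  )
  out$identity <- identity_percent(out, denominator)
  out
}

## Clustal conservation groups
.strong_groups <- c("STA", "NEQK", "NHQK", "NDEQ", "QHRK", "MILV",
                    "MILF", "HY", "FYW")
.weak_groups <- c("CSA", "ATV", "SAG", "STNK", "STPA", "SGND", "SDEQN",
                  "NDEQHK", "NEQHRK", "FVLIM", "HFY")

#' Clustal-style conservation line
#'
#' Per column: `*` for identity, `:` when both residues fall in one of the
#' Clustal strong groups, `.` for a weak group, and a space otherwise or at
#' gaps.
#'
#' @param a,b equal-length gapped strings, or a `pocket_alignment` as `a`.
#' @param strong,weak character vectors of residue groups (each group one
#'   string of one-letter codes).
#' @return string of the alignment length over `* : .` and space.
#' @export
conservation_line <- function(a, b = NULL, strong = .strong_groups,
                              weak = .weak_groups) {
  if (inherits(a, "pocket_alignment")) {
    b <- a$aligned_b
    a <- a$aligned_a
  }
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  in_group <- function(x, y, groups) {
    any(vapply(groups, function(g) {
      grepl(x, g, fixed = TRUE) && grepl(y, g, fixed = TRUE)
    }, logical(1)))
  }
  vapply(seq_along(ca), function(i) {
    x <- ca[i]; y <- cb[i]
    if (x == "-" || y == "-") return(" ")
    if (x == y) return("*")
    if (in_group(x, y, strong)) return(":")
    if (in_group(x, y, weak)) return(".")
    " "
  }, character(1)) |> paste(collapse = "")
}

#' Percent identity of an alignment
#'
#' `100 x` identical columns divided by the chosen denominator. The default
#' denominator is the shorter input sequence length, the convention that is
#' robust to end gaps; `"alignment_length"` divides by the gapped length.
#'
#' @param alignment a `pocket_alignment`.
#' @param denominator `"shorter_sequence_length"` or `"alignment_length"`.
#' @return percentage in `[0, 100]`.
#' @export
identity_percent <- function(alignment,
                             denominator = c("shorter_sequence_length",
                                             "alignment_length")) {
  denominator <- match.arg(denominator)
  ca <- strsplit(alignment$aligned_a, "")[[1]]
  cb <- strsplit(alignment$aligned_b, "")[[1]]
  ident <- sum(ca == cb & ca != "-")
  den <- switch(denominator,
    shorter_sequence_length = min(alignment$n_a, alignment$n_b),
    alignment_length = length(ca)
  )
  100 * ident / den
}

#' @export
print.pocket_alignment <- function(x, width = 60, ...) {
  cat(sprintf("pocket_alignment: score %.1f, identity %.1f%%\n",
              x$score, x$identity))
  n <- nchar(x$aligned_a)
  for (s in seq(1, n, by = width)) {
    e <- min(s + width - 1, n)
    cat("a  ", substr(x$aligned_a, s, e), "\n", sep = "")
    cat("b  ", substr(x$aligned_b, s, e), "\n", sep = "")
    cat("   ", substr(x$conservation, s, e), "\n\n", sep = "")
  }
  invisible(x)
}

#' Write an alignment in Clustal ALN format
#'
#' 60-column blocks with the conservation line under each block.
#'
#' @param alignment a `pocket_alignment`.
#' @param file output path.
#' @param names two sequence names.
#' @param width block width.
#' @return the path, invisibly.
#' @export
write_clustal <- function(alignment, file, names = c("seq_a", "seq_b"),
                          width = 60) {
  pad <- max(nchar(names)) + 3L
  fmt <- paste0("%-", pad, "s%s")
  lines <- c("CLUSTAL format alignment (pocketprofiler)", "")
  n <- nchar(alignment$aligned_a)
  for (s in seq(1, n, by = width)) {
    e <- min(s + width - 1, n)
    lines <- c(lines,
      sprintf(fmt, names[1], substr(alignment$aligned_a, s, e)),
      sprintf(fmt, names[2], substr(alignment$aligned_b, s, e)),
      sprintf(fmt, "", substr(alignment$conservation, s, e)), "")
  }
  writeLines(lines, file)
  invisible(file)
}

#' Read sequences from a FASTA file
#'
#' @param file path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(file) {
  s <- Biostrings::readAAStringSet(file)
  stats::setNames(as.character(s), names(s))
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector (or `pocket_sequence` objects in a
#'   list) to write.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, file) {
  if (is.list(seqs)) {
    seqs <- vapply(seqs, as_seq_string, character(1))
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    names(seqs) <- paste0("seq_", seq_along(seqs))
  }
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), file)
  invisible(file)
}
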