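# Stretcher-style global pairwise protein alignment with percent identity and
# percent similarity, as used to compare receptor M4 segments. The optimal
# affine-gap alignment is computed by Biostrings::pairwiseAlignment; the gap
# convention and the identity/similarity statistics are defined here.

.aa_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                  "M", "F", "P", "S", "T", "W", "Y", "V", "B", "Z", "X")

.check_protein <- function(seq, what) {
  ch <- strsplit(toupper(seq), "")[[1]]
  if (length(ch) == 0)
    stop_gd("%s sequence is empty", what, class = "groovedock_value_error")
  bad <- which(!ch %in% .aa_alphabet)
  if (length(bad) > 0)
    stop_gd("invalid residue '%s' at position %d of %s", ch[bad[1]], bad[1], what,
            class = "groovedock_value_error")
  paste(ch, collapse = "")
}

# substitution matrix with the X row/column zeroed (X scores 0 against all)
.sub_matrix <- function(matrix = "BLOSUM62") {
  if (is.matrix(matrix)) return(matrix)
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  M <- get(matrix, envir = e)
  if ("X" %in% rownames(M)) { M["X", ] <- 0L; M[, "X"] <- 0L }
  M
}

#' Global pairwise protein alignment with affine gap penalties
#'
#' Optimal Needleman-Wunsch global alignment with affine gaps and penalized
#' end gaps, in the convention of the EMBOSS global aligners: opening a gap
#' costs `gap_open` and each further gapped column `gap_extend` (so a gap of
#' length L costs `gap_open + (L-1) * gap_extend`).
#'
#' @param a,b protein sequences (strings; standard amino-acid alphabet, X
#'   allowed and scoring 0 against everything).
#' @param matrix substitution matrix name from \pkg{Biostrings} (default
#'   "BLOSUM62") or a scoring matrix.
#' @param gap_open cost of the first column of a gap.
#' @param gap_extend cost of each further gapped column.
#' @return object of class `alignment_result`: `aligned_a`, `aligned_b`
#'   (equal-length strings with '-' gaps), `score`, `identity_pct`,
#'   `similarity_pct`, `gaps` (gap-column count).
#' @export
global_align <- function(a, b, matrix = "BLOSUM62", gap_open = 12, gap_extend = 2) {
  a <- .check_protein(a, "first"); b <- .check_protein(b, "second")
  M <- .sub_matrix(matrix)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = M, gapOpening = gap_open - gap_extend,
    gapExtension = gap_extend, type = "global")
  al_a <- as.character(Biostrings::alignedPattern(pa))
  al_b <- as.character(Biostrings::alignedSubject(pa))
  res <- structure(list(aligned_a = al_a, aligned_b = al_b,
                        score = Biostrings::score(pa),
                        matrix = if (is.matrix(matrix)) "custom" else matrix,
                        gap_open = gap_open, gap_extend = gap_extend),
                   class = "alignment_result")
  ids <- identity_similarity(res, M)
  res$identity_pct <- ids[["identity_pct"]]
  res$similarity_pct <- ids[["similarity_pct"]]
  ca <- strsplit(al_a, "")[[1]]; cb <- strsplit(al_b, "")[[1]]
  res$gaps <- sum(ca == "-" | cb == "-")
  res
}

#' Percent identity and similarity of an alignment
#'
#' Identity: identical residue columns over the full alignment length (gap
#' columns count in the denominator only). Similarity: columns whose residue
#' pair scores > 0 in the substitution matrix, identical columns included.
#'
#' @param r an `alignment_result` (or any list with `aligned_a`, `aligned_b`).
#' @param matrix substitution matrix or its \pkg{Biostrings} name.
#' @return named vector c(identity_pct, similarity_pct).
#' @export
identity_similarity <- function(r, matrix = "BLOSUM62") {
  M <- .sub_matrix(matrix)
  ca <- strsplit(r$aligned_a, "")[[1]]
  cb <- strsplit(r$aligned_b, "")[[1]]
  if (length(ca) != length(cb))
    stop_gd("aligned strings differ in length", class = "groovedock_value_error")
  len <- length(ca)
  res_col <- ca != "-" & cb != "-"
  ident <- res_col & ca == cb
  pos <- res_col
  pos[res_col] <- M[cbind(ca[res_col], cb[res_col])] > 0
  simil <- pos | ident
  c(identity_pct = 100 * sum(ident) / len,
    similarity_pct = 100 * sum(simil) / len)
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> score %.1f (%s, open %g extend %g)\n",
              x$score, x$matrix, x$gap_open, x$gap_extend))
  cat(sprintf("  identity %.1f%%, similarity %.1f%%, %d gap column(s)\n",
              x$identity_pct, x$similarity_pct, x$gaps))
  w <- 60
  n <- nchar(x$aligned_a)
  for (i in seq(1, n, by = w)) {
    cat(" ", substr(x$aligned_a, i, min(i + w - 1, n)), "\n")
    cat(" ", substr(x$aligned_b, i, min(i + w - 1, n)), "\n")
  }
  invisible(x)
}

#' Align the two sequences of a FASTA file (or two files)
#'
#' @param path_a FASTA with one record, or two records if `path_b` is NULL.
#' @param path_b optional second FASTA.
#' @param ... passed to [global_align()].
#' @return an `alignment_result`.
#' @export
align_fasta <- function(path_a, path_b = NULL, ...) {
  ss <- Biostrings::readAAStringSet(path_a)
  if (is.null(path_b)) {
    if (length(ss) < 2)
      stop_gd("'%s' must contain two records when path_b is missing", path_a,
              class = "groovedock_io_error")
    return(global_align(as.character(ss[[1]]), as.character(ss[[2]]), ...))
  }
  tt <- Biostrings::readAAStringSet(path_b)
  global_align(as.character(ss[[1]]), as.character(tt[[1]]), ...)
}
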