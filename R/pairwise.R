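#' Scoring scheme for global pairwise alignment
#'
#' Defaults mirror the published defaults of the EMBOSS Needle program:
#' BLOSUM62, gap open 10, gap extend 0.5, end gaps unpenalized. The
#' substitution matrix is taken from the Biostrings data sets.
#'
#' @param matrix Substitution matrix name (`"BLOSUM62"`, `"BLOSUM45"`,
#'   `"PAM250"`, ...) or a numeric matrix with residue dimnames.
#' @param gap_open,gap_extend Non-negative gap penalties; a gap of length
#'   `l` costs `gap_open + gap_extend * l`.
#' @param end_gaps_penalized If `FALSE` (default), leading/trailing gaps
#'   are free (ends-free global alignment).
#' @return An `alignment_scoring` object.
#' @export
alignment_scoring <- function(matrix = "BLOSUM62", gap_open = 10,
                              gap_extend = 0.5,
                              end_gaps_penalized = FALSE) {
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be >= 0")
  submat <- if (is.matrix(matrix)) matrix else {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    get(matrix, envir = e)
  }
  if (is.null(rownames(submat)) || is.null(colnames(submat)))
    stop("substitution matrix must have residue dimnames")
  structure(list(matrix_name = if (is.character(matrix)) matrix else
                   "custom",
                 matrix = submat,
                 gap_open = gap_open, gap_extend = gap_extend,
                 end_gaps_penalized = isTRUE(end_gaps_penalized)),
            class = "alignment_scoring")
}

.encode_for_alignment <- function(sequence, submat, what) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  idx <- match(chars, rownames(submat))
  if (anyNA(idx))
    stop("residue(s) absent from the substitution matrix in ", what, ": ",
         paste(unique(chars[is.na(idx)]), collapse = ", "))
  idx
}

#' Optimal global alignment of two sequences
#'
#' Needleman–Wunsch/Gotoh global alignment with affine gap costs and,
#' by default, free end gaps. Percent identity follows the EMBOSS
#' "Identity" convention: identical aligned columns divided by the total
#' number of alignment columns, gap columns (including end gaps) in the
#' denominator.
#'
#' @param a,b Non-empty amino-acid sequences (character strings).
#' @param scoring An [alignment_scoring()] object.
#' @return A `pairwise_alignment` object: list with `score`, `aligned_a`,
#'   `aligned_b` (gapped strings), `matches`, `columns` and `identity`.
#' @examples
#' aln <- global_alignment("HEAGAWGHEE", "PAWHEAE")
#' aln$identity
#' @export
global_alignment <- function(a, b, scoring = alignment_scoring()) {
  stopifnot(inherits(scoring, "alignment_scoring"),
            is.character(a), is.character(b), nzchar(a), nzchar(b))
  a <- toupper(a)
  b <- toupper(b)
  ai <- .encode_for_alignment(a, scoring$matrix, "first sequence")
  bi <- .encode_for_alignment(b, scoring$matrix, "second sequence")
  res <- needle_align_cpp(ai, bi, scoring$matrix,
                          scoring$gap_open, scoring$gap_extend,
                          scoring$end_gaps_penalized)
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  col_a <- ifelse(res$a_pos > 0L, ca[pmax(res$a_pos, 1L)], "-")
  col_b <- ifelse(res$b_pos > 0L, cb[pmax(res$b_pos, 1L)], "-")
  matched <- res$a_pos > 0L & res$b_pos > 0L & col_a == col_b
  columns <- length(col_a)
  structure(list(score = res$score,
                 aligned_a = paste(col_a, collapse = ""),
                 aligned_b = paste(col_b, collapse = ""),
                 matches = sum(matched), columns = columns,
                 identity = 100 * sum(matched) / columns),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("Global alignment: score %.1f, identity %.4f%% (%d/%d)\n",
              x$score, x$identity, x$matches, x$columns))
  cat(x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Global-alignment percent identity
#'
#' @inheritParams global_alignment
#' @return Numeric identity in \[0, 100\].
#' @export
global_alignment_identity <- function(a, b, scoring = alignment_scoring()) {
  global_alignment(a, b, scoring)$identity
}

#' All-vs-all compositional identity and alignment identity
#'
#' Builds the two symmetric matrices used to show that matched regions
#' share composition but not primary sequence: compositional identity of
#' the full-sequence compositions, and global-alignment percent identity.
#'
#' @param seqs Labeled sequences: a named character vector, or a protein
#'   record data frame (labels taken from `id`).
#' @param scoring An [alignment_scoring()] object.
#' @return A `pairwise_matrix` object: list with `labels`, `ci` and
#'   `identity` (both symmetric, diagonal 100).
#' @export
pairwise_matrix <- function(seqs, scoring = alignment_scoring()) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$sequence, seqs$id)
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (anyDuplicated(names(seqs))) stop("duplicate sequence labels")
  labels <- names(seqs)
  n <- length(seqs)
  comps <- lapply(seqs, composition)
  ci <- matrix(100, n, n, dimnames = list(labels, labels))
  identity <- matrix(100, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ci[i, j] <- ci[j, i] <- compositional_identity(comps[[i]], comps[[j]])
      identity[i, j] <- identity[j, i] <-
        global_alignment_identity(seqs[[i]], seqs[[j]], scoring)
    }
  }
  structure(list(labels = labels, ci = ci, identity = identity),
            class = "pairwise_matrix")
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat("Pairwise comparison of", length(x$labels), "sequences\n")
  cat("Compositional identity (upper) / alignment identity (lower):\n")
  comb <- x$ci
  comb[lower.tri(comb)] <- x$identity[lower.tri(x$identity)]
  print(round(comb, 2))
  invisible(x)
}

#' Write pairwise matrices as labeled TSV files
#'
#' Each matrix is written with a label header row and leading label
#' column, values with 4 decimal places.
#'
#' @param pm A [pairwise_matrix()] object.
#' @param ci_path,identity_path Output paths for the two matrices.
#' @return Invisibly, the two paths.
#' @export
write_pairwise_tsv <- function(pm, ci_path, identity_path) {
  stopifnot(inherits(pm, "pairwise_matrix"))
  wr <- function(mat, path) {
    df <- data.frame(id = rownames(mat),
                     apply(mat, 2, fmt4),
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE)
  }
  wr(pm$ci, ci_path)
  wr(pm$identity, identity_path)
  invisible(c(ci_path, identity_path))
}
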