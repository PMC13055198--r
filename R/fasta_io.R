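#' Read a FASTA file into a protein-record table
#'
#' Parses a (multi-record) FASTA file into a data frame with one row per
#' record. The record id is the first whitespace-delimited token of the
#' header line (UniProt-style `sp|ACC|NAME` headers are kept whole — no
#' pipe-splitting), the description is the remainder of the header, and the
#' sequence is uppercased with line breaks and internal whitespace removed.
#' Terminal stop symbols (`*`) are stripped; an internal `*` is an error, as
#' are duplicate ids and records with an empty sequence.
#'
#' @param path Path to a FASTA file (optionally gzip-compressed).
#' @return A data frame with character columns `id`, `description` and
#'   `sequence`, in file order.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "acdef", ">p2 some protein", "GH", "IK"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop("'path' must be a single file path")
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- sub("^\\S*\\s*", "", headers)
  if (any(!nzchar(id)))
    stop("FASTA record ", which(!nzchar(id))[1L], " has an empty header id")
  dup <- unique(id[duplicated(id)])
  if (length(dup))
    stop("duplicate record id(s) in '", path, "': ",
         paste(dup, collapse = ", "))
  sequence <- toupper(gsub("[[:space:]]+", "", as.character(set)))
  sequence <- sub("\\*+$", "", sequence)
  if (any(!nzchar(sequence)))
    stop("record(s) with empty sequence: ",
         paste(id[!nzchar(sequence)], collapse = ", "))
  internal_stop <- grepl("\\*", sequence, fixed = FALSE)
  if (any(internal_stop))
    stop("internal stop symbol '*' in record(s): ",
         paste(id[internal_stop], collapse = ", "))
  data.frame(id = unname(id), description = unname(description),
             sequence = unname(sequence), stringsAsFactors = FALSE)
}

#' Write protein records to a FASTA file
#'
#' @param records Data frame with columns `id`, `description`, `sequence`
#'   (as returned by [read_fasta()] or [random_proteome()]).
#' @param path Output file path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records),
            all(c("id", "description", "sequence") %in% names(records)))
  header <- ifelse(nzchar(records$description),
                   paste(records$id, records$description),
                   records$id)
  set <- Biostrings::BStringSet(setNames(records$sequence, header))
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(width))
  invisible(path)
}

# column layout of a search-result table
.result_columns <- c("rank", "protein_id", "description", "start", "end",
                     "window_length", "distance", "compositional_identity",
                     "prominent_features", "matched_sequence")

#' Write a ranked search result as a tab-separated table
#'
#' One row per match, in rank order, with the numeric columns (`distance`,
#' `compositional_identity`) rendered with 4 decimal places. An empty result
#' writes the header row only.
#'
#' @param result A `compmatch_result` object from [scan_proteome()] or
#'   [rank_matches()].
#' @param path Output file path.
#' @param append Append to `path` instead of truncating (used to place the
#'   table after a commented parameter block).
#' @return `path`, invisibly.
#' @seealso [read_results_tsv()], [run_search()]
#' @export
write_results_tsv <- function(result, path, append = FALSE) {
  stopifnot(inherits(result, "compmatch_result"))
  m <- result$matches
  out <- data.frame(
    rank = m$rank,
    protein_id = m$protein_id,
    description = m$description,
    start = m$start,
    end = m$end,
    window_length = m$window_length,
    distance = fmt4(m$distance),
    compositional_identity = fmt4(m$ci),
    prominent_features = m$prominent_features,
    matched_sequence = m$subsequence,
    stringsAsFactors = FALSE
  )
  names(out) <- .result_columns
  con <- file(path, open = if (append) "a" else "w")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read back a search-result table written by [write_results_tsv()]
#'
#' `#`-prefixed comment lines (the parameter block written by
#' [run_search()]) are skipped.
#'
#' @param path Path to a results TSV.
#' @return Data frame with the table's columns; numeric columns parsed.
#' @export
read_results_tsv <- function(path) {
  read.delim(path, sep = "\t", comment.char = "#", header = TRUE,
             stringsAsFactors = FALSE,
             colClasses = c(rank = "integer", protein_id = "character",
                            description = "character", start = "integer",
                            end = "integer", window_length = "integer",
                            distance = "numeric",
                            compositional_identity = "numeric",
                            prominent_features = "character",
                            matched_sequence = "character"))
}
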