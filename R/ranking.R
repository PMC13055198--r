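#' Rank per-protein best regions into a search result
#'
#' Sorts one best region per protein into the final proteome-wide ranking:
#' descending compositional identity for the Manhattan metric, ascending
#' raw distance for the Euclidean metric. Ties are broken by protein id,
#' ascending bytewise, so rankings are identical across platforms and
#' input orders. Ranks are dense, `1..N`.
#'
#' @param regions Data frame of match regions (one row per protein, as
#'   produced by [scan_protein()]).
#' @param metric `"manhattan"` or `"euclidean"` — the key the regions were
#'   scored with.
#' @param query_id Identifier of the query sequence.
#' @param params Optional [search_params()] stored with the result.
#' @param skipped Optional data frame (`protein_id`, `reason`) of proteins
#'   that produced no region.
#' @return A `compmatch_result` object.
#' @export
rank_matches <- function(regions, metric = c("manhattan", "euclidean"),
                         query_id = "query", params = NULL,
                         skipped = NULL) {
  metric <- match.arg(metric)
  stopifnot(is.data.frame(regions),
            all(c("protein_id", "start", "end", "window_length",
                  "distance", "ci") %in% names(regions)))
  if (anyDuplicated(regions$protein_id))
    stop("duplicate protein ids: one region per protein expected")
  if (is.null(skipped))
    skipped <- data.frame(protein_id = character(0), reason = character(0),
                          stringsAsFactors = FALSE)
  if (any(skipped$protein_id %in% regions$protein_id))
    stop("protein id(s) appear in both matches and skip log")
  ord <- if (metric == "manhattan")
    order(-regions$ci, regions$protein_id, method = "radix")
  else
    order(regions$distance, regions$protein_id, method = "radix")
  matches <- regions[ord, , drop = FALSE]
  rownames(matches) <- NULL
  matches <- cbind(rank = seq_len(nrow(matches)), matches)
  if (is.null(matches$description))
    matches$description <- character(nrow(matches))
  if (is.null(matches$prominent_features))
    matches$prominent_features <- character(nrow(matches))
  structure(list(query_id = query_id,
                 params = params %||% search_params(metric = metric),
                 matches = matches, skipped = skipped),
            class = "compmatch_result")
}

#' @export
print.compmatch_result <- function(x, n = 10L, ...) {
  cat(sprintf("Composition-matching search: query '%s', %d ranked match%s",
              x$query_id, nrow(x$matches),
              if (nrow(x$matches) == 1L) "" else "es"))
  if (nrow(x$skipped)) cat(sprintf(", %d skipped", nrow(x$skipped)))
  cat("\n")
  print(x$params)
  show <- utils::head(x$matches[, c("rank", "protein_id", "start", "end",
                                    "window_length", "distance", "ci")], n)
  show$distance <- round(show$distance, 4)
  show$ci <- round(show$ci, 4)
  print(show, row.names = FALSE)
  if (nrow(x$matches) > n) cat("...", nrow(x$matches) - n, "more\n")
  invisible(x)
}

#' Keep the top-N ranked matches
#'
#' Truncation preserves the prefix of the full ranking (ranks stay
#' `1..n`).
#'
#' @param result A `compmatch_result`.
#' @param n Number of matches to keep.
#' @return The truncated `compmatch_result`.
#' @export
top_matches <- function(result, n) {
  stopifnot(inherits(result, "compmatch_result"), n >= 1)
  result$matches <- utils::head(result$matches, n)
  result
}

#' Prominent compositional features of a query/subject pair
#'
#' Amino acids whose percent composition strictly exceeds the threshold in
#' *either* the query or the subject — the residues worth highlighting
#' when eyeballing why two regions match.
#'
#' @param query_comp,subject_comp Composition vectors.
#' @param threshold_percent Strict threshold (default 10: "exceeding 10%"
#'   means `> 10`, so exactly 10.0% is excluded).
#' @return Character vector of one-letter codes, alphabetical.
#' @export
prominent_features <- function(query_comp, subject_comp,
                               threshold_percent = 10) {
  q <- .percent_vec(query_comp)
  s <- .percent_vec(subject_comp)
  sort(AA_CANONICAL[q > threshold_percent | s > threshold_percent])
}

.rank_of <- function(hit, result) {
  stopifnot(inherits(result, "compmatch_result"))
  i <- match(hit, result$matches$protein_id)
  if (is.na(i))
    stop("protein '", hit, "' is not among the ranked matches")
  result$matches$rank[i]
}

#' Rank percentile of a hit within another search's ranking
#'
#' `100 * (N - rank + 1) / N`, where `N` is the number of ranked matches:
#' the top hit always scores exactly 100, the bottom hit `100/N`. Used to
#' quantify how stable a best hit's standing is when the search is re-run
#' with different window sizes.
#'
#' @param reference_hit Protein id of the hit of interest.
#' @param other A `compmatch_result` to locate the hit in.
#' @return Numeric percentile in `(0, 100]`.
#' @export
rank_percentile <- function(reference_hit, other) {
  r <- .rank_of(reference_hit, other)
  n <- nrow(other$matches)
  100 * (n - r + 1) / n
}

#' Signed rank difference of one protein between two searches
#'
#' `rank in result_b - rank in result_a`: positive when the protein ranks
#' worse (larger rank) in `result_b`. Used to compare rankings across
#' distance metrics.
#'
#' @param hit Protein id present in both results.
#' @param result_a,result_b `compmatch_result` objects.
#' @return Integer rank difference.
#' @export
rank_difference <- function(hit, result_a, result_b) {
  .rank_of(hit, result_b) - .rank_of(hit, result_a)
}
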