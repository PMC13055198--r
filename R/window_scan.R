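#' Search parameters for a composition-matching scan
#'
#' The defaults — window range 90–120 (inclusive) and the Manhattan
#' distance metric — target prion-like domains: PrLDs shorter than ~80
#' residues rarely carry composition-driven activity on their own, and the
#' median active PrLD is ~120 residues long.
#'
#' @param min_window,max_window Inclusive window-size range (residues);
#'   `1 <= min_window <= max_window`.
#' @param metric Ranking metric: `"manhattan"` (default) or `"euclidean"`.
#'   The reported compositional identity is Manhattan-based either way;
#'   with `metric = "euclidean"` only the ranking key (the raw `distance`
#'   column) changes.
#' @param strict_noncanonical If `TRUE`, windows containing any
#'   non-canonical residue are skipped entirely. The default (`FALSE`) is
#'   the dilution model: non-canonical residues contribute to no canonical
#'   percent but still count toward window length, so they degrade CI
#'   gracefully instead of fabricating composition.
#' @return A `search_params` object.
#' @export
search_params <- function(min_window = 90L, max_window = 120L,
                          metric = c("manhattan", "euclidean"),
                          strict_noncanonical = FALSE) {
  metric <- match.arg(metric)
  min_window <- as.integer(min_window)
  max_window <- as.integer(max_window)
  if (is.na(min_window) || is.na(max_window) || min_window < 1L ||
      min_window > max_window)
    stop("need 1 <= min_window <= max_window")
  structure(list(min_window = min_window, max_window = max_window,
                 metric = metric,
                 strict_noncanonical = isTRUE(strict_noncanonical)),
            class = "search_params")
}

#' @export
print.search_params <- function(x, ...) {
  cat(sprintf("Search parameters: windows %d-%d, %s metric%s\n",
              x$min_window, x$max_window, x$metric,
              if (x$strict_noncanonical) ", strict non-canonical" else ""))
  invisible(x)
}

# Normalize a query (sequence string, ProteinRecord row, residue_counts or
# aa_composition) to the rational form percent[a] = 100 * num[a] / den.
# Integer counts keep window distances exactly comparable.
.query_terms <- function(query) {
  if (is.data.frame(query)) query <- query$sequence[1L]
  if (is.character(query)) query <- count_residues(query)
  if (inherits(query, "residue_counts")) {
    num <- as.numeric(query$counts)
    den <- as.numeric(query$length)
  } else if (inherits(query, "aa_composition")) {
    num <- as.numeric(unclass(query))
    den <- 100
  } else {
    stop("query must be a sequence, protein record, residue_counts or ",
         "aa_composition")
  }
  if (all(num == 0))
    stop("query contains no canonical residues")
  list(num = num, den = den, percent = 100 * num / den)
}

.protein_fields <- function(protein) {
  if (is.data.frame(protein)) {
    list(id = protein$id[1L],
         description = if ("description" %in% names(protein))
           protein$description[1L] else "",
         sequence = protein$sequence[1L])
  } else if (is.list(protein)) {
    list(id = protein$id, description = protein$description %||% "",
         sequence = protein$sequence)
  } else stop("protein must be a protein record (data frame row or list)")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Best composition-matched window of a single protein
#'
#' Slides every window size in `[min_window, max_window]` across the
#' protein, scores each window's percent composition against the query
#' with the selected metric, and returns the single best region. Ties are
#' broken deterministically: smallest distance, then leftmost start, then
#' largest window. Counts are updated incrementally so the scan is linear
#' in protein length per window size.
#'
#' @param protein A protein record (one-row data frame or list with `id`,
#'   `sequence`, optional `description`).
#' @param query Query composition: an amino-acid sequence, protein record,
#'   [count_residues()] result, or [as_composition()] vector.
#' @param params A [search_params()] object.
#' @return A one-row data frame (`protein_id`, `description`, `start`,
#'   `end`, `window_length`, `distance`, `ci`, `subsequence`) with a
#'   `windows_evaluated` attribute, or `NULL` when the protein is shorter
#'   than `min_window` (or, in strict mode, no window is free of
#'   non-canonical residues). Coordinates are 1-based inclusive; `ci` is
#'   always the Manhattan-based compositional identity.
#' @examples
#' scan_protein(list(id = "p", sequence = "GGGGAAAAGGGG"),
#'              as_composition(c(A = 100)),
#'              search_params(4, 4))
#' @export
scan_protein <- function(protein, query, params = search_params()) {
  stopifnot(inherits(params, "search_params"))
  p <- .protein_fields(protein)
  q <- .query_terms(query)
  codes <- encode_sequence(p$sequence)
  hit <- scan_best_window_cpp(codes, q$num, q$den,
                              params$min_window, params$max_window,
                              params$metric == "euclidean",
                              params$strict_noncanonical)
  if (!hit$found) return(NULL)
  out <- data.frame(protein_id = p$id, description = p$description,
                    start = hit$start, end = hit$end,
                    window_length = hit$window_length,
                    distance = hit$distance, ci = hit$ci,
                    subsequence = substr(p$sequence, hit$start, hit$end),
                    stringsAsFactors = FALSE)
  attr(out, "windows_evaluated") <- hit$windows_evaluated
  out
}

#' Composition-matching search of a whole proteome
#'
#' Computes the query composition once over the full query sequence, finds
#' the best-matching window of every protein with [scan_protein()], and
#' ranks proteins by that window's score (descending compositional
#' identity for the Manhattan metric, ascending raw distance for the
#' Euclidean metric). Proteins shorter than `min_window` are recorded in
#' the skip log rather than silently dropped.
#'
#' @param proteome Data frame of protein records (see [read_fasta()]).
#' @param query Query sequence, protein record, or composition (see
#'   [scan_protein()]).
#' @param params A [search_params()] object.
#' @param top_n Optional: keep only the first `top_n` ranked matches.
#' @return A `compmatch_result`: list with `query_id`, `params`, `matches`
#'   (ranked data frame including per-match prominent compositional
#'   features) and `skipped` (data frame of `protein_id`, `reason`).
#' @export
scan_proteome <- function(proteome, query, params = search_params(),
                          top_n = NULL) {
  stopifnot(is.data.frame(proteome), inherits(params, "search_params"))
  if (nrow(proteome) == 0L) stop("empty proteome")
  if (anyDuplicated(proteome$id))
    stop("duplicate protein ids in proteome")
  q <- .query_terms(query)
  query_id <- if (is.data.frame(query)) query$id[1L]
              else if (is.list(query) && !is.null(query$id)) query$id
              else "query"
  euclid <- params$metric == "euclidean"

  n <- nrow(proteome)
  regions <- vector("list", n)
  skipped_id <- character(0)
  skipped_reason <- character(0)
  for (i in seq_len(n)) {
    codes <- encode_sequence(proteome$sequence[i])
    hit <- scan_best_window_cpp(codes, q$num, q$den,
                                params$min_window, params$max_window,
                                euclid, params$strict_noncanonical)
    if (hit$found) {
      regions[[i]] <- data.frame(
        protein_id = proteome$id[i], description = proteome$description[i],
        start = hit$start, end = hit$end,
        window_length = hit$window_length,
        distance = hit$distance, ci = hit$ci,
        subsequence = substr(proteome$sequence[i], hit$start, hit$end),
        stringsAsFactors = FALSE)
    } else {
      skipped_id <- c(skipped_id, proteome$id[i])
      skipped_reason <- c(
        skipped_reason,
        if (length(codes) < params$min_window)
          sprintf("length %d < min_window %d", length(codes),
                  params$min_window)
        else "no window free of non-canonical residues")
    }
  }
  regions <- do.call(rbind, regions)
  skipped <- data.frame(protein_id = skipped_id, reason = skipped_reason,
                        stringsAsFactors = FALSE)
  if (is.null(regions))
    stop("no protein in the proteome is long enough to scan")

  result <- rank_matches(regions, metric = params$metric,
                         query_id = query_id, params = params,
                         skipped = skipped)
  qcomp <- as_composition(setNames(q$percent, AA_CANONICAL))
  result$matches$prominent_features <- vapply(
    result$matches$subsequence,
    function(s) paste(prominent_features(qcomp, composition(s)),
                      collapse = ","),
    character(1), USE.NAMES = FALSE)
  if (!is.null(top_n)) result <- top_matches(result, top_n)
  result
}

#' Slide a residue-count window one position
#'
#' Removes the residue leaving the window and adds the residue entering
#' it; the window length is unchanged. Equals recounting the shifted
#' window from scratch — this is the incremental update that makes the
#' proteome scan linear per window size.
#'
#' @param counts A `residue_counts` object.
#' @param leaving,entering Single one-letter residue codes.
#' @return Updated `residue_counts`.
#' @export
slide_counts <- function(counts, leaving, entering) {
  stopifnot(inherits(counts, "residue_counts"),
            is.character(leaving), nchar(leaving) == 1L,
            is.character(entering), nchar(entering) == 1L)
  dec <- function(cc, res) {
    if (res %in% AA_CANONICAL) {
      if (cc$counts[[res]] < 1L)
        stop("cannot remove '", res, "': count is zero")
      cc$counts[[res]] <- cc$counts[[res]] - 1L
    } else {
      if (cc$noncanonical < 1L)
        stop("cannot remove non-canonical residue: count is zero")
      cc$noncanonical <- cc$noncanonical - 1L
    }
    cc
  }
  inc <- function(cc, res) {
    if (res %in% AA_CANONICAL)
      cc$counts[[res]] <- cc$counts[[res]] + 1L
    else cc$noncanonical <- cc$noncanonical + 1L
    cc
  }
  inc(dec(counts, toupper(leaving)), toupper(entering))
}

#' Number of windows a scan evaluates
#'
#' For a protein of length `L` and window range `[min_window,
#' max_window]`: `sum over w of max(0, L - w + 1)`.
#'
#' @param length Protein length(s) in residues.
#' @param min_window,max_window Inclusive window range.
#' @return Numeric vector of window counts.
#' @export
n_windows <- function(length, min_window, max_window) {
  vapply(length, function(L) {
    w <- seq.int(min_window, max_window)
    sum(pmax(0, L - w + 1))
  }, numeric(1))
}
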