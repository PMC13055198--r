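#' Background composition biased toward charged residues
#'
#' Default sampling weights for [random_proteome()]: D/E/K/R make up ~46%
#' of residues, with Q and N rare (2% each). Deliberately far from a
#' prion-like composition, so a planted Q/N-rich region stands out the way
#' a PrLD stands out of a folded, charged proteome background.
#'
#' @return An `aa_composition` of sampling weights (percents, sum 100).
#' @export
charged_background <- function() {
  as_composition(c(A = 7, C = 1, D = 11, E = 12, F = 3, G = 6, H = 2,
                   I = 4, K = 12, L = 8, M = 2, N = 2, P = 3, Q = 2,
                   R = 11, S = 4, T = 3, V = 5, W = 1, Y = 1))
}

#' Q/N-rich target composition for planted regions
#'
#' A prion-like composition (Q + N = 42%, uncharged polar and aromatic
#' secondary enrichment, no charged residues). All percents are integers,
#' so the composition is exactly realizable as residue counts at window
#' 100 — and, because several percents (23, 19, 11, 7, 3) share no factor
#' with 100, at *no other* window size in 90–120, which keeps planted
#' ground truth unique in default searches.
#'
#' @return An `aa_composition` (percents, sum 100).
#' @export
qn_rich_target <- function() {
  as_composition(c(Q = 23, N = 19, S = 11, G = 10, P = 8, Y = 7, A = 6,
                   T = 5, M = 3, F = 3, L = 3, H = 2))
}

#' Random sequence realizing an exact composition
#'
#' Draws a uniformly random permutation of the exact residue multiset
#' implied by `target` at the given length. Errors when any
#' `percent * length / 100` is not an integer — compositions are never
#' rounded, so planted regions have a known CI-100 optimum.
#'
#' @param target Composition ([as_composition()] input).
#' @param length Sequence length (residues).
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @return A single sequence string.
#' @export
sequence_from_composition <- function(target, length, seed) {
  counts <- .realizable_counts(target, length)
  with_seed(seed, paste(sample(rep(AA_CANONICAL, counts)), collapse = ""))
}

.realizable_counts <- function(target, length) {
  p <- .percent_vec(target)
  if (abs(sum(p) - 100) > 1e-9)
    stop("target composition must sum to 100%")
  counts <- p * length / 100
  if (any(abs(counts - round(counts)) > 1e-9))
    stop("composition not realizable as integer residue counts at length ",
         length, " (offending amino acids: ",
         paste(AA_CANONICAL[abs(counts - round(counts)) > 1e-9],
               collapse = ", "), ")")
  as.integer(round(counts))
}

#' Seeded random proteome
#'
#' Generates `n_proteins` records with lengths uniform on `length_range`
#' and residues drawn independently with `background` percent weights.
#' A pure function of its arguments: the same spec and seed always yield
#' the identical proteome, and the caller's RNG state is preserved.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Inclusive `(min, max)` protein lengths.
#' @param background Sampling weights ([as_composition()] input, percents
#'   summing to 100; not all zero).
#' @param seed Integer seed.
#' @return Protein-record data frame (`id`, `description`, `sequence`)
#'   with ids `SYN0001`, `SYN0002`, ...
#' @export
random_proteome <- function(n_proteins, length_range = c(200L, 600L),
                            background = charged_background(), seed = 1L) {
  stopifnot(n_proteins >= 1, length(length_range) == 2L,
            length_range[1L] >= 1, length_range[1L] <= length_range[2L])
  w <- .percent_vec(background)
  if (all(w == 0)) stop("degenerate background: all weights zero")
  with_seed(seed, {
    lens <- sample.int(length_range[2L] - length_range[1L] + 1L,
                       n_proteins, replace = TRUE) + length_range[1L] - 1L
    residues <- sample(AA_CANONICAL, sum(lens), replace = TRUE,
                       prob = w / sum(w))
    stops <- cumsum(lens)
    starts <- stops - lens + 1L
    seqs <- vapply(seq_len(n_proteins), function(i)
      paste(residues[starts[i]:stops[i]], collapse = ""), character(1))
    data.frame(id = sprintf("SYN%04d", seq_len(n_proteins)),
               description = "synthetic background protein",
               sequence = seqs, stringsAsFactors = FALSE)
  })
}

#' Plant an exact-composition region into a proteome
#'
#' Overwrites a random in-bounds slice of one randomly chosen (long
#' enough) protein with a random permutation of the exact residue multiset
#' of `target` at length `window`, and returns the ground truth. Because
#' the planted multiset is exact, a scan with a matching query has a known
#' optimum: the planted coordinates at CI 100.
#'
#' The ground truth is guaranteed to be *unique* among windows of the
#' planted length: if the flanking background residues happen to complete
#' the target multiset in a shifted window (so a second window would also
#' score CI 100), the placement is deterministically resampled. Without
#' this guard roughly 1 planting in 20 would have an ambiguous optimum.
#'
#' @param proteome Protein-record data frame.
#' @param target Target composition (must be realizable at `window`).
#' @param window Planted region length.
#' @param seed Integer seed.
#' @return List with `proteome` (modified copy) and `truth` (list:
#'   `protein_id`, `start`, `end`, `target`).
#' @export
plant_region <- function(proteome, target, window, seed = 1L) {
  stopifnot(is.data.frame(proteome), nrow(proteome) >= 1L, window >= 1)
  counts <- .realizable_counts(target, window)
  lens <- nchar(proteome$sequence)
  eligible <- which(lens >= window)
  if (!length(eligible))
    stop("no protein is long enough to hold a planted window of ", window)
  with_seed(seed, {
    for (attempt in 1:50) {
      i <- eligible[sample.int(length(eligible), 1L)]
      start <- sample.int(lens[i] - window + 1L, 1L)
      slice <- paste(sample(rep(AA_CANONICAL, counts)), collapse = "")
      seq <- proteome$sequence[i]
      planted <- paste0(substr(seq, 1L, start - 1L), slice,
                        substr(seq, start + window, lens[i]))
      if (.n_exact_windows(planted, counts, window) == 1L) {
        proteome$sequence[i] <- planted
        return(list(proteome = proteome,
                    truth = list(protein_id = proteome$id[i], start = start,
                                 end = start + window - 1L,
                                 target = as_composition(target))))
      }
    }
    stop("could not place a unique planted region after 50 attempts; ",
         "the background composition may be too close to the target")
  })
}

# number of length-`window` windows of `sequence` whose residue counts
# equal `counts` exactly
.n_exact_windows <- function(sequence, counts, window) {
  codes <- encode_sequence(sequence)
  L <- length(codes)
  if (L < window) return(0L)
  cs <- vapply(1:21, function(a) cumsum(codes == a), numeric(L))
  cs <- rbind(0, cs)
  target <- c(counts, 0L)  # no non-canonical residues in a planted slice
  hits <- 0L
  for (s in seq_len(L - window + 1L)) {
    if (all(cs[s + window, ] - cs[s, ] == target)) hits <- hits + 1L
  }
  hits
}

#' Write planted-region ground truth as TSV
#'
#' @param truth Truth list from [plant_region()] (or a list of them).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  if (!is.null(truth$protein_id)) truth <- list(truth)
  df <- do.call(rbind, lapply(truth, function(t)
    data.frame(protein_id = t$protein_id, start = t$start, end = t$end,
               stringsAsFactors = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
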