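#' Count residues in an amino-acid sequence
#'
#' Tallies each of the 20 canonical amino acids exactly; any other symbol
#' (X, B, Z, U, O, J, ...) accumulates in the `noncanonical` count. The
#' total always satisfies `sum(counts) + noncanonical == length`.
#'
#' @param sequence Non-empty uppercase amino-acid string.
#' @return A `residue_counts` object: list with `counts` (named integer
#'   vector over [AA_CANONICAL]), `noncanonical` and `length`.
#' @examples
#' count_residues("AAGG")
#' @export
count_residues <- function(sequence) {
  codes <- encode_sequence(sequence)
  tab <- tabulate(codes, nbins = 21L)
  structure(
    list(counts = setNames(tab[1:20], AA_CANONICAL),
         noncanonical = tab[21L],
         length = length(codes)),
    class = "residue_counts")
}

#' @export
print.residue_counts <- function(x, ...) {
  cat("Residue counts over", x$length, "residues",
      if (x$noncanonical > 0L) sprintf("(%d non-canonical)", x$noncanonical),
      "\n")
  print(x$counts[x$counts > 0L])
  invisible(x)
}

#' Percent composition of a residue-count tally
#'
#' Each canonical amino acid's percent is `100 * count / length`, where
#' `length` is the total window length *including* non-canonical residues
#' (the dilution model): unknown residues contribute to no canonical
#' percent but still dilute the others, so the 20 percents sum to 100
#' exactly when the window is fully canonical and to less otherwise.
#'
#' @param counts A `residue_counts` object from [count_residues()].
#' @return An `aa_composition`: named numeric vector of 20 percents with a
#'   `n_residues` attribute.
#' @export
percent_composition <- function(counts) {
  stopifnot(inherits(counts, "residue_counts"))
  if (counts$length < 1L) stop("zero-length residue counts")
  structure(100 * counts$counts / counts$length,
            n_residues = counts$length,
            class = "aa_composition")
}

#' Percent composition of a sequence
#'
#' Convenience wrapper: `composition(x)` is
#' `percent_composition(count_residues(x))`.
#'
#' @param sequence Non-empty uppercase amino-acid string.
#' @return An `aa_composition` object.
#' @examples
#' composition("QQQQNNNN")
#' @export
composition <- function(sequence) {
  percent_composition(count_residues(sequence))
}

#' Build a composition vector from named percent values
#'
#' Used for target compositions of the synthetic generators and for
#' ad-hoc queries given as percentages rather than sequences. Amino acids
#' not named are set to 0.
#'
#' @param percent Named numeric vector; names must be canonical one-letter
#'   codes, values in \[0, 100\] summing to at most 100.
#' @param n_residues Optional residue count the vector notionally derives
#'   from (`NA` for an abstract target).
#' @return An `aa_composition` object.
#' @examples
#' as_composition(c(Q = 50, N = 50))
#' @export
as_composition <- function(percent, n_residues = NA_integer_) {
  if (inherits(percent, "aa_composition")) return(percent)
  stopifnot(is.numeric(percent), !is.null(names(percent)))
  bad <- setdiff(names(percent), AA_CANONICAL)
  if (length(bad))
    stop("non-canonical amino acid name(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(names(percent))) stop("duplicated amino acid names")
  if (any(percent < 0 | percent > 100)) stop("percents must lie in [0, 100]")
  if (sum(percent) > 100 + 1e-9) stop("percents sum to more than 100")
  full <- setNames(numeric(20L), AA_CANONICAL)
  full[names(percent)] <- percent
  structure(full, n_residues = n_residues, class = "aa_composition")
}

#' @export
print.aa_composition <- function(x, ...) {
  n <- attr(x, "n_residues")
  cat("Amino-acid composition (%)",
      if (!is.na(n)) sprintf("over %d residues", n), "\n")
  v <- unclass(x)
  attributes(v) <- list(names = names(v))
  print(round(v[v > 0], 4))
  invisible(x)
}

# coerce to a bare 20-long percent vector in AA_CANONICAL order
.percent_vec <- function(x) {
  x <- as_composition(x)
  v <- unclass(x)
  attributes(v) <- list(names = names(v))
  v
}

#' Manhattan distance between two composition vectors
#'
#' Sum over the 20 canonical amino acids of the absolute percent
#' differences; symmetric and bounded in \[0, 200\].
#'
#' @param q,s Composition vectors ([as_composition()] inputs accepted).
#' @return Non-negative numeric scalar.
#' @export
manhattan_distance <- function(q, s) {
  sum(abs(.percent_vec(q) - .percent_vec(s)))
}

#' Euclidean distance between two composition vectors
#'
#' @inheritParams manhattan_distance
#' @return Non-negative numeric scalar.
#' @export
euclidean_distance <- function(q, s) {
  sqrt(sum((.percent_vec(q) - .percent_vec(s))^2))
}

#' Compositional identity (CI) between two composition vectors
#'
#' `CI = 100 - manhattan_distance(q, s) / 2`: 100 for identical
#' compositions (in particular, for any permutation of the same residues)
#' down to 0 for fully disjoint compositions. CI deliberately ignores
#' residue order — it measures how similar two regions are in bulk
#' amino-acid makeup, the property that governs many intrinsically
#' disordered regions' activities.
#'
#' @inheritParams manhattan_distance
#' @return Numeric scalar in \[0, 100\].
#' @examples
#' compositional_identity(composition("QN"), composition("NQ"))  # 100
#' compositional_identity(as_composition(c(A = 100)), as_composition(c(G = 100)))  # 0
#' @export
compositional_identity <- function(q, s) {
  100 - manhattan_distance(q, s) / 2
}
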