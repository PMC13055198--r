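# Independent oracles, deliberately implemented along different routes
# than the package internals (cumulative-sum window counts here vs the
# incremental C++ scan; Biostrings alignment scores vs the package's DP).

# exhaustive window search: recompute every window's composition from a
# cumulative-sum matrix and apply the documented tie rule
oracle_scan <- function(sequence, query_percent, min_w, max_w,
                        metric = "manhattan", strict = FALSE) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(chars)
  cs <- rbind(0, vapply(AA_CANONICAL, function(a) cumsum(chars == a),
                        numeric(L)))
  best <- NULL
  for (w in seq.int(min_w, max_w)) {
    if (w > L) next
    for (s in seq_len(L - w + 1)) {
      cnt <- cs[s + w, ] - cs[s, ]
      if (strict && sum(cnt) < w) next
      pc <- 100 * cnt / w
      manh <- sum(abs(query_percent - pc))
      d <- if (metric == "manhattan") manh
           else sqrt(sum((query_percent - pc)^2))
      if (is.null(best) || d < best$distance - 1e-9 ||
          (abs(d - best$distance) <= 1e-9 &&
           (s < best$start ||
            (s == best$start && w > best$window_length)))) {
        best <- list(start = s, end = s + w - 1, window_length = w,
                     distance = d, ci = 100 - manh / 2)
      }
    }
  }
  best
}

# Biostrings as the independent alignment-score oracle
oracle_align_score <- function(a, b, gap_open = 10, gap_extend = 0.5,
                               penalize_ends = FALSE) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  Biostrings::score(Biostrings::pairwiseAlignment(
    a, b, substitutionMatrix = e$BLOSUM62,
    gapOpening = gap_open, gapExtension = gap_extend,
    type = if (penalize_ends) "global" else "overlap"))
}

random_aa_sequence <- function(n, weights = rep(1, 20)) {
  paste(sample(AA_CANONICAL, n, replace = TRUE, prob = weights),
        collapse = "")
}

shuffle_sequence <- function(sequence) {
  paste(sample(strsplit(sequence, "", fixed = TRUE)[[1]]), collapse = "")
}

random_composition <- function() {
  x <- stats::runif(20)
  as_composition(setNames(100 * x / sum(x), AA_CANONICAL))
}
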