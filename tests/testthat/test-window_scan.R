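test_that("scan_protein finds hand-checkable best windows", {
  hit <- scan_protein(list(id = "p", sequence = "GGGGAAAAGGGG"),
                      as_composition(c(A = 100)), search_params(4, 4))
  expect_equal(hit$start, 5L)
  expect_equal(hit$end, 8L)
  expect_identical(hit$ci, 100)
  expect_identical(hit$distance, 0)

  # too short for the window range
  expect_null(scan_protein(list(id = "p", sequence = strrep("A", 50)),
                           as_composition(c(A = 100)), search_params(90, 120)))
})

test_that("ties break to smallest distance, leftmost start, largest window", {
  # every window of AGAGAGAG at w = 4 is 50/50 A/G: leftmost wins
  hit <- scan_protein(list(id = "p", sequence = "AGAGAGAG"),
                      as_composition(c(A = 50, G = 50)), search_params(4, 4))
  expect_equal(hit$start, 1L)
  expect_identical(hit$ci, 100)
  # with range 4-6 on AGAGAG, w = 4 and w = 6 tie at CI 100 from start 1:
  # the larger window wins
  hit <- scan_protein(list(id = "p", sequence = "AGAGAG"),
                      as_composition(c(A = 50, G = 50)), search_params(4, 6))
  expect_equal(hit$start, 1L)
  expect_equal(hit$window_length, 6L)
})

test_that("incremental count sliding equals from-scratch recounting", {
  rc <- slide_counts(count_residues("AAGG"), "A", "C")
  expect_equal(rc, count_residues("AGGC"))
  # sliding off then back on is the identity
  rc0 <- count_residues("MKVQ")
  expect_equal(slide_counts(slide_counts(rc0, "M", "W"), "W", "M"), rc0)
  expect_error(slide_counts(rc0, "A", "G"), "count is zero")

  set.seed(10)
  s <- random_aa_sequence(500)
  w <- 90L
  rc <- count_residues(substr(s, 1, w))
  chars <- strsplit(s, "")[[1]]
  for (start in 2:(500 - w + 1)) {
    rc <- slide_counts(rc, chars[start - 1], chars[start + w - 1])
    expect_equal(rc, count_residues(substr(s, start, start + w - 1)))
  }
})

test_that("scan agrees with the exhaustive oracle on random cases", {
  set.seed(11)
  for (i in 1:15) {
    L <- sample(60:300, 1)
    minw <- sample(5:50, 1)
    maxw <- minw + sample(0:40, 1)
    s <- random_aa_sequence(L)
    qseq <- random_aa_sequence(sample(20:120, 1))
    metric <- sample(c("manhattan", "euclidean"), 1)
    hit <- scan_protein(list(id = "p", sequence = s), qseq,
                        search_params(minw, maxw, metric))
    ora <- oracle_scan(s, 100 * count_residues(qseq)$counts /
                            nchar(qseq), minw, maxw, metric)
    expect_equal(hit$start, ora$start)
    expect_equal(hit$end, ora$end)
    expect_equal(hit$window_length, ora$window_length)
    expect_equal(hit$distance, ora$distance, tolerance = 1e-9)
    expect_equal(hit$ci, ora$ci, tolerance = 1e-9)
  }
})

test_that("windows evaluated match the counting formula", {
  expect_equal(n_windows(12, 4, 4), 9)
  expect_equal(n_windows(50, 90, 120), 0)
  set.seed(12)
  for (i in 1:5) {
    L <- sample(50:400, 1)
    minw <- sample(2:60, 1)
    maxw <- minw + sample(0:60, 1)
    brute <- sum(vapply(minw:maxw, function(w) max(0L, L - w + 1L),
                        integer(1)))
    expect_equal(n_windows(L, minw, maxw), brute)
    s <- random_aa_sequence(L)
    hit <- scan_protein(list(id = "p", sequence = s), "QNQN",
                        search_params(minw, maxw))
    evaluated <- if (is.null(hit)) 0 else attr(hit, "windows_evaluated")
    if (!is.null(hit)) expect_equal(evaluated, brute)
  }
})

test_that("best CI over a window range dominates any subrange", {
  set.seed(13)
  s <- random_aa_sequence(250)
  q <- random_aa_sequence(80)
  full <- scan_protein(list(id = "p", sequence = s), q,
                       search_params(20, 60))
  for (sub in list(c(20, 40), c(30, 50), c(45, 60), c(33, 33))) {
    part <- scan_protein(list(id = "p", sequence = s), q,
                         search_params(sub[1], sub[2]))
    expect_gte(full$ci, part$ci - 1e-12)
  }
})

test_that("strict non-canonical mode skips contaminated windows", {
  # X every 3rd residue: no 4-window is clean
  s <- paste(rep("QNX", 20), collapse = "")
  p <- list(id = "p", sequence = s)
  expect_null(scan_protein(p, "QN", search_params(4, 4,
                                                  strict_noncanonical = TRUE)))
  # dilution mode still scans, but CI < 100 because X dilutes
  hit <- scan_protein(p, "QN", search_params(4, 4))
  expect_lt(hit$ci, 100)
  # a clean stretch is preferred under strict mode
  s2 <- paste0(s, "QNQNQNQN")
  hit2 <- scan_protein(list(id = "p", sequence = s2), "QN",
                       search_params(4, 4, strict_noncanonical = TRUE))
  expect_gte(hit2$start, 61L)
  expect_identical(hit2$ci, 100)
})

test_that("proteome scans are order-independent and self-matches win", {
  set.seed(14)
  prot <- random_proteome(40, c(100, 300), seed = 15)
  query <- prot[7, ]
  # window range spans the query's own length, so the self-match is exact
  params <- search_params(60, 300)
  res <- scan_proteome(prot, query, params)
  expect_equal(res$matches$protein_id[1], "SYN0007")
  expect_identical(res$matches$ci[1], 100)
  expect_equal(res$query_id, "SYN0007")

  shuffled <- prot[sample(nrow(prot)), ]
  res2 <- scan_proteome(shuffled, query, params)
  expect_equal(res$matches, res2$matches)

  # short proteins land in the skip log, never in the ranking
  prot$sequence[3] <- "MKV"
  res3 <- scan_proteome(prot, query, params)
  expect_equal(res3$skipped$protein_id, "SYN0003")
  expect_match(res3$skipped$reason, "min_window")
  expect_false("SYN0003" %in% res3$matches$protein_id)
})

test_that("degenerate searches fail loudly", {
  prot <- random_proteome(5, c(100, 200), seed = 16)
  expect_error(scan_proteome(prot[0, ], "QN"), "empty proteome")
  expect_error(scan_proteome(prot, "XXXX"), "no canonical")
  expect_error(search_params(10, 5), "min_window")
  expect_error(search_params(0, 5), "min_window")
})
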