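# Fragment matching, cosine scoring, ranking, metadata fusion.

test_that("normalize_relative scales the base peak to exactly 100", {
  p <- data.frame(mz = c(100, 150), intensity = c(50, 25))
  n <- normalize_relative(p)
  expect_equal(n$intensity, c(100, 50))
  expect_equal(normalize_relative(data.frame(mz = 120, intensity = 7))$intensity,
               100)
  expect_equal(normalize_relative(n), n) # idempotent
  expect_error(normalize_relative(data.frame(mz = numeric(),
                                             intensity = numeric())), "empty")
  expect_error(normalize_relative(data.frame(mz = 1, intensity = 0)), "zero")
})

test_that("match_fragments honors the ppm window with its absolute floor", {
  q <- data.frame(mz = 100.000, intensity = 1)
  # 0.002 Da at m/z 100 is 20 ppm: outside a 5 ppm window
  m <- match_fragments(q, data.frame(mz = 100.002, intensity = 1), tol_ppm = 5)
  expect_equal(nrow(m$pairs), 0)
  expect_equal(m$unmatched_query, 1L)
  # 4 ppm: inside
  m2 <- match_fragments(data.frame(mz = 100.0000, intensity = 1),
                        data.frame(mz = 100.0004, intensity = 1), tol_ppm = 5)
  expect_equal(nrow(m2$pairs), 1)
  # identical lists match fully at any tolerance
  pk <- data.frame(mz = c(50.1, 80.2, 120.3), intensity = c(10, 100, 50))
  m3 <- match_fragments(pk, pk, tol_ppm = 1)
  expect_equal(nrow(m3$pairs), 3)
  expect_length(m3$unmatched_query, 0)
  expect_length(m3$unmatched_library, 0)
  expect_error(match_fragments(pk, pk, tol_ppm = -1), "negative")
  expect_error(match_fragments(pk, pk, tol_da = -0.1), "negative")
})

test_that("competing peaks resolve nearest-first, tie to the lower query index", {
  # two query peaks both within tolerance of one library peak
  q <- data.frame(mz = c(100.0000, 100.0001), intensity = c(1, 1))
  l <- data.frame(mz = c(100.00005), intensity = c(1))
  m <- match_fragments(q, l, tol_da = 0.01)
  expect_equal(nrow(m$pairs), 1)
  expect_equal(unname(m$pairs[1, "query"]), 1L) # equidistant: lower index wins
  q2 <- data.frame(mz = c(100.0009, 100.0001), intensity = c(1, 1))
  m2 <- match_fragments(q2[order(q2$mz), ], l, tol_da = 0.01)
  expect_equal(unname(m2$pairs[1, "query"]), 1L) # nearer peak wins
})

test_that("greedy assignment is one-to-one and maximal-by-construction on tiny inputs", {
  set.seed(21)
  for (i in 1:100) {
    nq <- sample(1:6, 1); nl <- sample(1:6, 1)
    q <- data.frame(mz = sort(runif(nq, 100, 101)), intensity = 1)
    l <- data.frame(mz = sort(runif(nl, 100, 101)), intensity = 1)
    tol <- runif(1, 0.05, 0.5)
    m <- match_fragments(q, l, tol_da = tol)
    p <- m$pairs
    expect_equal(anyDuplicated(p[, 1]), 0)
    expect_equal(anyDuplicated(p[, 2]), 0)
    expect_true(all(abs(q$mz[p[, 1]] - l$mz[p[, 2]]) <= tol))
    # greedy replay against the exhaustive within-tolerance pair list
    cand <- all_within_pairs(q$mz, l$mz, tol)
    cand <- cand[order(cand$d, cand$qi, cand$li), ]
    uq <- logical(nq); ul <- logical(nl); ref <- NULL
    for (r in seq_len(nrow(cand))) {
      if (!uq[cand$qi[r]] && !ul[cand$li[r]]) {
        uq[cand$qi[r]] <- TRUE; ul[cand$li[r]] <- TRUE
        ref <- rbind(ref, c(cand$qi[r], cand$li[r]))
      }
    }
    expect_equal(nrow(p), NROW(ref))
    if (NROW(ref)) expect_equal(unname(p), unname(ref[order(ref[, 1]), , drop = FALSE])[order(order(p[, 1])), , drop = FALSE])
  }
})

test_that("cosine reproduces the worked two-peak example and its edge cases", {
  q <- normalize_relative(data.frame(mz = c(100, 150), intensity = c(100, 50)))
  l <- normalize_relative(data.frame(mz = c(100, 150), intensity = c(50, 100)))
  expect_equal(cosine_score(q, l), 0.8, tolerance = 1e-12)
  # self-match is exactly 1
  expect_equal(cosine_score(q, q), 1)
  # disjoint spectra score 0
  far <- data.frame(mz = c(300, 400), intensity = c(100, 50))
  expect_equal(cosine_score(q, far), 0)
  expect_error(cosine_score(q, data.frame(mz = numeric(),
                                          intensity = numeric())), "empty")
  bad <- match_fragments(q, l)
  bad$pairs[1, 2] <- 99L
  expect_error(cosine_score(q, l, bad), "out-of-range")
})

test_that("cosine is symmetric, scale-invariant and bounded on random spectra", {
  set.seed(31)
  for (i in 1:300) {
    nq <- sample(2:12, 1); nl <- sample(2:12, 1)
    q <- data.frame(mz = sort(runif(nq, 50, 500)),
                    intensity = runif(nq, 1, 100))
    l <- data.frame(mz = sort(runif(nl, 50, 500)),
                    intensity = runif(nl, 1, 100))
    # overlap some peaks so matches exist
    k <- min(nq, nl, sample(1:4, 1))
    l$mz[seq_len(k)] <- q$mz[seq_len(k)]
    l <- l[order(l$mz), ]
    m <- match_fragments(q, l, tol_da = 0.001)
    s <- cosine_score(q, l, m)
    expect_gte(s, 0); expect_lte(s, 1)
    # symmetry: swap roles (Da tolerance keeps the window symmetric)
    msw <- match_fragments(l, q, tol_da = 0.001)
    expect_equal(cosine_score(l, q, msw), s, tolerance = 1e-12)
    # uniform rescaling of either spectrum leaves the score unchanged
    q2 <- q; q2$intensity <- q2$intensity * runif(1, 0.01, 50)
    expect_equal(cosine_score(q2, l, m), s, tolerance = 1e-12)
  }
})

test_that("self-match maximizes the score among equal-size competitors", {
  set.seed(41)
  ref <- data.frame(mz = sort(runif(8, 50, 400)), intensity = runif(8, 5, 100))
  self <- cosine_score(ref, ref, match_fragments(ref, ref, tol_da = 0.001))
  expect_equal(self, 1)
  for (i in 1:50) {
    other <- data.frame(mz = sort(ref$mz + rnorm(8, 0, 0.5)),
                        intensity = runif(8, 5, 100))
    s <- cosine_score(other, ref, match_fragments(other, ref, tol_da = 0.001))
    expect_lte(s, self)
  }
})

test_that("score_candidate scores each present energy and sums them", {
  rec <- fixture_record()
  q <- query_spectrum(rec$energies$energy1[, c("mz", "intensity")],
                      parent_mass = rec$header$mass)
  sc <- score_candidate(q, rec)
  expect_equal(sc$score_energy1, 1)
  expect_equal(sc$matched_energy1, 2L)
  expect_true(sc$score_energy0 < 1)
  expect_equal(sc$sum_score,
               sc$score_energy0 + sc$score_energy1 + sc$score_energy2)
  # absent blocks are NA and excluded from the sum
  rec2 <- fixture_record()
  rec2$energies$energy2 <- NULL
  sc2 <- score_candidate(q, rec2)
  expect_true(is.na(sc2$score_energy2))
  expect_equal(sc2$sum_score, sc2$score_energy0 + sc2$score_energy1)
  # mode mismatch is an error
  qneg <- query_spectrum(data.frame(mz = 50, intensity = 1),
                         parent_mass = 100, mode = "ESI-")
  expect_error(score_candidate(qneg, rec), "mode mismatch")
})

test_that("a noisy copy of one energy scores highest at that energy", {
  lib <- generate_library(library_spec(30, seed = 17))
  hits <- 0L; trials <- 200L
  set.seed(18)
  for (i in seq_len(trials)) {
    rec <- lib$records[[sample(length(lib$records), 1)]]
    q <- make_query(rec, "energy0",
                    noise_spec(mz_jitter_ppm = 3, intensity_cv = 0.05))
    sc <- score_candidate(q$query, rec)
    if (sc$score_energy0 > max(sc$score_energy1, sc$score_energy2))
      hits <- hits + 1L
  }
  expect_gte(hits / trials, 0.95)
})

test_that("rank_candidates orders by key with competition ranks and documented ties", {
  scores <- data.frame(
    dtxcid = c("DTXCID0000004", "DTXCID0000002", "DTXCID0000003", "DTXCID0000001"),
    sum_score = c(0.2, 0.7, 0.7, 0.9),
    matched_total = c(1L, 3L, 5L, 4L))
  r <- rank_candidates(scores, "sum")
  expect_equal(r$rank, c(1L, 2L, 2L, 4L))
  # within the 0.7 tie, more matched peaks first
  expect_equal(r$dtxcid[2:3], c("DTXCID0000003", "DTXCID0000002"))
  # dtxcid breaks exact ties in score and matched count
  scores$matched_total <- 3L
  r2 <- rank_candidates(scores, "sum")
  expect_equal(r2$dtxcid[2:3], c("DTXCID0000002", "DTXCID0000003"))
  # single candidate gets rank 1; empty input stays empty without error
  expect_equal(rank_candidates(scores[1, , drop = FALSE], "sum")$rank, 1L)
  expect_equal(nrow(rank_candidates(scores[0, , drop = FALSE], "sum")), 0)
  # permuted input yields the identical ordered output
  set.seed(5)
  r3 <- rank_candidates(scores[sample(4), ], "sum")
  expect_identical(r3, r2)
  expect_error(rank_candidates(scores, "energy9"), "unknown ranking key")
})

test_that("combined_rank boosts prevalent chemicals and degenerates cleanly", {
  scores <- data.frame(
    dtxcid = c("DTXCID40232", "DTXCID10104684"),
    sum_score = c(0.8, 0.8), matched_total = c(4L, 4L))
  meta <- c(DTXCID40232 = 1162, DTXCID10104684 = 7)
  r <- combined_rank(scores, meta)
  expect_equal(r$dtxcid[1], "DTXCID40232") # 1162 data sources beat 7
  expect_equal(r$combined_rank, c(1L, 2L))
  # zero metadata weight reproduces the spectral ranking exactly
  base <- rank_candidates(scores, "sum")
  r0 <- combined_rank(scores, meta, metadata_weight = 0)
  expect_identical(r0$dtxcid, base$dtxcid)
  expect_identical(r0$rank, base$rank)
  # all-equal metadata counts also reduce to the spectral order
  scores2 <- data.frame(dtxcid = sprintf("DTXCID%07d", 1:5),
                        sum_score = c(0.9, 0.5, 0.7, 0.2, 0.6),
                        matched_total = 1:5)
  flat <- stats::setNames(rep(10, 5), scores2$dtxcid)
  expect_identical(combined_rank(scores2, flat)$dtxcid,
                   rank_candidates(scores2, "sum")$dtxcid)
  # unknown candidates fall back to zero-count with a warning
  expect_warning(combined_rank(scores2, flat[1:3]), "missing from metadata")
  expect_error(combined_rank(scores2, flat, rrf_k = -1), "rrf_k")
})

test_that("alternative fusion strategies run and respect degeneracy", {
  scores <- data.frame(dtxcid = sprintf("DTXCID%07d", 1:4),
                       sum_score = c(0.9, 0.7, 0.7, 0.1),
                       matched_total = c(2L, 2L, 2L, 2L))
  meta <- stats::setNames(c(5, 2, 900, 1), scores$dtxcid)
  z <- combined_rank(scores, meta, strategy = "zscore")
  expect_equal(nrow(z), 4)
  tb <- combined_rank(scores, meta, strategy = "tiebreak")
  # tiebreak keeps the top candidate and reorders only the tied pair
  expect_equal(tb$dtxcid[1], "DTXCID0000001")
  expect_equal(tb$dtxcid[2], "DTXCID0000003") # 900 sources beats 2 inside the tie
  tb0 <- combined_rank(scores, meta, strategy = "tiebreak", metadata_weight = 0)
  expect_identical(tb0$dtxcid, rank_candidates(scores, "sum")$dtxcid)
})

test_that("search_library finds a planted member at rank 1 with full scores", {
  lib <- generate_library(library_spec(40, near_isobar_fraction = 0.25,
                                       seed = 19))
  st <- load_library(lib$records)
  rec <- lib$records[[11]]
  q <- make_query(rec, "energy1", noise_spec())
  res <- search_library(st, q$query)
  expect_equal(res$dtxcid[1], q$truth)
  expect_equal(res$rank[1], 1L)
  expect_equal(res$score_energy1[1], 1)
  # formula search reaches the same chemical
  qf <- query_spectrum(rec$energies$energy1[, c("mz", "intensity")],
                       formula = rec$header$formula)
  resf <- search_library(st, qf)
  expect_true(q$truth %in% resf$dtxcid)
  # an off-library mass returns an empty table, not an error
  none <- search_library(st, query_spectrum(data.frame(mz = 50, intensity = 1),
                                            parent_mass = 1999))
  expect_equal(nrow(none), 0)
})
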