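test_that("indel calls are extracted and left-normalised", {
  aln <- dj_align("AAAACCCC", "AAAATTTTCCCC")
  calls <- call_indels(aln, min_len = 2)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$type, "deletion_in_query")
  expect_equal(calls$length, 4L)
  expect_equal(calls$ref_pos, 4L)

  expect_equal(nrow(call_indels(dj_align("ACGTACGT", "ACGTACGT"))), 0)

  # a deletion inside a homopolymer run normalises to the run start
  ref <- "GGGGTTTTTTTTCCCC"
  qry <- "GGGGTTTTTCCCC" # 3 Ts removed
  calls2 <- call_indels(dj_align(qry, ref), min_len = 2)
  expect_equal(calls2$ref_pos, 4L)
  expect_equal(calls2$length, 3L)
})

test_that("left-normalisation is idempotent", {
  set.seed(31)
  for (i in 1:25) {
    ref <- rand_dna(300)
    p <- sample(50:200, 1)
    L <- sample(5:40, 1)
    seg <- substr(ref, p + 1, p + L)
    n1 <- acrodj:::.left_normalise(ref, p, seg, "deletion_in_query")
    n2 <- acrodj:::.left_normalise(ref, n1$pos, n1$seg, "deletion_in_query")
    expect_equal(n2$pos, n1$pos)
    expect_equal(n2$seg, n1$seg)
  }
})

test_that("breakpoint matching clusters identical calls and flags near-matches", {
  sim <- threegroup_sim()
  alns <- threegroup_alignments()
  calls <- dplyr::bind_rows(lapply(alns, call_indels))
  calls <- dplyr::filter(calls, ref_pos < sim$manifest$prox_end)
  mk <- match_breakpoints(calls)
  expect_equal(nrow(mk), 3)
  expect_setequal(mk$carriers[[1]], c("m5", "m6", "m7"))

  # equal-length deletions with different flanks stay distinct markers
  fake <- tibble::tibble(
    reference_id = "r", query_id = c("q1", "q2"),
    ref_pos = c(100L, 900L), length = c(60L, 60L),
    type = "deletion_in_query",
    left_flank = c("AC", "GT"), right_flank = c("CA", "TG")
  )
  mk2 <- match_breakpoints(fake)
  expect_equal(nrow(mk2), 2)
  expect_equal(nrow(attr(mk2, "candidates")), 1)

  expect_equal(nrow(match_breakpoints(fake[0, ])), 0)

  dupe <- fake
  dupe$query_id <- "q1"
  dupe$ref_pos <- 100L
  dupe$left_flank <- "AC"
  dupe$right_flank <- "CA"
  expect_error(match_breakpoints(dupe), "duplicate carrier")
})

test_that("absence in the marker matrix is verified, not assumed", {
  set.seed(32)
  ref <- rand_dna(4000)
  q_clean <- plant_subs(ref, 4)$seq
  q_del <- paste0(substr(q_clean, 1, 2000), substr(q_clean, 2101, 4000))
  alns <- list(
    clean = dj_align(c(clean = q_clean), c(ref = ref)),
    del = dj_align(c(del = q_del), c(ref = ref)),
    partial = dj_align_range(
      c(partial = substr(ref, 1, 1000)), c(ref = ref), c(0, 1000)
    )
  )
  calls <- call_indels(alns$del)
  mk <- match_breakpoints(calls)
  mm <- build_marker_matrix(mk, alns)
  expect_equal(unname(mm$presence[1, "del"]), 1L)
  expect_equal(unname(mm$presence[1, "clean"]), 0L)
  expect_true(is.na(mm$presence[1, "partial"])) # locus outside the alignment
})

test_that("four-gamete test matches its published pattern and handles errors", {
  mm <- dj_reference_markers()
  expect_true(four_gamete("D1.5", "D0.3", mm))
  expect_false(four_gamete("D0.3", "D5.0", mm))
  expect_false(four_gamete("D1.5", "D1.5", mm))

  # symmetric in its arguments
  expect_equal(four_gamete("D0.3", "D1.5", mm), four_gamete("D1.5", "D0.3", mm))

  nas <- two_marker_matrix(c(1L, NA, 0L), c(NA, 1L, NA))
  expect_error(four_gamete("Ma", "Mb", nas), "untestable")
})

test_that("exchange intervals reproduce the published scan and bounds", {
  ei <- exchange_intervals(dj_reference_markers())
  expect_equal(ei$status, c("exchange_required", "linked"))
  expect_equal(ei$width, c(51000L, 11000L))
  expect_equal(attr(ei, "min_exchanges"), 1L)
  # the 11-kb shared block adjoining the exchange interval implies a CO
  expect_equal(ei$mechanism_class[1], "CO")

  zero <- marker_matrix(
    tibble::tibble(
      marker_id = c("a", "b", "c"), ref_pos = c(10L, 20L, 30L),
      length = 60L, type = "deletion_in_query"
    ),
    c("c1", "c2"), matrix(0L, 3, 2)
  )
  ez <- exchange_intervals(zero)
  expect_true(all(ez$status == "linked"))
  expect_equal(attr(ez, "min_exchanges"), 0L)
})

test_that("the minimum-exchange count is a valid lower bound", {
  # abstract crossover process on marker patterns, 50 seeds: suffix swaps
  # between members can never be undercounted upward
  set.seed(33)
  for (rep in 1:50) {
    n_mark <- sample(3:6, 1)
    pos <- sort(sample(1000:100000, n_mark))
    n_chr <- sample(4:7, 1)
    pres <- matrix(rbinom(n_mark * n_chr, 1, 0.4), n_mark, n_chr)
    # start from marker patterns with no exchange signal: each marker
    # carried by a nested chromosome prefix (perfect LD ordering)
    ord <- order(rowSums(pres), decreasing = TRUE)
    pres <- t(apply(
      matrix(seq_len(n_mark), ncol = 1), 1,
      function(i) as.integer(seq_len(n_chr) <= sum(pres[i, ]))
    ))[ord, , drop = FALSE]
    n_co <- sample(0:3, 1)
    for (xo in seq_len(n_co)) {
      pair <- sample(n_chr, 2)
      at <- sample(n_mark, 1)
      if (at < n_mark) {
        lower <- (at + 1):n_mark
        tmp <- pres[lower, pair[1]]
        pres[lower, pair[1]] <- pres[lower, pair[2]]
        pres[lower, pair[2]] <- tmp
      }
    }
    mk <- tibble::tibble(
      marker_id = sprintf("M%d", seq_len(n_mark)), ref_pos = pos,
      length = 60L, type = "deletion_in_query"
    )
    mm <- marker_matrix(mk, sprintf("c%d", seq_len(n_chr)), pres)
    ei <- exchange_intervals(mm)
    expect_lte(attr(ei, "min_exchanges"), n_co)
  }
})

test_that("mechanism classification applies the 1-kb tract threshold", {
  expect_equal(classify_mechanism(112000), "CO")
  expect_equal(classify_mechanism(1000), "NCO_possible")
  expect_equal(classify_mechanism(999), "NCO_possible")
  expect_equal(
    classify_mechanism(c(500, 5000)), c("NCO_possible", "CO")
  )
})
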