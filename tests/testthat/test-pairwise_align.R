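test_that("elementary alignments behave as specified", {
  aln <- dj_align("ACGT", "ACGT")
  expect_equal(tidy(aln), tibble::tibble(kind = "match", length = 4L))
  expect_equal(identity_pct(aln), 100)
  expect_equal(identity_pct(aln, "blast_like"), 100)

  aln2 <- dj_align("ACGTACGT", "ACGAACGT")
  expect_equal(aln2$substitutions, 1L)
  expect_equal(identity_pct(aln2), 87.5)

  expect_error(dj_align("", "ACGT"), "empty")
})

test_that("identity modes follow their definitions", {
  # 9 matches, 1 mismatch, 10 indel bases, assembled directly
  aln <- acrodj:::.finish_alignment(
    "q", "t",
    query = paste0("AAAAAAAAAC", strrep("G", 10)),
    target = "AAAAAAAAAT",
    opstr = paste0(strrep("=", 9), "X", strrep("I", 10)),
    query_span = c(0L, 20L), target_span = c(0L, 10L)
  )
  expect_equal(identity_pct(aln, "substitution_only"), 90)
  expect_equal(identity_pct(aln, "blast_like"), 45)

  # columns opposite N are excluded from both modes
  alnN <- dj_align("ACGTNNGT", "ACGANNGT")
  expect_equal(alnN$ambiguous_columns, 2L)
  expect_equal(alnN$aligned_columns, 6L)
  expect_equal(identity_pct(alnN), 100 * 5 / 6)
})

test_that("DP edit distance equals the independent oracle on random pairs", {
  set.seed(101)
  for (i in 1:100) {
    n1 <- sample(10:300, 1)
    a <- rand_dna(n1)
    b <- if (i %% 2 == 0) {
      rand_dna(sample(10:300, 1)) # unrelated
    } else {
      plant_subs(a, sample(0:20, 1))$seq # related
    }
    aln <- dj_align(a, b)
    expect_equal(aln$substitutions + aln$indel_bases, edit_dist_oracle(a, b))
  }
})

test_that("anchored alignment reproduces the exact DP distance on related pairs", {
  set.seed(102)
  a <- rand_dna(5000)
  b <- plant_subs(a, 25)$seq
  aln <- dj_align(a, b, dp_max_area = 1000) # force the anchored path
  expect_equal(aln$substitutions + aln$indel_bases, edit_dist_oracle(a, b))
  expect_equal(aln$substitutions, 25L)

  # with one planted 120-bp deletion
  b2 <- paste0(substr(b, 1, 2000), substr(b, 2121, 5000))
  aln2 <- dj_align(b2, a, dp_max_area = 1000)
  expect_equal(
    aln2$substitutions + aln2$indel_bases,
    edit_dist_oracle(b2, a)
  )

  # large unrelated inputs have no anchors
  expect_error(
    dj_align(rand_dna(20000), rand_dna(20000), dp_max_area = 1000),
    class = "dj_unalignable"
  )
})

test_that("alignment is symmetric up to indel-kind swap", {
  set.seed(103)
  a <- rand_dna(800)
  b <- paste0(substr(a, 1, 300), substr(a, 381, 800))
  f <- dj_align(a, b)
  r <- dj_align(b, a)
  expect_equal(f$substitutions, r$substitutions)
  expect_equal(f$insertion_bases, r$deletion_bases)
  expect_equal(f$deletion_bases, r$insertion_bases)
})

test_that("windowed identity tiles the reference and localises divergence", {
  set.seed(104)
  ref <- rand_dna(30000)
  same <- window_identity(ref, c(q1 = ref), window_bp = 10000)
  expect_equal(nrow(same), 3)
  expect_true(all(same$identity == 100))

  # substitutions planted only in the final window
  pl <- plant_subs(ref, 40, lo = 20001, hi = 30000)
  prof <- window_identity(ref, c(q = pl$seq), window_bp = 10000)
  expect_equal(prof$identity[1:2], c(100, 100))
  expect_equal(prof$identity[3], 100 * (10000 - 40) / 10000)

  # additivity: window substitution counts sum to the global count
  expect_equal(sum(prof$mismatches), 40L)

  # a query absent from distal windows is missing there, not zero
  short <- substr(ref, 1, 10000)
  prof2 <- window_identity(ref, c(s = short), window_bp = 10000)
  expect_true(is.na(prof2$identity[3]))
  expect_false(is.na(prof2$identity[1]))

  # final partial window kept only at >= half window size
  expect_equal(nrow(window_identity(substr(ref, 1, 25000), c(q1 = ref),
    window_bp = 10000
  )), 3)
  expect_equal(nrow(window_identity(substr(ref, 1, 24000), c(q1 = ref),
    window_bp = 10000
  )), 2)
})

test_that("raising the substitution rate never raises windowed identity", {
  set.seed(105)
  worse <- 0
  for (rep in 1:20) {
    ref <- rand_dna(3000)
    lo <- plant_subs(ref, 15)$seq
    hi <- plant_subs(lo, 30)$seq # strictly more divergence on top
    p_lo <- mean(window_identity(ref, c(q = lo), window_bp = 1000)$identity)
    p_hi <- mean(window_identity(ref, c(q = hi), window_bp = 1000)$identity)
    if (p_hi > p_lo) worse <- worse + 1
  }
  expect_equal(worse, 0)
})

test_that("range alignment locates the partner region and recovers indels", {
  set.seed(106)
  a <- rand_dna(30000)
  b <- paste0(substr(a, 1, 10000), substr(a, 11501, 30000)) # 1.5-kb deletion
  ar <- dj_align_range(b, a, c(5000, 15000))
  calls <- call_indels(ar)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$length, 1500L)
  expect_equal(calls$type, "deletion_in_query")

  # an interval covering an identical sequence matches the global alignment
  g <- dj_align(a, a)
  r <- dj_align_range(a, a, c(0, 30000))
  expect_equal(tidy(r), tidy(g))

  expect_error(
    dj_align_range(a, rand_dna(5000), c(0, 2000)),
    class = "dj_unalignable"
  )
})
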