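test_that("ancestor layout follows the architecture and is deterministic", {
  arch <- dj_architecture(
    rdna_stub_len = 800, unique1_len = 2000, ir_arm_len = 5000,
    ir_spacer_len = 500, unique2_len = 1000, satellite_period = 48,
    satellite_len = 4800, tail_len = 1500
  )
  anc <- build_ancestor(arch, seed = 5)
  expect_equal(nchar(anc$contig$sequence), arch$total_len)

  arms <- dplyr::filter(anc$annotations, feature_class == "inverted_repeat_arm")
  expect_equal(nrow(arms), 2)
  expect_equal(arms$end - arms$start, c(5000L, 5000L))
  a1 <- substr(anc$contig$sequence, arms$start[1] + 1, arms$end[1])
  a2 <- substr(anc$contig$sequence, arms$start[2] + 1, arms$end[2])
  expect_equal(a2, revcomp(a1))

  sat <- dplyr::filter(anc$annotations, feature_class == "satellite_block")
  satseq <- substr(anc$contig$sequence, sat$start + 1, sat$end)
  monomers <- substring(satseq, seq(1, 4800, 48), seq(48, 4800, 48))
  expect_length(unique(monomers), 1)  # 100 identical copies
  expect_equal(length(monomers), 100)

  stub <- substr(anc$contig$sequence, 1, 800)
  expect_equal(stub, substr(rdna_reference()$sequence, 1, 800))

  anc2 <- build_ancestor(arch, seed = 5)
  expect_identical(anc$contig$sequence, anc2$contig$sequence)
  expect_error(build_ancestor(arch, seed = 5, max_len = 1000), "max_len")
})

test_that("zero rates and no events reproduce the ancestor exactly", {
  arch <- dj_architecture(
    rdna_stub_len = 500, unique1_len = 1000, ir_arm_len = 1000,
    ir_spacer_len = 200, unique2_len = 500, satellite_len = 960,
    tail_len = 800
  )
  anc <- build_ancestor(arch, seed = 2)
  spec <- dj_cohort_spec(
    groups = list(g1 = c("a", "b")),
    proximal_sub_rate = 0, distal_sub_rate = 0, member_sub_rate = 0,
    seed = 3
  )
  ev <- evolve_cohort(anc, spec)
  expect_equal(unique(ev$cohort$sequence), anc$contig$sequence)
  expect_equal(ev$cohort$length, rep(arch$total_len, 2))
})

test_that("realized proximal substitution counts fall in the 99% binomial band", {
  # proximal region of exactly 10 kb at rate 0.01
  arch <- dj_architecture(
    rdna_stub_len = 1000, unique1_len = 2000, ir_arm_len = 2000,
    ir_spacer_len = 1000, unique2_len = 2000, satellite_len = 960,
    tail_len = 1000
  )
  expect_equal(arch$proximal_len, 10000L)
  anc <- build_ancestor(arch, seed = 9)
  spec <- dj_cohort_spec(
    groups = list(g1 = "a"),
    proximal_sub_rate = 0.01, distal_sub_rate = 0, member_sub_rate = 0,
    seed = 10
  )
  ev <- evolve_cohort(anc, spec)
  subs <- ev$manifest$group_events$g1$subs
  n_prox <- sum(subs$pos <= 10000)
  band <- qbinom(c(0.005, 0.995), size = 10000, prob = 0.01)
  expect_gte(n_prox, band[1])
  expect_lte(n_prox, band[2])
})

test_that("identical spec and seed give identical cohort and manifest", {
  s1 <- simulate_cohort("minimal", seed = 7)
  s2 <- simulate_cohort("minimal", seed = 7)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$manifest$member_subs, s2$manifest$member_subs)
  s3 <- simulate_cohort("minimal", seed = 8)
  expect_false(identical(s1$cohort$sequence, s3$cohort$sequence))
})

test_that("manifest replay reproduces every member sequence exactly", {
  sim <- threegroup_sim()
  rp <- replay_manifest(sim$ancestor, sim$manifest)
  expect_identical(unname(rp[sim$cohort$id]), sim$cohort$sequence)
})

test_that("invalid cohort specifications are rejected", {
  arch <- dj_architecture()
  anc <- build_ancestor(arch, seed = 1)
  expect_error(
    dj_cohort_spec(groups = list(g1 = "a", g2 = "a")),
    "exactly one group"
  )
  expect_error(
    dj_cohort_spec(groups = list(g1 = "a"), proximal_sub_rate = 0.7),
    "rates"
  )
  overlapping <- dj_cohort_spec(
    groups = list(g1 = "a"),
    shared_indels = tibble::tibble(
      groups = list("g1", "g1"), pos = c(13000L, 13500L),
      len = c(1000L, 200L), type = "deletion"
    ),
    seed = 1
  )
  expect_error(evolve_cohort(anc, overlapping), "overlapping")
  outside <- dj_cohort_spec(
    groups = list(g1 = c("a", "b")),
    exchange_events = tibble::tibble(
      recipient = "a", donor = "b", breakpoint = 10 * arch$total_len
    ),
    seed = 1
  )
  expect_error(evolve_cohort(anc, outside), "breakpoint outside")
})

test_that("threegroup preset plants the published carrier topology", {
  sim <- threegroup_sim()
  co <- sim$cohort
  exp <- manifest_expected_markers(
    sim$manifest, "m3", co$sequence[co$id == "m3"]
  )
  expect_equal(nrow(exp$markers), 3)
  carriers <- lapply(
    seq_len(nrow(exp$presence)),
    function(i) colnames(exp$presence)[exp$presence[i, ] == 1]
  )
  # one lineage (the recombinant m7) carries marker A together with B and C
  expect_setequal(carriers[[1]], c("m5", "m6", "m7"))
  expect_setequal(carriers[[2]], c("m1", "m2", "m7"))
  expect_setequal(carriers[[3]], c("m1", "m2", "m7"))
})
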