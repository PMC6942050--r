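test_that("period estimation recovers exact and mutated tandem periods", {
  expect_equal(estimate_period(strrep("ACGT", 100), allow_short = TRUE), 4L)

  set.seed(21)
  monomer <- rand_dna(48)
  arr <- strrep(monomer, 200)
  arr_mut <- plant_subs(arr, round(0.01 * nchar(arr)))$seq
  expect_equal(estimate_period(arr_mut), 48L)

  expect_true(is.na(estimate_period(rand_dna(7000))))
  expect_error(estimate_period(rand_dna(100)), "allow_short")
})

test_that("period estimation is invariant to rotation of a perfect array", {
  set.seed(22)
  monomer <- rand_dna(48)
  arr <- strrep(monomer, 120)
  for (rot in c(0, 7, 30, 47)) {
    rotated <- paste0(
      substr(arr, rot + 1, nchar(arr)), substr(arr, 1, rot)
    )
    expect_equal(estimate_period(rotated, allow_short = TRUE), 48L)
  }
})

test_that("satellite blocks are found where planted and nowhere else", {
  sim <- threegroup_sim()
  anc <- sim$ancestor
  blk <- find_satellite_blocks(anc$contig)
  sat <- dplyr::filter(anc$annotations, feature_class == "satellite_block")
  expect_equal(nrow(blk), 1)
  expect_lt(abs(blk$start - sat$start), 100)
  expect_lt(abs(blk$end - sat$end), 100)
  expect_equal(blk$period, 48L)
  expect_gt(blk$mean_monomer_identity, 99)

  set.seed(23)
  expect_equal(nrow(find_satellite_blocks(rand_dna(10000))), 0)

  # two arrays of different periods separated by unique sequence
  two <- paste0(
    rand_dna(2000), strrep(rand_dna(48), 60), rand_dna(5000),
    strrep(rand_dna(171), 20), rand_dna(2000)
  )
  blk2 <- find_satellite_blocks(two)
  expect_equal(nrow(blk2), 2)
  expect_equal(sort(blk2$period), c(48L, 171L))
})

test_that("satellite calls on evolved members are sensitive and specific", {
  sim <- threegroup_sim()
  co <- sim$cohort
  for (m in c("m1", "m3")) {
    row <- co[co$id == m, ]
    blk <- find_satellite_blocks(row)
    ins <- find_foreign_inserts(row, blk)
    # planted satellite interval in member coordinates (shared indels are
    # proximal; one 800-bp insert sits inside the array)
    segs <- sim$manifest$maps[[m]]
    sat0 <- acrodj:::.map_pos(segs, sim$manifest$sat_start)
    sat1 <- acrodj:::.map_pos(segs, sim$manifest$sat_start + 5000L)
    covered <- sum(pmin(blk$end, sat1) - pmax(blk$start, sat0)) -
      sum(ins$end - ins$start)
    planted <- (sat1 - sat0) - 800 # array minus the foreign insert
    expect_gt(covered / planted, 0.99)
    outside <- sum(blk$end - blk$start) - sum(ins$end - ins$start) - covered
    expect_lt(outside / (row$length - planted), 0.01)
  }
})

test_that("inverted repeats are recovered at construction coordinates", {
  set.seed(24)
  x <- rand_dna(5000)
  contig <- paste0(rand_dna(3000), x, rand_dna(1000), revcomp(x), rand_dna(3000))
  ir <- find_inverted_repeats(contig, min_arm = 4000)
  expect_equal(nrow(ir), 1)
  expect_lt(abs(ir$arm1_start - 3000), 50)
  expect_lt(abs(ir$arm1_end - 8000), 50)
  expect_lt(abs(ir$arm2_start - 9000), 50)
  expect_lt(abs(ir$arm2_end - 14000), 50)
  expect_equal(ir$arm_identity, 100)

  expect_equal(nrow(find_inverted_repeats(rand_dna(20000), min_arm = 4000)), 0)
})

test_that("inverted-repeat detection commutes with reverse complement", {
  sim <- threegroup_sim()
  m1 <- sim$cohort[sim$cohort$id == "m1", ]
  n <- m1$length
  fwd <- find_inverted_repeats(m1, min_arm = 2500)
  rev <- find_inverted_repeats(revcomp(m1$sequence), min_arm = 2500)
  expect_equal(nrow(fwd), nrow(rev))
  expect_equal(rev$arm1_start, n - fwd$arm2_end)
  expect_equal(rev$arm1_end, n - fwd$arm2_start)
  expect_equal(rev$arm2_start, n - fwd$arm1_end)
  expect_equal(rev$arm2_end, n - fwd$arm1_start)
})

test_that("foreign inserts are located inside satellite blocks", {
  set.seed(25)
  monomer <- rand_dna(48)
  insert <- rand_dna(3000)
  contig <- paste0(
    rand_dna(2000),
    strrep(monomer, 170), insert, strrep(monomer, 250),
    rand_dna(2000)
  )
  blk <- find_satellite_blocks(contig)
  expect_equal(nrow(blk), 1)
  ins <- find_foreign_inserts(contig, blk)
  expect_equal(nrow(ins), 1)
  planted_start <- 2000 + 170 * 48
  expect_lt(abs(ins$start - planted_start), 100)
  expect_lt(abs(ins$end - (planted_start + 3000)), 100)

  pure <- paste0(rand_dna(1000), strrep(monomer, 300), rand_dna(1000))
  expect_equal(nrow(find_foreign_inserts(pure, find_satellite_blocks(pure))), 0)
})

test_that("group-shared inserts are near-identical, cross-group inserts are not", {
  sim <- threegroup_sim()
  co <- sim$cohort
  get_insert <- function(m) {
    row <- co[co$id == m, ]
    ins <- find_foreign_inserts(row, find_satellite_blocks(row))
    expect_equal(nrow(ins), 1)
    substr(row$sequence, ins$start + 1, ins$end)
  }
  i_m1 <- get_insert("m1")
  i_m2 <- get_insert("m2")
  i_m3 <- get_insert("m3")
  same <- dj_align(i_m1, i_m2)
  expect_gt(identity_pct(same, "blast_like"), 99)
  other <- dj_align(i_m1, i_m3)
  expect_lt(identity_pct(other, "blast_like"), 80)
})
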