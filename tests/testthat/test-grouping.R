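test_that("distances follow their definition on simple cohorts", {
  set.seed(41)
  s <- rand_dna(2000)
  D <- distance_matrix(c(a = s, b = s), region = "whole")
  expect_equal(unname(D["a", "b"]), 0)

  # substitution-only cohort: distances equal Hamming / length exactly
  t1 <- plant_subs(s, 12)$seq
  t2 <- plant_subs(s, 30)$seq
  D2 <- distance_matrix(c(x = t1, y = t2), region = "whole")
  hamming <- sum(strsplit(t1, "")[[1]] != strsplit(t2, "")[[1]])
  expect_equal(unname(D2["x", "y"]), hamming / 2000)

  expect_error(
    distance_matrix(c(a = rand_dna(20000), b = rand_dna(20000)),
      region = "whole", dp_max_area = 1000
    ),
    "unalignable pair: a vs b"
  )
})

test_that("average linkage produces the documented tree geometry", {
  m <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  D <- structure(m, class = c("dj_dist", "matrix"))
  tree <- build_tree(D)
  # single cherry with branch lengths d/2
  expect_equal(sort(tree$phylo$edge.length), c(0.2, 0.2))

  # hand-built ultrametric 4-leaf matrix: ((a,b),(c,d))
  lab <- c("a", "b", "c", "d")
  m4 <- matrix(0.5, 4, 4, dimnames = list(lab, lab))
  m4[cbind(c(1, 2), c(2, 1))] <- 0.1
  m4[cbind(c(3, 4), c(4, 3))] <- 0.2
  diag(m4) <- 0
  D4 <- structure(m4, class = c("dj_dist", "matrix"))
  t4 <- build_tree(D4)
  gr <- assign_groups(t4, D4, k = 2)
  expect_equal(split(gr$groups$id, gr$groups$group),
    list(`1` = c("a", "b"), `2` = c("c", "d"))
  )
  # cophenetic distances equal the ultrametric input
  expect_equal(
    as.matrix(stats::cophenetic(t4$hclust))[lab, lab], m4,
    tolerance = 1e-12
  )
})

test_that("partitions are invariant to input order", {
  sim <- threegroup_sim()
  co <- sim$cohort
  tails <- setNames(
    substring(co$sequence, co$length - 11999, co$length), co$id
  )
  D1 <- distance_matrix(tails, region = "whole")
  set.seed(42)
  perm <- sample(length(tails))
  D2 <- distance_matrix(tails[perm], region = "whole")
  g1 <- tidy(assign_groups(build_tree(D1), k = 3))
  g2 <- tidy(assign_groups(build_tree(D2), k = 3))
  merged <- dplyr::left_join(g1, g2, by = "id")
  expect_equal(adjusted_rand_index(merged$group.x, merged$group.y), 1)
})

test_that("synthetic groups are recovered with ARI 1 across seeds", {
  # scaled-down cohorts (three groups of two, short tails) so 20 replicates
  # stay fast; divergence rates are the package defaults
  arch <- dj_architecture(
    rdna_stub_len = 500, unique1_len = 1500, ir_arm_len = 1000,
    ir_spacer_len = 300, unique2_len = 1200, satellite_len = 960,
    tail_len = 2500
  )
  for (seed in 1:20) {
    anc <- build_ancestor(arch, seed = seed)
    spec <- dj_cohort_spec(
      groups = list(g1 = c("a1", "a2"), g2 = c("b1", "b2"), g3 = c("c1", "c2")),
      seed = seed + 1000
    )
    ev <- evolve_cohort(anc, spec)
    D <- distance_matrix(ev$cohort, region = "terminal", tail_bp = 3000)
    gr <- tidy(assign_groups(build_tree(D), k = 3))
    truth <- setNames(ev$cohort$chromosome, ev$cohort$id)
    expect_equal(adjusted_rand_index(gr$group, truth[gr$id]), 1)
  }
})

test_that("threshold cuts must agree with graph components", {
  lab <- c("a", "b", "c")
  m <- matrix(c(0, 0.1, 0.4, 0.1, 0, 0.15, 0.4, 0.15, 0), 3,
    dimnames = list(lab, lab)
  )
  D <- structure(m, class = c("dj_dist", "matrix"))
  tree <- build_tree(D)
  # chain a-b-c under h = 0.2 is connected but the tree cut separates c
  expect_error(assign_groups(tree, D, cut_height = 0.2), "non-ultrametric")
  # a consistent threshold works
  gr <- assign_groups(tree, D, cut_height = 0.05)
  expect_equal(length(unique(gr$groups$group)), 3)

  expect_error(assign_groups(tree, D), "exactly one")
  nj <- build_tree(D, method = "neighbor_joining")
  expect_error(assign_groups(nj, D, k = 2), "average_linkage")
  expect_match(write_tree_newick(nj), "^\\(.*\\);$")
})

test_that("adjusted Rand index behaves at its reference points", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y")), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_lt(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0.01)
})
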