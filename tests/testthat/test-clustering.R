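toy_dist <- function() {
  matrix(c(0, 0.1, 0.9,
           0.1, 0, 0.8,
           0.9, 0.8, 0), 3, 3,
         dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
}

test_that("complete linkage merges by maximum pairwise distance", {
  hc <- complete_linkage(toy_dist())
  expect_equal(sort(hc$height), c(0.1, 0.9))  # {A,B} at 0.1, then C at max(0.9, 0.8)
  sets <- geneage:::clade_sets(hc)
  expect_equal(sets[[1]], c("A", "B"))
  expect_equal(sets[[2]], c("A", "B", "C"))

  two <- complete_linkage(matrix(c(0, 0.3, 0.3, 0), 2, 2,
                                 dimnames = list(c("x", "y"), c("x", "y"))))
  expect_equal(two$height, 0.3)

  bad <- toy_dist(); bad[1, 2] <- bad[2, 1] <- NaN
  expect_error(complete_linkage(bad), "NaN")
})

test_that("merge heights never decrease toward the root", {
  set.seed(14)
  for (i in 1:10) {
    cums <- replicate(6, random_cum(16))
    colnames(cums) <- paste0("c", 1:6)
    hc <- complete_linkage(geneage:::cum_dist_matrix(cums))
    expect_true(all(diff(hc$height) >= -1e-12))
  }
})

test_that("Newick export is ultrametric with leaf depth equal to root height", {
  hc <- complete_linkage(toy_dist())
  nwk <- to_newick(hc)
  expect_equal(nwk, "((A:0.1,B:0.1):0.8,C:0.9);")

  two <- complete_linkage(matrix(c(0, 0.5, 0.5, 0), 2, 2,
                                 dimnames = list(c("A", "B"), c("A", "B"))))
  expect_equal(to_newick(two), "(A:0.5,B:0.5);")

  skip_if_not_installed("ape")
  ph <- ape::read.tree(text = nwk)
  expect_setequal(ph$tip.label, c("A", "B", "C"))
  depths <- ape::node.depth.edgelength(ph)[seq_along(ph$tip.label)]
  expect_equal(depths, rep(0.9, 3))
  # serialisation is stable under parse -> write
  expect_equal(ape::read.tree(text = ape::write.tree(ph))$edge, ph$edge)
})

test_that("bootstrap support is 1 for point-mass classes and bounded in general", {
  tl <- tl16()
  ca <- as_class_ages(list(a = rep(1L, 20), b = rep(8L, 20), c = rep(16L, 20)))
  bt <- bootstrap_trees(ca, tl, n_boot = 50, seed = 1)
  expect_true(all(bt$support$support == 1))

  set.seed(4)
  ca2 <- as_class_ages(lapply(setNames(1:4, letters[1:4]), function(i)
    sample.int(16, 50, TRUE)))
  bt2 <- bootstrap_trees(ca2, tl, n_boot = 100, seed = 2)
  expect_true(all(bt2$support$support >= 0 & bt2$support$support <= 1))
  root <- which.max(bt2$support$node_id)
  expect_equal(bt2$support$support[root], 1)  # root clade is always present
  # bit-reproducible under the seed
  bt3 <- bootstrap_trees(ca2, tl, n_boot = 100, seed = 2)
  expect_identical(bt2$support, bt3$support)
})

test_that("bootstrap order rates partition and detect strict dominance", {
  r <- bootstrap_order_rates(rep(16L, 60), rep(1L, 60), k = 16,
                             n_boot = 200, seed = 3)
  expect_equal(r$a_lower, 1)

  tie <- bootstrap_order_rates(rep(4L, 30), rep(4L, 30), k = 16,
                               n_boot = 100, seed = 4)
  expect_equal(tie$a_lower, 0)
  expect_equal(tie$b_lower, 0)
  expect_equal(tie$tied, 1)
  expect_equal(tie$crossing, 1)  # no strict order counted under crossing

  set.seed(5)
  for (i in 1:5) {
    a <- sample.int(16, 40, TRUE); b <- sample.int(16, 40, TRUE)
    r <- bootstrap_order_rates(a, b, k = 16, n_boot = 100, seed = i)
    expect_equal(r$a_lower + r$b_lower + r$crossing, 1)
  }
})

test_that("bootstrap curve statistics are consistent with the original curve", {
  tl <- tl16()
  pt <- bootstrap_curve_stats(rep(7L, 25), tl, n_boot = 100, seed = 1)
  expect_true(all(pt$boot_mse == 0))
  expect_equal(pt$boot_mean, pt$original)

  set.seed(6)
  v <- sample.int(16, 400, TRUE, prob = default_base_profile(16))
  st <- bootstrap_curve_stats(v, tl, n_boot = 500, seed = 2)
  # bootstrap mean within 3 MC standard errors of the original curve
  se <- sqrt(pmax(st$boot_mse, 1e-12) / 500)
  expect_true(all(abs(st$boot_mean - st$original) <= 3 * se + 1e-8))
  expect_true(all(st$boot_q25 <= st$boot_median & st$boot_median <= st$boot_q75))
})

test_that("planted three-group structure is recovered with high support", {
  tl <- tl16()
  prof <- planted_profiles()
  set.seed(20)
  ages <- list(
    old1 = sample.int(16, 300, TRUE, prob = prof$old),
    old2 = sample.int(16, 300, TRUE, prob = prof$old),
    mid1 = sample.int(16, 300, TRUE, prob = prof$mid),
    mid2 = sample.int(16, 300, TRUE, prob = prof$mid),
    yng1 = sample.int(16, 300, TRUE, prob = prof$young),
    yng2 = sample.int(16, 300, TRUE, prob = prof$young)
  )
  bt <- bootstrap_trees(as_class_ages(ages), tl, n_boot = 200, seed = 9)
  groups <- cutree(bt$tree, k = 3)
  expect_equal(groups[["old1"]], groups[["old2"]])
  expect_equal(groups[["mid1"]], groups[["mid2"]])
  expect_equal(groups[["yng1"]], groups[["yng2"]])
  expect_equal(length(unique(groups)), 3)
})
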