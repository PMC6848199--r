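test_that("simulate_class draws i.i.d. from the origination profile", {
  tl <- tl3()
  pm <- class_spec("pm", 50, c(0, 1, 0))
  x <- simulate_class(pm, tl, seed = 1)
  expect_true(all(x$taxon_index == 2L))
  expect_equal(nrow(x), 50)

  expect_identical(simulate_class(pm, tl, seed = 7), simulate_class(pm, tl, seed = 7))

  spec <- class_spec("u", 1e5, rep(0.25, 4))
  y <- simulate_class(spec, tl4(), seed = 2)
  shares <- tabulate(y$taxon_index, 4) / 1e5
  bound <- 3 * sqrt(0.25 * 0.75 / 1e5)
  expect_true(all(abs(shares - 0.25) <= bound))

  expect_error(class_spec("bad", 10, c(0.5, 0.6)), "sum to 1")
})

test_that("simulate_study honors class sizes, overlap requests and the universe", {
  tl <- tl4()
  specs <- list(
    class_spec("a", 100, c(0.7, 0.1, 0.1, 0.1)),
    class_spec("b", 100, c(0.1, 0.1, 0.1, 0.7)),
    class_spec("c", 50, c(0.25, 0.25, 0.25, 0.25),
               overlap_with = "a", shared_frac = 0.5)
  )
  study <- simulate_study(specs, tl, seed = 5, universe_size = 500)
  expect_equal(nrow(study$age_table), 500)
  sz <- class_sizes(study$catalog)
  expect_equal(sz$n[match(c("a", "b", "c"), sz$class)], c(100L, 100L, 50L))

  uni <- attr(study$catalog, "universe")
  ov <- overlap_table(study$catalog, universe = uni)
  ab <- ov[ov$class_a == "a" & ov$class_b == "b", ]
  expect_equal(ab$observed, 0L)
  ac <- ov[ov$class_a == "a" & ov$class_b == "c", ]
  expect_equal(ac$observed, 25L)

  # full sharing between equal-size classes
  full <- simulate_study(list(
    class_spec("x", 40, rep(0.25, 4)),
    class_spec("y", 40, rep(0.25, 4), overlap_with = "x", shared_frac = 1)
  ), tl, seed = 1, universe_size = 100)
  expect_setequal(class_genes(full$catalog, "x"), class_genes(full$catalog, "y"))

  # shared genes carry one age honored by both classes
  ca <- join_ages(full$catalog, full$age_table)
  ages <- split(ca$taxon_index[order(ca$gene_id)], ca$class[order(ca$gene_id)])
  expect_equal(ages$x, ages$y)

  expect_error(simulate_study(list(
    class_spec("x", 10, rep(0.25, 4)),
    class_spec("y", 40, rep(0.25, 4), overlap_with = "x", shared_frac = 1)
  ), tl, seed = 1, universe_size = 100), "shared genes")
})

test_that("a study is a pure function of specs and seed", {
  tl <- tl16()
  specs <- study_scale_spec()
  s1 <- simulate_study(specs, tl, seed = 3)
  s2 <- simulate_study(specs, tl, seed = 3)
  expect_identical(s1$age_table, s2$age_table)
  expect_identical(tibble::as_tibble(s1$catalog), tibble::as_tibble(s2$catalog))
})

test_that("study-scale specs carry the documented class sizes and valid profiles", {
  specs <- study_scale_spec()
  sizes <- vapply(specs, `[[`, integer(1), "n")
  expect_true(224L %in% sizes)          # oncogene-like class
  expect_equal(sort(unname(sizes)), sort(c(6789L, 224L, 984L, 3697L, 231L,
                                           53L, 109L, 78L, 60L, 121L)))
  for (s in specs) expect_equal(sum(s$pi), 1, tolerance = 1e-12)
})

test_that("the full pipeline on study-scale specs recovers three profile families", {
  tl <- tl16()
  study <- simulate_study(study_scale_spec(), tl, seed = 42)
  ca <- join_ages(study$catalog, study$age_table)
  dist <- age_distributions(ca, tl)
  hc <- complete_linkage(ks_distance_matrix(dist))
  groups <- cutree(hc, k = 3)
  fam <- list(
    old = c("housekeeping", "oncogene", "tumor_suppressor", "differentiation"),
    mid = c("homeobox", "apoptosis", "ct_autosomal", "gstse_coding"),
    young = c("ct_x", "gstse_noncoding")
  )
  for (f in fam) expect_equal(length(unique(groups[f])), 1)
  expect_equal(length(unique(groups[vapply(fam, `[`, character(1), 1)])), 3)
})

test_that("class specs round-trip through JSON", {
  specs <- list(
    class_spec("a", 10, c(0.5, 0.5)),
    class_spec("b", 5, c(0.2, 0.8), overlap_with = "a", shared_frac = 0.4)
  )
  path <- withr::local_tempfile(fileext = ".json")
  write_class_specs(specs, path)
  back <- read_class_specs(path)
  expect_equal(back$a$pi, c(0.5, 0.5))
  expect_equal(back$b$overlap_with, "a")
  expect_equal(back$b$shared_frac, 0.4)
})
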