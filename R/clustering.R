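#' Complete-linkage clustering of classes by KS distance
#'
#' Agglomerative clustering where the distance between clusters is the
#' maximum pairwise KS distance between their member curves. Complete
#' linkage is monotone, so merge heights never decrease toward the root.
#'
#' @param d Symmetric distance matrix with labels (see
#'   [ks_distance_matrix()]).
#' @return An [stats::hclust] object.
#' @export
complete_linkage <- function(d) {
  d <- as.matrix(d)
  if (any(is.na(d)) || any(!is.finite(d))) abort("distance matrix contains NA/NaN.")
  if (nrow(d) < 2) abort("need at least 2 labels.")
  hclust(as.dist(d), method = "complete")
}

#' Serialize a dendrogram as an ultrametric Newick string
#'
#' Leaves sit at depth equal to the root merge height; each branch length
#' is the difference between the parent and child merge heights (leaves
#' have height 0). The output is parseable by standard Newick readers.
#'
#' @param hc An [stats::hclust] object.
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string, semicolon-terminated.
#' @export
to_newick <- function(hc, digits = 10) {
  stopifnot(inherits(hc, "hclust"))
  fmt <- function(x) format(x, digits = digits, trim = TRUE, scientific = FALSE)
  min_leaf <- function(i) {
    if (i < 0) hc$labels[-i]
    else min(vapply(hc$merge[i, ], min_leaf, character(1)))
  }
  # children ordered by their smallest leaf label, for a stable layout
  children <- function(i) hc$merge[i, order(vapply(hc$merge[i, ], min_leaf,
                                                   character(1)))]
  node <- function(i, parent_h) {
    if (i < 0) {
      lab <- hc$labels[-i]
      paste0(lab, ":", fmt(parent_h))
    } else {
      h <- hc$height[i]
      kids <- vapply(children(i), node, character(1), parent_h = h)
      paste0("(", paste(kids, collapse = ","), "):", fmt(parent_h - h))
    }
  }
  root <- nrow(hc$merge)
  h <- hc$height[root]
  kids <- vapply(children(root), node, character(1), parent_h = h)
  paste0("(", paste(kids, collapse = ","), ");")
}

# Leaf-label sets of every internal node, in merge order.
clade_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[i, ]
    sets[[i]] <- sort(unlist(lapply(kids, function(j) {
      if (j < 0) hc$labels[-j] else sets[[j]]
    })))
  }
  sets
}

# Bootstrap resample of a class's taxon counts: multinomial on the
# empirical profile (identical in law to resampling the age multiset
# with replacement at the same size).
boot_counts <- function(counts, n_boot) {
  n <- sum(counts)
  rmultinom(n_boot, n, counts / n)
}

#' Bootstrap support for the KS-distance classification
#'
#' Resamples every class at its own size `n_boot` times, rebuilds the
#' curves, the KS distance matrix and the complete-linkage tree on each
#' replicate, and reports for every internal node of the original tree
#' the fraction of replicate trees containing the same leaf set as a
#' clade (topology-only comparison). Classes are resampled independently
#' even when they share genes.
#'
#' @param class_ages A `class_ages` tibble.
#' @param tl A [timeline()].
#' @param n_boot Bootstrap replicates (study default 10000).
#' @param seed Integer seed.
#' @return List with `tree` (the original [stats::hclust]), `support`
#'   (tibble: `node_id`, `height`, `leaf_set`, `support`) and `n_boot`.
#' @export
bootstrap_trees <- function(class_ages, tl, n_boot = 10000, seed = 1L) {
  ages <- ages_by_class(class_ages)
  if (length(ages) < 2) abort("need at least 2 classes.")
  k <- n_taxa(tl)
  counts <- lapply(ages, tabulate, nbins = k)
  ns <- vapply(counts, sum, numeric(1))
  cums <- vapply(counts, function(cc) cumsum(cc) / sum(cc), numeric(k))
  d0 <- cum_dist_matrix(cums)
  tree <- complete_linkage(d0)
  orig <- clade_sets(tree)
  keys <- vapply(orig, paste, character(1), collapse = "\r")
  hits <- integer(length(orig))
  withr::with_seed(seed, {
    boots <- lapply(counts, boot_counts, n_boot = n_boot)
    for (b in seq_len(n_boot)) {
      cumb <- vapply(seq_along(counts), function(j) {
        cumsum(boots[[j]][, b]) / ns[j]
      }, numeric(k))
      colnames(cumb) <- names(counts)
      hcb <- complete_linkage(cum_dist_matrix(cumb))
      kb <- vapply(clade_sets(hcb), paste, character(1), collapse = "\r")
      hits <- hits + (keys %in% kb)
    }
  })
  support <- tibble::tibble(
    node_id = seq_along(orig),
    height = tree$height,
    leaf_set = vapply(orig, paste, character(1), collapse = ","),
    support = hits / n_boot
  )
  list(tree = tree, support = support, n_boot = n_boot, seed = seed)
}

# KS distance matrix from a k x m matrix of cumulative curves (columns).
cum_dist_matrix <- function(cums) {
  m <- ncol(cums)
  labs <- colnames(cums)
  d <- matrix(0, m, m, dimnames = list(labs, labs))
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      d[i, j] <- d[j, i] <- max(abs(cums[, i] - cums[, j]))
    }
  }
  d
}

#' Bootstrap rates of stochastic ordering for one class pair
#'
#' Resamples both classes `n_boot` times and classifies each replicate
#' pair by comparing the two cumulative curves at every breakpoint below
#' the last: `a_lower` when A's curve is everywhere <= B's with strict
#' inequality somewhere (A stochastically younger), `b_lower` the mirror
#' case, `crossing` otherwise. Replicates with identical curves carry no
#' strict order and are counted under `crossing` (reported separately as
#' `tied`). The three rates sum to 1.
#'
#' @param ages_a,ages_b Integer taxon index vectors.
#' @param k Number of timeline taxa.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @return One-row tibble: `a_lower`, `b_lower`, `crossing`, `tied`,
#'   `n_boot`.
#' @export
bootstrap_order_rates <- function(ages_a, ages_b, k = max(ages_a, ages_b),
                                  n_boot = 10000, seed = 1L) {
  ca <- tabulate(ages_a, k); cb <- tabulate(ages_b, k)
  na <- sum(ca); nb <- sum(cb)
  withr::with_seed(seed, {
    ba <- apply(boot_counts(ca, n_boot), 2, cumsum) / na
    bb <- apply(boot_counts(cb, n_boot), 2, cumsum) / nb
    diff <- (ba - bb)[-k, , drop = FALSE]
    lo <- colSums(diff < 0) ; hi <- colSums(diff > 0)
    a_lower <- mean(lo > 0 & hi == 0)
    b_lower <- mean(hi > 0 & lo == 0)
    tied <- mean(lo == 0 & hi == 0)
    tibble::tibble(a_lower = a_lower, b_lower = b_lower,
                   crossing = 1 - a_lower - b_lower, tied = tied,
                   n_boot = n_boot)
  })
}

#' Bootstrap exploratory statistics of one class curve
#'
#' Resamples the class `n_boot` times and summarises the bootstrapped
#' cumulative proportion at each taxon breakpoint: mean, mean squared
#' error about the original curve, median and quartiles.
#'
#' @param ages Integer taxon index vector of the class.
#' @param tl A [timeline()].
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @return Tibble with one row per breakpoint: `taxon_index`, `taxon`,
#'   `age_ma`, `original`, `boot_mean`, `boot_mse`, `boot_median`,
#'   `boot_q25`, `boot_q75`.
#' @export
bootstrap_curve_stats <- function(ages, tl, n_boot = 10000, seed = 1L) {
  k <- n_taxa(tl)
  counts <- tabulate(ages, k)
  n <- sum(counts)
  orig <- cumsum(counts) / n
  withr::with_seed(seed, {
    bc <- apply(boot_counts(counts, n_boot), 2, cumsum) / n  # k x n_boot
    qs <- apply(bc, 1, quantile, probs = c(0.25, 0.5, 0.75))
    tibble::tibble(
      taxon_index = seq_len(k), taxon = tl$taxon, age_ma = tl$age_ma,
      original = orig,
      boot_mean = rowMeans(bc),
      boot_mse = rowMeans((bc - orig)^2),
      boot_median = qs[2, ],
      boot_q25 = qs[1, ],
      boot_q75 = qs[3, ]
    )
  })
}
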