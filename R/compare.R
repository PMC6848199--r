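#' Kolmogorov-Smirnov distance between two class curves
#'
#' The maximum absolute difference between two cumulative origination
#' curves over the taxon breakpoints. Because both curves are step CDFs on
#' the same support, the breakpoint maximum is the full supremum distance.
#'
#' @param a,b Either numeric cumulative-proportion vectors of equal length,
#'   or single-class `age_distribution` tibbles on the same timeline.
#' @return A value in `[0, 1]`.
#' @export
ks_distance <- function(a, b) {
  ca <- if (is.data.frame(a)) one_class_cum(a) else as.numeric(a)
  cb <- if (is.data.frame(b)) one_class_cum(b) else as.numeric(b)
  if (length(ca) != length(cb)) {
    abort("cumulative curves live on different numbers of taxa.")
  }
  max(abs(ca - cb))
}

one_class_cum <- function(dist) {
  if (length(unique(dist$class)) != 1) {
    abort("expected a single-class distribution; got several classes.")
  }
  dist$cum[order(dist$taxon_index)]
}

#' Two-sample Kolmogorov-Smirnov test for discrete gene ages
#'
#' Computes the KS statistic between the empirical age distributions of
#' two classes and reports two p-values: the asymptotic two-sample
#' Kolmogorov p (conservative under the heavy ties of a 16-point support)
#' and a permutation p obtained by relabelling genes between the classes
#' (equivalently, drawing contingency tables with fixed margins), which is
#' the headline p-value for tied data.
#'
#' @param ages_a,ages_b Integer taxon indices of the two classes.
#' @param k Number of timeline taxa (defaults to the observed maximum).
#' @param n_perm Number of permutation replicates.
#' @param seed Integer seed for the permutation draw.
#' @return One-row tibble: `statistic`, `p_asym`, `p_perm`, `n_a`, `n_b`.
#' @export
ks_two_sample_test <- function(ages_a, ages_b, k = max(ages_a, ages_b),
                               n_perm = 9999, seed = 1L) {
  stopifnot(length(ages_a) >= 1, length(ages_b) >= 1)
  ca <- cumsum(tabulate(ages_a, k)) / length(ages_a)
  cb <- cumsum(tabulate(ages_b, k)) / length(ages_b)
  stat <- max(abs(ca - cb))
  p_asym <- if (stat == 0) 1 else
    suppressWarnings(ks.test(ages_a, ages_b, exact = FALSE)$p.value)
  p_perm <- ks_permutation_p(tabulate(ages_a, k), tabulate(ages_b, k),
                             stat, n_perm, seed)
  tibble::tibble(statistic = stat, p_asym = p_asym, p_perm = p_perm,
                 n_a = length(ages_a), n_b = length(ages_b))
}

# Permutation p for the tied KS statistic via fixed-margin tables.
ks_permutation_p <- function(counts_a, counts_b, stat, n_perm, seed) {
  na <- sum(counts_a); nb <- sum(counts_b)
  pooled <- counts_a + counts_b
  withr::with_seed(seed, {
    tabs <- r2dtable(n_perm, c(na, nb), pooled)
    exceed <- vapply(tabs, function(tb) {
      d <- max(abs(cumsum(tb[1, ]) / na - cumsum(tb[2, ]) / nb))
      d >= stat - 1e-12
    }, logical(1))
    (1 + sum(exceed)) / (1 + n_perm)
  })
}

#' Chi-square homogeneity test on a class-by-taxon count table
#'
#' Pearson's X^2 on an r x c origination count table after dropping
#' all-zero columns (taxa where no class originated anything contribute no
#' information and would zero the expected counts). Degrees of freedom are
#' (r - 1)(c_used - 1).
#'
#' @param counts Nonnegative integer matrix, classes in rows, taxa in
#'   columns; every row total must be positive.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `c_used`.
#' @export
chisq_homogeneity <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort("counts must be nonnegative.")
  if (any(rowSums(counts) == 0)) abort("degenerate table: empty row.")
  keep <- colSums(counts) > 0
  m <- counts[, keep, drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort("degenerate table: fewer than 2 usable rows or columns.")
  }
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = ct$p.value, c_used = ncol(m))
}

#' KS distance matrix over all classes
#'
#' @param dist An `age_distribution` tibble with >= 2 classes.
#' @return Symmetric matrix of KS distances with zero diagonal, labelled by
#'   class.
#' @export
ks_distance_matrix <- function(dist) {
  parts <- dist_split(dist)
  labs <- names(parts)
  if (length(labs) < 2) abort("need at least 2 classes.")
  if (anyDuplicated(labs)) abort("duplicate class labels.")
  k <- length(labs)
  d <- matrix(0, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d[i, j] <- d[j, i] <- max(abs(parts[[i]]$cum - parts[[j]]$cum))
    }
  }
  d
}

#' All pairwise class comparisons
#'
#' Runs the KS two-sample test (asymptotic and permutation p) and the
#' chi-square homogeneity test on every unordered class pair, returning
#' the KS distance matrix and a long-format test table with Holm-adjusted
#' permutation p-values.
#'
#' @param class_ages A `class_ages` tibble (see [join_ages()]).
#' @param tl A [timeline()].
#' @param n_perm Permutation replicates per pair.
#' @param seed Integer seed.
#' @return List with `distance` (matrix) and `tests` (tibble: `class_a`,
#'   `class_b`, `ks_stat`, `ks_p_asym`, `ks_p_perm`, `chi2`, `df`,
#'   `chi2_p`, `holm_p`).
#' @export
pairwise_tests <- function(class_ages, tl, n_perm = 9999, seed = 1L) {
  ages <- ages_by_class(class_ages)
  if (length(ages) < 2) abort("need at least 2 classes.")
  dist <- age_distributions(class_ages, tl)
  dmat <- ks_distance_matrix(dist)
  labs <- names(ages)
  pairs <- combn(labs, 2)
  k <- n_taxa(tl)
  rows <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    ks <- ks_two_sample_test(ages[[a]], ages[[b]], k = k,
                             n_perm = n_perm, seed = seed + i)
    tab <- rbind(tabulate(ages[[a]], k), tabulate(ages[[b]], k))
    ch <- chisq_homogeneity(tab)
    tibble::tibble(class_a = a, class_b = b,
                   ks_stat = ks$statistic, ks_p_asym = ks$p_asym,
                   ks_p_perm = ks$p_perm, chi2 = ch$statistic,
                   df = ch$df, chi2_p = ch$p_value)
  })
  rows$holm_p <- holm_adjust(rows$ks_p_perm)
  list(distance = dmat, tests = rows)
}

#' Holm step-down multiple-testing adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone, capped at 1), in input order.
#' @export
holm_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "holm")
}
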