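#' Pairwise gene-class overlap analysis
#'
#' Builds the 2x2 contingency table of joint membership over the gene
#' universe (in both / A only / B only / neither), the expected overlap
#' under independent attendance `N * (|A|/N) * (|B|/N)`, and the plain
#' chi-square (no continuity correction) and two-sided Fisher exact
#' p-values.
#'
#' @param genes_a,genes_b Character vectors of gene ids (both subsets of
#'   `universe`).
#' @param universe Character vector of all genes under consideration.
#' @return One-row tibble: `n_a`, `n_b`, `n_universe`, `observed`,
#'   `expected`, `a_only`, `b_only`, `neither`, `chi2_p`, `fisher_p`.
#' @export
contingency_2x2 <- function(genes_a, genes_b, universe) {
  universe <- unique(universe)
  genes_a <- unique(genes_a); genes_b <- unique(genes_b)
  extra <- c(setdiff(genes_a, universe), setdiff(genes_b, universe))
  if (length(extra)) {
    abort(paste0("gene(s) outside the universe: ",
                 paste(head(unique(extra), 5), collapse = ", ")))
  }
  n <- length(universe)
  both <- length(intersect(genes_a, genes_b))
  a_only <- length(genes_a) - both
  b_only <- length(genes_b) - both
  neither <- n - both - a_only - b_only
  tab <- matrix(c(both, a_only, b_only, neither), 2, 2, byrow = TRUE)
  chi2_p <- tryCatch(chisq_homogeneity(tab)$p_value, error = function(e) NA_real_)
  tibble::tibble(
    n_a = length(genes_a), n_b = length(genes_b), n_universe = n,
    observed = both,
    expected = n * (length(genes_a) / n) * (length(genes_b) / n),
    a_only = a_only, b_only = b_only, neither = neither,
    chi2_p = chi2_p,
    fisher_p = fisher_exact_2x2(tab)
  )
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Sums hypergeometric probabilities of all tables with the observed
#' margins whose point probability does not exceed that of the observed
#' table. A table with a zero margin is degenerate and returns p = 1 by
#' convention.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  fisher.test(tab, alternative = "two.sided")$p.value
}

#' Overlap table over all class pairs
#'
#' @param catalog A `gene_class_catalog`.
#' @param universe Universe of genes; defaults to the catalog's universe
#'   attribute (set it to the detected genes of an age table for
#'   study-style expected counts).
#' @return Tibble with one row per unordered class pair: `class_a`,
#'   `class_b` plus the [contingency_2x2()] columns.
#' @export
overlap_table <- function(catalog, universe = NULL) {
  if (is.null(universe)) universe <- attr(catalog, "universe")
  labs <- sort(unique(catalog$class))
  if (length(labs) < 2) abort("need at least 2 classes.")
  pairs <- combn(labs, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    dplyr::bind_cols(
      tibble::tibble(class_a = a, class_b = b),
      contingency_2x2(class_genes(catalog, a), class_genes(catalog, b), universe)
    )
  })
}

#' Derive a new class by set algebra
#'
#' Supports intersection (`"A x B"`) and difference (`"A - B"`) over
#' existing classes, so subclasses such as "differentiation x tumor
#' suppressor" or "differentiation - oncogene" can be pushed through every
#' other analysis stage.
#'
#' @param catalog A `gene_class_catalog`.
#' @param expr A string `"A x B"` or `"A - B"` naming two existing classes.
#' @param name Name of the derived class; defaults to the expression with
#'   spaces removed.
#' @return The catalog with the derived class appended.
#' @export
class_algebra <- function(catalog, expr, name = NULL) {
  m <- regmatches(expr, regexec("^\\s*(.+?)\\s+(x|-)\\s+(.+?)\\s*$", expr))[[1]]
  if (length(m) != 4) abort("expr must look like 'A x B' or 'A - B'.")
  a <- m[2]; op <- m[3]; b <- m[4]
  ga <- class_genes(catalog, a)
  gb <- class_genes(catalog, b)
  genes <- if (op == "x") intersect(ga, gb) else setdiff(ga, gb)
  if (is.null(name)) name <- paste0(a, if (op == "x") " x " else " - ", b)
  if (name %in% catalog$class) abort(paste0("class already exists: ", name))
  add <- tibble::tibble(gene = genes, class = name)
  out <- dplyr::bind_rows(tibble::as_tibble(catalog), add)
  class_catalog(out, universe = attr(catalog, "universe"))
}

#' Multi-way class intersections
#'
#' For every class triple (and quadruple when `max_order = 4`) reports the
#' intersection count and the share of the intersection within each member
#' class.
#'
#' @param catalog A `gene_class_catalog`.
#' @param max_order 3 or 4.
#' @return Tibble with one row per combination x member class: `classes`
#'   (comma-joined), `order`, `count`, `member`, `member_size`, `share`.
#' @export
multiway_intersections <- function(catalog, max_order = 3) {
  stopifnot(max_order %in% c(3, 4))
  labs <- sort(unique(catalog$class))
  sets <- lapply(labs, class_genes, catalog = catalog)
  names(sets) <- labs
  orders <- 3:max_order
  purrr::map_dfr(orders, function(ord) {
    if (length(labs) < ord) return(tibble::tibble())
    cmb <- combn(labs, ord)
    purrr::map_dfr(seq_len(ncol(cmb)), function(i) {
      members <- cmb[, i]
      inter <- Reduce(intersect, sets[members])
      tibble::tibble(
        classes = paste(members, collapse = ","),
        order = ord,
        count = length(inter),
        member = members,
        member_size = lengths(sets[members]),
        share = ifelse(lengths(sets[members]) > 0,
                       length(inter) / lengths(sets[members]), NA_real_)
      )
    })
  })
}
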