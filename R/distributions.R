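#' Cumulative origination curves of gene classes
#'
#' For each class, counts originations per timeline taxon and accumulates
#' them into the cumulative origination curve C(s) = share of the class's
#' genes with taxon index <= s. C is the CDF of the origination step;
#' equivalently 1 - C(s-1) is the survival function of gene age, so a class
#' whose age is stochastically smaller (the class is *younger*) has an age
#' CDF that is everywhere larger, i.e. an origination curve that lies
#' everywhere at or below the other class's curve.
#'
#' @param class_ages A `class_ages` tibble from [join_ages()], or any data
#'   frame with columns `class` and `taxon_index`.
#' @param tl A [timeline()].
#' @return An `age_distribution` tibble with one row per class x taxon:
#'   `class`, `taxon_index`, `taxon`, `age_ma`, `n` (class size), `count`,
#'   `cum`.
#' @export
#' @examples
#' tl <- timeline(c("A", "B", "C"), c(100, 50, 10), root_age = 150)
#' df <- data.frame(class = "x", taxon_index = c(1, 1, 2))
#' age_distributions(df, tl)
age_distributions <- function(class_ages, tl) {
  stopifnot(all(c("class", "taxon_index") %in% names(class_ages)))
  if (inherits(class_ages, "class_ages")) {
    # refuse classes flagged empty by the coverage report
    invisible(ages_by_class(class_ages))
  }
  if (nrow(class_ages) == 0) abort("empty class")
  k <- n_taxa(tl)
  if (any(class_ages$taxon_index < 1 | class_ages$taxon_index > k)) {
    abort("taxon_index outside the timeline.")
  }
  out <- purrr::imap_dfr(
    split(class_ages$taxon_index, class_ages$class),
    function(ages, cls) {
      counts <- tabulate(ages, nbins = k)
      tibble::tibble(
        class = cls,
        taxon_index = seq_len(k),
        taxon = tl$taxon,
        age_ma = tl$age_ma,
        n = length(ages),
        count = counts,
        cum = cumsum(counts) / length(ages)
      )
    }
  )
  class(out) <- c("age_distribution", class(out))
  out
}

#' @rdname age_distributions
#' @param age_vector Integer taxon indices of one class.
#' @param class_name Label for the class.
#' @export
build_distribution <- function(age_vector, tl, class_name = "class") {
  if (length(age_vector) == 0) abort("empty class")
  age_distributions(
    tibble::tibble(class = class_name, taxon_index = as.integer(age_vector)), tl
  )
}

# Split an age_distribution tibble into per-class lists (n, counts, cum).
dist_split <- function(dist) {
  lapply(split(dist, dist$class), function(d) {
    d <- d[order(d$taxon_index), ]
    list(class = d$class[1], n = d$n[1], counts = d$count, cum = d$cum)
  })
}

#' Median evolutionary age of each class
#'
#' The class age reported for a curve is the time point at which the
#' interpolated cumulative origination curve reaches 50%. The curve is the
#' polyline through the breakpoints (age_s, C(s)) on the Ma axis, anchored
#' on the left at (root_age, 0); the median is its unique 0.5 crossing
#' (the oldest such time when the crossing segment is flat). Linear
#' interpolation between taxon breakpoints is what lets the median fall
#' between divergence times.
#'
#' @param dist An `age_distribution` tibble.
#' @param tl The [timeline()] it was built on.
#' @return Tibble with `class`, `n`, `median_ma`.
#' @export
median_age <- function(dist, tl) {
  purrr::imap_dfr(dist_split(dist), function(d, cls) {
    tibble::tibble(
      class = cls, n = d$n,
      median_ma = median_from_curve(d$cum, tl$age_ma, root_age(tl))
    )
  })
}

# 0.5 crossing of the polyline ((root_age,0), (age_1,C1), ..., (age_k,Ck)).
median_from_curve <- function(cum, age_ma, root_age, prob = 0.5) {
  t_pts <- c(root_age, age_ma)
  c_pts <- c(0, cum)
  s <- which(c_pts >= prob)[1]
  if (is.na(s)) abort("curve never reaches the requested probability.")
  if (c_pts[s] == prob) return(t_pts[s])
  # c_pts[s-1] < prob < c_pts[s]; interpolate on the Ma axis
  t0 <- t_pts[s - 1]; t1 <- t_pts[s]
  c0 <- c_pts[s - 1]; c1 <- c_pts[s]
  t0 - (prob - c0) / (c1 - c0) * (t0 - t1)
}

#' Proportion of a class originated between two taxa
#'
#' The share of a class's genes with taxon index in `(a, b]` where `a` is
#' the older and `b` the younger query taxon — i.e. genes that originated
#' strictly after branch point `a` and at or before `b`. With `a == b` the
#' share of genes in that single bucket is returned.
#'
#' @param dist An `age_distribution` tibble.
#' @param tl The [timeline()].
#' @param from,to Taxon names; `from` must be at least as old as `to`.
#' @return Tibble with `class` and `proportion`.
#' @export
originated_between <- function(dist, tl, from, to) {
  a <- taxon_index(tl, from)
  b <- taxon_index(tl, to)
  if (a > b) abort("`from` must be older than (or equal to) `to`.")
  purrr::imap_dfr(dist_split(dist), function(d, cls) {
    p <- if (a == b) d$counts[a] / d$n else d$cum[b] - d$cum[a]
    tibble::tibble(class = cls, proportion = p)
  })
}

#' Export distribution curves as a plain CSV
#'
#' One row per class x taxon with the per-taxon count and the cumulative
#' share — the data behind cumulative origination figures.
#'
#' @param dist An `age_distribution` tibble.
#' @param path Output CSV path.
#' @export
write_distributions <- function(dist, path) {
  readr::write_csv(
    dist[, c("class", "taxon", "age_ma", "count", "cum")], path
  )
  invisible(path)
}
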