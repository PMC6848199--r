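#' Species timeline for gene-age analysis
#'
#' A timeline is the ordered set of branch points of a linear lineage
#' (oldest first) together with their divergence times in million years
#' (Ma). Every age distribution in the package lives on a timeline: a
#' gene's age is the index of the oldest taxon whose genomes contain a
#' detectable homolog, and the taxon's divergence time is reported as a
#' lower bound on the gene's origin time.
#'
#' @param taxa Character vector of taxon names, ordered oldest to newest.
#' @param age_ma Numeric vector of divergence times in Ma, strictly
#'   decreasing, same length as `taxa`; the last entry may be 0.
#' @param root_age Single Ma value assigned to the left anchor of the
#'   cumulative curve (the "before the oldest taxon" bucket). Must be
#'   strictly greater than `age_ma[1]`. A display and median-interpolation
#'   convention, not a biological claim.
#'
#' @return A `geneage_timeline`: a tibble with columns `taxon` and
#'   `age_ma` plus a `root_age` attribute.
#' @export
#' @examples
#' timeline(c("A", "B"), c(100, 10), root_age = 150)
timeline <- function(taxa, age_ma, root_age) {
  taxa <- as.character(taxa)
  age_ma <- as.numeric(age_ma)
  if (length(taxa) != length(age_ma)) {
    abort("`taxa` and `age_ma` must have the same length.")
  }
  if (length(taxa) < 2) abort("a timeline needs at least 2 taxa.")
  if (anyDuplicated(taxa)) {
    abort(paste0("duplicate taxon name: ", taxa[duplicated(taxa)][1]))
  }
  if (any(is.na(age_ma))) abort("ages must not be NA.")
  bad <- which(diff(age_ma) >= 0)
  if (length(bad)) {
    abort(sprintf(
      "ages not strictly decreasing at row %d (%s: %g followed by %s: %g)",
      bad[1] + 1, taxa[bad[1]], age_ma[bad[1]], taxa[bad[1] + 1], age_ma[bad[1] + 1]
    ))
  }
  if (age_ma[length(age_ma)] < 0) abort("last age must be >= 0.")
  root_age <- as.numeric(root_age)
  if (length(root_age) != 1 || is.na(root_age) || root_age <= age_ma[1]) {
    abort("`root_age` must be a single value strictly greater than the oldest taxon age.")
  }
  out <- tibble::tibble(taxon = taxa, age_ma = age_ma)
  attr(out, "root_age") <- root_age
  class(out) <- c("geneage_timeline", class(out))
  out
}

#' Default 16-taxon human-lineage timeline
#'
#' The branch points of the human lineage used throughout the package, from
#' Cellular Organisms down to *H. sapiens*. Divergence times for
#' Opisthokonta (1368 Ma), Bilateria (910 Ma), Chordata (797 Ma) and
#' Homininae (6 Ma) are fixed study values; the remaining ages are package
#' defaults in the TimeTree style and can be overridden by loading a custom
#' timeline with [read_timeline()].
#'
#' @param root_age Ma value of the left curve anchor; default 4200.
#' @return A [timeline()] of 16 taxa.
#' @export
#' @examples
#' tl <- default_timeline()
#' age_of(tl, "Opisthokonta")
default_timeline <- function(root_age = 4200) {
  timeline(
    taxa = c(
      "Cellular Organisms", "Eukaryota", "Opisthokonta", "Bilateria",
      "Deuterostomia", "Chordata", "Euteleostomi", "Tetrapoda", "Amniota",
      "Mammalia", "Theria", "Eutheria", "Euarchontoglires", "Catarrhini",
      "Homininae", "H. sapiens"
    ),
    age_ma = c(
      3900, 2101, 1368, 910, 860, 797, 435, 352, 312,
      177, 159, 105, 90, 29, 6, 0
    ),
    root_age = root_age
  )
}

#' Read / write a timeline CSV
#'
#' The on-disk form is a two-column CSV `taxon,age_ma` ordered oldest to
#' newest; lines starting with `#` are comments. The root age travels as a
#' `# root_age: <Ma>` comment on the first line.
#'
#' @param path File path.
#' @return `read_timeline()` returns a validated [timeline()];
#'   `write_timeline()` returns `path` invisibly.
#' @export
read_timeline <- function(path) {
  if (!file.exists(path)) abort(paste0("timeline file not found: ", path))
  first <- readLines(path, n = 1L)
  root_age <- NA_real_
  m <- regmatches(first, regexec("^#\\s*root_age:\\s*([0-9.eE+-]+)", first))[[1]]
  if (length(m) == 2) root_age <- as.numeric(m[2])
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(taxon = "c", age_ma = "d"))
  if (!all(c("taxon", "age_ma") %in% names(df))) {
    abort("timeline CSV must have columns `taxon` and `age_ma`.")
  }
  if (is.na(root_age)) root_age <- max(df$age_ma) * 1.05
  timeline(df$taxon, df$age_ma, root_age = root_age)
}

#' @rdname read_timeline
#' @param tl A [timeline()].
#' @export
write_timeline <- function(tl, path) {
  stopifnot(inherits(tl, "geneage_timeline"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# root_age: %.10g", root_age(tl)), con)
  writeLines("taxon,age_ma", con)
  writeLines(sprintf("%s,%.10g", tl$taxon, tl$age_ma), con)
  invisible(path)
}

#' Timeline accessors
#'
#' @param tl A [timeline()].
#' @param taxon Taxon name(s) to look up.
#' @return `age_of()` the divergence time(s) in Ma; `root_age()` the root
#'   anchor age; `n_taxa()` the number of taxa; `taxon_index()` the 1-based
#'   position (1 = oldest).
#' @details The oldest bucket is open-ended ("at or before this branch
#'   point"), so `age_of()` reports it at `root_age`; the bucket's own
#'   `age_ma` entry is the breakpoint used on cumulative curves.
#' @export
age_of <- function(tl, taxon) {
  i <- taxon_index(tl, taxon)
  ifelse(i == 1L, root_age(tl), tl$age_ma[i])
}

#' @rdname age_of
#' @export
taxon_index <- function(tl, taxon) {
  i <- match(taxon, tl$taxon)
  if (anyNA(i)) {
    abort(paste0(
      "unknown taxon: ", paste(taxon[is.na(i)], collapse = ", "),
      "; valid names are: ", paste(tl$taxon, collapse = ", ")
    ))
  }
  i
}

#' @rdname age_of
#' @export
root_age <- function(tl) attr(tl, "root_age")

#' @rdname age_of
#' @export
n_taxa <- function(tl) nrow(tl)
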