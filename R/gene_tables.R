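#' Read a gene-age table
#'
#' Reads per-gene age assignments in the style of ProteinHistorian output:
#' a TSV with a header and two columns, `gene_id` plus either `taxon`
#' (taxon-of-origin name, dialect A) or `age_ma` (divergence time in Ma,
#' dialect B). The dialect is auto-detected from the header. Ma values are
#' mapped to the oldest taxon whose divergence time is at most
#' `value + tolerance`.
#'
#' @param path TSV path.
#' @param tl A [timeline()].
#' @param tolerance Ma slack when matching dialect-B ages to taxa.
#' @return A tibble with columns `gene_id` and `taxon_index` (1 = oldest).
#' @export
read_age_table <- function(path, tl, tolerance = 1e-6) {
  if (!file.exists(path)) abort(paste0("age table not found: ", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  if (nrow(df) == 0) abort("age table is empty.")
  if (!"gene_id" %in% names(df)) abort("age table must have a `gene_id` column.")
  if ("taxon" %in% names(df)) {
    idx <- match(df$taxon, tl$taxon)
    if (anyNA(idx)) {
      bad <- unique(df$taxon[is.na(idx)])
      near <- vapply(bad, function(b) {
        d <- utils::adist(b, tl$taxon)
        paste(tl$taxon[order(d)][1:2], collapse = " / ")
      }, character(1))
      abort(paste0(
        "unknown taxon name(s) in age table: ",
        paste(sprintf("%s (nearest: %s)", bad, near), collapse = "; ")
      ))
    }
  } else if ("age_ma" %in% names(df)) {
    idx <- vapply(df$age_ma, function(a) {
      ok <- which(tl$age_ma <= a + tolerance)
      if (!length(ok)) length(tl$age_ma) else min(ok)
    }, integer(1))
  } else {
    abort("age table must have a `taxon` or an `age_ma` column.")
  }
  if (anyDuplicated(df$gene_id)) {
    abort(paste0("duplicate gene id(s): ",
                 paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", ")))
  }
  tibble::tibble(gene_id = as.character(df$gene_id), taxon_index = as.integer(idx))
}

#' Write a gene-age table (dialect A)
#'
#' @param age_table Tibble from [read_age_table()] or [simulate_study()].
#' @param tl A [timeline()].
#' @param path Output TSV path.
#' @export
write_age_table <- function(age_table, tl, path) {
  readr::write_tsv(
    tibble::tibble(gene_id = age_table$gene_id,
                   taxon = tl$taxon[age_table$taxon_index]),
    path
  )
  invisible(path)
}

#' Build a gene-class catalog
#'
#' A catalog is a long membership table (`gene`, `class`) plus a gene
#' universe. Classes may overlap; duplicates within a class are collapsed.
#'
#' @param membership Data frame with columns `gene` and `class`.
#' @param universe Optional character vector of gene ids. Defaults to all
#'   genes present in the membership table until a join against an age
#'   table supplies the detected-gene universe.
#' @param empty_classes Names of classes declared with no members (kept so
#'   size and coverage reports still list them).
#' @return A `gene_class_catalog` tibble.
#' @export
class_catalog <- function(membership, universe = NULL, empty_classes = character()) {
  stopifnot(all(c("gene", "class") %in% names(membership)))
  out <- tibble::tibble(
    gene = stringr::str_trim(as.character(membership$gene)),
    class = as.character(membership$class)
  ) |>
    dplyr::distinct()
  attr(out, "universe") <- if (is.null(universe)) unique(out$gene) else unique(universe)
  attr(out, "empty_classes") <- setdiff(empty_classes, out$class)
  class(out) <- c("gene_class_catalog", class(out))
  out
}

#' Read gene-class membership lists
#'
#' Accepts either a set of plain-text files (one gene id per line, class
#' named after the file, or after the element name if `paths` is named) or
#' a single two-column CSV `gene,class`.
#'
#' @param paths Character vector of list files, or a single `gene,class`
#'   CSV path.
#' @param universe Optional universe passed to [class_catalog()].
#' @return A `gene_class_catalog`.
#' @export
read_class_lists <- function(paths, universe = NULL) {
  stopifnot(length(paths) >= 1)
  one_csv <- length(paths) == 1 && grepl("\\.csv$", paths, ignore.case = TRUE)
  if (one_csv) {
    df <- readr::read_csv(paths, show_col_types = FALSE, comment = "#")
    if (!all(c("gene", "class") %in% names(df))) {
      abort("class CSV must have columns `gene` and `class`.")
    }
    membership <- df[, c("gene", "class")]
  } else {
    nms <- names(paths)
    if (is.null(nms)) nms <- rep("", length(paths))
    empty <- character()
    membership <- purrr::map2_dfr(paths, nms, function(p, nm) {
      if (!file.exists(p)) abort(paste0("class list not found: ", p))
      ids <- stringr::str_trim(readLines(p))
      ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
      cls <- if (nzchar(nm)) nm else tools::file_path_sans_ext(basename(p))
      if (!length(ids)) {
        warn(paste0("class list is empty: ", p, " (class '", cls, "' retained empty)"))
        empty <<- c(empty, cls)
        return(tibble::tibble(gene = character(), class = character()))
      }
      tibble::tibble(gene = ids, class = cls)
    })
    return(class_catalog(membership, universe = universe, empty_classes = empty))
  }
  class_catalog(membership, universe = universe)
}

#' Class names and sizes of a catalog
#' @param catalog A `gene_class_catalog`.
#' @return A tibble with columns `class` and `n`.
#' @export
class_sizes <- function(catalog) {
  out <- dplyr::count(tibble::as_tibble(catalog), .data$class, name = "n")
  empty <- attr(catalog, "empty_classes")
  if (length(empty)) {
    out <- dplyr::arrange(
      dplyr::bind_rows(out, tibble::tibble(class = empty, n = 0L)),
      .data$class
    )
  }
  out
}

#' Genes of one class
#' @param catalog A `gene_class_catalog`.
#' @param class_name Class to extract.
#' @return Character vector of gene ids.
#' @export
class_genes <- function(catalog, class_name) {
  if (!class_name %in% catalog$class) {
    abort(paste0("unknown class: ", class_name))
  }
  unique(catalog$gene[catalog$class == class_name])
}

#' Join class membership with gene ages
#'
#' For each class, collects the taxon indices of its genes that are present
#' in the age table. Genes absent from the age table are excluded from all
#' downstream statistics but counted in the coverage report, mirroring the
#' "detected vs listed" bookkeeping of phylostratigraphic studies.
#'
#' @param catalog A `gene_class_catalog`.
#' @param age_table Tibble (`gene_id`, `taxon_index`).
#' @return A `class_ages` tibble (`class`, `gene_id`, `taxon_index`) with a
#'   `coverage` attribute: per-class `listed`, `detected`, `missing` counts
#'   (retrievable with [coverage()]). Classes with zero detected genes are
#'   kept in the coverage report and refused by downstream distribution
#'   builders.
#' @export
join_ages <- function(catalog, age_table) {
  mem <- tibble::as_tibble(catalog)
  joined <- dplyr::inner_join(mem, age_table, by = c(gene = "gene_id"))
  empty <- attr(catalog, "empty_classes")
  cov <- mem |>
    dplyr::group_by(class = .data$class) |>
    dplyr::summarise(listed = dplyr::n_distinct(.data$gene), .groups = "drop") |>
    dplyr::bind_rows(
      if (length(empty)) tibble::tibble(class = empty, listed = 0L)
    ) |>
    dplyr::left_join(
      joined |>
        dplyr::group_by(class = .data$class) |>
        dplyr::summarise(detected = dplyr::n_distinct(.data$gene), .groups = "drop"),
      by = "class"
    ) |>
    dplyr::mutate(
      detected = dplyr::coalesce(.data$detected, 0L),
      missing = .data$listed - .data$detected
    )
  out <- joined |>
    dplyr::transmute(class = .data$class, gene_id = .data$gene,
                     taxon_index = .data$taxon_index) |>
    dplyr::arrange(.data$class, .data$gene_id)
  attr(out, "coverage") <- cov
  class(out) <- c("class_ages", class(out))
  out
}

#' Coverage report of a join
#' @param x A `class_ages` tibble from [join_ages()].
#' @return Tibble with `class`, `listed`, `detected`, `missing`.
#' @export
coverage <- function(x) {
  cov <- attr(x, "coverage")
  if (is.null(cov)) abort("no coverage attribute; was this made by join_ages()?")
  cov
}

# Named list class -> integer age vector; refuses empty classes on request.
ages_by_class <- function(class_ages, refuse_empty = TRUE) {
  sp <- split(class_ages$taxon_index, class_ages$class)
  if (refuse_empty) {
    cov <- attr(class_ages, "coverage")
    if (!is.null(cov) && any(cov$detected == 0)) {
      abort(paste0("class(es) with zero detected genes: ",
                   paste(cov$class[cov$detected == 0], collapse = ", ")))
    }
  }
  sp
}
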