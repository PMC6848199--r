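#' Parse BLAST tabular hits into per-query hit profiles
#'
#' Reads 12-column BLAST tabular output (`-outfmt 6`: qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore), keeps
#' hits with E-value at most `max_evalue`, and resolves each subject to a
#' genome label through `subject_to_genome`. Used for the homology-based
#' age rule applied to sequences (e.g. non-coding) that are absent from
#' protein-family databases.
#'
#' @param path BLAST tabular file.
#' @param max_evalue Per-hit E-value cutoff; hits above it are discarded.
#' @param subject_to_genome Optional function mapping subject ids to genome
#'   labels (default: the subject id up to the first `|` or `:`), or a
#'   named character vector lookup.
#' @return A tibble (`query_id`, `genome`), one row per retained
#'   query-genome pair, with attribute `rejects`: a tibble of subjects no
#'   mapping was found for (empty with the default mapper).
#' @export
parse_blast_tab <- function(path, max_evalue = 1e-3, subject_to_genome = NULL) {
  if (!file.exists(path)) abort(paste0("BLAST file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    out <- tibble::tibble(query_id = character(), genome = character())
    attr(out, "rejects") <- tibble::tibble(subject = character())
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield != 12)) {
    abort(sprintf("malformed BLAST row at line %d: expected 12 columns, found %d",
                  which(nfield != 12)[1], nfield[nfield != 12][1]))
  }
  m <- do.call(rbind, fields)
  qry <- m[, 1]
  sbj <- m[, 2]
  ev <- as.numeric(m[, 11])
  if (anyNA(ev)) abort(sprintf("malformed E-value at line %d", which(is.na(ev))[1]))
  keep <- ev <= max_evalue
  qry <- qry[keep]; sbj <- sbj[keep]
  if (is.null(subject_to_genome)) {
    genome <- sub("[|:].*$", "", sbj)
    rejects <- tibble::tibble(subject = character())
  } else if (is.function(subject_to_genome)) {
    genome <- vapply(sbj, subject_to_genome, character(1), USE.NAMES = FALSE)
    rejects <- tibble::tibble(subject = unique(sbj[is.na(genome)]))
  } else {
    genome <- unname(subject_to_genome[sbj])
    rejects <- tibble::tibble(subject = unique(sbj[is.na(genome)]))
  }
  ok <- !is.na(genome)
  out <- tibble::tibble(query_id = qry[ok], genome = genome[ok]) |> dplyr::distinct()
  attr(out, "rejects") <- rejects
  out
}

#' Read a genome-to-taxon map
#'
#' Two-column CSV `genome,taxon`: each searched genome's branch-off point
#' from the focal lineage.
#'
#' @param path CSV path.
#' @return Named character vector (genome -> taxon).
#' @export
read_genome_map <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  stopifnot(all(c("genome", "taxon") %in% names(df)))
  setNames(as.character(df$taxon), as.character(df$genome))
}

#' Age of a sequence from its homolog presence profile
#'
#' The age bucket of a query is the most recent common ancestor of the
#' focal species and the most distant genome with a detectable homolog:
#' the OLDEST timeline taxon among the mapped hit genomes. A query with no
#' hits outside the focal species falls in the youngest bucket. The
#' reported divergence time is a lower bound on the true origin time,
#' since the sequence may have arisen anywhere along that branch.
#'
#' @param hits Tibble (`query_id`, `genome`) from [parse_blast_tab()]; may
#'   be filtered to one query.
#' @param genome_to_taxon Named character vector mapping genome labels to
#'   timeline taxon names (see [read_genome_map()]).
#' @param tl A [timeline()].
#' @param query_ids Optional character vector of all queries (so hitless
#'   queries still appear); defaults to the queries present in `hits`.
#' @return Tibble (`gene_id`, `taxon_index`), one row per query.
#' @export
mrca_age <- function(hits, genome_to_taxon, tl, query_ids = NULL) {
  unmapped <- setdiff(unique(hits$genome), names(genome_to_taxon))
  if (length(unmapped)) {
    abort(paste0("genome(s) not in the genome-to-taxon map: ",
                 paste(unmapped, collapse = ", ")))
  }
  idx <- taxon_index(tl, unname(genome_to_taxon[hits$genome]))
  per_query <- tapply(idx, hits$query_id, min)
  if (is.null(query_ids)) query_ids <- sort(unique(hits$query_id))
  res <- per_query[query_ids]
  res[is.na(res)] <- n_taxa(tl)  # no hits: restricted to the focal species
  tibble::tibble(gene_id = query_ids, taxon_index = as.integer(res))
}
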