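#' Specification of one synthetic gene class
#'
#' A class is generated as `n` genes whose taxon-of-origin indices are
#' drawn i.i.d. from the origination probability vector `pi` over the
#' timeline's taxa. A class may request to share a fraction of its genes
#' with a previously declared class.
#'
#' @param name Class name.
#' @param n Class size (>= 1).
#' @param pi Numeric probability vector over the k taxa (sums to 1).
#' @param overlap_with Optional name of an earlier class to share genes
#'   with.
#' @param shared_frac Fraction of this class's genes drawn from
#'   `overlap_with`'s members (in `[0, 1]`).
#' @return A `class_spec` list.
#' @export
class_spec <- function(name, n, pi, overlap_with = NULL, shared_frac = 0) {
  pi <- as.numeric(pi)
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-12) {
    abort("`pi` must be nonnegative and sum to 1 (within 1e-12).")
  }
  stopifnot(n >= 1, shared_frac >= 0, shared_frac <= 1)
  structure(list(name = name, n = as.integer(n), pi = pi,
                 overlap_with = overlap_with, shared_frac = shared_frac),
            class = "class_spec")
}

#' Draw one synthetic class
#'
#' @param spec A [class_spec()].
#' @param tl A [timeline()].
#' @param seed Integer seed.
#' @param id_prefix Prefix for generated gene ids.
#' @return Tibble (`gene_id`, `taxon_index`) of `spec$n` genes.
#' @export
simulate_class <- function(spec, tl, seed = 1L, id_prefix = spec$name) {
  k <- n_taxa(tl)
  if (length(spec$pi) != k) abort("`pi` length must equal the number of taxa.")
  withr::with_seed(seed, {
    idx <- sample.int(k, spec$n, replace = TRUE, prob = spec$pi)
  })
  tibble::tibble(
    gene_id = sprintf("%s_%05d", id_prefix, seq_len(spec$n)),
    taxon_index = as.integer(idx)
  )
}

#' Generate a full synthetic gene-age study
#'
#' Produces an age table and a class catalog with the statistical
#' structure the pipeline assumes: a universe of genes with a base
#' origination profile, plus classes realized from their own profiles with
#' optional pairwise sharing. A shared gene has a single age (drawn from
#' the first declaring class's profile) honored by both classes. The
#' output feeds [join_ages()] directly.
#'
#' @param specs List of [class_spec()]s (classes referenced by
#'   `overlap_with` must come first).
#' @param tl A [timeline()].
#' @param seed Integer seed; the study is a pure function of
#'   `(specs, seed)`.
#' @param universe_size Total number of genes; defaults to 19911, the
#'   scale of the detected human protein-coding gene set. Background genes
#'   beyond the class members are filled in from `base_pi`.
#' @param base_pi Origination profile of background genes; default is the
#'   package's stylized genome-wide profile (see
#'   [default_base_profile()]).
#' @return List with `age_table` (tibble `gene_id`, `taxon_index`),
#'   `catalog` (a `gene_class_catalog` whose universe is all generated
#'   genes), `tl` and `seed`.
#' @export
simulate_study <- function(specs, tl, seed = 1L, universe_size = 19911,
                           base_pi = NULL) {
  if (inherits(specs, "class_spec")) specs <- list(specs)
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  if (is.null(base_pi)) base_pi <- default_base_profile(n_taxa(tl))
  k <- n_taxa(tl)
  stopifnot(length(base_pi) == k, abs(sum(base_pi) - 1) < 1e-9)
  n_class_genes <- sum(vapply(specs, function(s) {
    s$n - round(s$shared_frac * s$n)
  }, numeric(1)))
  if (n_class_genes > universe_size) {
    abort("universe_size smaller than the number of distinct class genes.")
  }
  withr::with_seed(seed, {
    members <- list()
    ages <- tibble::tibble(gene_id = character(), taxon_index = integer())
    counter <- 0L
    for (s in specs) {
      n_shared <- round(s$shared_frac * s$n)
      shared <- character()
      if (n_shared > 0) {
        if (is.null(s$overlap_with) || !s$overlap_with %in% names(members)) {
          abort(paste0("overlap_with must name an earlier class; got: ",
                       s$name))
        }
        donor <- members[[s$overlap_with]]
        if (n_shared > length(donor)) {
          abort(sprintf("class '%s' requests %d shared genes but '%s' has %d.",
                        s$name, n_shared, s$overlap_with, length(donor)))
        }
        shared <- sample(donor, n_shared)
      }
      n_new <- s$n - n_shared
      fresh <- sprintf("g%06d", counter + seq_len(n_new))
      counter <- counter + n_new
      idx <- sample.int(k, n_new, replace = TRUE, prob = s$pi)
      ages <- dplyr::bind_rows(ages,
        tibble::tibble(gene_id = fresh, taxon_index = as.integer(idx)))
      members[[s$name]] <- c(shared, fresh)
    }
    n_bg <- universe_size - counter
    if (n_bg > 0) {
      bg <- sprintf("g%06d", counter + seq_len(n_bg))
      idx <- sample.int(k, n_bg, replace = TRUE, prob = base_pi)
      ages <- dplyr::bind_rows(ages,
        tibble::tibble(gene_id = bg, taxon_index = as.integer(idx)))
    }
  })
  membership <- purrr::imap_dfr(members, function(g, nm) {
    tibble::tibble(gene = g, class = nm)
  })
  list(
    age_table = ages,
    catalog = class_catalog(membership, universe = ages$gene_id),
    tl = tl, seed = seed
  )
}

#' Stylized genome-wide origination profile
#'
#' The background profile used for non-class genes in synthetic studies:
#' heavy early mass with a mid-timeline rise, echoing the qualitative
#' shape of an all-protein-coding-genes curve. Not a reconstruction of any
#' real dataset.
#'
#' @param k Number of taxa (16 for the default timeline).
#' @return Probability vector of length `k`.
#' @export
default_base_profile <- function(k = 16) {
  if (k == 16) {
    p <- c(18, 8, 6, 10, 2, 14, 10, 6, 4, 6, 2, 4, 4, 2, 2, 2)
  } else {
    p <- rev(seq_len(k))  # mild old-skew for non-default timelines
  }
  p / sum(p)
}

#' Study-scale synthetic class specifications
#'
#' Ten classes with the detected sizes of the study's databases
#' (housekeeping 6789, oncogenes 224, tumor suppressors 984,
#' differentiation 3697, homeobox 231, apoptosis 53, CT autosomal 109,
#' CT-X 78, GSTSE coding 60, GSTSE non-coding 121) realized from three
#' stylized profile families — old, intermediate and young — echoing the
#' three clusters of curves such studies report. Illustrative structure
#' for exercising the pipeline, NOT a reconstruction of the real data. A
#' modest tumor-suppressor/differentiation overlap is included so the
#' overlap stage has signal.
#'
#' @param k Number of taxa (16).
#' @return Named list of [class_spec()]s.
#' @export
study_scale_spec <- function(k = 16) {
  stopifnot(k == 16)
  old <- c(20, 9, 7, 12, 3, 15, 10, 6, 4, 5, 2, 3, 2, 1, 0.5, 0.5)
  old <- old / sum(old)
  mid <- c(4, 3, 4, 6, 3, 12, 14, 12, 10, 10, 6, 6, 5, 3, 1, 1)
  mid <- mid / sum(mid)
  young <- c(1, 1, 1, 2, 1, 3, 4, 5, 6, 8, 8, 12, 16, 16, 8, 8)
  young <- young / sum(young)
  list(
    housekeeping = class_spec("housekeeping", 6789, old),
    oncogene = class_spec("oncogene", 224, old),
    tumor_suppressor = class_spec("tumor_suppressor", 984, old),
    differentiation = class_spec("differentiation", 3697, old,
                                 overlap_with = "tumor_suppressor",
                                 shared_frac = 0.02),
    homeobox = class_spec("homeobox", 231, mid),
    apoptosis = class_spec("apoptosis", 53, mid),
    ct_autosomal = class_spec("ct_autosomal", 109, mid),
    gstse_coding = class_spec("gstse_coding", 60, mid),
    ct_x = class_spec("ct_x", 78, young),
    gstse_noncoding = class_spec("gstse_noncoding", 121, young)
  )
}

#' Read / write class specs as JSON
#'
#' @param path JSON path: an array of objects with fields `name`, `n`,
#'   `pi`, optional `overlap_with`, `shared_frac`.
#' @return `read_class_specs()` a named list of [class_spec()]s.
#' @export
read_class_specs <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  specs <- lapply(raw, function(x) {
    class_spec(x$name, x$n, unlist(x$pi),
               overlap_with = x$overlap_with,
               shared_frac = x$shared_frac %||% 0)
  })
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' @rdname read_class_specs
#' @param specs Named list of [class_spec()]s.
#' @export
write_class_specs <- function(specs, path) {
  jsonlite::write_json(
    lapply(unname(specs), function(s) {
      out <- list(name = s$name, n = s$n, pi = s$pi)
      if (!is.null(s$overlap_with)) {
        out$overlap_with <- s$overlap_with
        out$shared_frac <- s$shared_frac
      }
      out
    }),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
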