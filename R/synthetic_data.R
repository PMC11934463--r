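#' Specification for a synthetic planted-module collection
#'
#' Emulates the modular structure of curated gene-set collections: `M`
#' modules with disjoint gene pools; every term draws `genes_per_term` genes
#' from its module's pool plus `noise_genes_per_term` from a shared
#' background pool, so within-module overlap exceeds between-module overlap
#' by construction. Defaults give a minute-scale collection: 4 modules of 15
#' terms, pools of 50 genes, 20 genes per term, 3 noise genes, background of
#' 200.
#'
#' @param n_modules Number of planted modules `M`.
#' @param terms_per_module Terms per module.
#' @param pool_size Genes in each module's private pool.
#' @param genes_per_term Genes drawn from the module pool per term
#'   (`<= pool_size`).
#' @param noise_genes_per_term Background genes added per term (may be 0).
#' @param background_pool_size Size of the shared background pool.
#' @param seed Integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_modules = 4L, terms_per_module = 15L,
                           pool_size = 50L, genes_per_term = 20L,
                           noise_genes_per_term = 3L,
                           background_pool_size = 200L, seed = 1L) {
  spec <- list(
    n_modules = as.integer(n_modules),
    terms_per_module = as.integer(terms_per_module),
    pool_size = as.integer(pool_size),
    genes_per_term = as.integer(genes_per_term),
    noise_genes_per_term = as.integer(noise_genes_per_term),
    background_pool_size = as.integer(background_pool_size),
    seed = as.integer(seed)
  )
  with(spec, {
    if (genes_per_term > pool_size) {
      stop("genes_per_term must not exceed pool_size", call. = FALSE)
    }
    if (noise_genes_per_term > background_pool_size) {
      stop("noise_genes_per_term must not exceed background_pool_size", call. = FALSE)
    }
    stopifnot(n_modules >= 1L, terms_per_module >= 1L, pool_size >= 1L,
              genes_per_term >= 1L, noise_genes_per_term >= 0L)
  })
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic collection with planted modules
#'
#' @param spec A [synthetic_spec()].
#' @return A [gs_collection()] of `n_modules * terms_per_module` terms;
#'   attribute `module_labels` is a tibble `(term_id, module)` of the hidden
#'   module assignment, for evaluation only — the pipeline never reads it.
#' @export
generate_collection <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr_seed(spec$seed, {
    pools <- lapply(seq_len(spec$n_modules), function(m)
      sprintf("M%02dG%04d", m, seq_len(spec$pool_size)))
    background <- sprintf("BG%04d", seq_len(spec$background_pool_size))
    term_id <- character(0)
    genes <- list()
    module <- integer(0)
    for (m in seq_len(spec$n_modules)) {
      for (t in seq_len(spec$terms_per_module)) {
        id <- sprintf("MOD%02d_TERM%03d", m, t)
        core <- sample(pools[[m]], spec$genes_per_term)
        noise <- if (spec$noise_genes_per_term > 0L) {
          sample(background, spec$noise_genes_per_term)
        } else character(0)
        term_id <- c(term_id, id)
        genes <- c(genes, list(c(core, noise)))
        module <- c(module, m)
      }
    }
    out <- gs_collection(term_id,
                         description = sprintf("synthetic module %d", module),
                         genes = genes, species_label = "synthetic")
    attr(out, "module_labels") <- tibble::tibble(term_id = term_id, module = module)
    out
  })
}

#' Hidden module labels of a synthetic collection
#' @param collection A [generate_collection()] result.
#' @return Tibble `(term_id, module)`.
#' @export
module_labels <- function(collection) {
  lab <- attr(collection, "module_labels")
  if (is.null(lab)) stop("collection carries no module labels", call. = FALSE)
  lab
}

#' Generate a synthetic ortholog table for a collection
#'
#' Gives a `mapped_fraction` subset of the collection's genes a one-to-one
#' "foreign" alias (the symbol prefixed), emulating an ortholog mapping with
#' attrition.
#'
#' @param collection A [gs_collection()].
#' @param mapped_fraction Fraction of genes receiving an alias, in `(0, 1]`;
#'   exactly `floor(fraction * n_genes)` pairs are produced.
#' @param seed Integer seed.
#' @param prefix Alias prefix.
#' @return An [ortholog_map()] with `source` = foreign alias and `target` =
#'   original symbol.
#' @export
generate_ortholog_map <- function(collection, mapped_fraction = 1, seed = 1L,
                                  prefix = "ORTH_") {
  stopifnot(inherits(collection, "gs_collection"))
  if (mapped_fraction <= 0 || mapped_fraction > 1) {
    stop("mapped_fraction must lie in (0, 1]", call. = FALSE)
  }
  genes <- unique(unlist(collection$genes, use.names = FALSE))
  n_map <- floor(mapped_fraction * length(genes))
  mapped <- withr_seed(seed, sample(genes, n_map))
  ortholog_map(source = paste0(prefix, mapped), target = mapped)
}

#' Generate foreign duplicates of host terms
#'
#' Picks `k_terms` host terms and emits foreign terms whose gene sets are
#' the aliased copies of the host sets, so that after ortholog conversion a
#' foreign duplicate's gene set equals its source term's set restricted to
#' mapped genes. Drives the cross-species duplicate-recovery check.
#'
#' @param collection Host [gs_collection()].
#' @param k_terms Number of host terms to duplicate (`<= n` terms).
#' @param seed Integer seed.
#' @param orthologs Optional [ortholog_map()] whose aliases to use; defaults
#'   to a full one-to-one map generated from the collection with `seed`.
#' @return A foreign `gs_collection`; attribute `source_terms` is a tibble
#'   `(foreign_term, host_term)`.
#' @export
generate_duplicated_foreign_terms <- function(collection, k_terms, seed = 1L,
                                              orthologs = NULL) {
  stopifnot(inherits(collection, "gs_collection"), k_terms <= nrow(collection))
  if (is.null(orthologs)) {
    orthologs <- generate_ortholog_map(collection, 1, seed = seed)
  }
  alias <- setNames(orthologs$source, orthologs$target)
  picked <- withr_seed(seed + 1L, sample(collection$term_id, k_terms))
  rows <- match(picked, collection$term_id)
  genes <- lapply(collection$genes[rows], function(g) {
    unname(alias[intersect(g, names(alias))])
  })
  out <- gs_collection(
    term_id = paste0("FOREIGN_", picked),
    description = "aliased duplicate of a host term",
    genes = genes,
    species_label = "synthetic-foreign"
  )
  attr(out, "source_terms") <- tibble::tibble(
    foreign_term = paste0("FOREIGN_", picked), host_term = picked)
  out
}
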