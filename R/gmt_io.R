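#' Normalize gene symbols
#'
#' Uppercases symbols and strips surrounding whitespace so that human symbols
#' and ortholog-converted symbols from other species live in one namespace.
#' Idempotent: normalizing twice equals normalizing once.
#'
#' @param x Character vector of gene symbols.
#' @return Character vector of normalized symbols.
#' @export
#' @examples
#' normalize_gene_symbols(c(" Trp53 ", "BRCA1"))
normalize_gene_symbols <- function(x) {
  toupper(trimws(x))
}

#' Construct a gene-set collection
#'
#' A collection is a tibble with one row per term: `term_id`, `description`
#' and a `genes` list-column of gene-symbol character vectors. Gene symbols
#' are normalized (uppercase, trimmed) and deduplicated per term; empty gene
#' sets and duplicate term identifiers are rejected.
#'
#' @param term_id Character vector of unique term identifiers.
#' @param description Character vector of free-text descriptions (recycled).
#' @param genes List of character vectors, one gene set per term.
#' @param species_label Free-text species tag stored as an attribute.
#' @return A `gs_collection` tibble.
#' @export
gs_collection <- function(term_id, description = "", genes,
                          species_label = "unspecified") {
  stopifnot(is.character(term_id), is.list(genes),
            length(term_id) == length(genes))
  if (length(term_id) == 0L) {
    stop("a gene-set collection must contain at least one term", call. = FALSE)
  }
  dup <- term_id[duplicated(term_id)]
  if (length(dup) > 0L) {
    stop("duplicate term identifiers: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  genes <- lapply(genes, function(g) unique(normalize_gene_symbols(as.character(g))))
  genes <- lapply(genes, function(g) g[nzchar(g)])
  empty <- lengths(genes) == 0L
  if (any(empty)) {
    stop("terms with empty gene sets after normalization: ",
         paste(term_id[empty], collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    term_id = term_id,
    description = rep_len(as.character(description), length(term_id)),
    genes = genes
  )
  attr(out, "species_label") <- species_label
  class(out) <- c("gs_collection", class(out))
  out
}

#' @export
print.gs_collection <- function(x, ...) {
  cat("<gs_collection> ", nrow(x), " terms, ",
      length(unique(unlist(x$genes))), " distinct genes (species: ",
      attr(x, "species_label") %||% "unspecified", ")\n", sep = "")
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a gene-set collection from a GMT file
#'
#' GMT is the tab-separated MSigDB dialect: one gene set per line with fields
#' name, description, then one or more member genes. Duplicate genes within a
#' line are collapsed and symbols normalized; lines with fewer than three
#' fields are a parse error naming the line number.
#'
#' @param path Path to a GMT file.
#' @param species_label Species tag attached to the collection.
#' @return A [gs_collection()] tibble.
#' @export
read_gmt <- function(path, species_label = "unspecified") {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("GMT file is empty: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    stop("malformed GMT line ", bad[1L], " (fewer than 3 tab-separated fields) in ",
         path, call. = FALSE)
  }
  gs_collection(
    term_id = vapply(fields, `[[`, character(1), 1L),
    description = vapply(fields, `[[`, character(1), 2L),
    genes = lapply(fields, function(f) f[-(1:2)]),
    species_label = species_label
  )
}

#' Write a gene-set collection to a GMT file
#'
#' Round-trips through [read_gmt()] up to gene order within a set.
#'
#' @param collection A `gs_collection`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gs_collection"))
  if (nrow(collection) == 0L) {
    stop("refusing to write an empty collection", call. = FALSE)
  }
  lines <- mapply(function(id, desc, genes) {
    paste(c(id, desc, genes), collapse = "\t")
  }, collection$term_id, collection$description, collection$genes)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a two-column ortholog mapping table
#'
#' Tab-separated source-to-target gene symbol pairs (e.g. mouse symbol to
#' human symbol), optional single header line auto-detected. One source
#' symbol may map to several targets; duplicate pairs are dropped.
#'
#' @param path Path to a 2-column TSV.
#' @return A tibble with class `ortholog_map` and columns `source`, `target`.
#' @export
read_ortholog_table <- function(path) {
  if (!file.exists(path)) stop("ortholog table not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("ortholog table is empty: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad) > 0L) {
    stop("malformed ortholog-table line ", bad[1L],
         " (expected exactly 2 tab-separated columns) in ", path, call. = FALSE)
  }
  src <- vapply(fields, `[[`, character(1), 1L)
  tgt <- vapply(fields, `[[`, character(1), 2L)
  # header heuristic: drop line 1 if neither of its fields recurs as data
  if (length(src) > 1L && !(src[1L] %in% src[-1L]) && !(tgt[1L] %in% tgt[-1L]) &&
      grepl("[a-z]", src[1L]) && grepl("[a-z]", tgt[1L]) &&
      all(c(src[1L], tgt[1L]) == trimws(c(src[1L], tgt[1L]))) &&
      any(grepl("sym|gene|source|target|human|mouse|ortho", c(src[1L], tgt[1L]),
                ignore.case = TRUE))) {
    src <- src[-1L]
    tgt <- tgt[-1L]
  }
  ortholog_map(src, tgt)
}

#' Construct an ortholog map from source/target symbol vectors
#'
#' @param source,target Character vectors of equal length.
#' @return A tibble with class `ortholog_map`; pairs deduplicated after
#'   symbol normalization.
#' @export
ortholog_map <- function(source, target) {
  out <- tibble::tibble(
    source = normalize_gene_symbols(source),
    target = normalize_gene_symbols(target)
  )
  out <- dplyr::distinct(out)
  class(out) <- c("ortholog_map", class(out))
  out
}

#' Write an ortholog map as 2-column TSV
#' @param orthologs An `ortholog_map`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ortholog_table <- function(orthologs, path) {
  readr::write_tsv(tibble::as_tibble(orthologs), path, col_names = FALSE)
  invisible(path)
}
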