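#' Expression tables and their on-disk format
#'
#' Expression data travel through the package as a wide tibble: a `gene_id`
#' column followed by one numeric column per sample. Sample columns are named
#' `ZT<hh>_r<k>` (e.g. `ZT04_r2`), encoding the Zeitgeber time in hours and the
#' technical replicate index. `sample_info()` parses those names; on disk the
#' same table is a tab-separated file with a header row.
#'
#' @param x An expression tibble.
#' @return `sample_info()` returns a tibble with columns `sample`, `zt`
#'   (hours) and `replicate` (integer), one row per sample column of `x`.
#' @examples
#' m <- tibble::tibble(gene_id = c("g1", "g2"), ZT00_r1 = c(1, 2), ZT04_r1 = c(3, 4))
#' sample_info(m)
#' @export
sample_info <- function(x) {
  check_expression_tbl(x)
  labels <- setdiff(names(x), "gene_id")
  parse_sample_labels(labels)
}

parse_sample_labels <- function(labels) {
  m <- regmatches(labels, regexec("^ZT([0-9]+(?:\\.[0-9]+)?)_r([0-9]+)$", labels))
  bad <- labels[vapply(m, length, 1L) != 3L]
  if (length(bad) > 0) {
    abort(paste0("unparseable sample label(s): ", paste(bad, collapse = ", "),
                 " (expected e.g. 'ZT04_r2')"))
  }
  tibble(
    sample = labels,
    zt = vapply(m, function(p) as.numeric(p[2]), 1),
    replicate = vapply(m, function(p) as.integer(p[3]), 1L)
  )
}

check_expression_tbl <- function(x) {
  if (!is.data.frame(x) || !"gene_id" %in% names(x)) {
    abort("expected an expression tibble with a `gene_id` first column")
  }
  dup <- x$gene_id[duplicated(x$gene_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate gene id(s): ", paste(unique(dup), collapse = ", ")))
  }
  invisible(x)
}

# numeric matrix view (genes x samples), rownames = gene ids
expr_matrix <- function(x) {
  check_expression_tbl(x)
  m <- as.matrix(x[setdiff(names(x), "gene_id")])
  storage.mode(m) <- "double"
  rownames(m) <- x$gene_id
  m
}

# rebuild the tibble from a matrix view, preserving column order
expr_from_matrix <- function(m) {
  tibble(gene_id = rownames(m)) %>%
    dplyr::bind_cols(as_tibble(m))
}

#' Read and write expression tables
#'
#' @param path Path to a tab-separated expression file (header row of sample
#'   labels, first column `gene_id`).
#' @param x Expression tibble to write.
#' @return `read_expression()` returns the expression tibble with row order
#'   preserved; `write_expression()` returns `x` invisibly.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  probs <- readr::problems(x)
  if (nrow(probs) > 0) abort(paste0("malformed expression file: ", path))
  check_expression_tbl(x)
  sample_info(x)  # validates labels
  x
}

#' @rdname read_expression
#' @export
write_expression <- function(x, path) {
  check_expression_tbl(x)
  readr::write_tsv(x, path, progress = FALSE)
  invisible(x)
}

#' Read and write gene--term annotation tables
#'
#' Two-column tab-separated files (`gene`, `term`), one association per line.
#'
#' @param path File path.
#' @param ann Annotation tibble with columns `gene` and `term`.
#' @return A tibble with columns `gene` and `term`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  ann <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), term = readr::col_character()
  ), progress = FALSE)
  if (!all(c("gene", "term") %in% names(ann))) {
    abort("annotation file must have columns `gene` and `term`")
  }
  distinct(ann, .data$gene, .data$term)
}

#' @rdname read_annotations
#' @export
write_annotations <- function(ann, path) {
  readr::write_tsv(ann[c("gene", "term")], path, progress = FALSE)
  invisible(ann)
}

#' Read and write plain gene-id lists (one id per line)
#'
#' @param path File path.
#' @param genes Character vector of gene ids.
#' @return Character vector of gene ids.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- readLines(path)
  x[nzchar(x)]
}

#' @rdname read_gene_set
#' @export
write_gene_set <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(genes)
}
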