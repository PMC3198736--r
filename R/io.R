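#' Read and write the package's plain-text interchange formats
#'
#' Expression matrices travel as tab-separated text with a leading
#' `gene_id` column and one column per sample (log2 values, 4 decimal
#' places on write). Sample sheets are two-column TSV
#' (`sample_id`, `genotype`), annotation maps are two-column TSV
#' (`gene_id`, `term_id`, one pair per line), and Ct tables are CSV in
#' the long format `sample,genotype,bio_rep,tech_rep,gene,ct`.
#'
#' @param path file path.
#' @return `read_expression_matrix()`: numeric matrix with gene ids as
#'   rownames; `read_sample_sheet()`: `data.frame(sample_id, genotype)`;
#'   `read_annotation()`: `data.frame(gene_id, term_id)` (see
#'   [as_annotation_map()]); `read_ct_table()`: long `data.frame`.
#'   Writers return the path invisibly.
#' @name io
NULL

#' @rdname io
#' @export
read_expression_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "gene_id") stop("first column must be 'gene_id'")
  if (anyDuplicated(tab$gene_id)) stop("gene ids must be unique")
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("expression values must be numeric")
  rownames(m) <- tab$gene_id
  m
}

#' @rdname io
#' @param x matrix (genes x samples) with dimnames.
#' @export
write_expression_matrix <- function(x, path) {
  x <- as.matrix(x)
  out <- data.frame(gene_id = rownames(x),
                    format(x, nsmall = 4, trim = TRUE, scientific = FALSE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_sample_sheet <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "genotype") %in% names(tab)))
    stop("sample sheet needs columns 'sample_id' and 'genotype'")
  tab[, c("sample_id", "genotype")]
}

#' @rdname io
#' @param samples `data.frame(sample_id, genotype)`.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples[, c("sample_id", "genotype")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_annotation <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("gene_id", "term_id"))
  tab
}

#' @rdname io
#' @param annotation an [annotation_map()].
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "annotation_map"))
  pairs <- do.call(rbind, lapply(names(annotation$terms), function(tm)
    data.frame(gene_id = annotation$terms[[tm]], term_id = tm,
               stringsAsFactors = FALSE)))
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build an annotation map from gene-term pairs
#'
#' @param pairs `data.frame` with columns `gene_id` and `term_id` (as
#'   from [read_annotation()]).
#' @param universe universe gene ids; defaults to all genes appearing
#'   in `pairs`.
#' @return an [annotation_map()].
#' @export
as_annotation_map <- function(pairs, universe = NULL) {
  if (!all(c("gene_id", "term_id") %in% names(pairs)))
    stop("'pairs' needs columns 'gene_id' and 'term_id'")
  if (is.null(universe)) universe <- unique(pairs$gene_id)
  annotation_map(split(pairs$gene_id, pairs$term_id), universe)
}

#' @rdname io
#' @export
read_ct_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "genotype", "bio_rep", "tech_rep", "gene", "ct")
  if (!all(need %in% names(tab))) stop("Ct table needs columns ",
                                       paste(need, collapse = ","))
  if (any(tab$ct <= 0)) stop("Ct values must be positive")
  tab[, need]
}

#' @rdname io
#' @param ct long-format Ct `data.frame`.
#' @export
write_ct_table <- function(ct, path) {
  utils::write.csv(ct, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
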