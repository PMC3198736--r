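#' Array distribution QC summary
#'
#' Per-array distribution statistics used to judge whether arrays are
#' similar enough to normalize together. An array is flagged when its
#' median deviates from the across-array median of medians by more than
#' `flag_threshold` log2 units.
#'
#' @param x genes x samples numeric matrix of log2 values.
#' @param flag_threshold flagging threshold in log2 units (default 1.0).
#' @return `data.frame` with one row per sample: `sample`, `min`, `q25`,
#'   `median`, `q75`, `max`, `mean`, `sd`, `flagged`.
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 100, seed = 1))
#' qc_distribution_summary(sim$matrix)
#' @export
qc_distribution_summary <- function(x, flag_threshold = 1.0) {
  x <- as.matrix(x)
  if (ncol(x) < 1L || nrow(x) < 1L) stop("empty matrix")
  qs <- apply(x, 2, stats::quantile, probs = c(0, 0.25, 0.5, 0.75, 1))
  med <- qs[3, ]
  out <- data.frame(sample = colnames(x),
                    min = qs[1, ], q25 = qs[2, ], median = med,
                    q75 = qs[4, ], max = qs[5, ],
                    mean = colMeans(x), sd = apply(x, 2, stats::sd),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$flagged <- abs(med - stats::median(med)) > flag_threshold
  out
}

#' Pairwise cyclic loess normalization
#'
#' Removes smooth intensity-dependent differences between arrays. For
#' each pair of arrays (i, j) the log-ratio `M = x_i - x_j` is regressed
#' on the average intensity `A = (x_i + x_j) / 2` by local regression;
#' half of the fitted trend is subtracted from array i and added to
#' array j. All pairs are cycled through `iterations` times. Because the
#' correction is pairwise symmetric, the grand mean of the matrix is
#' essentially conserved.
#'
#' The computation delegates to [limma::normalizeCyclicLoess()] with
#' `method = "pairs"`.
#'
#' @param x genes x samples matrix of log2 values (at least 2 samples,
#'   all finite).
#' @param span loess span as a fraction of points (default 0.3).
#' @param iterations number of cycles over all pairs (default 2).
#' @return normalized matrix of the same shape and dimnames.
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 200, seed = 1))
#' norm <- cyclic_loess_normalize(sim$matrix)
#' @export
cyclic_loess_normalize <- function(x, span = 0.3, iterations = 2) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least 2 arrays to normalize")
  if (!all(is.finite(x))) stop("matrix contains non-finite values")
  out <- limma::normalizeCyclicLoess(x, span = span,
                                     iterations = iterations,
                                     method = "pairs")
  dimnames(out) <- dimnames(x)
  out
}

#' Summarize probes into probe-set (gene) values by the mean
#'
#' Collapses probe-level rows into one row per target id, taking the
#' arithmetic mean of the probes' values in each sample. Probes without
#' a mapping are dropped (their count is reported via `message()`);
#' probes mapping to several targets contribute to each.
#'
#' @param x probes x samples numeric matrix with probe ids as rownames.
#' @param probe_to_gene mapping: two-column `data.frame`
#'   (`probe_id`, `gene_id`) or a named character vector
#'   (names = probe ids, values = target ids). Every mapped probe must
#'   be present in the matrix.
#' @return targets x samples matrix.
#' @examples
#' m <- matrix(c(4, 6), 2, 1, dimnames = list(c("p1", "p2"), "s1"))
#' summarize_probesets(m, data.frame(probe_id = c("p1", "p2"),
#'                                   gene_id = "g1"))   # 5
#' @export
summarize_probesets <- function(x, probe_to_gene) {
  x <- as.matrix(x)
  if (is.data.frame(probe_to_gene)) {
    if (ncol(probe_to_gene) < 2L) stop("mapping needs two columns")
    map <- data.frame(probe = as.character(probe_to_gene[[1]]),
                      gene = as.character(probe_to_gene[[2]]),
                      stringsAsFactors = FALSE)
  } else {
    if (is.null(names(probe_to_gene))) stop("mapping vector must be named")
    map <- data.frame(probe = names(probe_to_gene),
                      gene = as.character(probe_to_gene),
                      stringsAsFactors = FALSE)
  }
  if (nrow(map) == 0L) stop("empty probe-to-gene mapping")
  missing <- setdiff(map$probe, rownames(x))
  if (length(missing)) stop("mapped probes absent from the matrix: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  unmapped <- setdiff(rownames(x), map$probe)
  if (length(unmapped))
    message(length(unmapped), " unmapped probe(s) dropped")
  multi <- sum(duplicated(map$probe))
  if (multi > 0)
    message(multi, " probe-to-target assignment(s) beyond the first ",
            "(probes shared between targets contribute to each)")
  sub <- x[map$probe, , drop = FALSE]
  sums <- rowsum(sub, group = map$gene)
  counts <- as.vector(table(map$gene)[rownames(sums)])
  sums / counts
}
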