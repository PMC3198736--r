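#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` annotated genes in a candidate set of size `n`
#' sampled without replacement from a universe of `N` genes of which
#' `K` carry the annotation. This is the over-representation statistic
#' reported for gene families; computed via the numerically stable
#' survival function, which survives `N` in the tens of thousands and
#' p-values down past 1e-10.
#'
#' @param k observed overlap (candidates in the family).
#' @param K family size in the universe.
#' @param n candidate-set size.
#' @param N universe size.
#' @return the upper-tail probability; exactly 1 when `k = 0`.
#' @examples
#' hypergeom_upper_tail(2, 3, 3, 6)          # 0.5
#' hypergeom_upper_tail(7, 118, 31, 22810)   # ~2e-10
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  vals <- c(k = k, K = K, n = n, N = N)
  if (anyNA(vals) || any(vals < 0) || any(vals != round(vals)))
    stop("counts must be non-negative integers")
  if (K > N || n > N) stop("inconsistent counts: K and n cannot exceed N")
  if (k > min(K, n)) stop("inconsistent counts: k cannot exceed min(K, n)")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric over-representation of annotation terms
#'
#' Tests every annotation term that intersects the candidate set for
#' over-representation with [hypergeom_upper_tail()]. Candidates outside
#' the universe are dropped with a warning. Terms are returned sorted by
#' p, flagged enriched below `p_cutoff`; no multiple-testing correction
#' is applied by default (a Benjamini-Hochberg column can be requested).
#'
#' @param candidates candidate gene ids.
#' @param annotation an [annotation_map()].
#' @param p_cutoff enrichment flag cutoff (default 0.001).
#' @param adjust `"none"` (default) or `"BH"` to add an adjusted-p
#'   column (the flag still uses the raw p).
#' @return `data.frame` of class `"enrichment"` with one row per term
#'   with `k >= 1`: `term`, `k`, `K`, `n`, `N`, `p`, (optional `p_adj`),
#'   `enriched`. Empty candidate set gives zero rows.
#' @examples
#' ann <- annotation_map(list(fam = c("g1", "g2")), paste0("g", 1:10))
#' enrich_terms(c("g1", "g3"), ann)
#' @export
enrich_terms <- function(candidates, annotation, p_cutoff = 0.001,
                         adjust = c("none", "BH")) {
  stopifnot(inherits(annotation, "annotation_map"))
  adjust <- match.arg(adjust)
  candidates <- unique(as.character(candidates))
  out_of_universe <- setdiff(candidates, annotation$universe)
  if (length(out_of_universe)) {
    warning(length(out_of_universe),
            " candidate(s) outside the universe dropped")
    candidates <- intersect(candidates, annotation$universe)
  }
  N <- length(annotation$universe)
  n <- length(candidates)
  rows <- lapply(names(annotation$terms), function(tm) {
    genes <- annotation$terms[[tm]]
    k <- length(intersect(candidates, genes))
    if (k == 0L) return(NULL)
    data.frame(term = tm, k = k, K = length(genes), n = n, N = N,
               p = hypergeom_upper_tail(k, length(genes), n, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term = character(0), k = integer(0), K = integer(0),
               n = integer(0), N = integer(0), p = numeric(0),
               stringsAsFactors = FALSE)
  tab <- tab[order(tab$p, tab$term), , drop = FALSE]
  if (adjust == "BH") tab$p_adj <- stats::p.adjust(tab$p, method = "BH")
  tab$enriched <- tab$p < p_cutoff
  rownames(tab) <- NULL
  class(tab) <- c("enrichment", "data.frame")
  tab
}

#' @export
print.enrichment <- function(x, n = 10L, ...) {
  cat("Term over-representation (", nrow(x), " terms with overlap; ",
      sum(x$enriched), " enriched)\n", sep = "")
  print.data.frame(utils::head(x, n), digits = 3)
  invisible(x)
}
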