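#' Reference-normalized qPCR expression
#'
#' Delta-Ct quantification at 100% amplification efficiency. Technical
#' replicates are averaged on the Ct scale first; each biological
#' replicate then contributes `2^(Ct_ref - Ct_target)`, so values above
#' 1 mean the target amplifies earlier (is more abundant) than the
#' reference. Per genotype the mean, the standard error of the mean and
#' the number of biological replicates are reported.
#'
#' Biological replicates missing the reference gene are dropped with a
#' warning; if no replicate has the reference the call errors.
#'
#' @param ct long-format Ct table with columns `genotype`, `bio_rep`,
#'   `tech_rep`, `gene`, `ct` (see [simulate_qpcr()] /
#'   [read_ct_table()]).
#' @param gene target gene id.
#' @param reference_gene reference gene id.
#' @return list of class `"qpcr_expression"` with `per_rep`
#'   (`genotype`, `bio_rep`, `value`) and `summary` (`genotype`,
#'   `mean`, `sem`, `n_bio`).
#' @examples
#' tr <- data.frame(gene = "tgt", baseline = 4, effect_a = -1,
#'                  effect_b = 0, interaction_d = -2)
#' ct <- simulate_qpcr(tr, reference_gene = "ref")
#' normalized_expression(ct, "tgt", "ref")$summary
#' @export
normalized_expression <- function(ct, gene, reference_gene) {
  need <- c("genotype", "bio_rep", "tech_rep", "gene", "ct")
  if (!all(need %in% names(ct))) stop("Ct table needs columns ",
                                      paste(need, collapse = ", "))
  if (!gene %in% ct$gene) stop("target gene absent from the Ct table")
  if (!reference_gene %in% ct$gene) stop("reference gene absent from the Ct table")
  sub <- ct[ct$gene %in% c(gene, reference_gene), , drop = FALSE]
  mean_ct <- stats::aggregate(ct ~ genotype + bio_rep + gene, data = sub,
                              FUN = mean)
  tgt <- mean_ct[mean_ct$gene == gene, ]
  ref <- mean_ct[mean_ct$gene == reference_gene, ]
  merged <- merge(tgt, ref, by = c("genotype", "bio_rep"),
                  suffixes = c("_target", "_ref"))
  dropped <- nrow(tgt) - nrow(merged)
  if (nrow(merged) == 0L) stop("no biological replicate has the reference gene")
  if (dropped > 0)
    warning(dropped, " biological replicate(s) without the reference dropped")
  merged$value <- 2^(merged$ct_ref - merged$ct_target)
  glev <- unique(as.character(ct$genotype))
  gfac <- factor(merged$genotype, levels = glev)
  smry <- data.frame(
    genotype = glev,
    mean = as.vector(tapply(merged$value, gfac, mean)),
    sem = as.vector(tapply(merged$value, gfac,
                           function(v) stats::sd(v) / sqrt(length(v)))),
    n_bio = as.vector(tapply(merged$value, gfac, length)),
    stringsAsFactors = FALSE)
  structure(list(per_rep = merged[, c("genotype", "bio_rep", "value")],
                 summary = smry, gene = gene,
                 reference_gene = reference_gene),
            class = "qpcr_expression")
}

#' @export
print.qpcr_expression <- function(x, ...) {
  cat("qPCR expression of ", x$gene, " normalized to ", x$reference_gene,
      "\n", sep = "")
  print.data.frame(x$summary, digits = 4)
  invisible(x)
}

#' Pairwise reference-gene stability check
#'
#' For every pair of candidate reference genes the per-replicate
#' difference in (technical-replicate-averaged) Ct is subjected to a
#' one-way ANOVA by genotype. A stable pair shows no genotype effect on
#' the Ct difference (`p >= 0.05`). Degenerate fits (zero residual
#' variance) are treated as stable and flagged.
#'
#' @param ct long-format Ct table.
#' @param reference_candidates at least two gene ids, each measured in
#'   every (genotype, biological replicate).
#' @param alpha stability cutoff (default 0.05).
#' @return `data.frame` with `gene1`, `gene2`, `p`, `stable`,
#'   `degenerate`.
#' @export
reference_stability <- function(ct, reference_candidates, alpha = 0.05) {
  if (length(reference_candidates) < 2L)
    stop("need at least two reference candidates")
  if (!all(reference_candidates %in% ct$gene))
    stop("candidate(s) absent from the Ct table: ",
         paste(setdiff(reference_candidates, ct$gene), collapse = ", "))
  sub <- ct[ct$gene %in% reference_candidates, , drop = FALSE]
  mean_ct <- stats::aggregate(ct ~ genotype + bio_rep + gene, data = sub,
                              FUN = mean)
  pairs <- utils::combn(reference_candidates, 2)
  res <- apply(pairs, 2, function(pr) {
    a <- mean_ct[mean_ct$gene == pr[1], ]
    b <- mean_ct[mean_ct$gene == pr[2], ]
    m <- merge(a, b, by = c("genotype", "bio_rep"))
    if (nrow(m) == 0L) stop("candidates share no replicates")
    dct <- m$ct.x - m$ct.y
    fit <- fit_gene_anova(dct, m$genotype)
    const <- stats::sd(dct) < 1e-10   # identical differences everywhere
    c(p = unname(fit$p), degenerate = unname(fit$degenerate) || const)
  })
  out <- data.frame(gene1 = pairs[1, ], gene2 = pairs[2, ],
                    p = res["p", ], degenerate = as.logical(res["degenerate", ]),
                    stringsAsFactors = FALSE)
  out$stable <- out$degenerate | (!is.na(out$p) & out$p >= alpha)
  out[, c("gene1", "gene2", "p", "stable", "degenerate")]
}

#' Tukey-Kramer HSD with compact letter display
#'
#' All pairwise comparisons of group means by the Tukey-Kramer
#' studentized-range test on the pooled within-group variance, plus a
#' compact letter display: letters are assigned (insert-and-absorb
#' algorithm, groups taken in descending-mean order) so that two groups
#' share a letter exactly when they are NOT significantly different at
#' `alpha`.
#'
#' @param groups named list of numeric vectors (each length >= 2), e.g.
#'   normalized expression values per genotype.
#' @param alpha familywise significance level (default 0.05).
#' @return object of class `"tukey_cld"`: list with `summary`
#'   (`group`, `mean`, `sem`, `n`, `letters`, in input order),
#'   `p_matrix` (Tukey-adjusted pairwise p-values), `alpha`.
#' @examples
#' set.seed(1)
#' g <- list(WT = rnorm(4, 10, 0.1), A = rnorm(4, 5, 0.1),
#'           B = rnorm(4, 0, 0.1))
#' tukey_hsd(g)
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || is.null(names(groups)) || length(groups) < 2L)
    stop("'groups' must be a named list of at least two groups")
  if (any(lengths(groups) < 2L)) stop("every group needs at least 2 values")
  gnames <- names(groups)
  dat <- data.frame(value = unlist(groups, use.names = FALSE),
                    group = factor(rep(gnames, lengths(groups)),
                                   levels = gnames))
  fit <- stats::aov(value ~ group, data = dat)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  G <- length(gnames)
  pmat <- matrix(NA_real_, G, G, dimnames = list(gnames, gnames))
  diag(pmat) <- 1
  cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(cmp)) {
    a <- cmp[[i]][1]; b <- cmp[[i]][2]
    pmat[a, b] <- pmat[b, a] <- tk[i, "p adj"]
  }
  means <- vapply(groups, mean, numeric(1))
  ord <- order(means, decreasing = TRUE)          # stable for ties
  signif_mat <- pmat[ord, ord, drop = FALSE] < alpha
  letters <- cld_insert_absorb(signif_mat)
  letters <- letters[match(gnames, gnames[ord])]
  smry <- data.frame(group = gnames, mean = means,
                     sem = vapply(groups, function(v)
                       stats::sd(v) / sqrt(length(v)), numeric(1)),
                     n = lengths(groups), letters = letters,
                     row.names = NULL, stringsAsFactors = FALSE)
  structure(list(summary = smry, p_matrix = pmat, alpha = alpha),
            class = "tukey_cld")
}

# Insert-and-absorb compact letter display. `signif_mat` is a logical
# significance matrix with groups already in lettering (descending-mean)
# order; returns one letter string per group in that order.
cld_insert_absorb <- function(signif_mat) {
  g <- nrow(signif_mat)
  cols <- list(rep(TRUE, g))
  for (i in seq_len(g)) {
    for (j in seq_len(g)) {
      if (j <= i || !isTRUE(signif_mat[i, j])) next
      changed <- FALSE
      newcols <- list()
      for (col in cols) {
        if (col[i] && col[j]) {              # insert: split the column
          c1 <- col; c1[i] <- FALSE
          c2 <- col; c2[j] <- FALSE
          newcols <- c(newcols, list(c1, c2))
          changed <- TRUE
        } else newcols <- c(newcols, list(col))
      }
      if (changed) {                          # absorb: drop subset columns
        keep <- rep(TRUE, length(newcols))
        for (u in seq_along(newcols)) {
          for (v in seq_along(newcols)) {
            if (u == v || !keep[u] || !keep[v]) next
            if (all(newcols[[u]] <= newcols[[v]]) &&
                !identical(newcols[[u]], newcols[[v]])) keep[u] <- FALSE
          }
        }
        dup <- duplicated(lapply(newcols, as.integer))
        cols <- newcols[keep & !dup]
      }
    }
  }
  first <- vapply(cols, function(col) which(col)[1], integer(1))
  cols <- cols[order(first)]
  out <- vapply(seq_len(g), function(i) {
    paste(LETTERS[which(vapply(cols, `[`, logical(1), i))], collapse = "")
  }, character(1))
  out
}

#' @export
print.tukey_cld <- function(x, ...) {
  cat("Tukey-Kramer HSD at alpha =", x$alpha, "\n")
  print.data.frame(x$summary, digits = 4)
  invisible(x)
}
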