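#' Per-gene one-way ANOVA by genotype
#'
#' Fits, for every gene of an expression matrix at once, the one-way
#' fixed-effect ANOVA `expression ~ genotype`. The fit yields the
#' least-squares genotype means (LSmeans; in a balanced design these are
#' the arithmetic genotype means), the pooled residual variance, and the
#' omnibus F test against the grand mean. This object is the input to
#' [lsmean_contrast()], [approach1_screen()] and [synergy_screen()].
#'
#' Genes with zero residual variance but a non-zero genotype effect, or
#' with zero residual degrees of freedom, are flagged degenerate and get
#' `NA` test statistics. Genes whose values are all identical get
#' `F = 0`, `p = 1`.
#'
#' @param x numeric matrix of log2 expression values, genes in rows,
#'   samples in columns. A data frame of numeric columns is accepted.
#' @param genotypes genotype label per column of `x` (character or
#'   factor), or a sample sheet `data.frame` with columns `sample_id`
#'   and `genotype` which is matched against `colnames(x)`.
#' @param levels optional genotype level order; defaults to order of
#'   first appearance. The conventional order is `c("WT","A","B","AB")`.
#' @return An object of class `"genotype_anova"`: a list with components
#'   `lsmeans` (genes x genotypes matrix), `n` (replicates per
#'   genotype), `s2` (residual mean square per gene), `df` (residual
#'   degrees of freedom), `fstat`, `p`, `degenerate` (logical flag per
#'   gene), `genotypes` (the sample-to-genotype factor) and `data` (the
#'   input matrix).
#' @seealso [fit_gene_anova()] for a single gene, [lsmean_contrast()]
#'   for linear combinations of the LSmeans.
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 50, seed = 1))
#' fit <- genotype_anova(sim$matrix, sim$samples)
#' fit
#' head(coef(fit))
#' @export
genotype_anova <- function(x, genotypes, levels = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("'x' must be a numeric matrix")
  if (nrow(x) < 1L || ncol(x) < 2L) stop("'x' needs at least one gene and two samples")
  if (!all(is.finite(x))) stop("'x' contains non-finite values")
  if (is.data.frame(genotypes)) {
    if (!all(c("sample_id", "genotype") %in% names(genotypes)))
      stop("sample sheet needs columns 'sample_id' and 'genotype'")
    idx <- match(colnames(x), genotypes$sample_id)
    if (anyNA(idx)) stop("sample sheet is missing samples: ",
                         paste(setdiff(colnames(x), genotypes$sample_id), collapse = ", "))
    genotypes <- genotypes$genotype[idx]
  }
  genotypes <- as.character(genotypes)
  if (length(genotypes) != ncol(x))
    stop("'genotypes' must have one label per column of 'x'")
  if (is.null(levels)) levels <- unique(genotypes)
  g <- factor(genotypes, levels = levels)
  if (anyNA(g)) stop("genotype labels outside 'levels'")
  G <- nlevels(g)
  if (G < 2L) stop("need at least two genotypes")
  if (is.null(rownames(x))) rownames(x) <- paste0("gene", seq_len(nrow(x)))

  Z <- stats::model.matrix(~ 0 + g)            # samples x genotypes indicator
  n <- colSums(Z)
  M <- x %*% Z %*% diag(1 / n, G)
  dimnames(M) <- list(rownames(x), levels(g))
  fitted <- M %*% t(Z)
  ssw <- rowSums((x - fitted)^2)
  nu <- ncol(x) - G
  gm <- rowSums(x) / ncol(x)
  ssb <- as.vector((M - gm)^2 %*% n)

  tol <- 1e-10 * pmax(1, rowSums(x^2) / ncol(x))
  s2 <- if (nu > 0L) ssw / nu else rep(NA_real_, nrow(x))
  fstat <- (ssb / (G - 1)) / s2
  p <- stats::pf(fstat, G - 1, nu, lower.tail = FALSE)

  allconst <- ssw <= tol & ssb <= tol
  degenerate <- (nu == 0L) | (ssw <= tol & !allconst)
  fstat[allconst] <- 0
  p[allconst] <- 1
  fstat[degenerate] <- NA_real_
  p[degenerate] <- NA_real_

  structure(list(lsmeans = M, n = n, s2 = s2, df = nu, fstat = fstat,
                 p = p, degenerate = degenerate, genotypes = g, data = x),
            class = "genotype_anova")
}

#' One-way ANOVA for a single gene
#'
#' Convenience wrapper around [genotype_anova()] for one response vector.
#' Values can be given either as a named list of per-genotype replicate
#' vectors, or as a vector plus a genotype label vector.
#'
#' @param values named list of numeric vectors (one per genotype), or a
#'   numeric vector.
#' @param genotypes genotype label per value; ignored when `values` is a
#'   list.
#' @param levels optional genotype level order.
#' @return A one-gene `"genotype_anova"` object.
#' @examples
#' fit <- fit_gene_anova(list(WT = c(3, 4, 5), A = c(5, 6, 7), B = c(7, 8, 9)))
#' fit$fstat
#' @export
fit_gene_anova <- function(values, genotypes = NULL, levels = NULL) {
  if (is.list(values)) {
    genotypes <- rep(names(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  if (is.null(genotypes)) stop("'genotypes' required when 'values' is not a named list")
  genotype_anova(matrix(values, nrow = 1, dimnames = list("gene", NULL)),
                 genotypes, levels = levels)
}

#' Linear contrasts of genotype LSmeans
#'
#' Computes, per gene, the contrast `estimate = sum(w_g * mu_g)` of the
#' least-squares genotype means with standard error
#' `sqrt(s2 * sum(w_g^2 / n_g))` and a two-sided t test on the residual
#' degrees of freedom. Weights need not sum to zero (grand-mean
#' comparisons use weights `1 - 1/G` on the target and `-1/G` elsewhere).
#'
#' @param fit a `"genotype_anova"` object.
#' @param weights numeric contrast weights, either named by genotype or
#'   in the column order of `coef(fit)`. Unnamed genotypes get weight 0.
#' @param genes optional subset of gene ids.
#' @return `data.frame` with columns `gene`, `estimate`, `se`, `t`,
#'   `df`, `p`, `neg_log10_p`. Degenerate genes get `NA` statistics.
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 20, seed = 1))
#' fit <- genotype_anova(sim$matrix, sim$samples)
#' head(lsmean_contrast(fit, c(WT = 1, A = -1, B = -1, AB = 1)))
#' @export
lsmean_contrast <- function(fit, weights, genes = NULL) {
  stopifnot(inherits(fit, "genotype_anova"))
  lev <- colnames(fit$lsmeans)
  if (!is.null(names(weights))) {
    if (!all(names(weights) %in% lev))
      stop("unknown genotype in contrast weights: ",
           paste(setdiff(names(weights), lev), collapse = ", "))
    w <- stats::setNames(rep(0, length(lev)), lev)
    w[names(weights)] <- weights
  } else {
    if (length(weights) != length(lev))
      stop("unnamed 'weights' must have one entry per genotype")
    w <- stats::setNames(as.numeric(weights), lev)
  }
  M <- fit$lsmeans
  s2 <- fit$s2
  deg <- fit$degenerate
  if (!is.null(genes)) {
    idx <- match(genes, rownames(M))
    if (anyNA(idx)) stop("unknown gene id(s)")
    M <- M[idx, , drop = FALSE]; s2 <- s2[idx]; deg <- deg[idx]
  }
  if (all(deg) && nrow(M) == 1L)
    stop("contrast undefined: the fit is degenerate")
  est <- as.vector(M %*% w)
  se <- sqrt(s2 * sum(w^2 / fit$n))
  tt <- est / se
  p <- 2 * stats::pt(-abs(tt), fit$df)
  est[deg] <- NA_real_; se[deg] <- NA_real_; tt[deg] <- NA_real_; p[deg] <- NA_real_
  if (any(deg)) warning(sum(deg), " degenerate gene fit(s) returned NA statistics")
  data.frame(gene = rownames(M), estimate = est, se = se, t = tt,
             df = fit$df, p = p, neg_log10_p = -log10(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.genotype_anova <- function(x, ...) {
  cat("Per-gene one-way ANOVA by genotype\n")
  cat("  genes:    ", nrow(x$lsmeans), "\n")
  cat("  genotypes:", paste(sprintf("%s (n=%d)", colnames(x$lsmeans), x$n),
                            collapse = ", "), "\n")
  cat("  residual df per gene:", x$df, "\n")
  ok <- !is.na(x$p)
  if (any(ok))
    cat("  genes with ANOVA p < 0.05:", sum(x$p[ok] < 0.05), "of", sum(ok), "\n")
  if (any(x$degenerate))
    cat("  degenerate fits:", sum(x$degenerate), "\n")
  invisible(x)
}

#' @export
summary.genotype_anova <- function(object, ...) {
  out <- data.frame(gene = rownames(object$lsmeans),
                    object$lsmeans,
                    n_min = min(object$n),
                    s2 = object$s2, df = object$df,
                    fstat = object$fstat, p = object$p,
                    degenerate = object$degenerate,
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  class(out) <- c("summary.genotype_anova", "data.frame")
  out
}

#' @export
print.summary.genotype_anova <- function(x, n = 10L, ...) {
  cat("Gene-level one-way ANOVA summary (", nrow(x), " genes)\n", sep = "")
  print.data.frame(utils::head(x, n), digits = 4)
  if (nrow(x) > n) cat("... ", nrow(x) - n, " more genes\n", sep = "")
  invisible(x)
}

#' @export
coef.genotype_anova <- function(object, ...) object$lsmeans

#' @export
fitted.genotype_anova <- function(object, ...) {
  Z <- stats::model.matrix(~ 0 + object$genotypes)
  f <- object$lsmeans %*% t(Z)
  dimnames(f) <- dimnames(object$data)
  f
}

#' @export
residuals.genotype_anova <- function(object, ...) object$data - fitted(object)

#' Predicted genotype means
#'
#' @param object a `"genotype_anova"` object.
#' @param genotype optional genotype label(s); defaults to all.
#' @param ... unused.
#' @return matrix of LSmeans for the requested genotypes.
#' @export
predict.genotype_anova <- function(object, genotype = NULL, ...) {
  if (is.null(genotype)) return(object$lsmeans)
  if (!all(genotype %in% colnames(object$lsmeans))) stop("unknown genotype")
  object$lsmeans[, genotype, drop = FALSE]
}

#' Simulate replicate data sets from a fitted genotype model
#'
#' Draws new expression matrices from the fitted per-gene model: genotype
#' LSmean plus Gaussian noise with the gene's estimated residual SD.
#'
#' @param object a `"genotype_anova"` object.
#' @param nsim number of data sets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list of `nsim` matrices shaped like the input data.
#' @export
simulate.genotype_anova <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  f <- fitted(object)
  sd <- sqrt(object$s2)
  lapply(seq_len(nsim), function(i) {
    f + matrix(stats::rnorm(length(f), 0, rep(sd, ncol(f))), nrow(f))
  })
}

#' @export
plot.genotype_anova <- function(x, ...) {
  p <- x$p[!is.na(x$p)]
  graphics::hist(p, breaks = 20, main = "ANOVA p-value distribution",
                 xlab = "p", col = "grey80", border = "white", ...)
  graphics::abline(h = length(p) / 20, lty = 2)
  invisible(x)
}
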