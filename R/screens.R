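#' Differential-expression screen against a baseline
#'
#' The first candidate-selection route: per gene, the target genotype is
#' contrasted either against wild type or against the grand mean of all
#' genotypes, q-values control the positive FDR across genes, and a
#' minimum absolute log2 difference is required. Genes are split into an
#' under-expressed and an over-expressed set.
#'
#' Membership requires `q <= alpha`, `|estimate| > min_abs_lfc`
#' (strictly), and the sign matching the set's direction. The grand-mean
#' contrast uses weights `1 - 1/G` on the target genotype and `-1/G`
#' elsewhere.
#'
#' @param fit a `"genotype_anova"` object.
#' @param target genotype to screen, e.g. `"AB"`.
#' @param baseline `"wt"` (contrast against the `WT` LSmean) or
#'   `"grand_mean"`.
#' @param alpha q-value cutoff (default 0.05).
#' @param min_abs_lfc minimum absolute log2 difference, exclusive
#'   (default 0.35, about 1.27-fold).
#' @param multiple `"qvalue"` for Storey pFDR q-values (default) or
#'   `"bh"` for Benjamini-Hochberg.
#' @return An object of class `"de_screen"`: list with the per-gene
#'   `table` (gene, estimate, se, t, p, q), the member id vectors
#'   `under` and `over`, and the screen parameters.
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 200, seed = 1))
#' fit <- genotype_anova(sim$matrix, sim$samples)
#' scr <- approach1_screen(fit, target = "AB", baseline = "grand_mean")
#' scr
#' @export
approach1_screen <- function(fit, target, baseline = c("wt", "grand_mean"),
                             alpha = 0.05, min_abs_lfc = 0.35,
                             multiple = c("qvalue", "bh")) {
  stopifnot(inherits(fit, "genotype_anova"))
  baseline <- match.arg(baseline)
  multiple <- match.arg(multiple)
  lev <- colnames(fit$lsmeans)
  if (!target %in% lev) stop("unknown target genotype: ", target)
  G <- length(lev)
  if (baseline == "wt") {
    if (!"WT" %in% lev) stop("baseline 'wt' needs a WT genotype in the fit")
    if (target == "WT") stop("target cannot equal the baseline")
    w <- stats::setNames(rep(0, G), lev)
    w[target] <- 1; w["WT"] <- -1
  } else {
    w <- stats::setNames(rep(-1 / G, G), lev)
    w[target] <- 1 - 1 / G
  }
  tab <- lsmean_contrast(fit, w)
  ok <- !is.na(tab$p)
  q <- rep(NA_real_, nrow(tab))
  q[ok] <- if (multiple == "qvalue") pfdr_qvalues(tab$p[ok]) else
    stats::p.adjust(tab$p[ok], method = "BH")
  tab$q <- as.numeric(q)
  keep <- ok & tab$q <= alpha & abs(tab$estimate) > min_abs_lfc
  under <- sort(tab$gene[keep & tab$estimate < 0])
  over  <- sort(tab$gene[keep & tab$estimate > 0])
  structure(list(table = tab, under = under, over = over,
                 target = target, baseline = baseline, alpha = alpha,
                 min_abs_lfc = min_abs_lfc, multiple = multiple),
            class = "de_screen")
}

#' @export
print.de_screen <- function(x, ...) {
  cat("Differential-expression screen: ", x$target, " vs ",
      if (x$baseline == "wt") "wild type" else "grand mean", "\n", sep = "")
  cat(sprintf("  alpha = %g (%s), |log2 difference| > %g\n",
              x$alpha, x$multiple, x$min_abs_lfc))
  cat("  under-expressed:", length(x$under), "genes\n")
  cat("  over-expressed: ", length(x$over), "genes\n")
  invisible(x)
}

#' Additive expectation for the double mutant
#'
#' Under the additive (no interaction) null the two single-mutant
#' effects add on the log2 scale, so the expected double-mutant LSmean
#' is `mu_A + mu_B - mu_WT`.
#'
#' @param mu_wt,mu_a,mu_b log2 LSmeans of wild type and the two single
#'   mutants (vectorized).
#' @return expected log2 LSmean of the double mutant.
#' @examples
#' additive_expectation(8.42, 8.52, 7.85)   # 7.95
#' @export
additive_expectation <- function(mu_wt, mu_a, mu_b) {
  stopifnot(is.numeric(mu_wt), is.numeric(mu_a), is.numeric(mu_b))
  mu_a + mu_b - mu_wt
}

#' Per-gene non-additivity (interaction) contrast
#'
#' Computes the interaction contrast
#' `delta = mu_AB - (mu_A + mu_B - mu_WT)` (weights +1, -1, -1, +1 on
#' WT, A, B, AB) with its standard error and two-sided t test, plus the
#' two single-mutant "significantly below wild type" flags evaluated at
#' raw p-values. `delta < 0` means the double mutant is lower than the
#' additive expectation: a synergistic loss of expression.
#'
#' @param fit a `"genotype_anova"` object covering genotypes
#'   `WT`, `A`, `B`, `AB`.
#' @param alpha significance level for the flags (default 0.05).
#' @return `data.frame` of synergy records: `gene`, the four LSmeans,
#'   `delta`, `se`, `t`, `p`, `neg_log10_p`, `single_down_A`,
#'   `single_down_B`, `passes_approach2`. A gene passes when at least
#'   one single mutant is significantly below WT, `delta < 0` strictly,
#'   and `p < alpha`.
#' @examples
#' fit <- genotype_anova(
#'   rbind(g1 = c(10, 10, 9, 9, 9, 9, 7, 7)),
#'   rep(c("WT", "A", "B", "AB"), each = 2))
#' nonadditivity_contrast(fit)$delta   # -1
#' @export
nonadditivity_contrast <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "genotype_anova"))
  lev <- colnames(fit$lsmeans)
  need <- c("WT", "A", "B", "AB")
  if (!all(need %in% lev))
    stop("fit must cover genotypes WT, A, B, AB; missing: ",
         paste(setdiff(need, lev), collapse = ", "))
  dl <- lsmean_contrast(fit, c(WT = 1, A = -1, B = -1, AB = 1))
  ca <- lsmean_contrast(fit, c(A = 1, WT = -1))
  cb <- lsmean_contrast(fit, c(B = 1, WT = -1))
  down_a <- !is.na(ca$p) & ca$estimate < 0 & ca$p < alpha
  down_b <- !is.na(cb$p) & cb$estimate < 0 & cb$p < alpha
  rec <- data.frame(gene = dl$gene,
                    mu_WT = fit$lsmeans[, "WT"], mu_A = fit$lsmeans[, "A"],
                    mu_B = fit$lsmeans[, "B"], mu_AB = fit$lsmeans[, "AB"],
                    delta = dl$estimate, se = dl$se, t = dl$t, p = dl$p,
                    neg_log10_p = dl$neg_log10_p,
                    single_down_A = down_a, single_down_B = down_b,
                    row.names = NULL, stringsAsFactors = FALSE)
  rec$passes_approach2 <- (rec$single_down_A | rec$single_down_B) &
    !is.na(rec$delta) & rec$delta < 0 & !is.na(rec$p) & rec$p < alpha
  rec
}

#' Two-criterion synergy screen for the double mutant
#'
#' The second candidate-selection route. A gene is a synergy candidate
#' when (criterion 1) its expression is significantly lower than wild
#' type in at least one single mutant and (criterion 2) the
#' double-mutant LSmean falls significantly below the additive
#' expectation (`delta < 0` with `p < alpha` from
#' [nonadditivity_contrast()]).
#'
#' Criterion 1 significance can be judged on Storey q-values computed
#' across genes for each single-mutant-vs-WT contrast (default, matching
#' a pFDR-screened single-mutant gene list) or on raw per-gene p-values
#' (`criterion1 = "rawp"`).
#'
#' @param fit a `"genotype_anova"` object covering `WT`, `A`, `B`, `AB`.
#' @param alpha significance level for both criteria (default 0.05).
#' @param criterion1 `"qvalue"` or `"rawp"`.
#' @return An object of class `"synergy_screen"`: list with `records`
#'   (the [nonadditivity_contrast()] data frame, flags re-evaluated per
#'   `criterion1`, sorted by interaction p), `candidates` (gene ids),
#'   `alpha` and `criterion1`.
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 300, seed = 7))
#' fit <- genotype_anova(sim$matrix, sim$samples)
#' scr <- synergy_screen(fit)
#' scr
#' @export
synergy_screen <- function(fit, alpha = 0.05, criterion1 = c("qvalue", "rawp")) {
  criterion1 <- match.arg(criterion1)
  rec <- nonadditivity_contrast(fit, alpha = alpha)
  if (criterion1 == "qvalue") {
    ca <- lsmean_contrast(fit, c(A = 1, WT = -1))
    cb <- lsmean_contrast(fit, c(B = 1, WT = -1))
    ok_a <- !is.na(ca$p); ok_b <- !is.na(cb$p)
    qa <- rep(NA_real_, nrow(rec)); qb <- rep(NA_real_, nrow(rec))
    qa[ok_a] <- pfdr_qvalues(ca$p[ok_a])
    qb[ok_b] <- pfdr_qvalues(cb$p[ok_b])
    rec$single_down_A <- ok_a & ca$estimate < 0 & qa < alpha
    rec$single_down_B <- ok_b & cb$estimate < 0 & qb < alpha
    rec$passes_approach2 <- (rec$single_down_A | rec$single_down_B) &
      !is.na(rec$delta) & rec$delta < 0 & !is.na(rec$p) & rec$p < alpha
  }
  rec <- rec[order(rec$p), , drop = FALSE]
  rownames(rec) <- NULL
  structure(list(records = rec,
                 candidates = sort(rec$gene[rec$passes_approach2]),
                 alpha = alpha, criterion1 = criterion1),
            class = "synergy_screen")
}

#' @rdname synergy_screen
#' @param fits a `"genotype_anova"` object (alias kept for symmetry with
#'   [approach1_screen()]).
#' @param ... passed to [synergy_screen()].
#' @export
approach2_screen <- function(fits, ...) synergy_screen(fits, ...)

#' @export
print.synergy_screen <- function(x, ...) {
  cat("Synergy screen (non-additivity in the double mutant)\n")
  cat(sprintf("  alpha = %g, criterion 1 on %s\n", x$alpha,
              if (x$criterion1 == "qvalue") "q-values" else "raw p-values"))
  cat("  genes screened:", nrow(x$records), "\n")
  cat("  candidates:    ", length(x$candidates), "\n")
  invisible(x)
}

#' @export
summary.synergy_screen <- function(object, n = 10L, ...) {
  cat("Top synergy records (sorted by interaction p):\n")
  print.data.frame(utils::head(object$records, n), digits = 4)
  invisible(object$records)
}

#' @export
plot.synergy_screen <- function(x, ...) {
  rec <- x$records
  avg <- rowMeans(rec[, c("mu_WT", "mu_A", "mu_B", "mu_AB")])
  graphics::plot(avg, rec$delta, pch = 16, cex = 0.5,
                 col = ifelse(rec$passes_approach2, "firebrick", "grey60"),
                 xlab = "mean log2 expression",
                 ylab = expression(delta == mu[AB] - (mu[A] + mu[B] - mu[WT])),
                 main = "Non-additivity by expression level", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
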