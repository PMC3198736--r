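#' Configuration for the factorial expression simulator
#'
#' Collects the ground-truth parameters of a simulated 2x2 factorial
#' (WT / single mutant A / single mutant B / double mutant AB) log2
#' expression experiment. Per gene the genotype means are
#' `mu0` (WT), `mu0 + a` (A), `mu0 + b` (B) and `mu0 + a + b + d` (AB);
#' `d` is the interaction. For the synergistic fraction `d` is drawn
#' from `Normal(synergy_shift, 0.1 * |synergy_shift|)` and is exactly 0
#' otherwise, giving a sharp additive null.
#'
#' @param n_genes number of genes.
#' @param n_reps replicates (arrays) per genotype; must be >= 1, and
#'   >= 2 for a non-degenerate ANOVA.
#' @param frac_synergistic fraction of genes with a non-zero
#'   interaction, in \[0, 1\].
#' @param baseline_mean,baseline_sd log2 baseline distribution.
#' @param effect_mean_a,effect_mean_b mean single-mutant effects (log2),
#'   applied to every gene.
#' @param effect_sd_a,effect_sd_b SDs of the single-mutant effects.
#' @param synergy_shift mean interaction `d` for synergistic genes
#'   (log2; negative for a synergistic loss).
#' @param noise_sd replicate (array) noise SD on the log2 scale.
#' @param distortion optional named list, sample id -> curve (see
#'   [inject_intensity_distortion()]), applied after noise.
#' @param seed optional integer seed; same config and seed give
#'   bit-identical output.
#' @return object of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 2000, n_reps = 3, frac_synergistic = 0.05,
                       baseline_mean = 9, baseline_sd = 1,
                       effect_mean_a = 0, effect_mean_b = 0,
                       effect_sd_a = 0.3, effect_sd_b = 0.3,
                       synergy_shift = -1, noise_sd = 0.3,
                       distortion = NULL, seed = NULL) {
  if (n_genes < 1) stop("invalid config: n_genes must be positive")
  if (n_reps < 1) stop("invalid config: n_reps must be >= 1")
  if (frac_synergistic < 0 || frac_synergistic > 1)
    stop("invalid config: frac_synergistic must lie in [0, 1]")
  for (s in c(baseline_sd, effect_sd_a, effect_sd_b, noise_sd))
    if (s < 0) stop("invalid config: standard deviations must be >= 0")
  structure(list(n_genes = as.integer(n_genes), n_reps = as.integer(n_reps),
                 frac_synergistic = frac_synergistic,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 effect_mean_a = effect_mean_a, effect_mean_b = effect_mean_b,
                 effect_sd_a = effect_sd_a, effect_sd_b = effect_sd_b,
                 synergy_shift = synergy_shift, noise_sd = noise_sd,
                 distortion = distortion, seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Factorial expression simulation config\n")
  cat(sprintf("  %d genes x 4 genotypes x %d replicates\n", x$n_genes, x$n_reps))
  cat(sprintf("  synergistic fraction %.3g, interaction shift %.3g log2\n",
              x$frac_synergistic, x$synergy_shift))
  cat(sprintf("  noise SD %.3g log2\n", x$noise_sd))
  invisible(x)
}

#' Simulate a four-genotype factorial expression matrix
#'
#' Generates a genes x samples log2 expression matrix under the model
#' described in [sim_config()], together with a sample sheet and the
#' ground-truth table. Replicate noise is homoscedastic Gaussian on the
#' log2 scale, matching the ANOVA model fitted downstream.
#'
#' @param config a [sim_config()] object.
#' @param truth optional ground-truth `data.frame` with columns `gene`,
#'   `baseline`, `effect_a`, `effect_b`, `interaction_d`; overrides the
#'   randomly drawn truth (used to plant exact scenarios).
#' @return list with `matrix` (genes x samples, samples named
#'   `WT_1, ..., AB_n`), `samples` (`sample_id`, `genotype`) and
#'   `truth` (per-gene `baseline`, `effect_a`, `effect_b`,
#'   `interaction_d`, `is_synergistic`).
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 10, noise_sd = 0, seed = 1))
#' sim$matrix[1, 1:4]
#' @export
simulate_expression <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(truth)) {
    n <- config$n_genes
    gene <- sprintf("g%05d", seq_len(n))
    mu0 <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
    a <- stats::rnorm(n, config$effect_mean_a, config$effect_sd_a)
    b <- stats::rnorm(n, config$effect_mean_b, config$effect_sd_b)
    n_syn <- round(config$frac_synergistic * n)
    is_syn <- rep(FALSE, n)
    if (n_syn > 0 && config$synergy_shift != 0) {
      is_syn[sample.int(n, n_syn)] <- TRUE
    }
    d <- numeric(n)
    d[is_syn] <- stats::rnorm(sum(is_syn), config$synergy_shift,
                              0.1 * abs(config$synergy_shift))
    truth <- data.frame(gene = gene, baseline = mu0, effect_a = a,
                        effect_b = b, interaction_d = d,
                        is_synergistic = d != 0,
                        stringsAsFactors = FALSE)
  } else {
    need <- c("gene", "baseline", "effect_a", "effect_b", "interaction_d")
    if (!all(need %in% names(truth))) stop("'truth' needs columns ",
                                           paste(need, collapse = ", "))
    truth$is_synergistic <- truth$interaction_d != 0
  }
  gmeans <- cbind(WT = truth$baseline,
                  A  = truth$baseline + truth$effect_a,
                  B  = truth$baseline + truth$effect_b,
                  AB = truth$baseline + truth$effect_a + truth$effect_b +
                       truth$interaction_d)
  geno <- rep(c("WT", "A", "B", "AB"), each = config$n_reps)
  sample_id <- paste0(geno, "_", rep(seq_len(config$n_reps), times = 4))
  x <- gmeans[, geno, drop = FALSE] +
    matrix(stats::rnorm(nrow(truth) * length(geno), 0, config$noise_sd),
           nrow = nrow(truth))
  dimnames(x) <- list(truth$gene, sample_id)
  if (!is.null(config$distortion)) {
    for (s in names(config$distortion))
      x <- inject_intensity_distortion(x, s, config$distortion[[s]])
  }
  list(matrix = x,
       samples = data.frame(sample_id = sample_id, genotype = geno,
                            stringsAsFactors = FALSE),
       truth = truth)
}

#' Inject a smooth intensity distortion into one array
#'
#' Transforms the values of a single array (column) by a smooth curve,
#' creating the class of intensity-dependent artefact that loess
#' normalization is meant to remove. Other arrays are untouched.
#'
#' @param x genes x samples numeric matrix.
#' @param sample column (array) id to distort.
#' @param curve either a function `value -> value`, or a numeric vector
#'   of polynomial coefficients `c(c0, c1, c2, ...)` applied as
#'   `c0 + c1 * v + c2 * v^2 + ...`.
#' @return the matrix with the named column transformed.
#' @examples
#' m <- matrix(8, 2, 2, dimnames = list(NULL, c("s1", "s2")))
#' inject_intensity_distortion(m, "s2", c(0.5, 1))   # s2 shifted +0.5
#' @export
inject_intensity_distortion <- function(x, sample, curve) {
  x <- as.matrix(x)
  if (!sample %in% colnames(x)) stop("unknown array id: ", sample)
  f <- if (is.function(curve)) curve else {
    if (!is.numeric(curve)) stop("'curve' must be a function or coefficients")
    function(v) {
      out <- 0
      for (k in seq_along(curve)) out <- out + curve[k] * v^(k - 1)
      out
    }
  }
  x[, sample] <- f(x[, sample])
  x
}

#' Construct an annotation map
#'
#' @param terms named list of gene-id vectors, one per term/family.
#' @param universe gene-id vector the terms are drawn from.
#' @return object of class `"annotation_map"` with elements `terms` and
#'   `universe`.
#' @export
annotation_map <- function(terms, universe) {
  universe <- unique(as.character(universe))
  if (is.null(names(terms)) || any(names(terms) == ""))
    stop("'terms' must be a named list")
  terms <- lapply(terms, function(g) unique(as.character(g)))
  if (any(lengths(terms) == 0L)) stop("terms must be non-empty")
  out <- setdiff(unique(unlist(terms)), universe)
  if (length(out)) stop("annotated genes outside the universe: ",
                        paste(utils::head(out, 5), collapse = ", "))
  structure(list(terms = terms, universe = universe), class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat("Annotation map:", length(x$terms), "terms over a universe of",
      length(x$universe), "genes\n")
  invisible(x)
}

#' Simulate a gene-family annotation with one planted enrichment
#'
#' Builds an annotation universe in which each family is a random gene
#' set of the requested size, and the named enriched family contains
#' exactly `overlap` of the candidate genes (the planted ground truth
#' for over-representation testing).
#'
#' @param universe gene-id vector.
#' @param families named integer vector of family sizes.
#' @param enriched_family name of the family carrying the planted
#'   overlap; must appear in `families`.
#' @param candidates candidate gene ids (subset of `universe`).
#' @param overlap number of candidate genes placed into the enriched
#'   family.
#' @param seed optional integer seed.
#' @return an [annotation_map()].
#' @export
simulate_annotation <- function(universe, families, enriched_family,
                                candidates, overlap, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  universe <- unique(as.character(universe))
  if (is.data.frame(families))
    families <- stats::setNames(families$size, families$name)
  if (is.null(names(families))) stop("'families' must be named sizes")
  if (!enriched_family %in% names(families))
    stop("'enriched_family' not among the families")
  candidates <- unique(as.character(candidates))
  if (!all(candidates %in% universe)) stop("candidates must lie in the universe")
  N <- length(universe)
  if (any(families > N)) stop("invalid config: family size exceeds universe")
  K <- families[[enriched_family]]
  if (overlap > min(K, length(candidates)))
    stop("invalid config: overlap exceeds family or candidate size")
  non_cand <- setdiff(universe, candidates)
  if (K - overlap > length(non_cand))
    stop("invalid config: family cannot avoid the candidate set")
  terms <- vector("list", length(families))
  names(terms) <- names(families)
  for (nm in names(families)) {
    terms[[nm]] <- if (nm == enriched_family) {
      c(if (overlap > 0) sample(candidates, overlap) else character(0),
        if (K - overlap > 0) sample(non_cand, K - overlap) else character(0))
    } else {
      sample(universe, families[[nm]])
    }
  }
  annotation_map(terms, universe)
}

#' Simulate a long-format qRT-PCR Ct table
#'
#' Generates quantification-cycle values for the genes of a ground-truth
#' table across the four genotypes, with a reference gene whose level is
#' constant across genotypes. Amplification is modelled at 100%
#' efficiency (one cycle per doubling), so the expected normalized
#' expression of a target in genotype g is `2^(level_g - ref_log2)` --
#' the inverse of the delta-Ct quantification in
#' [normalized_expression()].
#'
#' Biological noise is added per (gene, genotype, biological replicate)
#' and technical noise per well, both in cycles.
#'
#' @param truth ground-truth `data.frame` (columns `gene`, `baseline`,
#'   `effect_a`, `effect_b`, `interaction_d`), e.g. a subset of
#'   `simulate_expression()$truth`.
#' @param n_bio_reps biological replicates per genotype (default 4).
#' @param n_tech_reps technical replicates per well (default 3).
#' @param reference_gene id of the reference gene. If present in
#'   `truth` it must be stable (zero effects) or a warning is issued;
#'   otherwise a stable reference at level `ref_log2` is added.
#' @param ref_log2 log2 level of the added reference gene (default 0).
#' @param ct_intercept Ct of a hypothetical zero-level transcript
#'   (default 30 cycles).
#' @param noise_sd biological noise SD in cycles (default 0).
#' @param tech_sd technical noise SD in cycles (default 0).
#' @param seed optional integer seed.
#' @return long `data.frame` with columns `sample`, `genotype`,
#'   `bio_rep`, `tech_rep`, `gene`, `ct`.
#' @export
simulate_qpcr <- function(truth, n_bio_reps = 4, n_tech_reps = 3,
                          reference_gene = "reference", ref_log2 = 0,
                          ct_intercept = 30, noise_sd = 0, tech_sd = 0,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_bio_reps < 1 || n_tech_reps < 1)
    stop("invalid config: replicate counts must be >= 1")
  need <- c("gene", "baseline", "effect_a", "effect_b", "interaction_d")
  if (!all(need %in% names(truth))) stop("'truth' needs columns ",
                                         paste(need, collapse = ", "))
  if (reference_gene %in% truth$gene) {
    r <- truth[truth$gene == reference_gene, ]
    if (any(abs(c(r$effect_a, r$effect_b, r$interaction_d)) > 0))
      warning("reference gene '", reference_gene,
              "' is not stable across genotypes")
  } else {
    truth <- rbind(truth[, need],
                   data.frame(gene = reference_gene, baseline = ref_log2,
                              effect_a = 0, effect_b = 0, interaction_d = 0))
  }
  lev <- cbind(WT = truth$baseline,
               A  = truth$baseline + truth$effect_a,
               B  = truth$baseline + truth$effect_b,
               AB = truth$baseline + truth$effect_a + truth$effect_b +
                    truth$interaction_d)
  rownames(lev) <- truth$gene
  grid <- expand.grid(tech_rep = seq_len(n_tech_reps),
                      bio_rep = seq_len(n_bio_reps),
                      gene = truth$gene,
                      genotype = c("WT", "A", "B", "AB"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # one biological deviation per (genotype, gene, bio_rep), shared by wells
  bio_key <- interaction(grid$genotype, grid$gene, grid$bio_rep, drop = TRUE)
  bio_dev <- stats::rnorm(nlevels(bio_key), 0, noise_sd)[as.integer(bio_key)]
  level <- lev[cbind(grid$gene, grid$genotype)] + bio_dev
  ct <- ct_intercept - level + stats::rnorm(nrow(grid), 0, tech_sd)
  data.frame(sample = paste0(grid$genotype, "_", grid$bio_rep),
             genotype = grid$genotype, bio_rep = grid$bio_rep,
             tech_rep = grid$tech_rep, gene = grid$gene, ct = ct,
             stringsAsFactors = FALSE)
}
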