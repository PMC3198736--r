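test_that("the vectorised ANOVA agrees with the lm route gene by gene", {
  set.seed(10)
  geno <- rep(c("WT", "A", "B", "AB"), times = c(3, 3, 2, 4))
  x <- matrix(rnorm(20 * length(geno), 9, 0.5), 20,
              dimnames = list(sprintf("g%02d", 1:20), NULL))
  fit <- genotype_anova(x, geno)
  for (i in c(1, 7, 20)) {
    ref <- lm_gene_oracle(x[i, ], geno)
    expect_equal(unname(coef(fit)[i, ]), as.numeric(ref$means))
    expect_equal(fit$s2[[i]], ref$s2)
    expect_equal(fit$fstat[[i]], ref$fstat)
    expect_equal(fit$p[[i]], ref$p)
    expect_equal(fit$df, ref$df)
  }
})

test_that("a classic three-group example gives the known F and p", {
  fit <- fit_gene_anova(list(g1 = c(3, 4, 5), g2 = c(5, 6, 7),
                             g3 = c(7, 8, 9)))
  ref <- lm_gene_oracle(c(3, 4, 5, 5, 6, 7, 7, 8, 9), rep(1:3, each = 3))
  expect_equal(unname(fit$fstat), ref$fstat)     # = 12 by hand (SSB 24, MSW 1)
  expect_equal(unname(fit$fstat), 12)
  expect_equal(unname(fit$p), ref$p)
  expect_equal(unname(fit$p), 0.008, tolerance = 1e-3)
})

test_that("degenerate and constant fits are handled as defined", {
  same <- fit_gene_anova(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(unname(same$fstat), 0)
  expect_equal(unname(same$p), 1)
  expect_false(same$degenerate)

  sep <- fit_gene_anova(list(a = c(0, 0), b = c(1, 1)))
  expect_true(sep$degenerate)
  expect_true(is.na(sep$p))

  nodf <- fit_gene_anova(list(a = 1, b = 2))    # zero residual df
  expect_true(nodf$degenerate)
  expect_true(is.na(nodf$p))

  expect_error(fit_gene_anova(list(a = c(1, 2))), "two genotypes")
})

test_that("LSmean contrasts follow the textbook estimate and SE", {
  x <- matrix(rep(9, 12), 1, dimnames = list("g", NULL))
  geno <- rep(c("WT", "A", "B", "AB"), each = 3)
  set.seed(2)
  x2 <- rbind(g = 9 + rnorm(12, 0, 0.2))
  fit <- genotype_anova(x2, geno)

  # estimate equals the weighted sum of the genotype means
  con <- lsmean_contrast(fit, c(WT = 1, A = -1, B = -1, AB = 1))
  expect_equal(con$estimate,
               sum(c(1, -1, -1, 1) * coef(fit)[1, c("WT", "A", "B", "AB")]))
  # SE formula at known s2: manufacture a fit with s2 = 0.04
  fit$s2 <- 0.04
  con2 <- lsmean_contrast(fit, c(WT = 1, A = -1, B = -1, AB = 1))
  expect_equal(con2$se, 0.2 * sqrt(4 / 3), tolerance = 1e-10)

  # equal means: zero estimate, p = 1
  flat <- genotype_anova(rbind(g = c(5, 5, 5.2, 5.2, 5.1, 5.1, 5.15, 5.05)),
                         rep(c("WT", "A", "B", "AB"), each = 2))
  flat$lsmeans[] <- 7
  czero <- lsmean_contrast(flat, c(WT = 1, A = -1))
  expect_equal(czero$estimate, 0)
  expect_equal(czero$p, 1)
  # grand-mean weights on equal means also vanish
  cg <- lsmean_contrast(flat, c(WT = -0.25, A = -0.25, B = -0.25, AB = 0.75))
  expect_equal(cg$estimate, 0)

  expect_error(lsmean_contrast(fit, c(XX = 1)), "unknown genotype")
  deg <- fit_gene_anova(list(a = c(0, 0), b = c(1, 1)))
  expect_error(suppressWarnings(lsmean_contrast(deg, c(a = 1, b = -1))),
               "degenerate")
})

test_that("balanced contrasts reduce to differences of sample means", {
  set.seed(3)
  geno <- rep(c("WT", "A", "B", "AB"), each = 4)
  x <- matrix(rnorm(30 * 16, 9), 30)
  fit <- genotype_anova(x, geno)
  con <- lsmean_contrast(fit, c(AB = 1, WT = -1))
  direct <- rowMeans(x[, geno == "AB"]) - rowMeans(x[, geno == "WT"])
  expect_equal(con$estimate, unname(direct))
})

test_that("pFDR q-values reduce to BH at pi0 = 1 and are monotone", {
  expect_equal(as.numeric(pfdr_qvalues(rep(1, 5))), rep(1, 5))
  expect_identical(pfdr_qvalues(numeric(0)), numeric(0))
  expect_error(pfdr_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(4)
  for (i in 1:10) {
    p <- c(runif(50), runif(20)^3)     # mixed null/signal shapes
    expect_equal(as.numeric(pfdr_qvalues(p, pi0 = 1)),
                 p.adjust(p, method = "BH"))
    q <- pfdr_qvalues(p)
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
    expect_true(all(q >= 0 & q <= 1))
  }

  # rank-1 bound on the smallest p
  p4 <- c(0.001, 0.8, 0.9, 0.95)
  q4 <- pfdr_qvalues(p4)
  expect_lte(q4[1], 4 * attr(q4, "pi0") * 0.001)
})

test_that("the differential screen enforces all three membership rules", {
  # strong but small shift: significant q, excluded by the 0.35 filter
  set.seed(5)
  tr <- data.frame(gene = sprintf("g%03d", 1:101),
                   baseline = rnorm(101, 9, 1), effect_a = 0, effect_b = 0,
                   interaction_d = c(-0.2, rep(0, 100)))
  sim <- simulate_expression(sim_config(n_genes = 101, noise_sd = 0.01,
                                        seed = 5), truth = tr)
  fit <- genotype_anova(sim$matrix, sim$samples)
  scr <- approach1_screen(fit, target = "AB", baseline = "wt")
  con <- scr$table[scr$table$gene == "g001", ]
  expect_lt(con$q, 0.05)                       # clearly significant
  expect_lt(abs(con$estimate), 0.35)           # ... but too small a change
  expect_false("g001" %in% scr$under)

  # alpha = 0 empties both sets
  scr0 <- approach1_screen(fit, target = "AB", baseline = "wt", alpha = 0)
  expect_length(scr0$under, 0)
  expect_length(scr0$over, 0)

  expect_error(approach1_screen(fit, target = "XX"), "unknown target")
})

test_that("screen membership matches an lm + BH oracle and is order-invariant", {
  set.seed(1)
  tr <- data.frame(gene = sprintf("g%04d", 1:1050),
                   baseline = rnorm(1050, 9, 1), effect_a = 0, effect_b = 0,
                   interaction_d = c(rep(-1, 50), rep(0, 1000)))
  sim <- simulate_expression(sim_config(n_genes = 1050, noise_sd = 0.3,
                                        n_reps = 3, seed = 11), truth = tr)
  fit <- genotype_anova(sim$matrix, sim$samples)
  scr <- approach1_screen(fit, target = "AB", baseline = "wt",
                          multiple = "bh")

  # oracle: per-gene lm contrast + BH
  geno <- sim$samples$genotype
  oracle <- t(vapply(seq_len(1050), function(i) {
    m <- tapply(sim$matrix[i, ], factor(geno, levels = c("WT","A","B","AB")),
                mean)
    f <- lm_gene_oracle(sim$matrix[i, ], geno)
    est <- m[["AB"]] - m[["WT"]]
    tt <- est / sqrt(f$s2 * 2 / 3)
    c(est = est, p = 2 * pt(-abs(tt), f$df))
  }, numeric(2)))
  qo <- p.adjust(oracle[, "p"], "BH")
  under_oracle <- sort(tr$gene[qo <= 0.05 & oracle[, "est"] < -0.35])
  expect_identical(scr$under, under_oracle)

  # the per-gene contrast has the power the design implies: raw-p recovery
  con <- lsmean_contrast(fit, c(AB = 1, WT = -1))
  raw_under <- con$gene[con$p < 0.05 & con$estimate < -0.35]
  expect_gte(length(intersect(raw_under, sprintf("g%04d", 1:50))), 45)
  # false q-value-screen members stay a small minority
  false_members <- setdiff(scr$under, sprintf("g%04d", 1:50))
  expect_lte(length(false_members), 0.05 * length(scr$under) + 2)

  # permuting the gene order leaves the member sets unchanged
  perm <- sample(nrow(sim$matrix))
  fit_p <- genotype_anova(sim$matrix[perm, ], sim$samples)
  scr_p <- approach1_screen(fit_p, target = "AB", baseline = "wt",
                            multiple = "bh")
  expect_identical(scr_p$under, scr$under)
  expect_identical(scr_p$over, scr$over)
})

test_that("the omnibus ANOVA holds its size under a global null", {
  sim <- simulate_expression(sim_config(n_genes = 10000,
                                        frac_synergistic = 0,
                                        effect_sd_a = 0, effect_sd_b = 0,
                                        noise_sd = 0.3, seed = 12))
  fit <- genotype_anova(sim$matrix, sim$samples)
  frac <- mean(fit$p < 0.05)
  band <- 3 * sqrt(0.05 * 0.95 / 10000)
  expect_gt(frac, 0.05 - band)
  expect_lt(frac, 0.05 + band)
})
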