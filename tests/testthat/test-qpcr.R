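make_ct <- function(ct_target, ct_ref, genotype = "WT", bio_rep = 1,
                    tech_rep = 1) {
  rbind(data.frame(sample = paste0(genotype, "_", bio_rep),
                   genotype = genotype, bio_rep = bio_rep,
                   tech_rep = tech_rep, gene = "tgt", ct = ct_target),
        data.frame(sample = paste0(genotype, "_", bio_rep),
                   genotype = genotype, bio_rep = bio_rep,
                   tech_rep = tech_rep, gene = "ref", ct = ct_ref))
}

test_that("delta-Ct quantification follows the doubling rule", {
  eq <- normalized_expression(make_ct(22, 22), "tgt", "ref")
  expect_equal(eq$summary$mean, 1)

  down <- normalized_expression(make_ct(24, 20), "tgt", "ref")
  expect_equal(down$summary$mean, 2^-4)     # 0.0625

  # technical replicates are averaged on the Ct scale before transforming
  ct <- rbind(make_ct(c(20, 24), 20, tech_rep = 1:2))
  out <- normalized_expression(ct, "tgt", "ref")
  expect_equal(out$summary$mean, 2^(20 - 22))      # mean Ct 22, not mean of 2^-x
  expect_false(isTRUE(all.equal(out$summary$mean, mean(c(1, 2^-4)))))
})

test_that("a published wild-type level round-trips through the generator", {
  # a target amplifying log2(15.78) cycles earlier than the reference
  tr <- data.frame(gene = "rem16", baseline = log2(15.78), effect_a = 0,
                   effect_b = 0, interaction_d = 0)
  ct <- simulate_qpcr(tr, reference_gene = "apt1", ref_log2 = 0)
  out <- normalized_expression(ct, "rem16", "apt1")$summary
  expect_equal(out$mean[out$genotype == "WT"], 15.78)
})

test_that("missing reference replicates are dropped, or fatal when total", {
  ct <- rbind(make_ct(24, 20, bio_rep = 1), make_ct(23, 20, bio_rep = 2))
  ct <- ct[!(ct$gene == "ref" & ct$bio_rep == 2), ]
  expect_warning(out <- normalized_expression(ct, "tgt", "ref"),
                 "without the reference")
  expect_equal(out$summary$n_bio, 1)

  ct2 <- ct[ct$gene == "tgt", ]
  expect_error(normalized_expression(ct2, "tgt", "ref"), "reference gene absent")
})

test_that("reference stability flags genotype-dependent references", {
  # identical differences everywhere: degenerate but stable
  base <- expand.grid(genotype = c("WT", "A", "B", "AB"), bio_rep = 1:4)
  ct_const <- rbind(
    data.frame(sample = "s", genotype = base$genotype, bio_rep = base$bio_rep,
               tech_rep = 1, gene = "r1", ct = 20),
    data.frame(sample = "s", genotype = base$genotype, bio_rep = base$bio_rep,
               tech_rep = 1, gene = "r2", ct = 22))
  st <- reference_stability(ct_const, c("r1", "r2"))
  expect_true(st$degenerate)
  expect_true(st$stable)
  expect_error(reference_stability(ct_const, "r1"), "at least two")

  # null calibration: a truly stable pair is flagged unstable ~5% of the time
  rejections <- vapply(1:1000, function(s) {
    set.seed(s)
    ct <- rbind(
      data.frame(sample = "s", genotype = base$genotype,
                 bio_rep = base$bio_rep, tech_rep = 1, gene = "r1",
                 ct = 20 + rnorm(16, 0, 0.15)),
      data.frame(sample = "s", genotype = base$genotype,
                 bio_rep = base$bio_rep, tech_rep = 1, gene = "r2",
                 ct = 22 + rnorm(16, 0, 0.15)))
    reference_stability(ct, c("r1", "r2"))$p < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.05 - 3 * sqrt(0.05 * 0.95 / 1000))
  expect_lt(mean(rejections), 0.05 + 3 * sqrt(0.05 * 0.95 / 1000))

  # a one-cycle shift confined to the double mutant is caught nearly always
  caught <- vapply(1:200, function(s) {
    set.seed(s)
    shift <- ifelse(base$genotype == "AB", 1, 0)
    ct <- rbind(
      data.frame(sample = "s", genotype = base$genotype,
                 bio_rep = base$bio_rep, tech_rep = 1, gene = "r1",
                 ct = 20 + shift + rnorm(16, 0, 0.15)),
      data.frame(sample = "s", genotype = base$genotype,
                 bio_rep = base$bio_rep, tech_rep = 1, gene = "r2",
                 ct = 22 + rnorm(16, 0, 0.15)))
    reference_stability(ct, c("r1", "r2"))$p < 0.05
  }, logical(1))
  expect_gte(mean(caught), 0.95)
})

test_that("Tukey-Kramer letters track the pairwise decisions", {
  # indistinguishable groups share a letter
  same <- tukey_hsd(list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4)))
  expect_equal(same$summary$letters, c("A", "A"))

  # well-separated groups get distinct letters
  set.seed(21)
  apart <- tukey_hsd(list(lo = rnorm(4, 0, 0.1), mid = rnorm(4, 10, 0.1),
                          hi = rnorm(4, 20, 0.1)))
  expect_setequal(apart$summary$letters, c("A", "B", "C"))
  expect_equal(apart$summary$letters[apart$summary$group == "hi"], "A")

  expect_error(tukey_hsd(list(a = 1, b = c(1, 2))), "at least 2 values")

  # two-group Tukey collapses to the pooled two-sample t test
  g2 <- list(a = c(5.1, 4.9, 5.3, 5.2), b = c(5.6, 5.8, 5.5, 5.9))
  tk <- tukey_hsd(g2)
  tt <- t.test(g2$a, g2$b, var.equal = TRUE)$p.value
  expect_lt(abs(tk$p_matrix["a", "b"] - tt), 1e-6)
})

test_that("letter display and p-matrix agree on random group patterns", {
  set.seed(22)
  for (i in 1:50) {
    G <- sample(2:5, 1)
    n <- sample(3:6, 1)
    means <- sample(0:4, G, replace = TRUE) * runif(1, 0, 2)
    groups <- stats::setNames(
      lapply(means, function(m) rnorm(n, m, 0.5)), paste0("grp", seq_len(G)))
    res <- tukey_hsd(groups)
    lett <- strsplit(res$summary$letters, "")
    for (a in seq_len(G - 1)) for (b in seq((a + 1), G)) {
      shares <- length(intersect(lett[[a]], lett[[b]])) > 0
      expect_identical(shares, res$p_matrix[a, b] >= 0.05,
                       label = sprintf("case %d pair %d-%d", i, a, b))
    }
  }
})

test_that("letters agree with the multcomp compact letter display", {
  library(multcomp)
  set.seed(23)
  for (i in 1:5) {
    G <- sample(3:5, 1)
    groups <- stats::setNames(
      lapply(sample(0:3, G, replace = TRUE), function(m) rnorm(5, m, 0.7)),
      paste0("g", seq_len(G)))
    res <- tukey_hsd(groups)
    dat <- data.frame(y = unlist(groups, use.names = FALSE),
                      grp = factor(rep(names(groups), lengths(groups))))
    glht_fit <- glht(aov(y ~ grp, dat), linfct = mcp(grp = "Tukey"))
    cld_ref <- cld(glht_fit, level = 0.05)$mcletters$Letters
    # same partition: pairs share a letter in ours iff they do in multcomp
    for (a in seq_len(G - 1)) for (b in seq((a + 1), G)) {
      ga <- names(groups)[a]; gb <- names(groups)[b]
      ours <- length(intersect(strsplit(res$summary$letters[a], "")[[1]],
                               strsplit(res$summary$letters[b], "")[[1]])) > 0
      ref <- length(intersect(strsplit(cld_ref[[ga]], "")[[1]],
                              strsplit(cld_ref[[gb]], "")[[1]])) > 0
      expect_identical(ours, ref)
    }
  }
})

test_that("published group summaries reconstruct the published letters", {
  und <- qpcr_verification_table("under")
  rem16 <- und[und$gene_name == "REM16", ]
  groups <- stats::setNames(
    lapply(seq_len(4), function(i)
      make_exact_group(rem16$mean[i], rem16$sem[i], n = 4)),
    rem16$genotype)
  res <- tukey_hsd(groups)
  got <- res$summary$letters[match(rem16$genotype, res$summary$group)]
  expect_identical(got, rem16$letters)     # wt A, seu C, ant B, double D
})
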