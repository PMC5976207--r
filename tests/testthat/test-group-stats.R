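test_that("focus summaries give exact group means and sizes", {
  d <- data.frame(genotype = c("WT", "WT", "WT", "msh4"),
                  temperature = "20C",
                  antibody = "MLH1",
                  count = c(9, 10, 11, 4))
  s <- summarize_foci(d, c("genotype", "temperature"))
  expect_equal(s$mean[s$genotype == "WT"], 10)
  expect_equal(s$n[s$genotype == "WT"], 3L)
  expect_equal(nrow(s), 2L)  # no empty groups appear
  expect_error(summarize_foci(transform(d, count = c(-1, 1, 1, 1))),
               "non-negative")
})

test_that("Welch's t-test matches the closed-form hand evaluation", {
  w <- welch_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(abs(w$t), sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(w$df, 4, tolerance = 1e-12)
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  const <- welch_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(const$t, 0); expect_equal(const$p, 1)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("Welch's t is shift-invariant and antisymmetric", {
  set.seed(41)
  a <- rpois(20, 10); b <- rpois(20, 12)
  w <- welch_t(a, b)
  expect_equal(welch_t(a + 100, b + 100)$t, w$t, tolerance = 1e-9)
  expect_equal(welch_t(b, a)$t, -w$t, tolerance = 1e-12)
})

test_that("Welch's p agrees with a permutation test on simulated foci", {
  set.seed(123)
  a <- rpois(30, 10); b <- rpois(30, 11.5)
  w <- welch_t(a, b)
  pool <- c(a, b); d0 <- abs(mean(a) - mean(b))
  perm <- vapply(1:20000, function(i) {
    idx <- sample(60, 30)
    abs(mean(pool[idx]) - mean(pool[-idx])) >= d0
  }, NA)
  expect_lt(abs(w$p - mean(perm)), 0.01)
})

test_that("delta-CT averages technical replicates before subtracting", {
  plate <- data.frame(
    sample = rep(c("s1", "s2"), each = 4),
    treatment = rep(c("ctrl", "trt"), each = 4),
    gene = rep(c("GOI", "GOI", "REF", "REF"), 2),
    rep = rep(1:2, 4),
    ct = c(24.9, 25.1, 22, 22, 26, 26, 22, 22))
  d <- delta_ct(plate, "GOI", "REF")
  expect_equal(d$delta_ct[d$sample == "s1"], 3)   # mean(24.9, 25.1) - 22
  expect_equal(d$delta_ct[d$sample == "s2"], 4)
  # equal CTs give zero
  plate0 <- transform(plate, ct = 22)
  expect_true(all(delta_ct(plate0, "GOI", "REF")$delta_ct == 0))
  # missing control wells are reported by sample
  expect_error(delta_ct(plate[plate$gene == "GOI" | plate$sample == "s1", ],
                        "GOI", "REF"), "s2")
})

test_that("fold changes follow 2^-ddCT with the reference at exactly 1", {
  dct <- data.frame(sample = paste0("s", 1:6),
                    treatment = rep(c("ctrl", "trt"), each = 3),
                    delta_ct = c(3, 3, 3, 0, 0, 0))
  fit <- ddct_fold_change(dct, "ctrl")
  tab <- fit$table
  expect_equal(tab$fold[tab$treatment == "ctrl"], 1)
  expect_equal(tab$ddct[tab$treatment == "trt"], -3)
  expect_equal(tab$fold[tab$treatment == "trt"], 8)
  expect_error(ddct_fold_change(dct, "missing"), "reference")
})

test_that("a simulated log2FC of 3 is recovered as a fold change near 8", {
  eff <- data.frame(treatment = rep(c("ctrl", "trt"), each = 2),
                    gene = rep(c("GOI", "REF"), 2),
                    log2fc = c(0, 0, 3, 0))
  plate <- simulate_qpcr_plate(eff, n_biological = 20, seed = 42)
  fit <- ddct_fold_change(delta_ct(plate, "GOI", "REF"), "ctrl")
  fold <- fit$table$fold[fit$table$treatment == "trt"]
  expect_lt(abs(fold / 8 - 1), 0.15)
})

test_that("fold change is invariant to a constant plate offset", {
  plate <- simulate_qpcr_plate(nacl_qpcr_effects(), seed = 43)
  f1 <- ddct_fold_change(delta_ct(plate, "BHLH122", "TUB4"), "0mM")
  plate$ct <- plate$ct + 2.5
  f2 <- ddct_fold_change(delta_ct(plate, "BHLH122", "TUB4"), "0mM")
  expect_equal(f1$table$fold, f2$table$fold, tolerance = 1e-9)
})

test_that("the control gene shows no treatment response by construction", {
  plate <- simulate_qpcr_plate(nacl_qpcr_effects(), n_biological = 30, seed = 44)
  fit <- ddct_fold_change(delta_ct(plate, "TUB4", "TUB4"), "0mM")
  expect_true(all(fit$table$fold == 1))  # a gene against itself is exactly 1
  # and an unaffected target against the control stays near 1
  eff <- nacl_qpcr_effects(); eff$log2fc[eff$gene == "BHLH122"] <- 0
  plate2 <- simulate_qpcr_plate(eff, n_biological = 30, seed = 45)
  fit2 <- ddct_fold_change(delta_ct(plate2, "BHLH122", "TUB4"), "0mM")
  expect_lt(max(abs(fit2$table$fold - 1)), 0.25)
})

test_that("two-group ANOVA reduces to the pooled t-test (F = t^2)", {
  set.seed(46)
  dct <- data.frame(sample = paste0("s", 1:12),
                    treatment = rep(c("a", "b"), each = 6),
                    delta_ct = rnorm(12))
  av <- anova_tukey(dct)
  tt <- t.test(delta_ct ~ treatment, data = dct, var.equal = TRUE)
  expect_equal(av$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(av$p, tt$p.value, tolerance = 1e-9)
})

test_that("Tukey adjusted p-values never fall below the unadjusted pairwise p", {
  set.seed(47)
  dct <- data.frame(sample = paste0("s", 1:18),
                    treatment = rep(c("a", "b", "c"), each = 6),
                    delta_ct = rnorm(18) + rep(c(0, 0.5, 1), each = 6))
  av <- anova_tukey(dct)
  raw <- pairwise.t.test(dct$delta_ct, dct$treatment, pool.sd = TRUE,
                         p.adjust.method = "none")$p.value
  raw_p <- c("b-a" = raw["b", "a"], "c-a" = raw["c", "a"], "c-b" = raw["c", "b"])
  expect_true(all(av$tukey$p_adj >= raw_p[av$tukey$pair] - 1e-12))
})

test_that("a large shift is detected by Tukey at p < 0.001", {
  set.seed(48)
  dct <- data.frame(sample = paste0("s", 1:18),
                    treatment = rep(c("a", "b", "c"), each = 6),
                    delta_ct = rnorm(18, sd = 0.3) + rep(c(0, 0, -3), each = 6))
  av <- anova_tukey(dct)
  expect_lt(av$tukey$p_adj[av$tukey$pair == "c-a"], 0.001)
})

test_that("ANOVA p-values are uniform under the null", {
  set.seed(49)
  ps <- vapply(1:300, function(i) {
    dct <- data.frame(sample = paste0("s", 1:15),
                      treatment = rep(c("a", "b", "c"), each = 5),
                      delta_ct = rnorm(15))
    anova_tukey(dct)$p
  }, 0)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("degenerate and undersized inputs are rejected", {
  dct <- data.frame(sample = paste0("s", 1:6),
                    treatment = rep(c("a", "b"), each = 3), delta_ct = 1)
  expect_error(anova_tukey(dct), "degenerate")
  expect_error(anova_tukey(dct[dct$treatment == "a", ]), "two treatments")
  expect_error(anova_tukey(dct[c(1, 2, 3, 4), ]), "n >= 2")
})

test_that("significance labels mirror the figure-legend convention", {
  expect_equal(sig_label(2e-5), "****")
  expect_equal(sig_label(5e-4), "***")
  expect_equal(sig_label(0.004), "**")
  expect_equal(sig_label(0.03), "*")
  expect_equal(sig_label(0.8), "ns")
  expect_equal(sig_label(0.2), "")
})

test_that("pollen viability flows through the same summary and Welch path", {
  p20 <- simulate_pollen_counts(22, 665.7, temperature = "20C", seed = 50)
  p28 <- simulate_pollen_counts(28, 294.5, temperature = "28C", seed = 51)
  w <- welch_t(p20$count, p28$count)
  expect_lt(w$p, 1e-6)
  expect_gt(w$means[1], w$means[2])
})
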