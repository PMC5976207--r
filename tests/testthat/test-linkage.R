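test_that("Perkins distance reproduces the defining cases", {
  expect_equal(perkins(class_counts(100, 0, 0))$X, 0)
  expect_equal(perkins(class_counts(0, 100, 0))$X, 50)
  expect_equal(perkins(class_counts(70, 28, 2))$X, 20)  # 100*(14+6)/100
  expect_error(perkins(class_counts(0, 0, 0)), "n = 0")
  # OTHER tetrads never enter the estimate
  expect_equal(perkins(class_counts(70, 28, 2, OTHER = 50))$X, 20)
})

test_that("estimator and SE match the per-tetrad score accumulation oracle", {
  set.seed(21)
  for (i in 1:200) {
    cnt <- rmultinom(1, sample(20:400, 1), c(0.7, 0.25, 0.05))[, 1]
    if (sum(cnt) == 0) next
    fit <- perkins(class_counts(cnt[1], cnt[2], cnt[3]))
    orc <- perkins_oracle(cnt[1], cnt[2], cnt[3])
    expect_equal(fit$X, orc$X, tolerance = 1e-12)
    expect_equal(fit$SE, orc$SE, tolerance = 1e-12)
  }
})

test_that("the delta-method SE matches a parametric bootstrap", {
  fit <- perkins(class_counts(70, 28, 2))
  set.seed(22)
  cnt <- rmultinom(1e5, 100, c(0.70, 0.28, 0.02))
  Xb <- 100 * (cnt[2, ] / 2 + 3 * cnt[3, ]) / 100
  expect_lt(abs(fit$SE / sd(Xb) - 1), 0.02)
})

test_that("SE is zero iff one class and scales as 1/sqrt(n)", {
  expect_equal(perkins_se(class_counts(50, 0, 0)), 0)
  expect_equal(perkins_se(class_counts(0, 80, 0)), 0)
  s1 <- perkins_se(class_counts(70, 28, 2))
  s10 <- perkins_se(class_counts(700, 280, 20))
  expect_equal(s10, s1 / sqrt(10), tolerance = 1e-12)
})

test_that("distance is strictly monotone in T and NPD at fixed n", {
  base <- perkins(class_counts(70, 28, 2))$X
  expect_gt(perkins(class_counts(69, 29, 2))$X, base)
  expect_gt(perkins(class_counts(69, 28, 3))$X, base)
})

test_that("distance comparison gives the expected Z and p", {
  a <- perkins(class_counts(70, 28, 2))
  expect_equal(compare_distances(a, a)$Z, 0)
  expect_equal(compare_distances(a, a)$p, 1)
  # X = 20, SE = 1 vs X = 23, SE = 1: |Z| = 3/sqrt(2), p = 0.0339
  fa <- structure(list(X = 20, SE = 1, n = 100,
                       counts = c(PD = 70, T = 28, NPD = 2, OTHER = 0)),
                  class = "perkins_fit")
  fb <- structure(list(X = 23, SE = 1, n = 100,
                       counts = c(PD = 65, T = 33, NPD = 2, OTHER = 0)),
                  class = "perkins_fit")
  cmp <- compare_distances(fa, fb)
  expect_equal(abs(cmp$Z), 3 / sqrt(2), tolerance = 1e-12)
  expect_equal(cmp$p, 0.0339, tolerance = 1e-3)
  # antisymmetric in its arguments
  expect_equal(compare_distances(fb, fa)$Z, -cmp$Z)
  expect_equal(compare_distances(fb, fa)$p, cmp$p)
  expect_true(is.finite(cmp$chisq$statistic))
})

test_that("the distance Z-test is calibrated under the null", {
  set.seed(23)
  p_true <- c(0.75, 0.23, 0.02)
  ps <- vapply(1:1000, function(i) {
    ca <- rmultinom(1, 500, p_true)[, 1]
    cb <- rmultinom(1, 500, p_true)[, 1]
    compare_distances(perkins(class_counts(ca[1], ca[2], ca[3])),
                      perkins(class_counts(cb[1], cb[2], cb[3])))$p
  }, 0)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.025)
})

test_that("perkins fit behaves like a model object", {
  fit <- perkins(class_counts(70, 28, 2))
  expect_equal(unname(coef(fit)), 20)
  expect_equal(unname(vcov(fit)[1, 1]), fit$SE^2)
  ci <- confint(fit)
  expect_lt(ci[1], fit$X); expect_gt(ci[2], fit$X)
  expect_output(print(fit), "20 cM")
  expect_output(print(summary(fit)), "95% CI")
})
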