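test_that("relative viability normalizes to the untreated mean within groups", {
  df <- tibble::tibble(
    treatment = rep(c("untreated", "drug"), each = 4),
    plate = rep(c("A", "B"), times = 4),
    signal = c(10, 12, 20, 18, 5, 6, 10, 9)
  )
  out <- relative_viability(df, signal, treatment)
  expect_equal(mean(out$relative_viability[out$treatment == "untreated"]), 1)
  byp <- relative_viability(df, signal, treatment, by = "plate")
  for (p in c("A", "B")) {
    expect_equal(mean(byp$relative_viability[byp$treatment == "untreated" &
                                               byp$plate == p]), 1)
  }
  expect_error(relative_viability(df, signal, treatment, untreated_label = "none"),
               "[Uu]ntreated")
})

test_that("treatment at half the control mean gives relative viability 0.5", {
  df <- tibble::tibble(treatment = c("untreated", "untreated", "drug", "drug"),
                       signal = c(100, 100, 50, 50))
  out <- relative_viability(df, signal, treatment)
  expect_equal(out$relative_viability[out$treatment == "drug"], c(0.5, 0.5))
})

test_that("noiseless 4PL tables regenerate the true IC50", {
  for (truth in c(3.1, 12.3, 34.7)) {
    tab <- generate_dose_response(truth, hill = 1.2, top = 1, bottom = 0.05,
                                  doses = 10^seq(-1, 4, length.out = 9),
                                  cv = 0, replicates = 2, seed = 1L)
    fit <- fit_4pl(tab)
    expect_true(fit$converged)
    expect_equal(fit$coefficients[["ic50"]], truth, tolerance = 1e-5)
    expect_equal(fit$coefficients[["hill"]], 1.2, tolerance = 1e-4)
    expect_equal(predict(fit, truth), (1 + 0.05) / 2, tolerance = 1e-5)
  }
})

test_that("4PL fit is scale-equivariant in dose", {
  tab <- generate_dose_response(5, hill = 1.5, top = 1.1, bottom = 0.1,
                                doses = 10^seq(-1, 3, length.out = 8),
                                cv = 0.03, replicates = 3, seed = 6L)
  f1 <- fit_4pl(tab)
  tab2 <- tab; tab2$dose <- 2 * tab2$dose
  f2 <- fit_4pl(tab2)
  expect_equal(f2$coefficients[["ic50"]], 2 * f1$coefficients[["ic50"]],
               tolerance = 1e-6)
  expect_equal(f2$coefficients[["hill"]], f1$coefficients[["hill"]],
               tolerance = 1e-6)
})

test_that("degenerate 4PL inputs produce diagnostics, not numbers", {
  flat <- tibble::tibble(dose = 10^(0:5), viability = 1)
  f <- fit_4pl(flat)
  expect_false(f$converged)
  expect_equal(f$diagnostic, "flat_response")
  expect_true(is.na(f$coefficients[["ic50"]]))
  expect_error(fit_4pl(tibble::tibble(dose = c(1, 2, 4), viability = c(1, .5, 0))),
               "4 distinct doses")
})

test_that("tidy and glance methods expose 4PL parameters", {
  tab <- generate_dose_response(3.1, hill = 1, top = 1, bottom = 0,
                                cv = 0, seed = 1L)
  f <- fit_4pl(tab)
  td <- generics::tidy(f)
  expect_setequal(td$term, c("top", "bottom", "ic50", "hill"))
  gl <- generics::glance(f)
  expect_true(gl$converged)
  expect_equal(gl$n, nrow(tab))
})

test_that("one-way ANOVA matches pooled t^2 with two groups", {
  set.seed(14)
  for (i in 1:20) {
    df <- tibble::tibble(g = rep(c("a", "b"), each = 6),
                         y = rnorm(12, mean = rep(c(0, 0.8), each = 6)))
    a <- one_way_anova(df, y, g)
    tt <- t.test(y ~ g, data = df, var.equal = TRUE)
    expect_equal(a$statistic[1], unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(a$p.value[1], tt$p.value, tolerance = 1e-10)
  }
})

test_that("one-way ANOVA: flat data, loop oracle, infinite-F convention", {
  df0 <- tibble::tibble(g = rep(c("a", "b", "c"), each = 4), y = 5)
  expect_equal(one_way_anova(df0, y, g)$statistic[1], 0)
  set.seed(2)
  df <- tibble::tibble(g = rep(letters[1:4], times = c(4, 5, 6, 3)),
                       y = rnorm(18, rep(1:4, times = c(4, 5, 6, 3))))
  a <- one_way_anova(df, y, g)
  # explicit textbook sums of squares
  grand <- mean(df$y); ssb <- 0; ssw <- 0
  for (g in unique(df$g)) {
    yg <- df$y[df$g == g]
    ssb <- ssb + length(yg) * (mean(yg) - grand)^2
    ssw <- ssw + sum((yg - mean(yg))^2)
  }
  f_oracle <- (ssb / 3) / (ssw / (18 - 4))
  expect_equal(a$statistic[1], f_oracle, tolerance = 1e-12)
  expect_equal(a$sumsq, c(ssb, ssw), tolerance = 1e-12)
  # zero within-variance with real differences
  dfi <- tibble::tibble(g = rep(c("a", "b"), each = 3), y = rep(c(1, 2), each = 3))
  ai <- one_way_anova(dfi, y, g)
  expect_identical(ai$statistic[1], Inf)
  expect_identical(ai$p.value[1], 0)
})

test_that("Dunnett with two groups reduces to the pooled t-test", {
  set.seed(3)
  df <- tibble::tibble(g = rep(c("ctrl", "trt"), each = 5), y = rnorm(10))
  fam <- dunnett(df, y, g, control = "ctrl")
  tt <- t.test(y ~ g, data = df, var.equal = TRUE)
  cmp <- generics::tidy(fam)
  expect_equal(cmp$adj.p.value, tt$p.value, tolerance = 1e-4)
  expect_equal(cmp$p.value, tt$p.value, tolerance = 1e-12)
})

test_that("Dunnett on identical group data gives adjusted p of 1", {
  df <- tibble::tibble(g = rep(c("ctrl", "a", "b"), each = 4),
                       y = rep(c(3, 1, 4, 1), times = 3))
  fam <- dunnett(df, y, g, control = "ctrl")
  expect_equal(generics::tidy(fam)$adj.p.value, c(1, 1))
  expect_error(dunnett(df, y, g, control = "zz"), "Control group")
})

test_that("Dunnett adjusted p-values match the multcomp reference", {
  skip_if_not_installed("multcomp")
  set.seed(17)
  for (i in 1:5) {
    k <- sample(3:5, 1)
    n <- sample(4:7, 1)
    df <- data.frame(g = factor(rep(c("ctrl", paste0("t", seq_len(k - 1))), each = n),
                                levels = c("ctrl", paste0("t", seq_len(k - 1)))),
                     y = rnorm(k * n, mean = rep(c(0, runif(k - 1, 0, 1.5)), each = n)))
    fam <- dunnett(df, y, g, control = "ctrl")
    ref <- summary(multcomp::glht(stats::aov(y ~ g, df),
                                  linfct = multcomp::mcp(g = "Dunnett")))
    expect_equal(generics::tidy(fam)$adj.p.value,
                 unname(as.numeric(ref$test$pvalues)), tolerance = 5e-3)
    expect_equal(generics::tidy(fam)$estimate, unname(ref$test$coefficients),
                 tolerance = 1e-10)
  }
})

test_that("Tukey HSD matches stats::TukeyHSD and the two-group reduction", {
  set.seed(23)
  df <- tibble::tibble(g = rep(letters[1:4], each = 5), y = rnorm(20, rep(0:3, each = 5)))
  fam <- tukey_hsd(df, y, g)
  ref <- stats::TukeyHSD(stats::aov(y ~ g, df))$g
  cmp <- generics::tidy(fam)
  # same pair ordering: b-a, c-a, d-a, c-b, d-b, d-c
  expect_equal(cmp$adj.p.value, unname(ref[, "p adj"]), tolerance = 1e-6)
  expect_equal(cmp$estimate, unname(ref[, "diff"]), tolerance = 1e-12)

  df2 <- tibble::tibble(g = rep(c("a", "b"), each = 6), y = rnorm(12))
  fam2 <- tukey_hsd(df2, y, g)
  tt <- t.test(y ~ g, data = df2, var.equal = TRUE)
  expect_equal(generics::tidy(fam2)$adj.p.value, tt$p.value, tolerance = 1e-9)
  # identical groups: all adjusted p = 1
  df3 <- tibble::tibble(g = rep(c("a", "b", "c"), each = 3), y = rep(c(1, 5, 2), 3))
  expect_equal(generics::tidy(tukey_hsd(df3, y, g))$adj.p.value, rep(1, 3))
})

test_that("adjusted p-values never fall below unadjusted ones", {
  set.seed(31)
  for (i in 1:10) {
    k <- sample(3:6, 1)
    df <- tibble::tibble(g = rep(letters[1:k], each = 4),
                         y = rnorm(4 * k, rep(runif(k, 0, 2), each = 4)))
    fam_d <- dunnett(df, y, g, control = "a")
    fam_t <- tukey_hsd(df, y, g)
    expect_true(all(generics::tidy(fam_d)$adj.p.value >=
                      generics::tidy(fam_d)$p.value - 1e-12))
    expect_true(all(generics::tidy(fam_t)$adj.p.value >=
                      generics::tidy(fam_t)$p.value - 1e-12))
  }
})

test_that("two-way ANOVA reproduces aov on balanced designs", {
  set.seed(41)
  df <- tidyr::expand_grid(coat = c("none", "laminin", "fibronectin"),
                           dose = c("0Gy", "5Gy", "20Gy"),
                           rep = 1:4)
  df$y <- rnorm(nrow(df), mean = as.integer(factor(df$coat)) +
                  0.5 * as.integer(factor(df$dose)))
  fam <- two_way_anova_tukey(df, y, coat, dose, tukey_on = "a")
  ref <- summary(stats::aov(y ~ coat * dose, df))[[1]]
  expect_equal(fam$omnibus$sumsq, unname(ref[, "Sum Sq"]), tolerance = 1e-9)
  expect_equal(fam$omnibus$statistic[1:3], unname(ref[1:3, "F value"]),
               tolerance = 1e-9)
  expect_equal(fam$omnibus$p.value[1:3], unname(ref[1:3, "Pr(>F)"]),
               tolerance = 1e-9)
})

test_that("two-way Tukey marginal comparisons match emmeans", {
  skip_if_not_installed("emmeans")
  set.seed(43)
  df <- tidyr::expand_grid(coat = c("none", "laminin", "fibronectin"),
                           dose = c("lo", "hi"), rep = 1:3)
  df$y <- rnorm(nrow(df), mean = 2 * (df$coat == "laminin"))
  fam <- two_way_anova_tukey(df, y, coat, dose, tukey_on = "a")
  em <- emmeans::emmeans(stats::lm(y ~ coat * dose, df), "coat")
  ref <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = "tukey"))
  cmp <- generics::tidy(fam)
  # emmeans orders pairs as level1 - level2 of the factor's sorted levels
  expect_equal(sort(abs(cmp$estimate)), sort(abs(ref$estimate)), tolerance = 1e-9)
  expect_equal(sort(cmp$adj.p.value), sort(ref$p.value), tolerance = 1e-6)
})

test_that("two-way design validation: empty cells and missing replicates", {
  df <- tidyr::expand_grid(a = c("x", "y"), b = c("u", "v"), rep = 1:2)
  df$y <- rnorm(8)
  expect_error(two_way_anova_tukey(df[df$a != "x" | df$b != "u", ], y, a, b),
               "Empty design cell")
  df1 <- tidyr::expand_grid(a = c("x", "y"), b = c("u", "v"))
  df1$y <- rnorm(4)
  expect_error(two_way_anova_tukey(df1, y, a, b), "replicates")
  dfu <- rbind(df, df[1, ])
  expect_warning(two_way_anova_tukey(dfu, y, a, b), "[Uu]nbalanced")
})

test_that("significance tiers use strict boundaries", {
  expect_equal(significance_tiers(c(0.049, 0.05, 0.009, 0.01, 0.00009, 1e-4, NA)),
               c("*", "ns", "**", "*", "****", "***", NA))
})
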