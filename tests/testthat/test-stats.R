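test_that("identical groups give t = 0, p = 1", {
  r <- two_group_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_identical(r$stars, "")
})

test_that("the pooled-variance t matches the textbook example", {
  r <- two_group_ttest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$statistic, -sqrt(3 / 2), tolerance = 1e-10)  # -1.2247
  expect_equal(r$df, 4)
  expect_equal(r$p_value, 0.2878641, tolerance = 1e-6)
})

test_that("summary-statistic and raw-data paths agree to 1e-10", {
  set.seed(99)
  for (i in 1:10) {
    a <- rnorm(sample(3:9, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:9, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    for (v in c("student", "welch")) {
      raw <- suppressMessages(two_group_ttest(a, b, variant = v))
      summ <- suppressMessages(two_group_ttest(
        group_summary(length(a), mean(a), sd(a)),
        group_summary(length(b), mean(b), sd(b)), variant = v))
      expect_equal(raw$statistic, summ$statistic, tolerance = 1e-10)
      expect_equal(raw$df, summ$df, tolerance = 1e-10)
      expect_equal(raw$p_value, summ$p_value, tolerance = 1e-10)
    }
  }
})

test_that("published IgG summaries reproduce the reported significance", {
  # 23.7 ± 6.5 % vs 6.0 ± 2.7 %, n = 8 per arm
  r <- suppressMessages(two_group_ttest(group_summary(8, 23.7, 6.5),
                                        group_summary(8, 6.0, 2.7),
                                        variant = "welch"))
  expect_lt(r$p_value, 1e-4)
  expect_identical(r$stars, "***")
  expect_error(two_group_ttest(group_summary(1, 1, 1),
                               group_summary(3, 1, 1)), ">= 2")
  expect_error(two_group_ttest(c(1), c(1, 2)), "at least 2")
})

test_that("significance stars follow the threshold convention", {
  expect_identical(stars(c(0.04, 0.5, 0.0005, 0.009)),
                   c("*", "", "***", "**"))
  expect_identical(stars(0.05), "")   # strict inequality
  expect_error(stars(-0.1), "\\[0, 1\\]")
  expect_error(stars(1.2), "\\[0, 1\\]")
})

test_that("two-way ANOVA matches a hand-computed sums-of-squares oracle", {
  # balanced 2x2 with 3 replicates per cell
  set.seed(5)
  df <- expand.grid(rep = 1:3, tr = c("T", "C"), cp = c("lumen", "shell"))
  cell_means <- c("T.lumen" = 10, "C.lumen" = 6, "T.shell" = 3,
                  "C.shell" = 2)
  df$v <- cell_means[paste(df$tr, df$cp, sep = ".")] + rnorm(12, 0, 0.8)

  # explicit decomposition
  gm <- mean(df$v)
  ss <- function(x) sum(x^2)
  m_tr <- tapply(df$v, df$tr, mean)
  m_cp <- tapply(df$v, df$cp, mean)
  m_cell <- tapply(df$v, paste(df$tr, df$cp), mean)
  ss_tr <- 6 * ss(m_tr - gm)
  ss_cp <- 6 * ss(m_cp - gm)
  ss_cell <- 3 * ss(m_cell - gm)
  ss_int <- ss_cell - ss_tr - ss_cp
  ss_res <- ss(df$v - m_cell[paste(df$tr, df$cp)])

  a <- two_way_anova_bonferroni(df, v, tr, cp)
  an <- a$anova
  expect_equal(an$sumsq[an$term == "treatment"], ss_tr, tolerance = 1e-10)
  expect_equal(an$sumsq[an$term == "compartment"], ss_cp, tolerance = 1e-10)
  expect_equal(an$sumsq[an$term == "interaction"], ss_int, tolerance = 1e-10)
  expect_equal(an$sumsq[an$term == "Residuals"], ss_res, tolerance = 1e-10)
  f_tr <- (ss_tr / 1) / (ss_res / 8)
  expect_equal(an$statistic[an$term == "treatment"], f_tr, tolerance = 1e-10)

  # per-compartment comparisons from the pooled residual variance
  cmp <- a$comparisons
  expect_equal(nrow(cmp), 2)
  mse <- ss_res / 8
  t_lumen <- (m_cell[["C lumen"]] - m_cell[["T lumen"]]) /
    sqrt(mse * (2 / 3))
  expect_equal(abs(cmp$statistic[cmp$compartment == "lumen"]),
               abs(t_lumen), tolerance = 1e-10)
  expect_equal(cmp$adjusted_p, pmin(1, 2 * cmp$p_value))
  expect_true(all(cmp$adjusted_p >= cmp$p_value))
})

test_that("a null design gives no significant adjusted comparisons", {
  set.seed(1)
  df <- expand.grid(rep = 1:4, tr = c("T", "C"),
                    cp = c("c1", "c2", "c3", "c4"))
  df$v <- rnorm(nrow(df))
  a <- two_way_anova_bonferroni(df, v, tr, cp)
  expect_true(all(a$comparisons$adjusted_p > 0.05))
  expect_equal(a$n_comparisons, 4)
})

test_that("degenerate ANOVA inputs are rejected with informative errors", {
  df <- expand.grid(rep = 1:3, tr = c("T", "C"), cp = c("c1", "c2"))
  df$v <- rnorm(nrow(df))
  expect_error(two_way_anova_bonferroni(df[df$tr == "T", ], v, tr, cp),
               "2 levels")
  df2 <- df[!(df$tr == "C" & df$cp == "c2"), ]
  expect_error(two_way_anova_bonferroni(df2, v, tr, cp), "empty cell")
  df3 <- df[-1, ]  # one cell down to 2 replicates: unbalanced but valid
  expect_no_error(two_way_anova_bonferroni(df3, v, tr, cp))
  df4 <- df[!(df$tr == "T" & df$cp == "c1" & df$rep > 1), ]
  expect_error(two_way_anova_bonferroni(df4, v, tr, cp), "2 replicates")
})

test_that("unbalanced designs use Type II sums of squares and stay valid", {
  set.seed(3)
  df <- expand.grid(rep = 1:4, tr = c("T", "C"), cp = c("c1", "c2"))
  df$v <- rnorm(nrow(df)) + ifelse(df$tr == "T", 2, 0)
  df <- df[-c(1, 9), ]  # unbalance two cells
  a <- two_way_anova_bonferroni(df, v, tr, cp)
  expect_false(a$balanced)
  expect_true(all(a$anova$p_value >= 0 & a$anova$p_value <= 1, na.rm = TRUE))
  expect_lt(a$anova$p_value[a$anova$term == "treatment"], 0.05)
  g <- glance(a)
  expect_true(all(c("f_treatment", "p_interaction", "df_residual") %in%
                    names(g)))
  expect_s3_class(tidy(a), "tbl_df")
})
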