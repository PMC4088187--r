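make_table <- function(n = 26, seed = 1) {
  set.seed(seed)
  data.frame(value = rnorm(n),
             group = rep(c("A", "B"), length.out = n),
             age = sample(20:60, n, replace = TRUE),
             gender = sample(c("F", "M"), n, replace = TRUE),
             n_trials = sample(10:24, n, replace = TRUE))
}

test_that("stepwise regression selects a perfect predictor with r^2 = 1", {
  tab <- make_table(26, seed = 30)
  tab$value <- as.numeric(tab$group == "B")
  res <- suppressWarnings(stepwise_regression(tab))  # perfect fit warns
  expect_equal(res$selected, "group")
  expect_equal(res$r_squared, 1, tolerance = 1e-10)
})

test_that("single-candidate stepwise reduces to simple regression", {
  tab <- make_table(26, seed = 31)
  tab$value <- 0.8 * tab$age + rnorm(26, sd = 4)
  res <- stepwise_regression(tab, predictors = "age")
  fit <- lm(value ~ age, tab)
  expect_equal(unname(res$coefficients["age"]), unname(coef(fit)["age"]),
               tolerance = 1e-10)
  expect_equal(unname(res$p_values["age"]),
               summary(fit)$coefficients["age", 4], tolerance = 1e-10)
  expect_equal(res$r_squared, summary(fit)$r.squared, tolerance = 1e-10)
})

test_that("r^2 is invariant to affine rescaling of the criterion", {
  tab <- make_table(26, seed = 32)
  tab$value <- as.numeric(tab$group == "B") + rnorm(26, sd = 0.7)
  r1 <- stepwise_regression(tab)
  tab2 <- tab; tab2$value <- 3.2 * tab$value - 11
  r2 <- stepwise_regression(tab2)
  expect_equal(r1$selected, r2$selected)
  expect_equal(r1$r_squared, r2$r_squared, tolerance = 1e-10)
})

test_that("stepwise inclusion stays near the entry level under the null", {
  # quick calibration at 200 reps; the full 1000-rep check runs in the
  # acceptance suite
  set.seed(33)
  hits <- 0
  for (r in 1:200) {
    tab <- make_table(26, seed = 3300 + r)
    res <- stepwise_regression(tab)
    hits <- hits + ("group" %in% res$selected)
  }
  expect_gte(hits / 200, 0.005)
  expect_lte(hits / 200, 0.10)
})

test_that("a 1-SD group effect is usually detected", {
  set.seed(34)
  found <- 0
  for (r in 1:200) {
    tab <- make_table(26, seed = 3400 + r)
    tab$value <- tab$value + as.numeric(tab$group == "B")
    found <- found + ("group" %in% stepwise_regression(tab)$selected)
  }
  expect_gte(found / 200, 0.6)
})

test_that("KS normality check behaves as a conservative gate", {
  # exact normal quantiles: near-perfect fit
  q <- qnorm(ppoints(100))
  expect_gt(ks_normality(q), 0.95)
  # strongly bimodal sample rejected
  set.seed(35)
  bim <- c(rnorm(50, -5), rnorm(50, 5))
  expect_lt(ks_normality(bim), 0.01)
  # standardisation makes the plain KS reference conservative, so the
  # null rejection rate must not exceed nominal + 2 points
  rej <- 0
  for (r in 1:200) {
    set.seed(3500 + r)
    rej <- rej + (ks_normality(rnorm(200)) < 0.05)
  }
  expect_lte(rej / 200, 0.07)
  expect_error(ks_normality(c(1, 2)), "n >= 3")
  expect_error(ks_normality(rep(1, 10)), "zero variance")
})

test_that("pooled t-test matches the longhand formula and is symmetric", {
  expect_error(posthoc_ttest(rep(1, 4), rep(1, 4)), "pooled variance")
  a <- c(0, 0, 0, 0) + c(0.001, -0.001, 0.0005, 0)
  b <- c(1, 1, 1, 1) + c(-0.0002, 0.0007, 0, 0.0001)
  res <- posthoc_ttest(a, b)
  expect_lt(res$p, 1e-4)
  expect_equal(res$direction, "B>A")

  set.seed(36)
  x <- rnorm(9); y <- rnorm(12, 0.4)
  got <- posthoc_ttest(x, y)
  sp2 <- ((8) * var(x) + (11) * var(y)) / 19
  t_oracle <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 9 + 1 / 12))
  expect_equal(got$t, t_oracle, tolerance = 1e-10)
  expect_equal(got$p, 2 * pt(-abs(t_oracle), 19), tolerance = 1e-10)
  rev <- posthoc_ttest(y, x)
  expect_equal(rev$p, got$p, tolerance = 1e-12)
  expect_equal(rev$t, -got$t, tolerance = 1e-12)
})

test_that("feature-table regressions produce one row per cell with gated post-hocs", {
  set.seed(37)
  ids <- sprintf("P%02d", 1:20)
  grid <- expand.grid(participant = ids, condition = c("hand", "feet"),
                      band = c("alpha", "mid_beta"),
                      segment = c("0-2", "4-6"), stringsAsFactors = FALSE)
  grid$group <- ifelse(grid$participant %in% ids[1:10], "A", "B")
  grid$age <- rep(sample(20:50, 20, TRUE), times = nrow(grid) / 20)
  grid$gender <- rep(sample(c("F", "M"), 20, TRUE),
                     times = nrow(grid) / 20)
  grid$n_trials <- 16
  grid$feature <- "bandpower"
  grid$value <- rnorm(nrow(grid))
  # plant a clean group effect in one cell only
  pick <- grid$band == "alpha" & grid$segment == "4-6" &
    grid$condition == "hand"
  grid$value[pick] <- grid$value[pick] - 3 * (grid$group[pick] == "A")
  rep_tab <- run_feature_regressions(grid)
  expect_equal(nrow(rep_tab), 2 * 2 * 2)   # condition x band x segment
  cell <- rep_tab[rep_tab$band == "alpha" & rep_tab$segment == "4-6" &
                    rep_tab$condition == "hand", ]
  expect_match(cell$selected, "group")
  expect_lt(cell$ttest_p, 0.01)
  expect_equal(cell$direction, "B>A")
  expect_true(all(rep_tab$p_uncorrected))
})
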