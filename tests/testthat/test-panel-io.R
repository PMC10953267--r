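# Ingestion, scoring, reliability and residualization.

test_that("read_panel accepts well-formed input and flags bad cells", {
  path <- write_toy_csv(toy_rows(3))
  pd <- read_panel(path, toy_scales())
  expect_s3_class(pd, "panel_dataset")
  expect_equal(nrow(pd$data), 3)
  expect_identical(pd$n_warnings, 0L)

  rows <- toy_rows(3)
  rows$mood_i1_t1[2] <- 9          # out of the 1-5 range
  rows$worry_i2_t2[3] <- "oops"    # unparseable
  expect_warning(pd <- read_panel(write_toy_csv(rows), toy_scales()),
                 "2 item response")
  expect_identical(pd$n_warnings, 2L)
  expect_true(is.na(pd$data$mood_i1_t1[2]))
  expect_true(is.na(pd$data$worry_i2_t2[3]))
})

test_that("read_panel rejects duplicates and missing mandatory columns", {
  rows <- toy_rows(3)
  rows$participant_id <- c(7, 7, 9)
  expect_error(read_panel(write_toy_csv(rows), toy_scales()),
               "7", class = "panelnet_data_error")

  rows <- toy_rows(3)
  rows$mood_i2_t2 <- NULL
  expect_error(read_panel(write_toy_csv(rows), toy_scales()),
               "mood_i2_t2", class = "panelnet_config_error")
})

test_that("scale scoring averages keyed items with the 75% rule", {
  rows <- toy_rows(4)
  for (cl in paste0("mood_i", 1:3, "_t1")) rows[[cl]] <- 4
  rows$mood_i3_t1 <- 2                       # reverse-keyed: contributes 1+5-2 = 4
  rows$worry_i1_t1[1] <- NA                  # 1 of 2 answered: 50% < 75%
  pd <- score_scales(read_panel(write_toy_csv(rows), toy_scales()))
  expect_equal(pd$data$mood_t1, rep(4, 4))   # all contributions equal 4
  expect_true(is.na(pd$data$worry_t1[1]))
  expect_false(anyNA(pd$data$worry_t1[-1]))

  # a 6-item scale with 4 answered stays missing (4/6 < 0.75)
  defs <- list(big = scale_definition("big", "parenting",
                                      paste0("big_i", 1:6), c(1, 5)))
  df <- data.frame(participant_id = 1)
  for (cl in paste0("big_i", 1:6, "_t1")) df[[cl]] <- 3
  for (cl in paste0("big_i", 1:6, "_t2")) df[[cl]] <- 3
  df$big_i1_t1 <- NA; df$big_i2_t1 <- NA
  pd2 <- score_scales(read_panel(write_toy_csv(df), defs))
  expect_true(is.na(pd2$data$big_t1))
  expect_equal(pd2$data$big_t2, 3)
})

test_that("reverse keying is an involution", {
  d <- toy_scales()$mood
  set.seed(1)
  m <- matrix(as.numeric(sample(1:5, 60, TRUE)), 20, 3)
  expect_identical(panelnet:::reverse_key(panelnet:::reverse_key(m, d), d), m)
})

test_that("cronbach_alpha matches its closed-form oracles", {
  set.seed(42)
  x <- rnorm(200)
  expect_equal(cronbach_alpha(cbind(x, x, x)), 1.0)

  # equi-correlated items: alpha converges to the Spearman-Brown value
  # k*rho / (1 + (k-1)*rho)
  n <- 100000; k <- 5; rho <- 0.3
  f <- rnorm(n)
  items <- sqrt(rho) * f + sqrt(1 - rho) * matrix(rnorm(n * k), n, k)
  expect_equal(cronbach_alpha(items), k * rho / (1 + (k - 1) * rho),
               tolerance = 0.01)

  # independent items share no variance
  expect_equal(cronbach_alpha(matrix(rnorm(n * k), n, k)), 0, tolerance = 0.02)
})

test_that("cronbach_alpha is invariant to item shifts and relabeling", {
  set.seed(7)
  m <- matrix(rnorm(300), 100, 3)
  a <- cronbach_alpha(m)
  expect_equal(cronbach_alpha(sweep(m, 2, c(10, -3, 0.5), "+")), a)
  expect_equal(cronbach_alpha(m[, c(3, 1, 2)]), a)
  expect_error(cronbach_alpha(matrix(1, 10, 3)),
               class = "panelnet_estimation_error")
  expect_error(cronbach_alpha(m[, 1, drop = FALSE]),
               class = "panelnet_config_error")
})

test_that("descriptives follow the reporting conventions", {
  pd <- pd_from_scores(c(-1, -1, 1, 1), c(2, 2, 2, 2))
  d <- descriptives(pd)
  expect_equal(d$skewness[d$wave == "t1"], 0)
  # constant wave: sd zero, shape statistics undefined
  expect_equal(d$sd[d$wave == "t2"], 0)
  expect_true(is.na(d$skewness[d$wave == "t2"]))
  expect_true(is.na(d$kurtosis[d$wave == "t2"]))

  set.seed(11)
  x <- rnorm(100000)
  pd2 <- pd_from_scores(x, x)
  d2 <- descriptives(pd2)
  expect_equal(d2$skewness[1], 0, tolerance = 0.05)
  expect_equal(d2$kurtosis[1], 0, tolerance = 0.05)

  # row order is irrelevant
  perm <- sample(length(x))
  d3 <- descriptives(pd_from_scores(x[perm], x[perm]))
  expect_equal(d3$mean, d2$mean)
  expect_equal(d3$skewness, d2$skewness)
  expect_equal(d3$alpha, d2$alpha)
})

test_that("reliability screen drops a scale only when weak at both waves", {
  descr <- data.frame(
    scale = rep(c("discipline", "harshness", "edge"), each = 2),
    wave = rep(c("t1", "t2"), 3),
    alpha = c(0.50, 0.54, 0.59, 0.67, 0.60, 0.60)
  )
  kept <- drop_unreliable(descr, 0.60)
  expect_setequal(kept, c("harshness", "edge"))
  expect_identical(attr(kept, "dropped"), "discipline")
})

test_that("attrition summary reproduces the printed arithmetic", {
  expect_equal(cohort_summary(642, 591)$attrition_pct, 7.9)
  expect_equal(cohort_summary(100, 100)$attrition_pct, 0)
  expect_equal(cohort_summary(200, 150)$attrition_pct, 25.0)
  expect_error(cohort_summary(100, 120), class = "panelnet_data_error")
})

test_that("residualization removes covariate signal exactly", {
  set.seed(5)
  n <- 300
  age <- runif(n, 8, 17)
  gender <- sample(c("f", "m"), n, TRUE)
  y <- 2 * age + rnorm(n)
  z <- rnorm(n)  # unrelated score
  res <- residualize(cbind(y = y, z = z),
                     data.frame(age = age, gender = gender))
  expect_lt(max(abs(colMeans(res))), 1e-8)
  expect_lt(abs(cor(res[, "y"], age)), 1e-10)
  # regressing residuals on the same covariates returns nothing
  refit <- lm(res[, "y"] ~ age + gender)
  expect_lt(max(abs(coef(refit))), 1e-8)
})

test_that("degenerate covariates are dropped, not fatal", {
  set.seed(6)
  y <- rnorm(50)
  expect_warning(
    res <- residualize(cbind(y = y), data.frame(k = rep(2, 50))),
    "degenerate")
  expect_equal(as.numeric(res[, "y"]), y - mean(y))

  # collinear pair: one of the two is dropped, fit unaffected
  x <- rnorm(50)
  expect_warning(
    res2 <- residualize(cbind(y = y), data.frame(a = x, b = 2 * x)),
    "degenerate")
  expect_lt(abs(cor(res2[, "y"], x)), 1e-10)
})
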