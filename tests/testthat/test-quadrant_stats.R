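test_that("summary statistics use the n-1 denominator and a consistent SEM", {
  s <- summary_stats(c(2, 2, 2, 2))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 0)
  s <- summary_stats(1:5)
  expect_equal(s$mean, 3)
  expect_equal(s$sd, sqrt(2.5))
  expect_equal(s$sem, s$sd / sqrt(5))
  expect_error(summary_stats(3), "at least 2")
  expect_error(as_summary_stats(1, -1, 10), "non-negative")
})

test_that("two-sample t from raw values matches stats::t.test", {
  set.seed(101)
  for (i in 1:20) {
    x <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    w <- t_independent(x, y, "welch")
    ref_w <- t.test(x, y)
    expect_equal(w$t, unname(ref_w$statistic), tolerance = 1e-12)
    expect_equal(w$df, unname(ref_w$parameter), tolerance = 1e-12)
    expect_equal(w$p, ref_w$p.value, tolerance = 1e-12)
    p <- t_independent(x, y, "pooled")
    ref_p <- t.test(x, y, var.equal = TRUE)
    expect_equal(p$t, unname(ref_p$statistic), tolerance = 1e-12)
    expect_equal(p$p, ref_p$p.value, tolerance = 1e-12)
  }
})

test_that("raw-value and summary-statistic t routes coincide", {
  set.seed(101)
  for (i in 1:10) {
    x <- rnorm(30); y <- rnorm(25, 0.5)
    for (m in c("welch", "pooled")) {
      a <- t_independent(x, y, m)
      b <- t_from_summary(summary_stats(x), summary_stats(y), m)
      expect_lt(abs(a$t - b$t), 1e-9)
      expect_lt(abs(a$p - b$p), 1e-9)
    }
  }
  # hand-computed pooled case
  tt <- t_independent(c(1, 2, 3), c(4, 5, 6), "pooled")
  expect_equal(tt$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(round(abs(tt$t), 3), 3.674)
})

test_that("equal group sizes make pooled and Welch t identical", {
  a <- as_summary_stats(5.2, 2.1, 40)
  b <- as_summary_stats(4.1, 3.3, 40)
  expect_equal(t_from_summary(a, b, "welch")$t,
               t_from_summary(a, b, "pooled")$t, tolerance = 1e-12)
})

test_that("degenerate and identical inputs behave as documented", {
  x <- c(1, 2, 3, 4)
  expect_equal(t_independent(x, x)$t, 0)
  expect_error(t_from_summary(as_summary_stats(2, 0, 5),
                              as_summary_stats(2, 0, 5)),
               "undefined")
  # zero variance, different means: infinite t, p = 0
  inf <- t_from_summary(as_summary_stats(3, 0, 5), as_summary_stats(1, 0, 5))
  expect_true(is.infinite(inf$t) && inf$p == 0)
})

test_that("one-way ANOVA matches the sum-of-squares oracle and oneway.test", {
  gs <- list(c(1, 2, 3), c(1, 2, 3), c(7, 8, 9))
  a <- anova_oneway(gs)
  expect_equal(a$f, oracle_anova_f(gs), tolerance = 1e-12)
  expect_equal(a$f, 36)
  expect_equal(a$df_between, 2L)
  expect_equal(a$df_within, 6L)

  set.seed(101)
  gs <- lapply(1:4, function(i) rnorm(sample(5:20, 1), mean = i / 2))
  a <- anova_oneway(gs)
  expect_equal(a$f, oracle_anova_f(gs), tolerance = 1e-9)

  # fully degenerate: all values identical
  d <- anova_oneway(list(c(2, 2), c(2, 2), c(2, 2, 2)))
  expect_equal(d$f, 0)
  expect_equal(d$p, 1)

  expect_error(anova_oneway(list(1:3)), "at least 2 groups")
  expect_error(anova_oneway(list(1:3, 5)), "at least 2 values")
})

test_that("two-group ANOVA F equals the squared pooled t", {
  set.seed(101)
  x <- rnorm(15, 1); y <- rnorm(22, 2)
  f <- anova_oneway(list(x, y))$f
  t2 <- t_independent(x, y, "pooled")$t^2
  expect_lt(abs(f - t2), 1e-9)
})

test_that("cohort report has the full grade x quadrant shape", {
  set.seed(101)
  spec <- cohort_spec("messidor", n = c(Mild = 8, Moderate = 8, Severe = 8),
                      seed = 101)
  co <- simulate_cohort(spec)
  counts <- cohort_counts(co)
  rep <- build_report(counts, data.frame(image_id = co$strata$image_id,
                                         grade = co$strata$grade),
                      database = "messidor")
  expect_s3_class(rep, "cohort_report")
  expect_equal(nrow(rep$summary), 2 * 3 * 4)        # lesion x grade x quadrant
  expect_equal(nrow(rep$pairwise_t), 2 * 3 * 3)     # reference vs 3 others
  expect_equal(nrow(rep$anova_by_grade), 2 * 3)
  expect_equal(nrow(rep$anova_by_quadrant), 2 * 4)
  expect_true(all(rep$summary$n == 8))
  expect_true(all(grepl("^temporal vs ", rep$pairwise_t$comparison)))
})

test_that("a cohort of identical images gives all-zero F and t", {
  fr <- test_frame("right")
  # one MA and one HEM in each quadrant, identically on every image
  d1 <- 2000 / 9; d2 <- 3000 / 9
  marks1 <- data.frame(
    lesion_type = rep(c("MA", "HEM"), each = 4),
    x_px = fr$fovea_x + c(d1, -d1, 0, 0, d2, -d2, 0, 0),
    y_px = fr$fovea_y + c(0, 0, d1, -d1, 0, 0, d2, -d2))
  counts <- do.call(rbind, lapply(sprintf("i%02d", 1:6), function(id) {
    fr_i <- fundus_frame(fr$width_px, fr$height_px, fr$fovea_x, fr$fovea_y,
                         fr$disc_x, fr$disc_y, image_id = id)
    count_by_region(marks1, fr_i)
  }))
  grades <- data.frame(image_id = sprintf("i%02d", 1:6), grade = "Mild")
  rep <- build_report(counts, grades)
  expect_true(all(rep$anova_by_grade$f == 0))
  expect_true(all(rep$anova_by_grade$p == 1))
  expect_true(all(rep$pairwise_t$t == 0))
})

test_that("missing grade cells appear as explicit absences, not zeros", {
  fr <- test_frame("right")
  counts <- count_by_region(data.frame(lesion_type = "MA",
                                       x_px = fr$fovea_x + 300,
                                       y_px = fr$fovea_y), fr)
  counts <- rbind(counts, counts)
  counts$image_id <- rep(c("a", "b"), each = 6)
  grades <- data.frame(image_id = c("a", "b"), grade = c("Mild", "Mild"))
  grades$grade <- factor(grades$grade, levels = c("Mild", "Severe"))
  rep <- build_report(counts, grades)
  absent <- rep$summary[rep$summary$grade == "Severe", ]
  expect_true(all(absent$n == 0))
  expect_true(all(is.na(absent$mean)))
})

test_that("summaries of calibrated draws recover the generating mean", {
  set.seed(101)
  s <- summary_stats(sample_count(261, 5.50, 6.52))
  expect_lt(abs(s$mean - 5.50), 3 * 6.52 / sqrt(261))
})
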