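test_that("paired comparison matches the textbook t statistic", {
  x <- c(10, 11, 12); y <- x - c(1, 2, 3)  # differences {1,2,3}
  r <- paired_comparison(x, y)
  expect_equal(r$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(r$statistic, 3.464, tolerance = 1e-3)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, 0.074, tolerance = 1e-2)
  same <- paired_comparison(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(paired_comparison(1, 2), "at least 2")
  expect_error(paired_comparison(1:3, 1:4), "equal length")
})

test_that("unpaired comparison uses the pooled-variance formula", {
  r <- unpaired_comparison(c(1, 2, 3), c(3, 4, 5))
  expect_equal(r$statistic, -2.449, tolerance = 1e-3)
  expect_equal(r$df, 4)
  same <- unpaired_comparison(c(2, 2), c(2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(unpaired_comparison(1, c(1, 2)), "at least 2")
})

make_rm_design <- function(n_per_group, n_time, seed, effect = 0.5) {
  withr::with_seed(seed, {
    subj <- paste0("s", seq_len(sum(n_per_group)))
    grp <- rep(paste0("g", seq_along(n_per_group)), n_per_group)
    tidyr::expand_grid(subject = subj, time = paste0("t", seq_len(n_time))) |>
      dplyr::left_join(tibble::tibble(subject = subj, group = grp),
                       by = "subject") |>
      dplyr::mutate(value = rnorm(dplyr::n()) +
                      effect * as.numeric(factor(group)) +
                      0.3 * as.numeric(factor(time)))
  })
}

test_that("repeated-measures ANOVA matches the aov sums-of-squares oracle", {
  for (s in 1:20) {
    dims <- withr::with_seed(1000 + s,
                             list(n = sample(3:8, 1), t = sample(3:6, 1)))
    df <- make_rm_design(c(dims$n, dims$n), dims$t, seed = s)
    mine <- rm_anova_two_way(df)
    or <- summary(stats::aov(value ~ group * time + Error(subject), data = df))
    f_oracle <- c(or[["Error: subject"]][[1]]$`F value`[1],
                  or[["Error: Within"]][[1]]$`F value`[1:2])
    f_mine <- mine$table$f[match(c("group", "time", "group_time"),
                                 mine$table$term)]
    expect_equal(f_mine, f_oracle, tolerance = 1e-8)
  }
})

test_that("RM ANOVA partitions sums of squares exactly and nulls vanish", {
  df <- make_rm_design(c(4, 4), 5, seed = 9)
  a <- rm_anova_two_way(df)
  grand <- mean(df$value)
  expect_equal(sum(a$table$ss), sum((df$value - grand)^2), tolerance = 1e-10)
  # zero treatment difference with a time trend: F_group = 0 exactly
  # (subject offsets mirrored across groups so group means coincide)
  offsets <- c(-1, 0, 2, 5)
  null_df <- df |>
    dplyr::mutate(value = as.numeric(factor(time)) +
                    offsets[(as.integer(factor(subject)) - 1) %% 4 + 1])
  a0 <- rm_anova_two_way(null_df)
  expect_equal(a0$table$f[a0$table$term == "group"], 0, tolerance = 1e-12)
  expect_error(rm_anova_two_way(df[-1, ]), "balanced")
})

test_that("assumption screening runs Shapiro-Wilk and Bartlett", {
  x <- withr::with_seed(2, rnorm(10))
  # force exact sample variances 1 and 4
  a <- (x - mean(x)) / sd(x)
  b <- 2 * a + 10
  scr <- assumption_screen(list(a = a, b = b))
  # closed-form Bartlett statistic for variances {1, 4}, n = 10 each
  n <- 10; k <- 2
  sp2 <- (9 * 1 + 9 * 4) / 18
  stat <- ((2 * n - k) * log(sp2) - 9 * (log(1) + log(4))) /
    (1 + (2 / 9 - 1 / 18) / (3 * (k - 1)))
  expect_equal(scr$variance$statistic, stat, tolerance = 1e-9)
  # identical variances give a zero statistic and p = 1
  scr0 <- assumption_screen(list(a = a, b = a + 5))
  expect_equal(scr0$variance$statistic, 0, tolerance = 1e-12)
  expect_equal(scr0$variance$p_value, 1)
  expect_error(assumption_screen(list(a = 1:2)), "n >= 3")
})

test_that("percent change reproduces printed worked examples", {
  expect_equal(round(percent_change(19.5, 13.8)), 41)
  expect_equal(round(percent_change(0.31, 0.28)), 11)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(1, 0), "non-zero")
  # antisymmetry up to scale
  for (p in list(c(19.5, 13.8), c(0.31, 0.28), c(2, 8))) {
    fwd <- percent_change(p[1], p[2]); rev <- percent_change(p[2], p[1])
    expect_equal(fwd, -100 * rev / (100 + rev), tolerance = 1e-9)
  }
})

test_that("paired t equals one-sample t of differences against zero", {
  x <- withr::with_seed(4, rnorm(12, 1)); y <- withr::with_seed(5, rnorm(12))
  r <- paired_comparison(x, y)
  one <- stats::t.test(x - y)
  expect_equal(r$statistic, unname(one$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, one$p.value, tolerance = 1e-12)
})

test_that("attrition shares reproduce the printed accounting", {
  a <- attrition_summary(81, 40, c(hyphema = 29, suture_failure = 12))
  expect_equal(round(a$share_rounded[a$cause == "hyphema"]), 71)
  expect_equal(round(a$share_rounded[a$cause == "suture_failure"]), 29)
  expect_equal(attr(a, "success_percent"), 100 * 40 / 81)
  clean <- attrition_summary(10, 10)
  expect_equal(attr(clean, "success_percent"), 100)
  expect_equal(nrow(clean), 0)
  expect_error(attrition_summary(81, 40, c(hyphema = 5)), "Inconsistent")
})
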