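test_that("ICC(2,1) matches the independent ANOVA oracle", {
  d <- tibble::tibble(a = c(4, 5, 7, 9), b = c(4, 6, 8, 9))
  fit <- icc21(d, a, b)
  expect_equal(fit$icc, oracle_icc21(d$a, d$b), tolerance = 1e-10)
  expect_equal(fit$icc, 0.95, tolerance = 1e-10)
  # interval cross-checked against an independent implementation of the
  # absolute-agreement ICC (two decimal places of its published rounding)
  expect_equal(round(fit$ci95_low, 2), 0.49)
  expect_equal(fit$category, "excellent")

  for (seed in 1:40) {
    tab <- random_count_table(seed)
    fit <- icc21(tab, a, b)
    expect_equal(fit$icc, oracle_icc21(tab$a, tab$b), tolerance = 1e-10,
                 label = sprintf("seed %d", seed))
    expect_true(fit$ci95_low <= fit$icc && fit$icc <= fit$ci95_high)
  }
})

test_that("identical non-constant vectors give ICC exactly 1", {
  d <- tibble::tibble(a = c(3, 8, 5, 11), b = c(3, 8, 5, 11))
  fit <- icc21(d, a, b)
  expect_equal(fit$icc, 1)
  expect_equal(fit$ci95_low, 1)
})

test_that("ICC is invariant to shifting both sources and to swapping them", {
  tab <- random_count_table(99)
  base <- icc21(tab, a, b)$icc
  shifted <- icc21(dplyr::mutate(tab, a = a + 7, b = b + 7), a, b)$icc
  swapped <- icc21(tab, b, a)$icc
  expect_equal(shifted, base, tolerance = 1e-12)
  expect_equal(swapped, base, tolerance = 1e-12)
})

test_that("ICC recovers the theoretical value of the generating model", {
  set.seed(2024)
  n <- 1000
  sigma_p <- 3; sigma_r <- 0.5; sigma_e <- 1
  theo <- sigma_p^2 / (sigma_p^2 + sigma_r^2 + sigma_e^2)
  p <- rnorm(n, 0, sigma_p)
  r <- rnorm(2, 0, sigma_r)
  y <- tibble::tibble(a = 10 + p + r[1] + rnorm(n, 0, sigma_e),
                      b = 10 + p + r[2] + rnorm(n, 0, sigma_e))
  fit <- icc21(y, a, b)
  expect_lt(abs(fit$icc - theo), 0.05)
})

test_that("ICC input contracts are enforced and categories follow Fleiss", {
  expect_error(icc21(tibble::tibble(a = 1:2, b = 2:3), a, b),
               class = "fms_insufficient_data_error")
  expect_error(icc21(tibble::tibble(a = rep(4, 5), b = rep(4, 5)), a, b),
               class = "fms_degenerate_data_error")
  expect_equal(icc_category(0.84), "excellent")
  expect_equal(icc_category(0.75), "excellent")
  expect_equal(icc_category(0.69), "moderate")
  expect_equal(icc_category(0.40), "moderate")
  expect_equal(icc_category(0.39), "poor")
})

test_that("percentage agreement follows the min/max definition", {
  expect_equal(percentage_agreement(tibble::tibble(a = c(5, 9), b = c(5, 9)),
                                    a, b), 100)
  expect_equal(percentage_agreement(tibble::tibble(a = 20, b = 10), a, b), 50)
  expect_equal(percentage_agreement(tibble::tibble(a = c(0, 10), b = c(0, 8)),
                                    a, b), 90)
  expect_error(percentage_agreement(tibble::tibble(a = -1, b = 2), a, b),
               class = "fms_validation_error")
  # bounded in [0, 100]; 100 only for identical vectors
  for (seed in 1:20) {
    tab <- random_count_table(seed + 500)
    p <- percentage_agreement(tab, a, b)
    expect_true(p >= 0 && p <= 100)
    expect_equal(p == 100, all(tab$a == tab$b))
  }
})

test_that("Bland-Altman limits follow the 1.96-SD construction", {
  same <- tibble::tibble(a = c(4, 7, 9), b = c(4, 7, 9))
  ba0 <- bland_altman(same, a, b)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))

  d <- tibble::tibble(a = c(1, 0, 1, 0), b = c(0, 1, 0, 1))  # d = 1,-1,1,-1
  ba <- bland_altman(d, a, b)
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, sqrt(4 / 3))
  expect_equal(ba$loa_high, 1.96 * sqrt(4 / 3))
  expect_equal(ba$loa_low, -1.96 * sqrt(4 / 3))

  # limits are symmetric about the mean difference by construction
  tab <- random_count_table(7)
  bar <- bland_altman(tab, a, b)
  expect_equal(bar$loa_high - bar$mean_diff, bar$mean_diff - bar$loa_low)

  expect_error(bland_altman(tibble::tibble(a = 1, b = 2), a, b),
               class = "fms_insufficient_data_error")
})

test_that("Bland-Altman limits contain about 95% of normal differences", {
  set.seed(31)
  n <- 4000
  d <- tibble::tibble(a = rnorm(n, 12, 3), b = rnorm(n, 10, 3))
  ba <- bland_altman(d, a, b)
  diffs <- d$a - d$b
  coverage <- mean(diffs >= ba$loa_low & diffs <= ba$loa_high)
  expect_lt(abs(coverage - 0.95), 0.02)
})

synthetic_counts <- function() {
  # 9 participants; consensus/system totals engineered to 189 and 243
  tibble::tibble(
    participant = sprintf("P%02d", 1:9),
    condition = "game_play",
    skill = "sidestep",
    rater1 = c(20, 22, 25, 18, 21, 23, 19, 20, 22),
    rater2 = c(21, 21, 26, 17, 22, 22, 20, 19, 23),
    consensus = c(21, 22, 26, 18, 22, 23, 19, 17, 21),
    system = c(27, 28, 33, 23, 28, 30, 25, 22, 27)
  )
}

test_that("reliability reports reproduce the published table layout", {
  counts <- synthetic_counts()
  expect_equal(sum(counts$consensus), 189)
  expect_equal(sum(counts$system), 243)
  rep1 <- reliability_report(counts, "sidestep", "game_play",
                             comparison = "consensus_vs_system")
  expect_equal(rep1$summary$total, c(189L, 243L))
  expect_equal(rep1$summary$mean, c(mean(counts$consensus),
                                    mean(counts$system)))
  printed <- capture.output(print(rep1))
  expect_true(any(grepl("totals: 189, 243", printed)))

  # the JSON view carries the same numbers as the printed table
  tf <- tempfile(fileext = ".json")
  write_report_json(rep1, tf)
  rec <- jsonlite::read_json(tf, simplifyVector = TRUE)
  expect_equal(rec$totals, c(189L, 243L))
  expect_equal(rec$icc$icc, rep1$icc$icc)
  expect_equal(rec$pct_agreement, rep1$pct_agreement)
  expect_equal(rec$bland_altman$loa_low, rep1$ba$loa_low)

  # rater comparison uses the rater columns
  rep2 <- reliability_report(counts, "sidestep", "game_play",
                             comparison = "raters")
  expect_equal(rep2$summary$source, c("rater1", "rater2"))
  expect_equal(rep2$icc$icc, icc21(counts, rater1, rater2)$icc)
})

test_that("reports handle degenerate sizes and bad requests", {
  counts <- synthetic_counts()
  expect_error(reliability_report(counts, "hop", "game_play"),
               class = "fms_validation_error")
  expect_error(reliability_report(counts, "sidestep", "fms"),
               class = "fms_validation_error")

  single <- counts[1, ]
  rep1 <- reliability_report(single, "sidestep", "game_play")
  expect_true(rep1$small_n)
  expect_null(rep1$icc)
  expect_equal(rep1$summary$mean, c(20, 21))
  expect_equal(rep1$summary$sd, c(0, 0))
})

test_that("count tables read from CSV with column mapping and validation", {
  counts <- synthetic_counts()
  tf <- tempfile(fileext = ".csv")
  renamed <- dplyr::rename(counts, KART = system)
  write.csv(as.data.frame(renamed), tf, row.names = FALSE)
  back <- read_counts(tf, column_map = c(system = "KART"))
  expect_true("system" %in% names(back))
  expect_equal(back$system, counts$system)

  bad <- counts
  bad$rater1[1] <- -2
  write.csv(as.data.frame(bad), tf, row.names = FALSE)
  expect_error(read_counts(tf), class = "fms_validation_error")
  bad$rater1[1] <- 2.5
  write.csv(as.data.frame(bad), tf, row.names = FALSE)
  expect_error(read_counts(tf), class = "fms_validation_error")
})

test_that("tidy and glance views expose the fitted statistics", {
  tab <- random_count_table(3)
  fit <- icc21(tab, a, b)
  td <- tidy(fit)
  expect_equal(td$estimate, fit$icc)
  gl <- glance(fit)
  expect_equal(gl$n, nrow(tab))

  ba <- bland_altman(tab, a, b)
  expect_equal(nrow(tidy(ba)), nrow(tab))
  expect_equal(glance(ba)$mean_diff, ba$mean_diff)

  p <- ggplot2::autoplot(ba)
  expect_s3_class(p, "ggplot")
})
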