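# Reliability of movement counts between two sources (rater vs rater, or
# rater consensus vs the automated system): intraclass correlation from the
# two-way random-effects model with single measures and absolute agreement
# (Shrout-Fleiss ICC(2,1)) with its F-based 95% CI, percentage agreement,
# and Bland-Altman limits of agreement.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

two_col_matrix <- function(data, a, b, min_n, what) {
  a <- rlang::enquo(a); b <- rlang::enquo(b)
  va <- rlang::eval_tidy(a, data)
  vb <- rlang::eval_tidy(b, data)
  if (length(va) != length(vb)) {
    abort_validation("the two count columns must have equal length")
  }
  if (length(va) < min_n) {
    rlang::abort(
      sprintf("insufficient data for %s: need at least %d paired values, got %d",
              what, min_n, length(va)),
      class = c("fms_insufficient_data_error", "fms_validation_error")
    )
  }
  if (any(!is.finite(va)) || any(!is.finite(vb))) {
    abort_validation("counts must be finite")
  }
  cbind(va, vb)
}

#' Intraclass correlation ICC(2,1)
#'
#' Single-measures, absolute-agreement intraclass correlation from the
#' two-way random-effects model: participants and sources (raters) are both
#' random, and the statistic is computed from the two-way ANOVA mean squares
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + k (MS_C - MS_E)/n}}
#' with the standard F-based 95% confidence interval. The result is
#' categorised by the Fleiss criteria: >= 0.75 excellent, < 0.40 poor,
#' moderate between.
#'
#' @param data Data frame with one row per participant.
#' @param a,b Unquoted names of the two count columns.
#' @param conf_level Confidence level of the interval (default 0.95).
#' @return An `fms_icc` object with `icc`, `ci95_low`, `ci95_high`, `n`, `k`,
#'   `category` and the mean squares; see [tidy()] / [glance()].
#' @export
#' @examples
#' counts <- tibble::tibble(r1 = c(4, 5, 7, 9), r2 = c(4, 6, 8, 9))
#' icc21(counts, r1, r2)
icc21 <- function(data, a, b, conf_level = 0.95) {
  y <- two_col_matrix(data, {{ a }}, {{ b }}, min_n = 3, what = "ICC(2,1)")
  n <- nrow(y); k <- ncol(y)
  grand <- mean(y)
  if (all(y == y[1])) {
    rlang::abort("degenerate data: all counts identical, ICC undefined",
                 class = c("fms_degenerate_data_error", "fms_validation_error"))
  }
  row_means <- rowMeans(y)
  col_means <- colMeans(y)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  sse <- sum((y - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))

  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  alpha <- 1 - conf_level
  if (mse == 0 && msc == 0) {
    ci <- c(icc, icc)  # perfect agreement: interval collapses
  } else {
    a_ <- (k * icc) / (n * (1 - icc))
    b_ <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a_ * msc + b_ * mse)^2 /
      ((a_ * msc)^2 / (k - 1) + (b_ * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(lower, upper)
  }

  structure(
    list(icc = icc, ci95_low = min(ci[1], icc), ci95_high = max(ci[2], icc),
         n = n, k = k, category = icc_category(icc),
         ms = list(msr = msr, msc = msc, mse = mse),
         conf_level = conf_level),
    class = "fms_icc"
  )
}

#' @rdname icc21
#' @param icc A numeric ICC value.
#' @details `icc_category()` applies the Fleiss interpretation bands on
#' their own.
#' @export
icc_category <- function(icc) {
  ifelse(icc >= 0.75, "excellent", ifelse(icc < 0.40, "poor", "moderate"))
}

#' @export
print.fms_icc <- function(x, ...) {
  cat(sprintf(
    "ICC(2,1) = %.3f (%d%% CI %.3f-%.3f), n = %d, k = %d: %s reliability\n",
    x$icc, round(100 * x$conf_level), x$ci95_low, x$ci95_high, x$n, x$k,
    x$category
  ))
  invisible(x)
}

#' @method tidy fms_icc
#' @export
tidy.fms_icc <- function(x, ...) {
  tibble::tibble(
    term = "ICC(2,1)", estimate = x$icc,
    conf.low = x$ci95_low, conf.high = x$ci95_high,
    category = x$category
  )
}

#' @method glance fms_icc
#' @export
glance.fms_icc <- function(x, ...) {
  tibble::tibble(
    icc = x$icc, ci95_low = x$ci95_low, ci95_high = x$ci95_high,
    n = x$n, k = x$k, category = x$category,
    msr = x$ms$msr, msc = x$ms$msc, mse = x$ms$mse
  )
}

#' Percentage agreement between two count vectors
#'
#' For each participant the agreement of the two counts is
#' `100 * min(a, b) / max(a, b)` (with a pair of zeros counting as full
#' agreement), averaged over participants. This scale-free definition
#' reduces to 100 exactly when the vectors are identical. Note that
#' published percentage-agreement figures do not always state their formula;
#' this package's definition is documented here precisely so results can be
#' compared knowingly.
#'
#' @inheritParams icc21
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' percentage_agreement(tibble::tibble(a = c(0, 10), b = c(0, 8)), a, b)
percentage_agreement <- function(data, a, b) {
  y <- two_col_matrix(data, {{ a }}, {{ b }}, min_n = 1,
                      what = "percentage agreement")
  if (any(y < 0)) abort_validation("counts must be nonnegative")
  lo <- pmin(y[, 1], y[, 2])
  hi <- pmax(y[, 1], y[, 2])
  ratio <- ifelse(hi == 0, 1, lo / hi)
  100 * mean(ratio)
}

#' Bland-Altman limits of agreement
#'
#' Differences `d = a - b` per participant; the limits of agreement are the
#' mean difference plus/minus 1.96 sample standard deviations (n - 1), the
#' conventional bounds expected to contain about 95% of differences.
#'
#' @inheritParams icc21
#' @return An `fms_ba` object: `mean_diff`, `sd_diff`, `loa_low`,
#'   `loa_high`, and per-participant `(mean, diff)` pairs for plotting (see
#'   [tidy()], [glance()], [ggplot2::autoplot()]).
#' @export
#' @examples
#' ba <- bland_altman(tibble::tibble(a = c(4, 5, 7, 9), b = c(4, 6, 8, 9)), a, b)
#' glance(ba)
bland_altman <- function(data, a, b) {
  y <- two_col_matrix(data, {{ a }}, {{ b }}, min_n = 2,
                      what = "Bland-Altman limits")
  d <- y[, 1] - y[, 2]
  mean_diff <- mean(d)
  sd_diff <- stats::sd(d)
  structure(
    list(mean_diff = mean_diff, sd_diff = sd_diff,
         loa_low = mean_diff - 1.96 * sd_diff,
         loa_high = mean_diff + 1.96 * sd_diff,
         pairs = tibble::tibble(mean = rowMeans(y), diff = d)),
    class = "fms_ba"
  )
}

#' @export
print.fms_ba <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman: mean difference %.3f, SD %.3f, limits of agreement [%.3f, %.3f] (n = %d)\n",
    x$mean_diff, x$sd_diff, x$loa_low, x$loa_high, nrow(x$pairs)
  ))
  invisible(x)
}

#' @method tidy fms_ba
#' @export
tidy.fms_ba <- function(x, ...) x$pairs

#' @method glance fms_ba
#' @export
glance.fms_ba <- function(x, ...) {
  tibble::tibble(mean_diff = x$mean_diff, sd_diff = x$sd_diff,
                 loa_low = x$loa_low, loa_high = x$loa_high,
                 n = nrow(x$pairs))
}

# ---- count tables and reports ----------------------------------------------

#' Read a per-participant movement-count table
#'
#' Expected columns: `participant`, `condition`, `skill`, and the count
#' sources `rater1`, `rater2`, `consensus` (the raters' 100%-agreement
#' count, supplied as data, not computed) and `system`. Spreadsheet sources
#' should be exported to CSV; `column_map` renames nonstandard source
#' columns, e.g. `c(system = "KART")` if the file calls the system column
#' "KART".
#'
#' @param path CSV file path.
#' @param column_map Optional named character vector `c(standard = "source")`.
#' @return A validated tibble.
#' @export
read_counts <- function(path, column_map = NULL) {
  if (!file.exists(path)) {
    abort_validation(paste0("counts file not found: ", path))
  }
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  for (std in names(column_map)) {
    src <- column_map[[std]]
    if (!src %in% names(df)) {
      abort_validation(paste0("column_map source column not found: ", src))
    }
    names(df)[names(df) == src] <- std
  }
  required <- c("participant", "condition", "skill")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort_validation(paste0("counts table missing column(s): ",
                            paste(missing_cols, collapse = ", ")))
  }
  for (col in intersect(c("rater1", "rater2", "consensus", "system"),
                        names(df))) {
    v <- df[[col]]
    if (any(!is.finite(v)) || any(v < 0) || any(v != round(v))) {
      abort_validation(paste0("counts in column '", col,
                              "' must be nonnegative integers"))
    }
  }
  df
}

report_sources <- list(
  raters = c("rater1", "rater2"),
  consensus_vs_system = c("consensus", "system")
)

#' Reliability report for one skill and condition
#'
#' Reproduces the layout of a movement-count validation table: per-source
#' mean and SD, exact integer totals, ICC(2,1) with 95% CI and Fleiss
#' category, percentage agreement, and Bland-Altman limits. With fewer than
#' three participants the ICC is omitted and a small-sample caveat flagged
#' (a single participant's SD is reported as 0).
#'
#' @param data Count table as from [read_counts()].
#' @param skill Skill label to report (e.g. `"jump"`).
#' @param condition Condition label (e.g. `"game_play"`).
#' @param comparison `"raters"` (rater 1 vs rater 2) or
#'   `"consensus_vs_system"`.
#' @return An `fms_report` object; `print()` renders the aligned-text table
#'   and [write_report_json()] the JSON equivalent, from the same numbers.
#' @export
reliability_report <- function(data, skill, condition,
                               comparison = c("raters",
                                              "consensus_vs_system")) {
  comparison <- match.arg(comparison)
  if (!skill %in% data$skill) {
    abort_validation(paste0("unknown skill: ", skill))
  }
  if (!condition %in% data$condition) {
    abort_validation(paste0("unknown condition: ", condition))
  }
  sources <- report_sources[[comparison]]
  missing_cols <- setdiff(sources, names(data))
  if (length(missing_cols) > 0) {
    abort_validation(paste0("counts table missing column(s): ",
                            paste(missing_cols, collapse = ", ")))
  }
  rows <- data[data$skill == skill & data$condition == condition, ]
  n <- nrow(rows)
  if (n == 0) abort_validation("no rows match the requested skill and condition")

  n_part <- n
  summary <- tibble::tibble(
    source = sources,
    n = n_part,
    mean = vapply(sources, function(s) mean(rows[[s]]), numeric(1),
                  USE.NAMES = FALSE),
    sd = vapply(sources, function(s) {
      if (n_part < 2) 0 else stats::sd(rows[[s]])
    }, numeric(1), USE.NAMES = FALSE),
    total = vapply(sources, function(s) as.integer(sum(rows[[s]])),
                   integer(1), USE.NAMES = FALSE)
  )
  icc <- if (n >= 3) {
    tryCatch(
      icc21(rows, !!rlang::sym(sources[1]), !!rlang::sym(sources[2])),
      fms_degenerate_data_error = function(e) NULL
    )
  } else NULL
  ba <- if (n >= 2) {
    bland_altman(rows, !!rlang::sym(sources[1]), !!rlang::sym(sources[2]))
  } else NULL

  structure(
    list(
      skill = skill, condition = condition, comparison = comparison,
      n = n, summary = summary,
      icc = icc,
      pct_agreement = percentage_agreement(rows, !!rlang::sym(sources[1]),
                                           !!rlang::sym(sources[2])),
      ba = ba,
      small_n = n < 3
    ),
    class = "fms_report"
  )
}

#' @export
print.fms_report <- function(x, ...) {
  cat(sprintf("Reliability report: %s, %s (%s), n = %d\n",
              x$skill, x$condition, x$comparison, x$n))
  s <- x$summary
  width <- max(nchar(s$source))
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-*s  mean %6.2f +/- %.2f   total %d\n", width,
                s$source[i], s$mean[i], s$sd[i], s$total[i]))
  }
  cat(sprintf("  totals: %s\n", paste(s$total, collapse = ", ")))
  if (!is.null(x$icc)) {
    cat("  "); print(x$icc)
  } else {
    cat("  ICC: not computed (fewer than 3 participants or degenerate counts)\n")
  }
  cat(sprintf("  percentage agreement: %.2f%%\n", x$pct_agreement))
  if (!is.null(x$ba)) {
    cat("  "); print(x$ba)
  }
  if (x$small_n) {
    cat("  caveat: fewer than 3 participants; dispersion estimates unreliable\n")
  }
  invisible(x)
}

#' @method tidy fms_report
#' @export
tidy.fms_report <- function(x, ...) x$summary

#' @method glance fms_report
#' @export
glance.fms_report <- function(x, ...) {
  tibble::tibble(
    skill = x$skill, condition = x$condition, comparison = x$comparison,
    n = x$n,
    total_a = x$summary$total[1], total_b = x$summary$total[2],
    icc = if (is.null(x$icc)) NA_real_ else x$icc$icc,
    icc_ci_low = if (is.null(x$icc)) NA_real_ else x$icc$ci95_low,
    icc_ci_high = if (is.null(x$icc)) NA_real_ else x$icc$ci95_high,
    icc_category = if (is.null(x$icc)) NA_character_ else x$icc$category,
    pct_agreement = x$pct_agreement,
    ba_mean_diff = if (is.null(x$ba)) NA_real_ else x$ba$mean_diff,
    ba_loa_low = if (is.null(x$ba)) NA_real_ else x$ba$loa_low,
    ba_loa_high = if (is.null(x$ba)) NA_real_ else x$ba$loa_high
  )
}

#' @rdname reliability_report
#' @param report An `fms_report`.
#' @param path JSON destination.
#' @export
write_report_json <- function(report, path) {
  out <- list(
    skill = report$skill, condition = report$condition,
    comparison = report$comparison, n = report$n,
    summary = as.data.frame(report$summary),
    totals = report$summary$total,
    icc = if (is.null(report$icc)) NULL else {
      list(icc = report$icc$icc, ci95_low = report$icc$ci95_low,
           ci95_high = report$icc$ci95_high, category = report$icc$category)
    },
    pct_agreement = report$pct_agreement,
    bland_altman = if (is.null(report$ba)) NULL else {
      list(mean_diff = report$ba$mean_diff, sd_diff = report$ba$sd_diff,
           loa_low = report$ba$loa_low, loa_high = report$ba$loa_high)
    },
    small_n = report$small_n
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
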