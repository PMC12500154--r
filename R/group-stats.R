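#' One-way repeated-measures ANOVA
#'
#' Fits a one-way within-participant ANOVA (subject effect removed) on a
#' long table of per-participant condition values, via `stats::aov` with an
#' `Error(participant)` stratum. Degrees of freedom are `(k - 1,
#' (k - 1)(n - 1))` for `k` conditions and `n` participants (no sphericity
#' correction). Effect size is partial eta squared,
#' `SS_effect / (SS_effect + SS_error)`. Requires complete cases: every
#' participant must contribute exactly one value per condition.
#'
#' @param data long tibble.
#' @param value,class,participant column names (strings) of the measured
#'   value, the within-participant condition, and the participant id.
#' @return an `rm_anova` object with [generics::tidy()] and
#'   [generics::glance()] methods.
#' @export
rm_anova <- function(data, value = "value", class = "class",
                     participant = "participant") {
  d <- tibble(value = data[[value]],
              class = factor(data[[class]]),
              participant = factor(data[[participant]]))
  if (anyNA(d)) stop("missing cells are not allowed (no imputation)",
                     call. = FALSE)
  tab <- table(d$participant, d$class)
  if (any(tab != 1))
    stop("each participant must have exactly one value per class",
         call. = FALSE)
  n <- nlevels(d$participant)
  k <- nlevels(d$class)
  if (k < 2 || n < 3) stop("need k >= 2 classes and n >= 3 participants",
                           call. = FALSE)
  fit <- aov(value ~ class + Error(participant), data = d)
  s <- summary(fit)[["Error: Within"]][[1]]
  ss_effect <- s["class", "Sum Sq"]
  ss_error <- s["Residuals", "Sum Sq"]
  f_val <- s["class", "F value"]
  p_val <- s["class", "Pr(>F)"]
  pes <- ss_effect / (ss_effect + ss_error)
  if (ss_effect <= 1e-12 * max(sum(d$value^2), 1e-300)) {
    # numerically null effect (e.g. identical conditions): 0/0 guard
    f_val <- 0; p_val <- 1; pes <- 0
  }
  out <- list(F = f_val,
              df1 = s["class", "Df"], df2 = s["Residuals", "Df"],
              p = p_val,
              pes = pes,
              ss_effect = ss_effect, ss_error = ss_error,
              n = n, k = k,
              means = tapply(d$value, d$class, mean))
  class(out) <- "rm_anova"
  out
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("One-way repeated-measures ANOVA: F(%d, %d) = %.3f, p = %.4g, partial eta^2 = %.3f\n",
              x$df1, x$df2, x$F, x$p, x$pes))
  invisible(x)
}

#' Paired and one-sample t tests with Bonferroni correction
#'
#' Runs two-sided t tests over a family of comparisons on a long
#' participant x class table: a length-2 comparison `c("a", "b")` is a
#' paired test of a minus b; a length-1 comparison tests that class
#' against zero. Cohen's d is `mean(diff) / sd(diff)` (for one-sample
#' tests, of the values themselves). Bonferroni adjustment multiplies the
#' raw p by `m` (default: the family size), capped at 1.
#'
#' @inheritParams rm_anova
#' @param comparisons list of class-name vectors (length 1 or 2).
#' @param m Bonferroni family size (default `length(comparisons)`).
#' @return tibble: `comparison`, `t`, `df`, `d`, `p`, `p_adj`.
#' @export
paired_tests <- function(data, comparisons, m = length(comparisons),
                         value = "value", class = "class",
                         participant = "participant") {
  wide <- tidyr::pivot_wider(
    tibble(participant = data[[participant]], class = data[[class]],
           value = data[[value]]),
    names_from = "class", values_from = "value")
  rows <- purrr::map(comparisons, function(cmp) {
    dif <- if (length(cmp) == 2) wide[[cmp[1]]] - wide[[cmp[2]]]
           else wide[[cmp[1]]]
    dif <- dif[!is.na(dif)]
    if (sd(dif) == 0)
      stop("zero-variance differences in comparison ",
           paste(cmp, collapse = " - "), call. = FALSE)
    tt <- t.test(dif)
    tibble(comparison = paste(c(cmp, if (length(cmp) == 1) "0"),
                              collapse = " - "),
           t = unname(tt$statistic), df = unname(tt$parameter),
           d = mean(dif) / sd(dif), p = tt$p.value)
  })
  out <- bind_rows(rows)
  out$p_adj <- pmin(1, out$p * m)
  out
}

#' Two-step response-time trimming and behavioral summaries
#'
#' Cleans response times in the stated order: first, trials with RT
#' exceeding `max_rt_ms` are excluded; second, trials beyond `sd_cutoff`
#' standard deviations from the participant's mean are excluded, where the
#' mean and SD are computed per participant over the step-1 survivors
#' (pooled across classes). A participant whose surviving RTs have zero SD
#' gets no step-2 trimming. Accuracy and mean RT are then summarized per
#' participant and class on the trimmed data, with across-participant
#' means and SEs.
#'
#' @param data tibble with columns `participant`, `class`, `rt_ms`,
#'   `correct` (logical or 0/1).
#' @param max_rt_ms step-1 cutoff (default 3000 ms).
#' @param sd_cutoff step-2 cutoff in SD units (default 2.5).
#' @return list: `trimmed` (surviving trials), `by_participant`
#'   (participant x class mean RT and accuracy), `summary`
#'   (across-participant mean and SE per class), `n_removed`
#'   (per-step counts).
#' @export
trim_rts <- function(data, max_rt_ms = 3000, sd_cutoff = 2.5) {
  stopifnot(all(c("participant", "class", "rt_ms", "correct") %in%
                  names(data)))
  step1 <- filter(data, .data$rt_ms <= max_rt_ms)
  n1 <- nrow(data) - nrow(step1)
  lims <- step1 |>
    group_by(.data$participant) |>
    summarise(mu = mean(.data$rt_ms), sigma = sd(.data$rt_ms),
              .groups = "drop")
  step2 <- step1 |>
    left_join(lims, by = "participant") |>
    filter(is.na(.data$sigma) | .data$sigma == 0 |
             abs(.data$rt_ms - .data$mu) <= sd_cutoff * .data$sigma) |>
    select(-"mu", -"sigma")
  n2 <- nrow(step1) - nrow(step2)
  byp <- step2 |>
    group_by(.data$participant, .data$class) |>
    summarise(mean_rt_ms = mean(.data$rt_ms),
              accuracy = mean(as.numeric(.data$correct)),
              n_trials = n(), .groups = "drop")
  summ <- byp |>
    group_by(.data$class) |>
    summarise(rt_mean = mean(.data$mean_rt_ms),
              rt_se = sd(.data$mean_rt_ms) / sqrt(n()),
              acc_mean = mean(.data$accuracy),
              acc_se = sd(.data$accuracy) / sqrt(n()),
              .groups = "drop")
  list(trimmed = step2, by_participant = byp, summary = summ,
       n_removed = c(step1 = n1, step2 = n2))
}
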