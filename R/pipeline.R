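#' Run the full microsaccade / N2pc analysis pipeline
#'
#' Orchestrates the complete analysis on a simulated experiment: per
#' participant, simulate gaze and EEG, mask blinks, detect microsaccades,
#' classify trials by the first in-window shift, baseline-correct the EEG
#' and build per-class lateralized waves and windowed N2pc amplitudes;
#' then, at the group level, class proportions, a one-way repeated-measures
#' ANOVA on N2pc amplitude per task, per-class tests against zero and
#' Bonferroni-corrected pairwise comparisons, cluster-based sign-flip
#' permutation tests on the per-class difference waves, behavioral
#' summaries after two-step RT trimming, and (optionally) latency-sorted
#' ERP images with alignment statistics for the HEOG, Oz and lateralized
#' derivations. With `out_dir`, results are written as CSV/JSON together
#' with a provenance manifest (configuration, seed, package version, file
#' digests); identical configuration and seed give identical outputs.
#'
#' @param config a [sim_config]; `config$seed` drives all randomness.
#' @param out_dir optional report directory.
#' @param params [detect_params] for saccade detection.
#' @param class_window,n2pc_window,baseline_window analysis windows (ms).
#' @param n_perm permutations for the cluster tests.
#' @param stages character subset of
#'   `c("erp", "stats", "cluster", "behavior", "erp_image")`.
#' @return a `saccatt_pipeline` list: `class_table`, `proportions`,
#'   `amplitudes`, `waves`, `anova`, `tests`, `clusters`, `behavior`,
#'   `erp_images`, `alignment`, `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         params = detect_params(),
                         class_window = c(150, 400),
                         n2pc_window = c(200, 300),
                         baseline_window = c(-250, 0),
                         n_perm = 2000,
                         stages = c("erp", "stats", "cluster", "behavior",
                                    "erp_image")) {
  stages <- match.arg(stages, several.ok = TRUE)
  tasks <- c("perception", "wm")
  classes <- c("toward", "away", "none")
  class_tables <- list(); amp_rows <- list(); wave_acc <- list()
  img_rows <- list(onset = list(), heog = list(), oz = list(), diff = list())
  etime <- eeg_time_axis(config)

  for (p in seq_len(config$n_participants)) {
    sim <- simulate_participant(config, p)
    gaze <- mask_blinks(sim$gaze)
    events <- detect_saccades(gaze, params)
    ct <- classify_trials(events, gaze, window = class_window)
    class_tables[[p]] <- ct
    eeg <- baseline_correct(sim$eeg, baseline_window)
    if ("erp" %in% stages || "cluster" %in% stages) {
      for (tk in tasks) for (cl in classes) {
        sel <- which(ct$task == tk & ct$class == cl)
        wave <- tryCatch(contra_ipsi(subset_trials(eeg, sel)),
                         error = function(e) NULL)
        if (is.null(wave)) next
        amp_rows[[length(amp_rows) + 1]] <-
          tibble(participant = p, task = tk, class = cl,
                 n_trials = length(sel),
                 amplitude = n2pc_amplitude(wave, n2pc_window))
        wave_acc[[paste(tk, cl, sep = ".")]][[as.character(p)]] <- wave$diff
      }
    }
    if ("erp_image" %in% stages) {
      tow <- which(ct$class == "toward")
      if (length(tow)) {
        sub <- subset_trials(eeg, tow)
        img_rows$onset[[p]] <- ct$first_saccade_onset_ms[tow]
        # sign-align HEOG to the toward direction (leftward saccades give
        # negative EOG steps; without alignment left- and right-cued rows
        # cancel under trial smoothing)
        sgn <- ifelse(ct$cued_side[tow] == "left", -1, 1)
        img_rows$heog[[p]] <- sgn * ch_slice(sub, seq_along(tow),
                                             match("HEOG", sub$channels))
        img_rows$oz[[p]] <- ch_slice(sub, seq_along(tow),
                                     match("Oz", sub$channels))
        img_rows$diff[[p]] <- trialwise_diff(sub)
      }
    }
    rm(sim, eeg, gaze)
  }

  class_table <- bind_rows(class_tables)
  proportions <- class_proportions(class_table)
  amplitudes <- bind_rows(amp_rows)

  anova <- list(); tests <- list()
  if ("stats" %in% stages && nrow(amplitudes)) {
    for (tk in tasks) {
      sub <- filter(amplitudes, .data$task == tk)
      if (length(unique(sub$class)) == 3 &&
          all(table(sub$participant) == 3)) {
        anova[[tk]] <- rm_anova(sub, value = "amplitude")
        tests[[tk]] <- bind_rows(
          paired_tests(sub, as.list(classes), m = 1, value = "amplitude"),
          paired_tests(sub, list(c("toward", "none"), c("toward", "away"),
                                 c("none", "away")),
                       m = 3, value = "amplitude"))
      }
    }
  }

  clusters <- list()
  if ("cluster" %in% stages) {
    for (key in names(wave_acc)) {
      mat <- do.call(rbind, wave_acc[[key]])
      if (!is.null(mat) && nrow(mat) >= 2)
        clusters[[key]] <- permutation_test(
          mat, n_perm = n_perm,
          seed = derive_seed(config$seed, 7001, match(key, names(wave_acc))))
    }
  }

  behavior <- NULL
  if ("behavior" %in% stages) {
    beh <- class_table |>
      filter(.data$class %in% classes) |>
      select("participant", "class", "rt_ms", "correct")
    behavior <- trim_rts(beh)
  }

  erp_images <- list(); alignment <- NULL
  if ("erp_image" %in% stages && length(img_rows$onset)) {
    onsets <- unlist(img_rows$onset)
    specs <- list(HEOG = list(rows = img_rows$heog, method = "slope"),
                  Oz = list(rows = img_rows$oz, method = "max"),
                  `N2pc-diff` = list(rows = img_rows$diff, method = "min"))
    al <- list()
    for (nm in names(specs)) {
      m <- do.call(rbind, specs[[nm]]$rows)
      img <- build_erp_image(m, onsets, etime, label = nm)
      erp_images[[nm]] <- img
      al[[nm]] <- mutate(
        alignment_statistic(img, method = specs[[nm]]$method,
                            seed = derive_seed(config$seed, 7100,
                                               match(nm, names(specs)))),
        derivation = nm, .before = 1)
    }
    alignment <- bind_rows(al)
  }

  res <- list(class_table = class_table, proportions = proportions,
              amplitudes = amplitudes,
              waves = purrr::map(wave_acc, ~ do.call(rbind, .x)),
              time_ms = etime,
              anova = anova, tests = tests, clusters = clusters,
              behavior = behavior, erp_images = erp_images,
              alignment = alignment,
              manifest = list(config = unclass(config),
                              seed = config$seed,
                              detect_params = unclass(params),
                              class_window = class_window,
                              n2pc_window = n2pc_window,
                              baseline_window = baseline_window,
                              n_perm = n_perm, stages = stages,
                              package_version =
                                as.character(utils::packageVersion("saccatt"))))
  class(res) <- "saccatt_pipeline"
  if (!is.null(out_dir)) write_pipeline_report(res, out_dir)
  res
}

write_pipeline_report <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  w <- function(x, f) readr::write_csv(x, file.path(out_dir, f),
                                       progress = FALSE)
  w(res$class_table, "class_table.csv")
  w(res$proportions$by_participant, "class_proportions.csv")
  if (nrow(res$amplitudes)) w(res$amplitudes, "n2pc_amplitudes.csv")
  if (length(res$tests)) {
    tt <- bind_rows(purrr::imap(res$tests, ~ mutate(.x, task = .y,
                                                    .before = 1)))
    w(tt, "posthoc_tests.csv")
  }
  if (length(res$anova))
    jsonlite::write_json(
      purrr::map(res$anova, ~ unclass(.x)[c("F", "df1", "df2", "p", "pes")]),
      file.path(out_dir, "anova.json"), digits = NA, auto_unbox = TRUE)
  if (length(res$clusters))
    jsonlite::write_json(
      purrr::map(res$clusters, function(ct)
        list(clusters = as.data.frame(ct$clusters), n_perm = ct$n_perm,
             alpha = ct$alpha, seed = ct$seed)),
      file.path(out_dir, "clusters.json"), digits = NA, auto_unbox = TRUE,
      dataframe = "columns")
  if (!is.null(res$behavior)) w(res$behavior$summary, "behavior_summary.csv")
  if (!is.null(res$alignment)) w(res$alignment, "erp_image_alignment.csv")
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, "provenance.json"))
  jsonlite::write_json(
    list(files = as.list(tools::md5sum(files))),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE)
  invisible(out_dir)
}

#' Packaged test datasets
#'
#' Convenience generator for a small, fully self-contained synthetic
#' dataset: `"tiny"` is 3 participants x 60 trials per task and runs end
#' to end in well under a minute; `"default"` is the full-scale experiment
#' configuration.
#'
#' @param size `"tiny"` or `"default"`.
#' @param dir optional directory to write the dataset to.
#' @param seed master seed (default 42).
#' @return list with `config` and the [simulate_experiment()] result.
#' @export
make_fixtures <- function(size = c("tiny", "default"), dir = NULL,
                          seed = 42) {
  size <- match.arg(size)
  config <- switch(size,
    tiny = sim_config(n_participants = 3, trials_per_task = 60, seed = seed),
    default = sim_config(seed = seed))
  list(config = config, data = simulate_experiment(config, dir = dir))
}
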