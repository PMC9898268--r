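# End-to-end orchestration: filter -> segment -> CRP -> cluster (BIC scan +
# plateau) -> label sequences -> degree-1/degree-3 DMMs per learner and
# speed condition -> exploration profiles -> learning-curve fits -> stats.

#' Build a pipeline configuration
#'
#' @param scenario Either a trace tibble / path to an angle CSV, or a named
#'   list describing a synthetic scenario passed to [simulate_learner()]
#'   per learner: fields `n_learners`, `strategies` (recycled), plus any
#'   [simulate_learner()] arguments (`m`, `n_sessions`, ...). Both speed
#'   conditions (`"low"`, `"high"`) are generated per learner.
#' @param k_range Candidate cluster counts (default 2:16).
#' @param degrees The two drift degrees compared by the exploration
#'   statistic (default `c(1, 3)`).
#' @param mode Exploration distance mode (default `"appearance"`).
#' @param L Points per cycle (default 100).
#' @param cutoff Low-pass cut-off in Hz (default 8).
#' @param min_period Minimum cycle period in s (default 0.5).
#' @param n_init Clustering restarts (default 10).
#' @param seed Master seed.
#' @param out_dir Output directory (optional; created if missing).
#' @return A `"pipeline_config"` list.
#' @export
pipeline_config <- function(scenario, k_range = 2:16, degrees = c(1, 3),
                            mode = "appearance", L = 100, cutoff = 8,
                            min_period = 0.5, n_init = 10, seed = 1,
                            out_dir = NULL) {
  stopifnot(length(k_range) >= 1, length(degrees) == 2,
            degrees[1] != degrees[2])
  structure(
    list(scenario = scenario, k_range = k_range, degrees = degrees,
         mode = mode, L = L, cutoff = cutoff, min_period = min_period,
         n_init = n_init, seed = seed, out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes every stage on either recorded traces or a synthetic scenario
#' and returns (and optionally writes) a report bundle. All randomness
#' derives from `config$seed`; rerunning with the same config reproduces
#' byte-identical outputs.
#'
#' @param config A `"pipeline_config"` from [pipeline_config()].
#' @return A list: `k_scan` (BIC scores and selected K), `labels` (labelled
#'   cycle tibble), `profiles` (per-pattern mean CRP), `exploration`
#'   (long tibble learner x speed x pattern), `learning` (per learner x
#'   speed fit table), `stats` (list of test results), `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- split_seed(config$seed, 4)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  # ---- inputs -------------------------------------------------------------
  sim <- NULL
  if (is.list(config$scenario) && !is.data.frame(config$scenario)) {
    sim <- stage("simulate", run_scenario(config$scenario, seeds[1]))
    traces <- sim$traces
    perf <- sim$performance
  } else {
    traces <- if (is.character(config$scenario)) {
      stage("read", read_angle_csv(config$scenario))
    } else {
      config$scenario
    }
    perf <- NULL
  }
  # ---- kinematics ---------------------------------------------------------
  if (!is.null(sim) && !is.null(sim$curves)) {
    crp <- sim$curves   # curve-level scenario: CRP cycles observed directly
  } else {
    filtered <- stage("filter", lowpass_fourier(traces, cutoff = config$cutoff))
    cycles <- stage("segment",
                    segment_cycles(filtered, min_period = config$min_period,
                                   L = config$L))
    crp <- stage("crp", compute_crp(filtered, cycles, L = config$L))
  }
  crp <- arrange(crp, .data$learner, .data$speed, .data$session,
                 .data$trial, .data$cycle)
  # ---- clustering ---------------------------------------------------------
  scan <- stage("cluster", scan_k(crp, k_range = config$k_range,
                                  seed = seeds[2], n_init = config$n_init))
  assignment <- stage("label",
                      assign_labels(scan$models[[as.character(scan$k_star)]],
                                    crp))
  labelled <- assignment$data %>%
    group_by(.data$learner, .data$speed) %>%
    mutate(cycle_index = dplyr::row_number() - 1L) %>%
    ungroup()
  # ---- DMM + exploration per learner x speed ------------------------------
  k_star <- scan$k_star
  groups <- labelled %>%
    select("learner", "speed", "pattern") %>%
    group_by(.data$learner, .data$speed) %>%
    tidyr::nest(.key = "seq") %>%
    ungroup()
  exploration <- stage("explore", purrr::pmap_dfr(
    groups, function(learner, speed, seq) {
      prof <- explore_sequence(seq$pattern, m = k_star, mode = config$mode)
      mutate(tidy(prof), learner = learner, speed = speed,
             sd_q = prof$sd_q, n_visited = prof$n_visited)
    }))
  # ---- learning curves ----------------------------------------------------
  learning <- NULL
  if (!is.null(perf)) {
    learning <- stage("learncurve", perf %>%
      group_by(.data$learner, .data$speed) %>%
      tidyr::nest(.key = "perf") %>%
      ungroup() %>%
      mutate(fit = purrr::map(.data$perf, fit_exponential)) %>%
      mutate(g = purrr::map(.data$fit, glance)) %>%
      select("learner", "speed", "g") %>%
      tidyr::unnest("g"))
  }
  # ---- statistics ---------------------------------------------------------
  stats_out <- stage("stats", pipeline_stats(exploration, learning))
  manifest <- list(
    package_version = as.character(utils::packageVersion("driftlearn")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    k_star = k_star,
    n_cycles = nrow(labelled),
    timestamp = NULL  # omitted for byte-identical reruns
  )
  bundle <- list(k_scan = scan$scores, k_star = k_star,
                 labels = labelled, profiles = assignment$profiles,
                 exploration = exploration, learning = learning,
                 stats = stats_out, manifest = manifest,
                 truth = if (!is.null(sim)) sim$truth else NULL)
  if (!is.null(config$out_dir)) {
    write_bundle(bundle, config$out_dir)
  }
  bundle
}

run_scenario <- function(sc, seed) {
  n_learners <- sc$n_learners %||% 2
  strategies <- rep_len(sc$strategies %||% "anchored_local", n_learners)
  args <- sc[setdiff(names(sc), c("n_learners", "strategies"))]
  seeds <- split_seed(seed, n_learners * 2)
  i <- 0
  runs <- purrr::map(seq_len(n_learners), function(l) {
    purrr::map(c("low", "high"), function(sp) {
      i <<- i + 1
      do.call(simulate_learner, c(
        list(strategy = strategies[l], seed = seeds[i],
             meta = list(learner = l, speed = sp)),
        args))
    })
  })
  flat <- purrr::flatten(runs)
  perf <- purrr::imap_dfr(flat, function(r, j) {
    mutate(r$performance,
           learner = ((j - 1) %/% 2) + 1,
           speed = c("low", "high")[((j - 1) %% 2) + 1])
  })
  curves <- purrr::compact(purrr::map(flat, "curves"))
  list(
    traces = bind_rows(purrr::map(flat, "traces")),
    curves = if (length(curves) > 0) bind_rows(curves) else NULL,
    labels = bind_rows(purrr::map(flat, "labels")),
    performance = perf,
    truth = purrr::map(flat, "truth")
  )
}

pipeline_stats <- function(exploration, learning) {
  out <- list()
  n_learners <- dplyr::n_distinct(exploration$learner)
  if (!is.null(learning) && n_learners >= 2 &&
      all(c("low", "high") %in% learning$speed)) {
    wide <- learning %>%
      select("learner", "speed", "b") %>%
      tidyr::pivot_wider(names_from = "speed", values_from = "b")
    if (sd(wide$low - wide$high) > 1e-15) {
      out$learning_rate_paired_t <- paired_t(wide$low, wide$high)
    }
    out$learning_rate_levene <- tryCatch(
      levene_mean_centered(list(wide$low, wide$high)),
      error = function(e) NULL)
  }
  if (n_learners >= 3) {
    out$exploration_anova <- tryCatch(
      rm_anova2(exploration, value = "q_percent", subject = "learner",
                a = "pattern", b = "speed"),
      error = function(e) NULL)
  }
  out
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# driftlearn %s | seed %s | config %s",
                 bundle$manifest$package_version, bundle$manifest$seed,
                 bundle$manifest$config_hash)
  wr <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_lines(hdr, path)
    readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  }
  wr(bundle$k_scan, "bic_scan.csv")
  write_labels_tsv(bundle$labels, file.path(out_dir, "labels.tsv"))
  wr(select(bundle$profiles, -"mean_crp"), "profiles.csv")
  profile_means <- do.call(rbind, bundle$profiles$mean_crp)
  readr::write_csv(as_tibble(as.data.frame(profile_means), .name_repair = "minimal"),
                   file.path(out_dir, "profile_means.csv"))
  wr(bundle$exploration, "exploration.csv")
  if (!is.null(bundle$learning)) wr(bundle$learning, "learning_fits.csv")
  jsonlite::write_json(
    c(bundle$manifest,
      list(stats = purrr::map(bundle$stats, function(s) {
        if (is.data.frame(s)) as.list(s) else s
      }))),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
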