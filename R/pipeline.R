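#' Pipeline run configuration
#'
#' Bundles every stage parameter plus a single global seed. Each random
#' stage consumes a sub-seed derived deterministically from the global
#' seed and the stage name, so adding or toggling a stage never perturbs
#' another stage's randomness.
#'
#' @param session_path Path to a session bundle; `NULL` simulates one.
#' @param out_dir Output directory.
#' @param stages Stages to run, a subset of `simulate`, `pev`, `decode`,
#'   `states`, `isi`, `mixture`, `psd`, `rt`.
#' @param seed Global integer seed.
#' @param sim A [sim_config()] for the simulate stage.
#' @param decoder A [decoder_config()].
#' @param n_state_shuffles Label shuffles for the confidence null
#'   (default 50).
#' @param n_tuning_shuffles Tuning-curve debiasing shuffles (default 1000).
#' @param n_isi_iter ISI shuffle iterations (default 10000).
#' @param n_pseudo Pseudo-populations (default 100).
#' @param min_population Minimum ISI population size (default 5).
#' @return A `run_config` list.
#' @export
run_config <- function(session_path = NULL, out_dir = tempfile("wmstates_run"),
                       stages = c("simulate", "pev", "decode", "states",
                                  "isi", "mixture"),
                       seed = 1, sim = sim_config(), decoder = decoder_config(),
                       n_state_shuffles = 50, n_tuning_shuffles = 1000,
                       n_isi_iter = 10000, n_pseudo = 100,
                       min_population = 5) {
  structure(list(session_path = session_path, out_dir = out_dir,
                 stages = stages, seed = as.integer(seed), sim = sim,
                 decoder = decoder, n_state_shuffles = n_state_shuffles,
                 n_tuning_shuffles = n_tuning_shuffles,
                 n_isi_iter = n_isi_iter, n_pseudo = n_pseudo,
                 min_population = min_population),
            class = "run_config")
}

#' Run the analysis pipeline on one session
#'
#' Executes the selected stages in dependency order, writing every result
#' as a machine-readable file (CSV/JSON) under `cfg$out_dir` together with
#' a `summary.json` logging seeds, parameters, stage status and exclusion
#' counts. A failed stage is recorded and its dependents are skipped.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with `out_dir`, per-stage `status`, and the
#'   in-memory stage results.
#' @export
run_pipeline <- function(cfg = run_config()) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  status <- list()
  results <- list()
  log_csv <- function(df, name) {
    utils::write.csv(df, file.path(cfg$out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  run_stage <- function(name, deps, fun) {
    if (!name %in% cfg$stages) {
      status[[name]] <<- "skipped"
      return(invisible(NULL))
    }
    if (length(deps) && !all(vapply(deps, function(d)
      identical(status[[d]], "ok"), logical(1)))) {
      status[[name]] <<- paste0("skipped (needs ",
                                paste(deps, collapse = ", "), ")")
      return(invisible(NULL))
    }
    res <- tryCatch({
      out <- fun()
      status[[name]] <<- "ok"
      out
    }, error = function(e) {
      status[[name]] <<- paste0("failed: ", conditionMessage(e))
      NULL
    })
    results[[name]] <<- res
    invisible(res)
  }

  # --- session -------------------------------------------------------
  ds <- NULL
  run_stage("simulate", character(), function() {
    ds <<- if (is.null(cfg$session_path)) {
      sim <- cfg$sim
      sim$seed <- stage_seed(cfg$seed, "simulate")
      simulate_tuned_session(sim)
    } else {
      read_session(cfg$session_path)
    }
    write_session(ds, file.path(cfg$out_dir, "session"))
    ds
  })
  if (is.null(ds)) {
    if (!is.null(cfg$session_path)) {
      ds <- read_session(cfg$session_path)
    } else {
      summary_out <- list(seed = cfg$seed, status = status)
      jsonlite::write_json(summary_out, file.path(cfg$out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA)
      return(invisible(list(out_dir = cfg$out_dir, status = status,
                            results = results)))
    }
  }

  run_stage("pev", character(), function() {
    pev <- pev_timecourse(ds, width = cfg$decoder$width,
                          step = cfg$decoder$step,
                          seed = stage_seed(cfg$seed, "pev"))
    log_csv(pev, "pev")
    log_csv(pev_session_summary(pev)$timecourse, "pev_summary")
    pev
  })

  run_stage("decode", character(), function() {
    tc <- decode_timecourse(ds, cfg$decoder)
    log_csv(tc, "decode_timecourse")
    tc
  })

  conf <- NULL
  run_stage("states", character(), function() {
    locs <- sort(unique(ds$trials$cue_location_deg))
    pair <- if (length(locs) == 2) locs else {
      cand <- locs[(locs + 180) %% 360 %in% locs]
      if (!length(cand)) abort("no diametric location pair present")
      c(cand[1], (cand[1] + 180) %% 360)
    }
    conf <<- confidence_null(ds, pair = pair, cfg = cfg$decoder,
                             n_shuffles = cfg$n_state_shuffles,
                             seed = stage_seed(cfg$seed, "states"))
    labels <- label_states(conf)
    log_csv(as_tibble(labels), "state_labels")
    labels
  })

  run_stage("isi", character(), function() {
    pops <- select_populations(ds, min_n = cfg$min_population)
    if (nrow(pops) < 3) {
      inform(sprintf("only %d population(s) pass the size gate; regression needs >= 3",
                     nrow(pops)))
      log_csv(pops[, c("location_deg", "n_units")], "isi_populations")
      return(list(populations = pops, test = NULL))
    }
    emp <- purrr::map_dfr(pops$unit_ids, function(u) population_isi(ds, u))
    nulls <- do.call(rbind, purrr::imap(pops$unit_ids, function(u, i) {
      isi_shuffle_null(ds, u, n_iter = cfg$n_isi_iter,
                       seed = stage_seed(cfg$seed, paste0("isi", i)))$max_isi_s
    }))
    test <- isi_loglog_test(emp, nulls)
    log_csv(dplyr::bind_cols(pops[, c("location_deg", "n_units")], emp),
            "isi_populations")
    jsonlite::write_json(
      list(slope = test$slope, intercept = test$intercept,
           p_flatter = test$p_flatter, p_steeper = test$p_steeper),
      file.path(cfg$out_dir, "isi_test.json"), auto_unbox = TRUE, digits = NA)
    list(populations = pops, empirical = emp, test = test)
  })

  run_stage("mixture", "states", function() {
    delay <- epoch_interval("delay", ds$epochs)
    vals <- as.vector(conf$posterior)
    fit <- fit_beta_mixture(vals, seed = stage_seed(cfg$seed, "mixture"))
    jsonlite::write_json(as.list(glance(fit)),
                         file.path(cfg$out_dir, "beta_mixture.json"),
                         auto_unbox = TRUE, digits = NA)
    fit
  })

  run_stage("psd", "states", function() {
    labels <- results$states
    psd <- state_psd(labels, state = "off", bin_s = 0.05)
    log_csv(psd, "state_psd")
    psd
  })

  run_stage("rt", "states", function() {
    tab <- rt_state_table(ds, results$states)
    log_csv(tab, "rt_state")
    tab
  })

  summary_out <- list(
    seed = cfg$seed,
    stage_seeds = setNames(
      lapply(cfg$stages, function(s) stage_seed(cfg$seed, s)), cfg$stages),
    parameters = list(lambda = cfg$decoder$lambda,
                      n_state_shuffles = cfg$n_state_shuffles,
                      n_tuning_shuffles = cfg$n_tuning_shuffles,
                      n_isi_iter = cfg$n_isi_iter,
                      n_pseudo = cfg$n_pseudo,
                      min_population = cfg$min_population),
    status = status)
  jsonlite::write_json(summary_out, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  ok <- !any(grepl("^failed", unlist(status)))
  invisible(list(out_dir = cfg$out_dir, status = status, results = results,
                 ok = ok))
}
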