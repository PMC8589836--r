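# End-to-end synthetic pipeline: generate -> analyze -> report.

pipeline_stages <- c("synth", "stoich", "coordination", "engage", "trap", "kmc")

#' Default pipeline configuration
#'
#' A nested list configuring every stage of [run_pipeline()] at demo scale
#' (a full run takes tens of seconds). Stage blocks can be edited freely;
#' `stages` selects which stages run. The global `seed` is expanded into
#' fixed per-stage sub-seeds so that runs are reproducible stage by stage.
#'
#' @param seed Global seed.
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(seed = 1) {
  structure(list(
    stages = pipeline_stages,
    seed = as.integer(seed),
    synth = list(
      n_photobleach_traces = 60, label_prob = 0.66, doping_fraction = 0,
      photobleach_duration = 100, bleach_mean = 15, step_amplitude = 1,
      noise_sd = 1 / 3,
      n_engagement_traces = 20, engagement_duration = 240,
      n_extension_traces = 4
    ),
    stoich = list(candidate_n = 3:8, truncate_zero = TRUE,
                  min_amplitude = 0.5),
    coordination = list(k_min_true = 3, noise_sd = 0.03,
                        doping_grid = seq(0, 0.8, by = 0.2), n_rep = 3),
    engage = list(threshold_multiple = 3, orders = 1:3),
    trap = list(window = 0.1, n_screen_curves = 6),
    kmc = list(
      n_traj = 150,
      conditions = list(
        list(condition = "0_inactive", n_inactive = 0, p_pause_slip = 0.65),
        list(condition = "1_inactive", n_inactive = 1, p_pause_slip = 0.75),
        list(condition = "2_inactive", n_inactive = 2, p_pause_slip = 0.75)
      )
    )
  ), class = "run_config")
}

stage_seed <- function(config, stage) {
  # fixed offsets keep sub-seeds deterministic and below 2^31
  offs <- stats::setNames(seq_along(pipeline_stages) * 1000L, pipeline_stages)
  (config$seed %% 2000000000L) + offs[[stage]]
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the requested stages in order — synthetic data generation,
#' stoichiometry analysis, coordination-model fit, engagement-kinetics
#' analysis, trap-trace analysis, and the packaging simulation — writing
#' every stage's artifacts (TSV tables, JSON reports) under `out_dir` and
#' returning a summary with each stage's headline metrics. Identical
#' configurations and seeds give byte-identical summaries.
#'
#' Analysis stages consume the synthetic data produced by the `synth` stage
#' within the same run and fail with a dependency error if it is missing.
#'
#' @param config A [default_run_config()]-style list.
#' @param out_dir Output directory (created if needed).
#' @return The summary list, invisibly; also written as `summary.json`.
#' @export
run_pipeline <- function(config = default_run_config(),
                         out_dir = tempfile("motorlab_run_")) {
  unknown <- setdiff(config$stages, pipeline_stages)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown pipeline stage: %s", paste(unknown, collapse = ", ")))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(stages = config$stages, seed = config$seed)
  artifacts <- new.env(parent = emptyenv())

  need_synth <- function(what) {
    if (!exists(what, envir = artifacts)) {
      abort(sprintf("Dependency error: stage requires synth artifact `%s`; run the synth stage first.", what))
    }
    get(what, envir = artifacts)
  }

  for (stage in config$stages) {
    sd <- stage_seed(config, stage)
    summary[[stage]] <- switch(
      stage,
      synth = {
        sc <- config$synth
        comps <- sample_motor_composition(
          sc$n_photobleach_traces, sc$doping_fraction,
          label_prob = sc$label_prob, seed = sd
        )
        pb <- gen_photobleach_traces(
          comps, step_amplitude = sc$step_amplitude, noise_sd = sc$noise_sd,
          bleach_mean = sc$bleach_mean, duration = sc$photobleach_duration,
          seed = sd + 1L
        )
        eng <- gen_engagement_trajectory(
          engagement_kinetics(), duration = sc$engagement_duration,
          n_traces = sc$n_engagement_traces, seed = sd + 2L
        )
        ext <- gen_extension_trace(trap_sim_params(), n_traces = sc$n_extension_traces,
                                   seed = sd + 3L)
        assign("photobleach", pb, envir = artifacts)
        assign("engagement", eng, envir = artifacts)
        assign("extension", ext, envir = artifacts)
        write_trace_tsv(pb$traces, file.path(out_dir, "cy3_traces.tsv"))
        write_trace_tsv(dplyr::select(pb$truth, -"step_times"),
                        file.path(out_dir, "cy3_truth.tsv"))
        write_trace_tsv(eng$traces, file.path(out_dir, "cy5_traces.tsv"))
        write_trace_tsv(eng$events, file.path(out_dir, "cy5_events_truth.tsv"))
        write_trace_tsv(ext$traces, file.path(out_dir, "extension_traces.tsv"))
        write_trace_tsv(ext$pauses, file.path(out_dir, "pauses_truth.tsv"))
        jsonlite::write_json(sc, file.path(out_dir, "synth_config.json"),
                             auto_unbox = TRUE, digits = NA)
        list(
          n_photobleach_traces = nrow(pb$truth),
          n_engagement_traces = sc$n_engagement_traces,
          n_extension_traces = sc$n_extension_traces,
          n_engagement_events = nrow(eng$events)
        )
      },
      stoich = {
        pb <- need_synth("photobleach")
        sc <- config$stoich
        detectable <- pb$truth$trace_id[pb$truth$detectable]
        counts <- pb$traces |>
          dplyr::filter(.data$trace_id %in% detectable) |>
          dplyr::group_split(.data$trace_id) |>
          purrr::map_int(function(tr) {
            count_steps(nonlinear_fb_filter(tr),
                        min_amplitude = sc$min_amplitude)$n_steps
          })
        counts <- counts[counts > 0]
        fit <- fit_binomial_stoichiometry(counts, sc$candidate_n,
                                          sc$truncate_zero)
        write_trace_tsv(tibble(count = counts),
                        file.path(out_dir, "step_counts.tsv"))
        jsonlite::write_json(as.list(glance(fit)),
                             file.path(out_dir, "stoich_fit.json"),
                             auto_unbox = TRUE, digits = NA)
        list(n_hat = fit$n_hat, p_hat = fit$p_hat, n_traces = length(counts))
      },
      coordination = {
        sc <- config$coordination
        withr::with_seed(sd, {
          obs <- tidyr::expand_grid(rep = seq_len(sc$n_rep),
                                    doping_p = sc$doping_grid) |>
            dplyr::mutate(
              activity = pmin(1, pmax(0, predicted_activity(
                sc$k_min_true, .data$doping_p
              ) + stats::rnorm(dplyr::n(), sd = sc$noise_sd)))
            )
        })
        fit <- fit_kmin(obs)
        write_trace_tsv(activity_curves(), file.path(out_dir, "activity_curves.tsv"))
        write_trace_tsv(obs, file.path(out_dir, "activity_observations.tsv"))
        jsonlite::write_json(as.list(glance(fit)),
                             file.path(out_dir, "kmin_fit.json"),
                             auto_unbox = TRUE, digits = NA)
        list(k_min_true = sc$k_min_true, k_min_hat = fit$k_min)
      },
      engage = {
        eng <- need_synth("engagement")
        sc <- config$engage
        dur <- config$synth$engagement_duration
        events <- eng$traces |>
          dplyr::group_split(.data$trace_id) |>
          purrr::map(idealize_engagements,
                     threshold_multiple = sc$threshold_multiple) |>
          dplyr::bind_rows()
        freq <- engagement_frequencies(events, dur * length(unique(eng$traces$trace_id)))
        trans <- class_transition_matrix(events)
        gaps <- engagement_gap_times(events, dur)
        fit <- fit_exponential_mixture(gaps$gap_s, gaps$censored,
                                       candidate_orders = sc$orders)
        write_trace_tsv(events, file.path(out_dir, "cy5_events_detected.tsv"))
        write_trace_tsv(as_tibble(trans$probabilities, rownames = "from"),
                        file.path(out_dir, "transition_matrix.tsv"))
        jsonlite::write_json(as.list(glance(fit)),
                             file.path(out_dir, "gap_mixture_fit.json"),
                             auto_unbox = TRUE, digits = NA)
        list(
          n_events = nrow(events),
          tau_avg_s = fit$tau_avg,
          n_gap_components = fit$n_components,
          per_minute = stats::setNames(as.list(freq$per_minute),
                                       as.character(freq$class)),
          packaged_dna_total = count_packaged_dna(events)
        )
      },
      trap = {
        ext <- need_synth("extension")
        sc <- config$trap
        wlc <- wlc_params()
        # tether screening on synthetic force-extension curves
        withr::with_seed(sd, {
          fe_force <- seq(1, 10, by = 0.25)
          screens <- purrr::map_dfr(seq_len(sc$n_screen_curves), function(i) {
            off <- stats::runif(1, -150, 80)
            fe <- tibble(
              force_pN = fe_force,
              extension_nm = wlc$contour_length *
                wlc_relative_extension(fe_force, wlc) + off +
                stats::rnorm(length(fe_force), sd = 2)
            )
            dplyr::mutate(screen_tether(fe, wlc), true_offset_nm = off)
          })
        })
        metrics <- ext$traces |>
          dplyr::group_split(.data$trace_id) |>
          purrr::map_dfr(function(tr) {
            vel <- rolling_velocity(tr, window = sc$window, params = wlc)
            pauses <- detect_pauses(vel)
            dplyr::mutate(trace_metrics(tr, pauses, params = wlc),
                          trace_id = tr$trace_id[1])
          })
        write_trace_tsv(screens, file.path(out_dir, "tether_screening.tsv"))
        write_trace_tsv(metrics, file.path(out_dir, "trap_metrics.tsv"))
        jsonlite::write_json(
          list(
            mean_pause_free_velocity_bp_per_s = mean(metrics$pause_free_velocity_bp_s),
            mean_pause_frequency_per_kb = mean(metrics$pause_frequency_per_kb)
          ),
          file.path(out_dir, "trap_summary.json"), auto_unbox = TRUE, digits = NA
        )
        list(
          n_traces = nrow(metrics),
          n_tethers_accepted = sum(screens$accepted),
          mean_pause_free_velocity_bp_per_s = mean(metrics$pause_free_velocity_bp_s),
          mean_pause_frequency_per_kb = mean(metrics$pause_frequency_per_kb)
        )
      },
      kmc = {
        sc <- config$kmc
        res <- purrr::imap_dfr(sc$conditions, function(cond, i) {
          cfg <- sim_config(n_inactive = cond$n_inactive,
                            p_pause_slip = cond$p_pause_slip)
          out <- simulate_packaging(cfg, n_traj = sc$n_traj, seed = sd + i)
          out$condition <- cond$condition
          out
        })
        summ <- summarize_simulations(res)
        v0 <- summ$mean_velocity_success[summ$condition == "0_inactive"]
        doped <- res$outcome == "success" & res$condition != "0_inactive"
        ratio <- if (length(v0) == 1 && any(doped)) {
          v0 / mean(res$mean_velocity[doped])
        } else {
          NA_real_
        }
        write_trace_tsv(summ, file.path(out_dir, "kmc_summary.tsv"))
        list(
          conditions = summ$condition,
          success_fraction = summ$success_fraction,
          mean_velocity_success = summ$mean_velocity_success,
          velocity_ratio_0_vs_doped = ratio
        )
      }
    )
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
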