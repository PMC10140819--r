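# Orchestration: healthy -> disease population simulation, NCA, summaries
# and report output from a single configuration.

#' Default pipeline configuration
#'
#' @param n Population size per stage.
#' @param stages Disease stages to simulate.
#' @param routes Dosing routes (`"iv"`, `"oral"`).
#' @param dose_base Base dose, mg.
#' @param infusion_duration IV infusion duration, min.
#' @param times Output/NCA grid, h.
#' @param seed Root seed; all stage randomness is sub-seeded from it.
#' @param female_fraction,age_range,weight_range,variability_cv Population
#'   spec arguments (see [population_spec()]).
#' @param drug_path Drug YAML path.
#' @param scaler_path Disease-scaler YAML path.
#' @param GFR_reference Healthy reference GFR for renal-clearance scaling.
#' @param eq_form Intrinsic-clearance back-calculation form (`NULL`: drug
#'   file default).
#' @param n_boot Bootstrap resamples for median CIs.
#' @param out_dir Optional output directory for CSV/JSON reports.
#' @return A `run_config` list.
#' @export
run_config <- function(n = 100,
                       stages = .DISEASE_STAGES,
                       routes = c("iv", "oral"),
                       dose_base = 155,
                       infusion_duration = 30,
                       times = seq(0, 72, by = 0.25),
                       seed = 1L,
                       female_fraction = 0.6,
                       age_range = c(19, 27),
                       weight_range = c(55, 68),
                       variability_cv = list(),
                       drug_path = hcq_extdata("hydroxychloroquine.yaml"),
                       scaler_path = hcq_extdata("disease_scalers.yaml"),
                       GFR_reference = 90,
                       eq_form = NULL,
                       n_boot = 1000,
                       out_dir = NULL) {
  stopifnot(all(stages %in% .DISEASE_STAGES), all(routes %in% c("iv", "oral")))
  structure(as.list(environment()), class = "run_config")
}

#' Run the full simulation-and-evaluation pipeline
#'
#' Builds a healthy virtual population, applies each disease stage's
#' physiology scaling, simulates every individual under each route,
#' runs NCA, and summarises each stage/route by median AUC0-t with a
#' seeded bootstrap CI plus a VPC envelope.  Percent changes versus the
#' healthy stage are computed from the simulated medians.  With
#' `out_dir` set, writes `population.csv`, `nca.csv`, `summaries.csv`,
#' `percent_changes.csv`, envelope CSVs and a `manifest.json` recording
#' every parameter and seed used.
#'
#' @param config A [run_config()].
#' @return List with `summaries` (data frame), `percent_changes`,
#'   `envelopes` (named list), `nca` (per-subject data frame),
#'   `population` (data frame), `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  drug <- load_drug_parameters(config$drug_path)
  scalers <- load_disease_scalers(config$scaler_path)

  spec <- population_spec(n = config$n,
                          female_fraction = config$female_fraction,
                          age_range = config$age_range,
                          weight_range = config$weight_range,
                          variability_cv = config$variability_cv,
                          seed = sub_seed(config$seed, "population"))
  healthy_pop <- sample_population(spec)

  regimens <- list()
  if ("iv" %in% config$routes) {
    regimens$iv <- dosing_regimen("iv_infusion", config$dose_base,
                                  infusion_duration = config$infusion_duration,
                                  times = config$times)
  }
  if ("oral" %in% config$routes) {
    regimens$oral <- dosing_regimen("oral", config$dose_base,
                                    dissolution_time = drug$formulation$dissolution_time_min,
                                    lag_time = drug$formulation$lag_time_min,
                                    release_cap = drug$formulation$release_cap,
                                    times = config$times)
  }

  summaries <- list()
  envelopes <- list()
  nca_rows <- list()
  for (stage in config$stages) {
    dspec <- disease_spec(stage, scalers)
    pop <- lapply(healthy_pop, apply_disease, disease = dspec)
    for (route in names(regimens)) {
      profiles <- lapply(pop, function(phys) {
        sys <- build_ode_system(phys, drug, regimen = regimens[[route]])
        simulate_profile(sys)
      })
      ncas <- lapply(profiles, run_nca, dose_base = config$dose_base)
      key <- paste(stage, route, sep = "/")
      summaries[[key]] <- summarize_population_auc(
        ncas, stage = stage, route = route, n_boot = config$n_boot,
        seed = sub_seed(config$seed, key))
      envelopes[[key]] <- vpc_envelope(profiles)
      nca_rows[[key]] <- data.frame(
        stage = stage, route = route,
        subject_id = vapply(pop, `[[`, character(1), "subject_id"),
        Cmax = vapply(ncas, `[[`, numeric(1), "Cmax"),
        Tmax = vapply(ncas, `[[`, numeric(1), "Tmax"),
        AUC0_t = vapply(ncas, `[[`, numeric(1), "AUC0_t"),
        AUC0_inf = vapply(ncas, `[[`, numeric(1), "AUC0_inf"),
        CL = vapply(ncas, `[[`, numeric(1), "CL"),
        stringsAsFactors = FALSE
      )
    }
  }

  summary_df <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(stage = s$stage, route = s$route, n = s$n,
               median_AUC0_t = s$median_AUC0_t,
               ci95_low = s$ci95_low, ci95_high = s$ci95_high,
               p5 = s$p5, p95 = s$p95, stringsAsFactors = FALSE)
  }))
  rownames(summary_df) <- NULL

  pct <- NULL
  if ("healthy" %in% config$stages && length(config$stages) > 1) {
    pct <- do.call(rbind, lapply(names(regimens), function(route) {
      d <- summary_df[summary_df$route == route, ]
      healthy_med <- d$median_AUC0_t[d$stage == "healthy"]
      dd <- d[d$stage != "healthy", ]
      if (!nrow(dd)) return(NULL)
      data.frame(stage = dd$stage, route = route,
                 percent_change = percent_change(healthy_med, dd$median_AUC0_t),
                 stringsAsFactors = FALSE)
    }))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("hcqpbpk")),
    seed = config$seed,
    sub_seeds = c(population = sub_seed(config$seed, "population"),
                  setNames(vapply(names(summaries), function(k)
                    sub_seed(config$seed, k), integer(1)), names(summaries))),
    config = config[setdiff(names(config), "out_dir")],
    drug = unclass(drug)
  )

  report <- list(summaries = summary_df, percent_changes = pct,
                 envelopes = envelopes,
                 nca = do.call(rbind, c(nca_rows, list(make.row.names = FALSE))),
                 population = population_to_df(healthy_pop),
                 manifest = manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(report$population, file.path(config$out_dir, "population.csv"),
              row.names = FALSE)
    write.csv(report$nca, file.path(config$out_dir, "nca.csv"), row.names = FALSE)
    write.csv(report$summaries, file.path(config$out_dir, "summaries.csv"),
              row.names = FALSE)
    if (!is.null(report$percent_changes)) {
      write.csv(report$percent_changes,
                file.path(config$out_dir, "percent_changes.csv"),
                row.names = FALSE)
    }
    for (key in names(envelopes)) {
      write.csv(envelopes[[key]],
                file.path(config$out_dir,
                          paste0("vpc_", gsub("/", "_", key), ".csv")),
                row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}

#' Plot a VPC envelope
#'
#' Visual predictive check: simulated mean, min/max and 5th-95th
#' percentile band, optionally overlaid with observed points.  Requires
#' ggplot2.
#'
#' @param envelope Data frame from [vpc_envelope()].
#' @param observed Optional profile with `time_h`, `conc_ng_per_ml`.
#' @param log_y Log-scale concentration axis.
#' @return A ggplot object.
#' @export
plot_vpc <- function(envelope, observed = NULL, log_y = TRUE) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  gg <- ggplot2::ggplot(envelope, ggplot2::aes(x = .data$time_h)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p5, ymax = .data$p95),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), color = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$min), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$max), linetype = "dashed") +
    ggplot2::labs(x = "time (h)", y = "whole-blood concentration (ng/mL)")
  if (!is.null(observed)) {
    gg <- gg + ggplot2::geom_point(
      data = observed, ggplot2::aes(x = .data$time_h, y = .data$conc_ng_per_ml),
      color = "red")
  }
  if (log_y) gg <- gg + ggplot2::scale_y_log10()
  gg
}
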