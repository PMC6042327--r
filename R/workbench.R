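# Virtual-experiment workbench: generates open and scenario (open/closed/
# mixed) dimer ensembles, simulates and analyzes the four data types (SAXS,
# EOM, NMR relaxation, DEER), and evaluates the cross-technique closed-state
# signatures: (1) a more pronounced inter-domain P(r) peak, (2) EOM-selected
# ensemble Rg below the pool mean, (3) a larger central-domain correlation
# time, (4) a shorter C-proximal interspin DEER mode.

#' Default virtual-experiment configuration
#'
#' All stochastic stages carry explicit seeds; pool sizes and GA settings are
#' desk-scale (documented in the methods vignette) and can be raised to
#' study scale in the config.
#'
#' @param scenario `"open"`, `"closed"` or `"mixed"`.
#' @param seed base seed from which all stage seeds are derived.
#' @param n_per_state conformers per ensemble.
#' @param mixed_fraction closed fraction when `scenario = "mixed"`.
#' @return named list, the `experiment_config`.
#' @export
default_experiment_config <- function(scenario = "closed", seed = 1,
                                      n_per_state = 50,
                                      mixed_fraction = 0.5) {
  list(
    scenario = scenario,
    mixed_fraction = mixed_fraction,
    n_per_state = n_per_state,
    seed_pool_open = seed_stream(seed, 101),
    seed_pool_scenario = seed_stream(seed, 202),
    seed_saxs = seed_stream(seed, 303),
    seed_eom = seed_stream(seed, 404),
    seed_nmr_open = seed_stream(seed, 505),
    seed_nmr_scenario = seed_stream(seed, 506),
    seed_deer_open = seed_stream(seed, 606),
    seed_deer_scenario = seed_stream(seed, 607),
    seed_ms = seed_stream(seed, 707),
    saxs = list(s_min = 0.07, s_max = 4.8, n_s = 120, noise_frac = 0.01),
    eom = list(ensemble_size = 15, population = 60, generations = 60,
               mutation = 0.05, elitism = 6, rg_margin_sd = 0.5),
    nmr = list(nu_N_hz = 70.94e6, noise_sd = 0.03,
               tc_open = list(NT = 10.5, TPR = 9.5),
               tc_closed = list(NT = 10.5, TPR = 12),
               nt_range = c(5, 65), tpr_range = c(87, 206),
               tc_ratio_threshold = 1.05),
    deer = list(site = 197, lambda = 0.3, bg_k = 0.05, snr = 30,
                alpha = 2, kde_bw = 0.3,
                r_min = 1.5, r_max = 10, n_r = 201, mode_margin_nm = 0.1),
    ms = list(monomer_mass_da = 34000, adduct_da = 359, adduct_rungs = 4,
              mz_noise_ppm = 10),
    pofr = list(peak_window_nm = c(2, 8), peak_ratio_threshold = 1.1),
    output_dir = NULL
  )
}

#' @keywords internal
validate_experiment_config <- function(config) {
  known <- names(default_experiment_config())
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(known, names(config))
  if (length(missing) > 0) {
    stop("missing config keys: ", paste(missing, collapse = ", "))
  }
  stopifnot(config$scenario %in% c("open", "closed", "mixed"))
  seeds <- grep("^seed_", names(config), value = TRUE)
  if (any(!vapply(config[seeds], is.numeric, logical(1)))) {
    stop("every stage seed must be numeric")
  }
  invisible(TRUE)
}

#' Read an experiment config from YAML
#'
#' Unknown keys are rejected; required keys must all be present (start from
#' [default_experiment_config()] and override).
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
read_experiment_config <- function(path) {
  cfg <- utils::modifyList(default_experiment_config(), yaml::read_yaml(path))
  validate_experiment_config(cfg)
  cfg
}

#' @keywords internal
config_hash <- function(config) {
  cfg <- config
  cfg$output_dir <- NULL
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' @keywords internal
ensemble_distance_distribution <- function(pool, site, r_grid, bw = 0.3) {
  d <- vapply(pool$conformers, interlabel_distance, numeric(1), site = site)
  P <- vapply(r_grid, function(r) mean(stats::dnorm(r, d, bw)), numeric(1))
  distance_distribution(r_grid, pmax(P, 0) + 1e-12)
}

#' @keywords internal
pofr_packing_peak <- function(pofr_obj, window) {
  # peak density of the unit-area p(r) inside the domain-packing window: a
  # closed, well-organized dimer concentrates pair distances there, raising
  # the peak relative to the smeared open ensemble
  r <- pofr_obj$r
  p <- pofr_obj$p / sum(trapz_weights(r) * pofr_obj$p)
  max(p[r >= window[1] & r <= window[2]])
}

#' Run the virtual open-versus-closed experiment
#'
#' Generates a baseline open ensemble and a scenario ensemble, pushes both
#' through the four forward models and analyses, and evaluates the four
#' closed-state signatures for the scenario-versus-baseline comparison. Any
#' stage failure halts with the stage named; results of completed stages are
#' retained in the error condition.
#'
#' @param config an experiment config (see [default_experiment_config()]).
#' @return object of class `experiment_report`.
#' @export
run_virtual_experiment <- function(config = default_experiment_config()) {
  validate_experiment_config(config)
  arch <- sgta_architecture()
  frac <- switch(config$scenario, open = 0, closed = 1,
                 mixed = config$mixed_fraction)
  stages <- list()
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      stop(errorCondition(
        paste0("stage '", name, "' failed: ", conditionMessage(e)),
        class = c("stage_failure", "error"),
        stage = name, partial = stages))
    })
    stages[[name]] <<- res
    res
  }

  pools <- run_stage("ensembles", function() {
    list(open = generate_pool(arch, config$n_per_state, 0,
                              config$seed_pool_open),
         scenario = generate_pool(arch, config$n_per_state, frac,
                                  config$seed_pool_scenario))
  })

  saxs_res <- run_stage("saxs", function() {
    sx <- config$saxs
    s_grid <- seq(sx$s_min, sx$s_max, length.out = sx$n_s)
    curves <- lapply(pools, function(p) pool_curves(p, s_grid))
    avg <- lapply(curves, function(cm) scattering_curve(s_grid, colMeans(cm)))
    noisy <- list(
      open = perturb_curve(avg$open, sx$noise_frac,
                           seed_stream(config$seed_saxs, 1)),
      scenario = perturb_curve(avg$scenario, sx$noise_frac,
                               seed_stream(config$seed_saxs, 2)))
    dmax <- lapply(pools, function(p)
      1.05 * max(vapply(p$conformers,
                        function(m) max(stats::dist(bm_coords(m))),
                        numeric(1))))
    pofrs <- list(open = ift_pofr(noisy$open, dmax$open),
                  scenario = ift_pofr(noisy$scenario, dmax$scenario))
    guiniers <- lapply(noisy, guinier_fit)
    ratio <- lapply(pofrs, pofr_packing_peak,
                    window = config$pofr$peak_window_nm)
    list(curves = curves, data = noisy, pofr = pofrs, guinier = guiniers,
         peak_ratio = ratio, s_grid = s_grid)
  })

  eom_res <- run_stage("eom", function() {
    eo <- config$eom
    pool_all_curves <- rbind(saxs_res$curves$open, saxs_res$curves$scenario)
    pool_all_rg <- c(pools$open$rg, pools$scenario$rg)
    fit <- eom_select(pool_all_curves, saxs_res$data$scenario,
                      ensemble_size = eo$ensemble_size,
                      ga = list(population = eo$population,
                                generations = eo$generations,
                                mutation = eo$mutation, elitism = eo$elitism),
                      rng_seed = config$seed_eom, pool_rg = pool_all_rg)
    list(fit = fit, rg_pool_mean = mean(pool_all_rg),
         rg_pool_sd = stats::sd(pool_all_rg),
         rg_selected_mean = mean(fit$rg_selected))
  })

  nmr_res <- run_stage("nmr", function() {
    nm <- config$nmr
    one <- function(tc_map, seed) {
      doms <- list(list(name = "NT", range = nm$nt_range, tc_ns = tc_map$NT),
                   list(name = "TPR", range = nm$tpr_range, tc_ns = tc_map$TPR))
      ds <- simulate_relaxation_dataset(doms, nm$nu_N_hz, nm$noise_sd, seed)
      f1 <- fit_relaxation_set(ds$t1); f2 <- fit_relaxation_set(ds$t2)
      list(NT = summarize_domain(f1, f2, nm$nt_range, nm$nu_N_hz, "NT"),
           TPR = summarize_domain(f1, f2, nm$tpr_range, nm$nu_N_hz, "TPR"))
    }
    tc_scen <- if (config$scenario == "open") nm$tc_open else nm$tc_closed
    list(open = one(nm$tc_open, config$seed_nmr_open),
         scenario = one(tc_scen, config$seed_nmr_scenario))
  })

  deer_res <- run_stage("deer", function() {
    de <- config$deer
    r_grid <- seq(de$r_min, de$r_max, length.out = de$n_r)
    one <- function(pool, seed) {
      P <- ensemble_distance_distribution(pool, de$site, r_grid, de$kde_bw)
      tr <- simulate_trace(P, bg = list(k = de$bg_k, lambda = de$lambda),
                           noise_sd = 1 / de$snr, rng_seed = seed)
      an <- deer_analyze(tr, r_grid, alpha = de$alpha)
      main <- an$stats[which.max(an$stats$mass), , drop = FALSE]
      list(truth = P, analysis = an, main_mode = main$mode,
           main_mean = main$mean)
    }
    list(open = one(pools$open, config$seed_deer_open),
         scenario = one(pools$scenario, config$seed_deer_scenario))
  })

  ms_res <- run_stage("ms", function() {
    msx <- config$ms
    dimer <- 2 * msx$monomer_mass_da
    has_ladder <- config$scenario != "open"
    species <- if (has_ladder) {
      data.frame(mass_da = dimer + (0:msx$adduct_rungs) * msx$adduct_da,
                 abundance = c(5, 4, 3, 2, 1)[seq_len(msx$adduct_rungs + 1)])
    } else {
      data.frame(mass_da = dimer, abundance = 5)
    }
    pk <- simulate_spectrum(species, mz_noise_ppm = msx$mz_noise_ppm,
                            rng_seed = config$seed_ms)
    rep <- ms_analyze(pk, msx$monomer_mass_da)
    list(report = rep,
         dimer_assigned = any(rep$oligomers$n_mer == 2, na.rm = TRUE),
         ladder_expected = has_ladder,
         ladder_found = !is.null(rep$ladder))
  })

  # ---- signatures ----------------------------------------------------------
  sig <- list(
    pofr_peak = list(
      metric_scenario = saxs_res$peak_ratio$scenario,
      metric_open = saxs_res$peak_ratio$open,
      pass = saxs_res$peak_ratio$scenario >
        config$pofr$peak_ratio_threshold * saxs_res$peak_ratio$open),
    eom_rg = list(
      metric_scenario = eom_res$rg_selected_mean,
      metric_open = eom_res$rg_pool_mean,
      pass = eom_res$rg_pool_mean - eom_res$rg_selected_mean >
        config$eom$rg_margin_sd * eom_res$rg_pool_sd),
    tpr_tc = list(
      metric_scenario = nmr_res$scenario$TPR$tc_ns,
      metric_open = nmr_res$open$TPR$tc_ns,
      pass = nmr_res$scenario$TPR$tc_ns >
        config$nmr$tc_ratio_threshold * nmr_res$open$TPR$tc_ns),
    deer_mode = list(
      metric_scenario = deer_res$scenario$main_mode,
      metric_open = deer_res$open$main_mode,
      pass = deer_res$scenario$main_mode <
        deer_res$open$main_mode - config$deer$mode_margin_nm)
  )
  report <- structure(list(
    scenario = config$scenario,
    config = config,
    config_hash = config_hash(config),
    version = as.character(utils::packageVersion("sgtadimer")),
    signatures = sig,
    results = list(
      saxs = list(
        guinier_rg = lapply(saxs_res$guinier, `[[`, "rg"),
        pofr_rg = lapply(saxs_res$pofr, `[[`, "rg"),
        pofr_dmax = lapply(saxs_res$pofr, `[[`, "dmax"),
        peak_ratio = saxs_res$peak_ratio),
      eom = list(chi2 = eom_res$fit$chi2,
                 rg_pool_mean = eom_res$rg_pool_mean,
                 rg_pool_sd = eom_res$rg_pool_sd,
                 rg_selected_mean = eom_res$rg_selected_mean),
      nmr = lapply(nmr_res, function(x) list(
        NT_tc_ns = x$NT$tc_ns, TPR_tc_ns = x$TPR$tc_ns,
        NT_n = x$NT$n, TPR_n = x$TPR$n)),
      deer = lapply(deer_res, function(x) list(
        main_mode_nm = x$main_mode,
        lambda = x$analysis$evolution$lambda)),
      ms = list(dimer_assigned = ms_res$dimer_assigned,
                ladder_expected = ms_res$ladder_expected,
                ladder_found = ms_res$ladder_found,
                ladder_increment_da = if (!is.null(ms_res$report$ladder))
                  ms_res$report$ladder$increment_da else NULL)
    ),
    pools = list(rg_open = pools$open$rg, rg_scenario = pools$scenario$rg)
  ), class = "experiment_report")
  if (!is.null(config$output_dir)) {
    write_report(report, file.path(config$output_dir, "report.json"))
  }
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Virtual experiment:", x$scenario, "vs open baseline (hash",
      substr(x$config_hash, 1, 8), ")\n")
  for (nm in names(x$signatures)) {
    s <- x$signatures[[nm]]
    cat(sprintf("  %-10s scenario %7.3f  open %7.3f  %s\n", nm,
                s$metric_scenario, s$metric_open,
                if (s$pass) "PASS" else "-"))
  }
  invisible(x)
}

#' Serialize an experiment report to JSON
#'
#' Reports regenerate byte-identically from the same config and seeds: the
#' JSON rendering is fully deterministic (full-precision numbers, fixed key
#' order).
#'
#' @param report an `experiment_report`.
#' @param path output file.
#' @export
write_report <- function(report, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  out <- report
  out$config$output_dir <- NULL
  json <- jsonlite::toJSON(unclass(out), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Compare two experiment reports
#'
#' @param report_a,report_b `experiment_report` objects from the same
#'   architecture/config family.
#' @return data frame with per-signature metrics of both reports, deltas, and
#'   pass flags.
#' @export
compare_reports <- function(report_a, report_b) {
  if (!identical(names(report_a$signatures), names(report_b$signatures))) {
    stop("reports have mismatched signature sets")
  }
  if (!identical(report_a$config$n_per_state, report_b$config$n_per_state)) {
    stop("reports come from different ensemble architectures/sizes")
  }
  do.call(rbind, lapply(names(report_a$signatures), function(nm) {
    a <- report_a$signatures[[nm]]; b <- report_b$signatures[[nm]]
    data.frame(signature = nm,
               a_scenario = a$metric_scenario, b_scenario = b$metric_scenario,
               delta_scenario = a$metric_scenario - b$metric_scenario,
               a_pass = a$pass, b_pass = b$pass)
  }))
}
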