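#' Default run configuration
#'
#' All tunables of the simulation/analysis pipeline in one serializable
#' list: generator parameter sets (non-permeant and permeant presets),
#' protocol settings, analysis options (threshold factor, windows, model
#' orders, bootstrap settings) and the seed. Saved alongside every
#' [run_pipeline()] output, so a run is reproducible from its artifacts.
#'
#' @param ... Named overrides merged (recursively) into the defaults.
#' @return A named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    blocker = "naspm", # "naspm" (non-permeant) or "spermine" (permeant)
    concentration_uM = 100,
    gating = list(), # overrides for gating_params()
    ramp = list(sample_rate = 2, from = -80, to = 60, speed = 100, noise_sd = 5, leak_g = 1),
    step = list(sample_rate = 20, glu_onset = 20, pulse_length = 100, noise_sd = 0),
    mepsc = list(
      sample_rate = 20, duration_ms = 40000, noise_sd = 3.5,
      event_rate_hz = 5, mean_amp_pA = 36, amp_cv = 0.3, tau_r = 0.2, tau_d = 1.2
    ),
    analysis = list(
      threshold_factor = 2.5, ri_window = 15, exclude_mV = 5,
      decay_components = "auto", bootstrap_n = 5000
    )
  )
  utils::modifyList(cfg, list(...))
}

blocker_preset <- function(cfg) {
  fun <- switch(cfg$blocker,
    naspm = naspm_params,
    spermine = spermine_params,
    stop("unknown blocker preset: ", cfg$blocker)
  )
  fun(concentration = cfg$concentration_uM)
}

read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  utils::modifyList(default_config(), config)
}

log_line <- function(dir, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%OS3"), paste0(...))
  cat(msg, "\n", sep = "", file = file.path(dir, "run.log"), append = TRUE)
  invisible(msg)
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
}

#' Run a simulation/analysis pipeline stage
#'
#' Ties the simulator and the analysis layers into reproducible,
#' file-to-file runs. Every invocation writes its outputs (CSV tables and
#' JSON summaries), the fully resolved configuration, the package version
#' and a log of seeds into `out_dir`, so identical config + seed reproduce
#' identical artifacts for the deterministic stages. A failing sweep is
#' logged and skipped rather than aborting the run.
#'
#' Subcommands: `simulate` writes ramp/step/mEPSC sweep files; `ramp` runs
#' leak subtraction, RI, reversal, G-V and Boltzmann fitting on a ramp set;
#' `steps` measures peak/steady and decay kinetics across voltages; `mepsc`
#' runs noise calibration, detection, QC, averaging and the
#' frequency-weighted RI; `eepsc` averages stimulus-locked responses and
#' fits the peak I-V; `potency` fits Vb against log concentration;
#' `stats` compares two CSV columns (Welch t, mean difference, BCa CI);
#' `figures` regenerates the ramp I-V, Vb-concentration, step G-V, recovery
#' and mEPSC-RI summary tables from simulated inputs.
#'
#' @param config A config list (see [default_config()]) or a path to a YAML
#'   file of overrides.
#' @param subcommand One of `"simulate"`, `"ramp"`, `"steps"`, `"mepsc"`,
#'   `"eepsc"`, `"potency"`, `"stats"`, `"figures"`.
#' @param out_dir Output directory (created if missing).
#' @param input_dir Directory of sweep files for analysis subcommands;
#'   defaults to `out_dir` (i.e. analyze what `simulate` wrote there).
#' @return The output directory, invisibly; summaries are also returned as
#'   the attribute `"summary"`.
#' @export
run_pipeline <- function(config = default_config(),
                         subcommand = c(
                           "simulate", "ramp", "steps", "mepsc", "eepsc",
                           "potency", "stats", "figures"
                         ),
                         out_dir = tempfile("polyblock_run_"),
                         input_dir = out_dir) {
  subcommand <- match.arg(subcommand)
  cfg <- read_config(if (is.list(config)) config else config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_json_out(
    list(
      config = cfg,
      package_version = as.character(utils::packageVersion("polyblock")),
      subcommand = subcommand
    ),
    file.path(out_dir, paste0(subcommand, "_config.json"))
  )
  log_line(out_dir, "subcommand=", subcommand, " seed=", cfg$seed)
  summary <- switch(subcommand,
    simulate = stage_simulate(cfg, out_dir),
    ramp = stage_ramp(cfg, out_dir, input_dir),
    steps = stage_steps(cfg, out_dir),
    mepsc = stage_mepsc(cfg, out_dir),
    eepsc = stage_eepsc(cfg, out_dir),
    potency = stage_potency(cfg, out_dir),
    stats = stage_stats(cfg, out_dir),
    figures = stage_figures(cfg, out_dir)
  )
  write_json_out(summary, file.path(out_dir, paste0(subcommand, "_summary.json")))
  structure(invisible(out_dir), summary = summary)
}

sim_objects <- function(cfg) {
  gating <- do.call(gating_params, cfg$gating %||% list())
  block <- blocker_preset(cfg)
  ramp_proto <- protocol_spec("ramp",
    sample_rate = cfg$ramp$sample_rate, ramp_from = cfg$ramp$from,
    ramp_to = cfg$ramp$to, ramp_speed = cfg$ramp$speed,
    noise_sd = cfg$ramp$noise_sd, leak_g = cfg$ramp$leak_g, seed = cfg$seed
  )
  list(gating = gating, block = block, ramp_proto = ramp_proto)
}

stage_simulate <- function(cfg, out_dir) {
  so <- sim_objects(cfg)
  pair <- simulate_ramp_pair(so$gating, so$block, so$ramp_proto)
  write_sweep(pair$control, file.path(out_dir, "ramp_control.tsv"))
  write_sweep(pair$agonist, file.path(out_dir, "ramp_agonist.tsv"))
  free <- simulate_ramp_pair(so$gating, block_params(0, 0, 0), so$ramp_proto)
  write_sweep(free$agonist, file.path(out_dir, "ramp_agonist_free.tsv"))
  write_sweep(free$control, file.path(out_dir, "ramp_control_free.tsv"))
  list(files = list.files(out_dir, pattern = "[.]tsv$"), seed = cfg$seed)
}

stage_ramp <- function(cfg, out_dir, input_dir) {
  read_pair <- function(stem) {
    list(
      control = read_sweep(file.path(input_dir, paste0("ramp_control", stem, ".tsv"))),
      agonist = read_sweep(file.path(input_dir, paste0("ramp_agonist", stem, ".tsv")))
    )
  }
  pair <- read_pair("")
  iv <- sweep_to_iv(leak_subtract(pair$agonist, pair$control))
  ri <- rectification_index_ramp(iv, window = cfg$analysis$ri_window)
  vr <- tryCatch(reversal_potential(iv), error = function(e) NULL)
  free_ref <- NULL
  if (file.exists(file.path(input_dir, "ramp_agonist_free.tsv"))) {
    fp <- read_pair("_free")
    ivf <- sweep_to_iv(leak_subtract(fp$agonist, fp$control))
    vrf <- reversal_potential(ivf)
    # a deeply blocked curve can lack a usable crossing; fall back to the
    # polyamine-free reversal
    if (is.null(vr)) vr <- vrf
    free_ref <- raw_conductance_curve(ivf, vrf, exclude_mV = cfg$analysis$exclude_mV)
  }
  if (is.null(vr)) stop("no usable reversal potential in the ramp set")
  gv <- conductance_curve(iv, vr,
    free_reference = free_ref,
    exclude_mV = cfg$analysis$exclude_mV
  )
  utils::write.csv(
    data.frame(voltage_mV = gv$voltages, conductance = gv$conductances),
    file.path(out_dir, "gv_curve.csv"),
    row.names = FALSE
  )
  fit <- tryCatch(fit_boltzmann(gv, "single"), error = function(e) NULL)
  list(
    ri = ri, v_rev = vr,
    boltzmann = if (is.null(fit)) {
      list(converged = FALSE)
    } else {
      list(converged = TRUE, g_max = fit$g_max, v_b = fit$v_b, k_b = fit$k_b, rss = fit$rss)
    }
  )
}

stage_steps <- function(cfg, out_dir, voltages = c(-60, 60)) {
  so <- sim_objects(cfg)
  proto <- protocol_spec("step",
    sample_rate = cfg$step$sample_rate, glu_onset = cfg$step$glu_onset,
    pulse_length = cfg$step$pulse_length, noise_sd = cfg$step$noise_sd,
    seed = cfg$seed
  )
  rows <- list()
  sweeps <- list()
  for (vm in voltages) {
    sw <- tryCatch(simulate_step_response(so$gating, so$block, proto, vm),
      error = function(e) NULL
    )
    if (is.null(sw)) {
      log_line(out_dir, "step at ", vm, " mV failed; skipped")
      next
    }
    ps <- peak_and_steady(sw)
    sweeps[[as.character(vm)]] <- sw
    rows[[length(rows) + 1]] <- data.frame(
      voltage_mV = vm, peak_pA = ps[["peak"]], steady_pA = ps[["steady"]]
    )
  }
  tab <- do.call(rbind, rows)
  prof <- decay_voltage_profile(sweeps, n_components = cfg$analysis$decay_components)
  utils::write.csv(merge(tab, prof, by = "voltage_mV"),
    file.path(out_dir, "step_kinetics.csv"),
    row.names = FALSE
  )
  list(n_voltages = nrow(tab), failures = length(voltages) - nrow(tab))
}

mepsc_pipeline <- function(gating, block, cfg, seed) {
  m <- cfg$mepsc
  amp <- list(mean_pA = m$mean_amp_pA, cv = m$amp_cv, tau_r = m$tau_r, tau_d = m$tau_d)
  proto_at <- function(vm, s) {
    protocol_spec("mepsc",
      sample_rate = m$sample_rate, duration = m$duration_ms,
      hold_voltages = vm, noise_sd = m$noise_sd, seed = s
    )
  }
  rec_neg <- simulate_mepsc_recording(gating, block, proto_at(-60, seed), m$event_rate_hz, amp)
  rec_pos <- simulate_mepsc_recording(gating, block, proto_at(60, seed + 1), m$event_rate_hz, amp)
  # noise calibrated at +60 mV; the same threshold used at both voltages
  sigma <- noise_sd(rec_pos$sweep, t_range = c(0, 500))
  thr <- cfg$analysis$threshold_factor * sigma
  tr_neg <- detect_events(rec_neg$sweep, thr, tau_d = m$tau_d)
  tr_pos <- detect_events(rec_pos$sweep, thr, tau_d = m$tau_d)
  qc <- qc_record(tr_neg)
  mean_neg <- if (nrow(tr_neg$events)) average_events(tr_neg, rec_neg$sweep) else NULL
  mean_pos <- if (nrow(tr_pos$events)) average_events(tr_pos, rec_pos$sweep) else NULL
  ri <- if (is.null(mean_neg)) NULL else ri_mepsc(mean_neg, tr_neg$frequency_hz, mean_pos, tr_pos$frequency_hz)
  list(
    sigma = sigma, threshold = thr, qc = qc,
    train_neg = tr_neg, train_pos = tr_pos,
    mean_neg = mean_neg, mean_pos = mean_pos, ri = ri,
    ground_truth = list(neg = rec_neg$ground_truth, pos = rec_pos$ground_truth)
  )
}

stage_mepsc <- function(cfg, out_dir) {
  so <- sim_objects(cfg)
  res <- mepsc_pipeline(so$gating, so$block, cfg, cfg$seed)
  utils::write.csv(res$train_neg$events, file.path(out_dir, "events_neg60.csv"), row.names = FALSE)
  utils::write.csv(res$train_pos$events, file.path(out_dir, "events_pos60.csv"), row.names = FALSE)
  if (!is.null(res$mean_neg)) {
    utils::write.csv(res$mean_neg$waveform, file.path(out_dir, "mean_event_neg60.csv"),
      row.names = FALSE
    )
  }
  list(
    noise_sd_pA = res$sigma, threshold_pA = res$threshold,
    qc_pass = res$qc$pass,
    frequency_neg_hz = res$train_neg$frequency_hz,
    frequency_pos_hz = res$train_pos$frequency_hz,
    ri = if (is.null(res$ri)) NA else res$ri$ri
  )
}

stage_eepsc <- function(cfg, out_dir, voltages = c(-60, 60), n_stim = 20) {
  so <- sim_objects(cfg)
  m <- cfg$mepsc
  stim_times <- seq(50, by = 50, length.out = n_stim)
  dur <- max(stim_times) + 50
  amp <- list(mean_pA = 80, cv = 0.2, tau_r = m$tau_r, tau_d = m$tau_d)
  sweeps <- lapply(voltages, function(vm) {
    proto <- protocol_spec("mepsc",
      sample_rate = m$sample_rate, duration = dur,
      hold_voltages = vm, noise_sd = m$noise_sd, seed = cfg$seed + round(vm)
    )
    rec <- simulate_mepsc_recording(so$gating, so$block, proto, event_rate = 0, amp_params = amp)
    sw <- rec$sweep
    # deterministic stimulus-locked responses on top of the noise
    u <- equilibrium_unblocked_fraction(so$block, vm)
    scale <- if (vm == -60) -1 else sign(vm - so$gating$v_rev) * u * abs((vm - so$gating$v_rev) / (-60 - so$gating$v_rev))
    dt <- 1 / m$sample_rate
    wlen <- ceiling(8 * m$tau_d / dt)
    w <- mepsc_template((0:wlen) * dt, m$tau_r, m$tau_d)
    for (t0 in stim_times) {
      i0 <- round(t0 / dt) + 1
      idx <- i0:min(i0 + wlen, length(sw$current_pA))
      sw$current_pA[idx] <- sw$current_pA[idx] + scale * amp$mean_pA * w[seq_along(idx)]
    }
    sw
  })
  names(sweeps) <- as.character(voltages)
  res <- eepsc_analyze(sweeps, stim_times, fit_degree = 1)
  utils::write.csv(res$ri$components, file.path(out_dir, "eepsc_peaks.csv"), row.names = FALSE)
  list(ri = res$ri$ri, n_stim = n_stim)
}

stage_potency <- function(cfg, out_dir, concentrations = c(1, 10, 100, 500)) {
  so <- sim_objects(cfg)
  proto <- so$ramp_proto
  vb <- vapply(concentrations, function(conc) {
    cfg2 <- cfg
    cfg2$concentration_uM <- conc
    block <- blocker_preset(cfg2)
    pair <- simulate_ramp_pair(so$gating, block, proto)
    free <- simulate_ramp_pair(so$gating, block_params(0, 0, 0), proto)
    iv <- sweep_to_iv(leak_subtract(pair$agonist, pair$control))
    ivf <- sweep_to_iv(leak_subtract(free$agonist, free$control))
    # reversal from the polyamine-free curve: at high blocker concentrations
    # the near-zero outward limb makes the crossing ill-defined
    vr <- reversal_potential(ivf)
    free_ref <- raw_conductance_curve(ivf, vr)
    gv <- conductance_curve(iv, vr, free_reference = free_ref)
    fit_boltzmann(gv, "single")$v_b
  }, numeric(1))
  tab <- data.frame(concentration = concentrations, v_b = vb)
  utils::write.csv(tab, file.path(out_dir, "vb_by_concentration.csv"), row.names = FALSE)
  pf <- fit_potency(tab)
  list(slope_mV_per_decade = pf$slope, ic50_0mv_uM = pf$ic50_0mv)
}

stage_stats <- function(cfg, out_dir) {
  if (is.null(cfg$stats_input)) stop("stats subcommand needs cfg$stats_input (csv with columns x, y)")
  d <- utils::read.csv(cfg$stats_input)
  x <- d$x[is.finite(d$x)]
  y <- d$y[is.finite(d$y)]
  w <- welch_t(x, y)
  es <- bootstrap_bca_ci(x, y, n_resamples = cfg$analysis$bootstrap_n, seed = cfg$seed)
  list(
    t = w$t, df = w$df, p = w$p,
    mean_difference = es$estimate, ci_low = es$ci_low, ci_high = es$ci_high
  )
}

stage_figures <- function(cfg, out_dir) {
  ramp_dir <- file.path(out_dir, "sim")
  run_pipeline(cfg, "simulate", out_dir = ramp_dir)
  ramp <- attr(run_pipeline(cfg, "ramp", out_dir = out_dir, input_dir = ramp_dir), "summary")
  pot <- attr(run_pipeline(cfg, "potency", out_dir = out_dir), "summary")
  mep <- attr(run_pipeline(cfg, "mepsc", out_dir = out_dir), "summary")
  list(ramp_ri = ramp$ri, ic50_0mv_uM = pot$ic50_0mv_uM, mepsc_ri = mep$ri)
}
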