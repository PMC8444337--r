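PIPELINE_STAGES <- c("fixtures", "cec", "xi", "spectrum", "grid", "fit",
                     "metad-demo")

#' Run the CEC analysis pipeline
#'
#' Executes the requested stages in order from a single configuration
#' document (a YAML file or an equivalent named list). The configuration is
#' validated fully — unknown stages or missing input files abort before any
#' computation — and every run writes a JSON manifest next to its outputs
#' so analyses are auditable. Runs are deterministic given the `seed`
#' field.
#'
#' Recognized top-level fields: `stages`, `seed`, `out_prefix`,
#' `trajectory`, `dt_fs`, `functional`, `ct_params` (JSON path),
#' `charge_table` (JSON path), `acid` (`o_atoms`, `group_atoms`, `kind`),
#' `max_shell`, `cutoff`, plus per-stage blocks `fixtures`, `spectrum`,
#' `xi`, `grid`, `fit`, `metad`.
#'
#' @param config Path to a YAML configuration file, or a named list.
#' @return Invisibly, a named list of written file paths per stage.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("configuration error: config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("configuration error: config must be a list")
  stages <- config$stages
  if (!length(stages)) stop("configuration error: no stages requested")
  unknown <- setdiff(stages, PIPELINE_STAGES)
  if (length(unknown))
    stop("configuration error: unknown stage(s): ",
         paste(unknown, collapse = ", "), " (known: ",
         paste(PIPELINE_STAGES, collapse = ", "), ")")
  prefix <- config$out_prefix %||% "cectrack_run"
  seed <- as.integer(config$seed %||% 1L)
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)

  ## resolve shared inputs up front so misconfiguration fails fast
  params <- if (!is.null(config$ct_params)) read_ct_params(config$ct_params)
            else default_ct_params(config$functional %||% "BLYP")
  charges <- if (!is.null(config$charge_table))
               read_charge_table(config$charge_table)
             else default_charge_table()
  acid <- if (!is.null(config$acid))
            acid_spec(config$acid$o_atoms,
                      config$acid$group_atoms %||% config$acid$o_atoms,
                      config$acid$kind %||% "glu")
  for (st in stages) {
    if (st %in% c("cec", "xi", "spectrum") && is.null(config$trajectory) &&
        is.null(config$spectrum$track) && !"fixtures" %in% stages)
      stop("configuration error: stage '", st, "' needs a trajectory")
    if (st == "fit") {
      tab <- config$fit$table
      if (is.null(tab) || !file.exists(tab))
        stop("configuration error: stage 'fit' needs an existing fit$table")
    }
    if (st %in% c("cec", "xi") && !is.null(config$trajectory) &&
        !file.exists(config$trajectory))
      stop("configuration error: trajectory not found: ", config$trajectory)
  }

  outputs <- list()
  for (i in seq_along(stages)) {
    st <- stages[i]
    pipeline_log(config, "running stage '", st, "'")
    set.seed(seed + i)
    outputs[[st]] <- switch(
      st,
      fixtures = stage_fixtures(config, prefix, seed),
      cec = stage_cec(config, prefix, seed, params, charges, acid,
                      with_xi = FALSE),
      xi = stage_cec(config, prefix, seed, params, charges, acid,
                     with_xi = TRUE),
      spectrum = stage_spectrum(config, prefix),
      grid = stage_grid(config, prefix),
      fit = stage_fit(config, prefix),
      `metad-demo` = stage_metad(config, prefix, seed))
  }
  invisible(outputs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_log <- function(config, ...) {
  if (!identical(config$log_level, "quiet")) message("[cectrack] ", ...)
}

stage_fixtures <- function(config, prefix, seed) {
  fx <- config$fixtures %||% list()
  kind <- fx$kind %||% "ideal-network"
  path <- paste0(prefix, "_fixture.xyz")
  switch(kind,
    "ideal-network" = write_xyz_trajectory(
      make_ideal_network(fx$branching %||% c(3L, 2L, 2L),
                         fx$hbond_len %||% 1.6), path),
    "zundel-scan" = write_xyz_trajectory(
      make_zundel_scan(fx$r_oo %||% 2.6, fx$n_frames %||% 21L), path),
    "shuttle" = write_xyz_trajectory(
      make_shuttle_trajectory(fx$n_waters %||% 4L, fx$hops %||% 2L,
                              fx$frames_per_hop %||% 40L), path),
    "oscillating-track" = {
      path <- paste0(prefix, "_track.csv")
      tr <- make_oscillating_track(fx$freq_cm %||% 1200,
                                   fx$dt_fs %||% 0.5, fx$n %||% 4096L,
                                   noise = fx$noise %||% 0,
                                   seed = fx$seed %||% seed)
      utils::write.csv(data.frame(
        frame = seq_len(nrow(tr)),
        time_fs = (seq_len(nrow(tr)) - 1L) * (fx$dt_fs %||% 0.5),
        cec_x = tr[, 1L], cec_y = tr[, 2L], cec_z = tr[, 3L]),
        path, row.names = FALSE)
      path
    },
    stop("configuration error: unknown fixture kind '", kind, "'"))
  c(fixture = path)
}

stage_cec <- function(config, prefix, seed, params, charges, acid, with_xi) {
  traj <- config$trajectory %||% paste0(prefix, "_fixture.xyz")
  if (!file.exists(traj))
    stop("configuration error: trajectory not found: ", traj)
  series <- read_xyz_trajectory(traj, dt = config$dt_fs %||% 0.5)
  max_shell <- config$max_shell %||% 3L
  cutoff <- config$cutoff %||% 2.5
  results <- track_cec(series, params = params, charges = charges,
                       acid = acid, max_shell = max_shell, cutoff = cutoff)
  xi <- NULL
  if (with_xi) {
    xs <- config$xi %||% list()
    o1 <- xs$o1 %||% (if (!is.null(acid)) acid$o_atoms[1L])
    o2 <- xs$o2 %||% (if (!is.null(acid)) acid$o_atoms[2L])
    if (is.null(o1) || is.null(o2))
      stop("configuration error: xi stage needs xi$o1/xi$o2 or an acid block")
    kappa <- xs$kappa %||% 40
    xi <- vapply(seq_along(results), function(f)
      xi_cv(results[[f]]$cec, series$frames[[f]]$positions[o1, ],
            series$frames[[f]]$positions[o2, ], kappa)$value, numeric(1))
  }
  if (isTRUE(config$dump_states)) {
    f1 <- series$frames[[1L]]
    topo <- assign_topology(f1, acid = acid)
    st <- enumerate_states(f1, topo, max_shell = max_shell, cutoff = cutoff)
    jsonlite::write_json(states_as_list(st), paste0(prefix, "_states.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  write_cec_outputs(series, results, prefix, xi = xi, manifest = list(
    seed = seed, trajectory = basename(traj), max_shell = max_shell,
    cutoff = cutoff,
    functional = config$functional %||% "BLYP",
    ct_params = lapply(seq_len(nrow(params)), function(r)
      as.list(params[r, c("pair_kind", "k", "delta0")]))))
}

stage_spectrum <- function(config, prefix) {
  sp <- config$spectrum %||% list()
  track_path <- sp$track %||% paste0(prefix, "_track.csv")
  if (!file.exists(track_path))
    stop("configuration error: CEC track not found: ", track_path,
         " (run the 'cec' stage first or set spectrum$track)")
  tab <- utils::read.csv(track_path)
  track <- as.matrix(tab[, c("cec_x", "cec_y", "cec_z")])
  dt <- sp$dt_fs %||% config$dt_fs %||%
    (if (nrow(tab) > 1L) diff(tab$time_fs[1:2]) else 0.5)
  window_cm <- sp$window_cm %||% 33
  spec <- track_spectrum(track, dt, window_cm = window_cm,
                         window = sp$taper %||% "hann")
  path <- paste0(prefix, "_spectrum.csv")
  utils::write.csv(data.frame(frequency_cm = spec$frequency,
                              intensity = spec$intensity_raw,
                              intensity_smoothed = spec$intensity),
                   path, row.names = FALSE)
  c(spectrum = path)
}

stage_grid <- function(config, prefix) {
  gr <- config$grid %||% list()
  pair <- gr$pair %||% "h3o-water"
  grid <- switch(pair,
                 "h3o-water" = generate_h3o_water_grid(),
                 "glu-water" = generate_glu_water_grid(),
                 stop("configuration error: unknown grid pair '", pair, "'"))
  xyz <- paste0(prefix, "_grid.xyz")
  write_training_grid(grid, xyz)
  csv <- paste0(prefix, "_grid.csv")
  utils::write.csv(grid$labels, csv, row.names = FALSE)
  c(grid_xyz = xyz, grid_csv = csv)
}

stage_fit <- function(config, prefix) {
  ft <- config$fit %||% list()
  tab <- utils::read.csv(ft$table)
  if (!all(c("delta", "fct") %in% names(tab)))
    stop("configuration error: fit table needs 'delta' and 'fct' columns")
  fit <- fit_ct_parameters(tab$delta, tab$fct,
                           fix_delta0 = isTRUE(ft$fix_delta0),
                           log_space = isTRUE(ft$log_space))
  path <- paste0(prefix, "_ct_params.json")
  write_ct_params(ct_params(ft$pair_kind %||% "h3o-water", fit$k,
                            fit$delta0, ft$functional %||% NA_character_),
                  path)
  summary_path <- paste0(prefix, "_fit.json")
  jsonlite::write_json(list(k = fit$k, delta0 = fit$delta0,
                            residual_rms = fit$residual_rms,
                            n_points = fit$n_points,
                            se_k = sqrt(fit$covariance["k", "k"])),
                       summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  c(params = path, summary = summary_path)
}

stage_metad <- function(config, prefix, seed) {
  md <- config$metad %||% list()
  bias <- bias_state(height0 = md$height %||% 0.2,
                     width = md$width %||% 0.1,
                     gamma = md$gamma %||% 12,
                     stride_fs = md$stride_fs %||% 50,
                     temperature = md$temperature %||% 300)
  run <- run_toy_metad(double_well_coefs(md$barrier %||% 3),
                       bias = bias, n_steps = md$n_steps %||% 2e6,
                       diffusion = md$diffusion %||% 2e-5, seed = seed)
  hills <- paste0(prefix, "_hills.csv")
  utils::write.csv(data.frame(time_fs = run$bias$times,
                              center = run$bias$centers,
                              height = run$bias$heights,
                              width = run$bias$width),
                   hills, row.names = FALSE)
  fes <- paste0(prefix, "_fes.csv")
  utils::write.csv(run$fes, fes, row.names = FALSE)
  summary_path <- paste0(prefix, "_metad.json")
  jsonlite::write_json(list(barrier_true = md$barrier %||% 3,
                            barrier_estimate = fes_barrier(run$fes),
                            cv_range = range(run$cv), n_hills =
                              length(run$bias$centers), seed = seed),
                       summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  c(hills = hills, fes = fes, summary = summary_path)
}

#' Command-line entry point
#'
#' Thin shell wrapper over [run_pipeline()]: the first argument selects the
#' stage (`cec`, `spectrum`, `xi`, `fit`, `grid`, `metad-demo`,
#' `fixtures`), followed by `--config=FILE`, `--seed=N`,
#' `--out-prefix=PATH`, `--log-level=info|quiet` and stage shortcuts
#' (`--trajectory=`, `--kind=`, `--pair=`, `--in=`, `--window-cm=`,
#' `--dt-fs=`, `--barrier=`). A launcher script is installed at
#' `system.file("cli", "cectrack", package = "cectrack")`.
#'
#' @param args Character vector of CLI arguments.
#' @return Invisibly, the [run_pipeline()] outputs.
#' @export
cectrack_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1L] %in% c("-h", "--help")) {
    cat("usage: cectrack <stage> [--config=FILE] [--seed=N]",
        "[--out-prefix=PATH] [--log-level=info|quiet] [options]\n",
        "stages:", paste(PIPELINE_STAGES, collapse = " "), "\n")
    return(invisible(NULL))
  }
  stage <- args[1L]
  opts <- list()
  for (a in args[-1L]) {
    if (!grepl("^--[a-z-]+=", a))
      stop("malformed argument: ", a, " (expected --key=value)")
    key <- sub("^--([a-z-]+)=.*", "\\1", a)
    val <- sub("^--[a-z-]+=", "", a)
    opts[[key]] <- val
  }
  config <- if (!is.null(opts$config)) yaml::read_yaml(opts$config) else list()
  config$stages <- stage
  if (!is.null(opts$seed)) config$seed <- as.integer(opts$seed)
  if (!is.null(opts$`out-prefix`)) config$out_prefix <- opts$`out-prefix`
  if (!is.null(opts$`log-level`)) config$log_level <- opts$`log-level`
  if (!is.null(opts$trajectory)) config$trajectory <- opts$trajectory
  if (!is.null(opts$`dt-fs`)) config$dt_fs <- as.numeric(opts$`dt-fs`)
  if (!is.null(opts$kind))
    config$fixtures <- utils::modifyList(config$fixtures %||% list(),
                                         list(kind = opts$kind))
  if (!is.null(opts$pair))
    config$grid <- utils::modifyList(config$grid %||% list(),
                                     list(pair = opts$pair))
  if (!is.null(opts$`in`))
    config$fit <- utils::modifyList(config$fit %||% list(),
                                    list(table = opts$`in`))
  if (!is.null(opts$`fix-delta0`))
    config$fit <- utils::modifyList(config$fit %||% list(),
                                    list(fix_delta0 =
                                           opts$`fix-delta0` == "true"))
  if (!is.null(opts$`window-cm`))
    config$spectrum <- utils::modifyList(config$spectrum %||% list(),
                                         list(window_cm =
                                                as.numeric(opts$`window-cm`)))
  if (!is.null(opts$barrier))
    config$metad <- utils::modifyList(config$metad %||% list(),
                                      list(barrier =
                                             as.numeric(opts$barrier)))
  run_pipeline(config)
}
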