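## ---------------------------------------------------------------------------
## Scenario orchestration: phantom -> valve reconstruction -> moving domain ->
## RIIS/LES flow solve -> hemodynamic report, for the three study scenarios:
##   H  : healthy valve, heart rate 75 bpm, T_S = 0.32 s
##   R1 : P2 posterior prolapse, heart rate 90 bpm, T_S = 0.26 s
##   R2 : the R1 valve and motion dilated by 1.25, heart rate 75 bpm
## ---------------------------------------------------------------------------

#' Scenario configuration
#'
#' Encodes the per-scenario study conditions.  The healthy scenario uses a
#' constant 10 mmHg atrial pressure and starts with the aortic valve open
#' (the simulation begins just after the opening, `t_o = 0`); the
#' regurgitant scenarios use an elevated V-wave atrial waveform, the
#' null-tangential backflow treatment at the atrial outlet, and start with
#' both valves closed.  The R2 systole duration is not restated by the
#' shared motion protocol; it is taken equal to H's 0.32 s since R2 keeps
#' the 75 bpm heart rate.
#'
#' @param scenario `"H"`, `"R1"` or `"R2"`.
#' @param hr_bpm heart rate; defaults 75 (H, R2) / 90 (R1).
#' @param t_s systole duration (s); defaults 0.32 (H, R2) / 0.26 (R1).
#' @param target_sv_ml phantom target stroke volume before dilation (mL).
#' @param orifice_area_mm2 regurgitant orifice area of the undilated valve.
#' @param dt solver time step (s).
#' @param mesh phantom mesh density (see [phantom_spec()]); the default is a
#'   desk-scale resolution.
#' @param riis_R,riis_eps RIIS resistance (kg/(m s)) and half-thickness (m).
#' @param les_C sigma-model constant.
#' @param rho,mu blood density and viscosity (SI).
#' @param aortic_waveform,atrial_waveform CSV paths (`t_s,p_mmhg`); defaults
#'   to the packaged synthetic tables, time-rescaled to `t_s`.
#' @param seed integer seed.
#' @param out_dir output directory.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("H", "R1", "R2"),
                            hr_bpm = NULL, t_s = NULL,
                            target_sv_ml = 92, orifice_area_mm2 = 40,
                            dt = 6.5e-3,
                            mesh = list(ns = 6L, nr = 3L, n_vent = 7L,
                                        n_atr = 8L, n_ao = 6L),
                            riis_R = 1e4, riis_eps = 7.5e-4,
                            les_C = 1.5, rho = 1.06e3, mu = 3.5e-3,
                            aortic_waveform = NULL, atrial_waveform = NULL,
                            seed = 1L, out_dir = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(hr_bpm)) hr_bpm <- if (scenario == "R1") 90 else 75
  if (is.null(t_s)) t_s <- if (scenario == "R1") 0.26 else 0.32
  cfg <- list(scenario = scenario, hr_bpm = hr_bpm, t_s = t_s,
              target_sv_ml = target_sv_ml,
              orifice_area_mm2 = if (scenario == "H") 0 else orifice_area_mm2,
              dilation = if (scenario == "R2") 1.25 else 1.0,
              valve = if (scenario == "H") "healthy" else "prolapse",
              dt = dt, mesh = mesh,
              riis_R = riis_R, riis_eps = riis_eps, les_C = les_C,
              rho = rho, mu = mu,
              aortic_waveform = aortic_waveform,
              atrial_waveform = atrial_waveform,
              backflow = if (scenario == "H") "none" else "null_tangential",
              aortic_state0 = if (scenario == "H") "open" else "closed",
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
}

validate_scenario_config <- function(cfg) {
  stopifnot(cfg$scenario %in% c("H", "R1", "R2"),
            cfg$t_s > 0, cfg$hr_bpm > 0, cfg$dt > 0)
  if (cfg$scenario == "H" && (cfg$valve != "healthy" || cfg$orifice_area_mm2 != 0))
    stop("scenario H requires a healthy, fully coapting valve")
  if (cfg$scenario %in% c("R1", "R2") && cfg$valve != "prolapse")
    stop("regurgitant scenarios require the prolapsed valve")
  if (cfg$scenario == "R2" && cfg$dilation != 1.25)
    stop("scenario R2 requires dilation 1.25")
  cfg
}

#' Read / write a scenario configuration as YAML
#' @param cfg a `scenario_config`.
#' @param path YAML file.
#' @export
write_scenario_yaml <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @export
read_scenario_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- scenario_config(raw$scenario)
  for (nm in names(raw)) if (!is.null(raw[[nm]])) cfg[[nm]] <- raw[[nm]]
  if (!is.null(cfg$mesh)) cfg$mesh <- lapply(cfg$mesh, as.integer)
  cfg$seed <- as.integer(cfg$seed)
  validate_scenario_config(cfg)
}

## waveform CSV -> function of time, rescaled from the file's own time base
## to [0, t_s] ("the frequency has been suitably adapted").
load_waveform <- function(path, t_s) {
  df <- read.csv(path)
  t0 <- max(df$t_s)
  function(t) approx(df$t_s, df$p_mmhg, xout = pmin(pmax(t / t_s, 0), 1) * t0,
                     rule = 2)$y
}

default_waveform <- function(which) {
  system.file("extdata",
              if (which == "aortic") "synthetic_aortic_pressure.csv"
              else "synthetic_atrial_vwave_pressure.csv",
              package = "cardioriis", mustWork = TRUE)
}

## scenario slice plan in meters, derived from the phantom geometry
scenario_slices <- function(geom) {
  spec <- geom$spec
  mod <- geom$model
  f <- spec$dilation
  mm <- 1e-3
  at <- function(p_ref) from_reference(geom, matrix(p_ref, 1L))[1L, ] * mm
  list(
    lvot = plane_slice(at(c(mod$cx_ao(0.15), 0, 0.15 * spec$ao_h)), c(0, 0, 1),
                       rmax = 1.3 * mod$r_eq * f * mm, region = 3L, name = "LVOT"),
    aortic_plane = plane_slice(at(c(mod$cx_ao(0.35), 0, 0.35 * spec$ao_h)), c(0, 0, 1),
                               rmax = 1.2 * mod$r_eq * f * mm, region = 3L,
                               name = "aortic valve plane"),
    aorta = plane_slice(at(c(mod$cx_ao(0.6), 0, 0.6 * spec$ao_h)), c(0, 0, 1),
                        rmax = 1.2 * mod$r_eq * f * mm, region = 3L, name = "aorta"),
    ventricle = plane_slice(at(c(0, 0, -0.25 * spec$vent_c)), c(0, 0, 1),
                            region = 1L, name = "ventricle"),
    mitral = plane_slice(at(c(mod$cx_atr(0.55), 0, 0.55 * spec$atr_h)), c(0, 0, 1),
                         rmax = 1.2 * mod$r_eq * f * mm, region = 2L,
                         name = "mitral orifice")
  )
}

#' Run one scenario end to end
#'
#' Generates the phantom (geometry, motion, valve traces), reconstructs the
#' immersed valves, builds the moving domain, advances the stabilized
#' ALE/RIIS/LES solver over systole, and computes the hemodynamic report.
#' Writes (if `out_dir` is set): the flow-rate/pressure time series (CSV),
#' the index report (JSON), final fields (legacy VTK), valve surfaces (STL)
#' and a run manifest with the config hash.
#'
#' @param cfg a [scenario_config()].
#' @param keep_history return the full `flow_history` as attribute
#'   `history` (large).
#' @param verbose per-step progress.
#' @return the index report (list), invisibly annotated with stage timings.
#' @export
run_scenario <- function(cfg, keep_history = FALSE, verbose = FALSE) {
  cfg <- validate_scenario_config(cfg)
  timings <- c()
  tic <- function() Sys.time()
  lap <- function(t0, nm) {
    timings[nm] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }

  t0 <- tic()
  spec <- phantom_spec(target_sv_ml = cfg$target_sv_ml, t_s = cfg$t_s,
                       dilation = cfg$dilation, valve = cfg$valve,
                       orifice_area_mm2 = cfg$orifice_area_mm2,
                       seed = cfg$seed, mesh = cfg$mesh)
  geom <- generate_geometry(spec)
  motion <- generate_motion(spec, geom)
  traces <- generate_valve_traces(spec, geom)
  lap(t0, "phantom")

  t0 <- tic()
  valves <- make_scenario_valves(cfg$scenario, geom, traces = traces,
                                 eps_m = cfg$riis_eps, R = cfg$riis_R)
  lap(t0, "valves")

  t0 <- tic()
  domain <- moving_domain(geom, motion, dt = cfg$dt)
  lap(t0, "domain")

  p2 <- load_waveform(if (is.null(cfg$aortic_waveform)) default_waveform("aortic")
                      else cfg$aortic_waveform, cfg$t_s)
  p1 <- if (cfg$scenario == "H") 10 else
    load_waveform(if (is.null(cfg$atrial_waveform)) default_waveform("atrial")
                  else cfg$atrial_waveform, cfg$t_s)
  forcing <- boundary_forcing(p_sigma1 = p1, p_sigma2 = p2,
                              backflow = cfg$backflow)
  slices <- scenario_slices(geom)

  t0 <- tic()
  hist <- solve_flow(domain, valves,
                     props = fluid_properties(rho = cfg$rho, mu = cfg$mu),
                     les = les_params(C = cfg$les_C),
                     forcing = forcing, dt = cfg$dt, t_end = cfg$t_s,
                     aortic_state0 = cfg$aortic_state0,
                     controller_slices = list(vent = slices$ventricle,
                                              aorta = slices$aorta,
                                              aortic_plane = slices$aortic_plane),
                     verbose = verbose)
  lap(t0, "solve")

  t0 <- tic()
  report <- index_report(hist, slices, cfg)
  lap(t0, "postprocess")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(report$series, file.path(cfg$out_dir, "timeseries.csv"),
              row.names = FALSE)
    jsonlite::write_json(report[setdiff(names(report), "series")],
                         file.path(cfg$out_dir, "index_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    ## final fields and valve surface
    s <- length(hist$times)
    nodes <- domain$nodes0 + hist$d[s, , ]
    write_vtk(nodes, domain$tets, file.path(cfg$out_dir, "final_fields.vtk"),
              point_data = list(velocity = hist$u[s, , ],
                                pressure = hist$p[s, ]))
    write_stl(valves$surface$nodes, valves$surface$tris,
              file.path(cfg$out_dir, "mitral_valve.stl"))
    write_traces_csv(traces, file.path(cfg$out_dir, "valve_traces.csv"))
    cfg_path <- file.path(cfg$out_dir, "config.yaml")
    write_scenario_yaml(cfg, cfg_path)
    manifest <- list(package = "cardioriis",
                     version = as.character(utils::packageVersion("cardioriis")),
                     scenario = cfg$scenario, seed = cfg$seed,
                     config_md5 = unname(tools::md5sum(cfg_path)),
                     stage_seconds = as.list(round(timings, 2)))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  attr(report, "timings") <- timings
  if (keep_history) attr(report, "history") <- hist
  invisible(report)
}

## Assemble the full index report from a run.
index_report <- function(hist, slices, cfg) {
  ctrl <- hist$controller
  t_o <- if (is.na(ctrl$t_open)) NA_real_ else ctrl$t_open
  t_c <- if (is.na(ctrl$t_close)) cfg$t_s else ctrl$t_close
  q_lvot <- slice_flow_rate(hist, slices$lvot)
  q_mv <- slice_flow_rate(hist, slices$mitral)
  pv <- slice_pressure_series(hist, slices$ventricle)
  pa <- slice_pressure_series(hist, slices$aorta)
  idx <- compute_indices(q_lvot$t, q_lvot$q_ml_s, q_mv$q_ml_s, cfg$hr_bpm)
  pm <- pressure_metrics(pv$t, pv$p_mmhg, pa$p_mmhg,
                         t_o = max(t_o, min(pv$t), na.rm = TRUE), t_c = t_c)
  tf <- timing_features(q_lvot$t, q_lvot$q_ml_s, t_c = t_c, t_s = cfg$t_s)
  tr <- turbulence_ratio(hist)
  stride <- max(1L, length(hist$times) %/% 25L)
  u_av <- velocity_maxima(hist, slices$aortic_plane, stride = stride)
  u_mv <- velocity_maxima(hist, slices$mitral, stride = stride)
  wmv <- wss_summary(hist, "mitral", stride = stride)
  ww <- wss_summary(hist, "wall", stride = stride)
  ## t_a: instant of maximum mitral (regurgitant) flow rate
  t_a <- q_mv$t[which.max(q_mv$q_ml_s)]
  list(scenario = cfg$scenario, hr_bpm = cfg$hr_bpm, t_s = cfg$t_s,
       t_o = t_o, t_c = t_c, ejection_s = t_c - t_o,
       t_v1 = tf$t_v1, t_v2 = tf$t_v2, t_dec = tf$t_dec, t_a = t_a,
       dp_mean_mmhg = pm$dp_mean,
       sv_ml = idx$sv_ml, co_l_min = idx$co_l_min,
       rv_ml = idx$rv_ml, rf_pct = idx$rf_pct,
       u_av_m_s = u_av, u_mv_m_s = u_mv,
       r_bar = tr$r_bar,
       wss_mv_pa = wmv$wss_bar, wss_w_pa = ww$wss_bar,
       wss_mv_hist = wmv$hist, wss_w_hist = ww$hist,
       valve_log = ctrl$log,
       series = data.frame(t = q_lvot$t, q_lvot_ml_s = q_lvot$q_ml_s,
                           q_mv_ml_s = q_mv$q_ml_s,
                           p_vent_mmhg = pv$p_mmhg, p_aorta_mmhg = pa$p_mmhg,
                           r_atrium = tr$r$ratio))
}

#' Compare completed scenario runs
#'
#' Builds the scenario comparison table (one row per run) with the standard
#' column set: mean ventriculo-aortic pressure drop, ejection duration, SV,
#' CO, RV, RF, transvalvular velocity maxima, atrial turbulence ratio and
#' WSS summaries.
#'
#' @param runs list of index reports (from [run_scenario()]) or run
#'   directories containing `index_report.json`.
#' @param out optional CSV path.
#' @return data.frame.
#' @export
compare_scenarios <- function(runs, out = NULL) {
  if (length(runs) < 2L) stop("need at least two completed runs to compare")
  reports <- lapply(runs, function(r) {
    if (is.character(r)) jsonlite::read_json(file.path(r, "index_report.json"),
                                             simplifyVector = TRUE)
    else r
  })
  cols <- c("scenario", "dp_mean_mmhg", "ejection_s", "sv_ml", "co_l_min",
            "rv_ml", "rf_pct", "u_av_m_s", "u_mv_m_s", "r_bar",
            "wss_mv_pa", "wss_w_pa")
  for (r in reports)
    if (!all(cols %in% names(r)))
      stop("index report lacks the expected column set (schema mismatch)")
  df <- do.call(rbind, lapply(reports, function(r)
    as.data.frame(r[cols], stringsAsFactors = FALSE)))
  if (!is.null(out)) write.csv(df, out, row.names = FALSE)
  df
}
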