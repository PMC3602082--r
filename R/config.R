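.config_defaults <- function() {
  list(
    grid = list(
      nx = list(v = 61L, src = "implementation default (desk-scale sheet)"),
      ny = list(v = 21L, src = "implementation default (desk-scale sheet)"),
      hs = list(v = 0.5, src = "source-cited (validated space-step range 0.25-0.5 mm)"),
      D  = list(v = 0.154, src = "source-cited (TP06 tissue diffusivity, mm^2/ms)")),
    electrics = list(
      dt = list(v = 0.02, src = "source-cited (validated electrical step, ms)"),
      gates = list(v = "exponential", src = "reference TP06 integration scheme"),
      stim_amp = list(v = -52, src = "source-cited (TP06 stimulus, pA/pF)"),
      stim_dur = list(v = 2, src = "implementation default (ms)"),
      init_period = list(v = 1000, src = "implementation default (conditioning pacing, ms)"),
      init_beats = list(v = 60L, src = "implementation default")),
    tension = list(
      relax_mult = list(v = 2, src = "adopted human adjustment (relaxation speed-up)"),
      T_ref = list(v = 120, src = "adopted human adjustment (kPa)"),
      pCa50 = list(v = 6.2, src = "adopted human adjustment")),
    mechanics = list(
      E = list(v = 280, src = "implementation default (kPa; 10-15% free-fibre twitch shortening)"),
      damping_ratio = list(v = 0.05, src = "implementation default (stable regime of the convergence study)"),
      cap_frac = list(v = 0.9, src = "implementation default (damping cap fraction)"),
      cap_on = list(v = TRUE, src = "implementation default"),
      f_th_rel = list(v = 1e-4, src = "implementation default (convergence threshold / k*l0)")),
    sac = list(
      gs = list(v = 0, src = "swept within the reported physiological range (nS/pF)"),
      es = list(v = 0, src = "source-cited range (reversal potential, mV)"),
      lambda_max = list(v = 1.1, src = "source-cited convention"),
      rectified = list(v = TRUE, src = "adopted reading (current gated to stretch)")),
    protocol = list(
      name = list(v = "sheet", src = "user"),
      mode = list(v = "constant_stretch", src = "user"),
      period = list(v = 600, src = "user (ms)"),
      periods = list(v = c(1000, 600, 450, 350, 300), src = "user (ms)"),
      gs_values = list(v = c(0, 0.01, 0.02, 0.03), src = "user (nS/pF)"),
      n_cond = list(v = 2L, src = "user"),
      n_meas = list(v = 2L, src = "user"),
      duration = list(v = 800, src = "user (ms)"),
      lambda = list(v = 1.1, src = "user (constant stretch)")))
}

#' Load and validate a run configuration
#'
#' YAML configuration with sections `grid`, `electrics`, `tension`,
#' `mechanics`, `sac`, `protocol`. Missing keys are filled from the package
#' defaults; unknown sections or keys are rejected with a message listing
#' every offending key. Each resolved parameter carries a provenance tag
#' (source-cited value vs implementation default vs user).
#'
#' @param path YAML file, or `NULL` for pure defaults
#' @return list of class `run_config` with attributes `provenance` and `hash`
#' @export
load_config <- function(path = NULL) {
  defs <- .config_defaults()
  user <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  }
  if (is.null(user)) user <- list()
  bad <- character(0)
  for (sec in names(user)) {
    if (!sec %in% names(defs)) { bad <- c(bad, sec); next }
    for (k in names(user[[sec]]))
      if (!k %in% names(defs[[sec]])) bad <- c(bad, paste(sec, k, sep = "."))
  }
  if (length(bad)) stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  cfg <- list(); prov <- list()
  for (sec in names(defs)) {
    cfg[[sec]] <- list(); prov[[sec]] <- list()
    for (k in names(defs[[sec]])) {
      if (!is.null(user[[sec]]) && k %in% names(user[[sec]])) {
        cfg[[sec]][[k]] <- user[[sec]][[k]]
        prov[[sec]][[k]] <- "user"
      } else {
        cfg[[sec]][[k]] <- defs[[sec]][[k]]$v
        prov[[sec]][[k]] <- defs[[sec]][[k]]$src
      }
    }
  }
  .validate_config(cfg)
  attr(cfg, "provenance") <- prov
  attr(cfg, "hash") <- config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

.validate_config <- function(cfg) {
  bad <- character(0)
  chk <- function(ok, key) if (!isTRUE(ok)) bad <<- c(bad, key)
  chk(cfg$electrics$dt > 0, "electrics.dt (must be positive)")
  chk(cfg$electrics$dt <= 0.05, "electrics.dt (exceeds validated step)")
  chk(cfg$grid$hs > 0, "grid.hs (must be positive)")
  chk(cfg$grid$D > 0, "grid.D (must be positive)")
  chk(cfg$grid$D * cfg$electrics$dt / cfg$grid$hs^2 < 0.25,
      "grid (diffusion stability D*dt/h^2 < 1/4)")
  chk(cfg$grid$nx >= 3 && cfg$grid$ny >= 1, "grid.nx/ny")
  chk(cfg$mechanics$E > 0, "mechanics.E (must be positive)")
  chk(cfg$sac$gs >= 0, "sac.gs (must be non-negative)")
  chk(cfg$sac$lambda_max > 1, "sac.lambda_max (must exceed 1)")
  chk(all(cfg$protocol$gs_values >= 0), "protocol.gs_values")
  chk(cfg$protocol$name %in% c("cell", "fiber", "sheet", "restitution", "spiral"),
      "protocol.name")
  chk(cfg$protocol$mode %in% c("constant_stretch", "contracting"),
      "protocol.mode")
  if (length(bad)) stop("invalid configuration: ", paste(bad, collapse = "; "))
  invisible(cfg)
}

#' Write a resolved configuration to YAML
#' @param cfg `run_config`
#' @param path output file
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Stable hash of a configuration (polynomial hash of its serialized form)
#' @param cfg configuration list
#' @return hex string
#' @export
config_hash <- function(cfg) {
  raw <- serialize(lapply(unclass(cfg), unclass), NULL, version = 2)
  h <- 0
  for (b in as.integer(raw)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Helper objects from a configuration
#' @param cfg `run_config`
#' @return list with `params`, `nhs`, `mech`, `sac` ready for the protocol
#'   functions
#' @export
config_objects <- function(cfg) {
  list(
    params = tp06_params(gates = cfg$electrics$gates),
    nhs = nhs_params(adjust = human_adjustments(
      relax_mult = cfg$tension$relax_mult,
      T_ref = cfg$tension$T_ref, pCa50 = cfg$tension$pCa50)),
    mech = mech_params(E = cfg$mechanics$E, l0 = 2 * cfg$grid$hs,
                       damping_ratio = cfg$mechanics$damping_ratio,
                       cap_frac = cfg$mechanics$cap_frac,
                       cap_on = cfg$mechanics$cap_on,
                       f_th_rel = cfg$mechanics$f_th_rel),
    sac = sac_params(gs = cfg$sac$gs, es = cfg$sac$es,
                     lambda_max = cfg$sac$lambda_max,
                     rectified = cfg$sac$rectified))
}

#' Run a protocol described by a configuration
#'
#' Dispatches on `protocol.name`, writes the resolved configuration, a run
#' log (including per-step mechanics iteration counts where applicable) and
#' the protocol outputs as CSV into `out_dir`.
#'
#' @param cfg `run_config`
#' @param out_dir output directory (created if needed)
#' @return protocol-specific result, invisibly
#' @export
run_from_config <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  save_config(cfg, file.path(out_dir, "config-resolved.yaml"))
  ob <- config_objects(cfg)
  logf <- file.path(out_dir, "run.log")
  cat(sprintf("cardiomech run %s protocol=%s mode=%s config=%s\n",
              format(Sys.time()), cfg$protocol$name, cfg$protocol$mode,
              attr(cfg, "hash")), file = logf)
  cell <- paced_initial_state(cfg$electrics$init_period,
                              n_beats = cfg$electrics$init_beats,
                              params = ob$params, dt = cfg$electrics$dt)
  pr <- cfg$protocol
  res <- switch(pr$name,
    cell = {
      r <- run_cell(cell, duration = pr$period * 2, dt = cfg$electrics$dt,
                    params = ob$params, sac = ob$sac,
                    lambda = if (pr$mode == "constant_stretch") pr$lambda else 1,
                    vset = list(list(t = 5, v = 0), list(t = 5 + pr$period, v = 0)),
                    nhs = list(params = ob$nhs))
      utils::write.csv(r$trace, file.path(out_dir, "cell-trace.csv"),
                       row.names = FALSE)
      r
    },
    fiber = {
      r <- run_cell(cell, duration = pr$duration, dt = cfg$electrics$dt,
                    params = ob$params, lambda = 1,
                    vset = list(list(t = 5, v = 0)),
                    nhs = list(params = ob$nhs))
      utils::write.csv(r$trace, file.path(out_dir, "fiber-trace.csv"),
                       row.names = FALSE)
      r
    },
    sheet = {
      r <- run_paced_sheet(cell, period = pr$period, n_beats = pr$n_cond + pr$n_meas,
                           nx = cfg$grid$nx, ny = cfg$grid$ny, hs = cfg$grid$hs,
                           D = cfg$grid$D, dt = cfg$electrics$dt, mode = pr$mode,
                           sac = ob$sac, lambda = pr$lambda, params = ob$params,
                           mech = ob$mech, nhs = ob$nhs,
                           stim_amp = cfg$electrics$stim_amp,
                           stim_dur = cfg$electrics$stim_dur,
                           record_from = pr$n_cond * pr$period)
      utils::write.csv(rbind(cbind(r$trace_center, probe_name = "center"),
                             cbind(r$trace_down, probe_name = "down")),
                       file.path(out_dir, "sheet-traces.csv"), row.names = FALSE)
      cat(sprintf("mech iterations: median %.0f max %.0f\n",
                  if (length(r$mech_iters)) median(r$mech_iters) else 0,
                  if (length(r$mech_iters)) max(r$mech_iters) else 0),
          file = logf, append = TRUE)
      r
    },
    restitution = {
      r <- restitution_scan(pr$periods, pr$gs_values, mode = pr$mode,
                            cell = cell, n_cond = pr$n_cond, n_meas = pr$n_meas,
                            nx = cfg$grid$nx, ny = cfg$grid$ny, hs = cfg$grid$hs,
                            D = cfg$grid$D, dt = cfg$electrics$dt,
                            params = ob$params, mech = ob$mech, nhs = ob$nhs,
                            stim_amp = cfg$electrics$stim_amp,
                            stim_dur = cfg$electrics$stim_dur)
      utils::write.csv(as.data.frame(r), file.path(out_dir, "restitution.csv"),
                       row.names = FALSE)
      r
    },
    spiral = {
      init <- s1s2_spiral_init(cell, nx = cfg$grid$nx, ny = cfg$grid$ny,
                               hs = cfg$grid$hs, D = cfg$grid$D,
                               dt = cfg$electrics$dt, mode = pr$mode,
                               params = ob$params, mech = ob$mech, nhs = ob$nhs)
      rows <- lapply(pr$gs_values, function(g) {
        r <- spiral_run(init, mode = pr$mode, gs = g, duration = pr$duration,
                        lambda = pr$lambda, sac_template = ob$sac)
        m <- tryCatch(spiral_metrics(r$traj), error = function(e) NULL)
        utils::write.csv(r$traj, file.path(
          out_dir, sprintf("tip-trajectory-gs%.3f.csv", g)), row.names = FALSE)
        data.frame(gs = g,
                   core_radius = if (is.null(m)) NA else m$core_radius,
                   period = if (is.null(m)) NA else m$period,
                   drift_velocity = if (is.null(m)) NA else m$drift_velocity)
      })
      out <- do.call(rbind, rows)
      utils::write.csv(out, file.path(out_dir, "spiral-metrics.csv"),
                       row.names = FALSE)
      out
    })
  invisible(res)
}
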