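## Scenario orchestration: each command reproduces one of the standard
## experiment designs (kinetics time series, steady-state mass and
## turnover sweeps over serum T / R_t / inhibition, AR-evolution runs,
## calibration round trips) and writes RFC 4180 CSVs plus a JSON run
## manifest.

## kinetic params for a scenario's eta (inhibition multiplier on K_M)
.kp_with_eta <- function(kp, eta) {
  kp$K_M <- kp$K_M * eta
  kp
}

.fmt_tag <- function(x) gsub("\\.", "p", format(x, trim = TRUE))

#' Run a scenario command
#'
#' Executes one of the orchestrated experiment designs under a validated
#' configuration and writes its outputs (CSV files and a JSON manifest)
#' into `out_dir`. Commands:
#'
#' * `kinetics`: time series of the kinetics model for each `(T_S, eta)`
#'   scenario.
#' * `growth-sweep`: steady-state cell count and turnover over the
#'   `sweep$T_S` x `sweep$R_t` grid.
#' * `turnover-sweep`: turnover over `sweep$T_S` x `sweep$eta` at the
#'   configured `R_t`.
#' * `evolve`: average-AR evolution series for each scenario.
#' * `fixtures`: synthetic steady-state tissue dataset.
#' * `calibrate`: influx inference + saturating fit + reductase fit on the
#'   configured dataset (or a generated fixture when none is given).
#'
#' @param cfg a [parse_config()] object.
#' @param command one of `"kinetics"`, `"growth-sweep"`,
#'   `"turnover-sweep"`, `"evolve"`, `"calibrate"`, `"fixtures"`.
#' @param out_dir output directory (created if missing).
#' @param seed optional integer overriding `cfg$seed`.
#' @return (invisibly) character vector of files written, the manifest
#'   last.
#' @export
run_scenario <- function(cfg, command = c("kinetics", "growth-sweep",
                                          "turnover-sweep", "evolve",
                                          "calibrate", "fixtures"),
                         out_dir = ".", seed = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  command <- match.arg(command)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- if (is.null(seed)) as.integer(cfg$seed) else as.integer(seed)
  lvl <- cfg$log_level
  t0 <- proc.time()[["elapsed"]]
  kp <- cfg$kinetic_params
  g <- cfg$growth_params
  outputs <- character(0)
  ok <- TRUE
  err <- NULL

  log_msg("info", "command=", command, " seed=", seed,
          " effective_K_M=", format(kp$K_M *
            (1 + kp$inhibitor_I / kp$K_I)), " nM", cfg_level = lvl)

  result <- tryCatch({
    if (command == "kinetics") {
      for (sc in cfg$scenarios) {
        kpe <- .kp_with_eta(kp, sc$eta)
        traj <- simulate_kinetics(kpe, sc$T_S,
                                  t_end = cfg$simulation$t_end_h,
                                  n_out = cfg$simulation$n_out)
        f <- file.path(out_dir, sprintf("kinetics_TS%s_eta%s.csv",
                                        .fmt_tag(sc$T_S),
                                        .fmt_tag(sc$eta)))
        write_trajectory_csv(traj, f)
        outputs <- c(outputs, f)
      }
    } else if (command == "growth-sweep") {
      rows <- expand.grid(T_S_nM = cfg$sweep$T_S, R_t_nM = cfg$sweep$R_t,
                          eta = 1, KEEP.OUT.ATTRS = FALSE)
      rows <- .sweep_rows(rows, kp, g)
      f <- file.path(out_dir, "growth_sweep.csv")
      utils::write.csv(rows, f, row.names = FALSE)
      outputs <- c(outputs, f)
    } else if (command == "turnover-sweep") {
      rows <- expand.grid(T_S_nM = cfg$sweep$T_S, R_t_nM = kp$R_t,
                          eta = cfg$sweep$eta, KEEP.OUT.ATTRS = FALSE)
      rows <- .sweep_rows(rows, kp, g)
      f <- file.path(out_dir, "turnover_sweep.csv")
      utils::write.csv(rows, f, row.names = FALSE)
      outputs <- c(outputs, f)
    } else if (command == "evolve") {
      grid <- build_state_grid(cfg$evolution$Q, cfg$evolution$Rt_min,
                               cfg$evolution$step)
      ep <- evolution_params(gamma = cfg$evolution$gamma,
                             t_end = cfg$evolution$t_end,
                             init_mode = cfg$evolution$init_mode,
                             init_state_Rt = cfg$evolution$init_state_Rt,
                             output_stride = cfg$evolution$output_stride)
      for (sc in cfg$scenarios) {
        env <- per_state_environment(grid, kp, sc$T_S, sc$eta, g)
        sim <- simulate_evolution(grid, env, g, ep)
        f <- file.path(out_dir, sprintf("evolve_TS%s_eta%s.csv",
                                        .fmt_tag(sc$T_S),
                                        .fmt_tag(sc$eta)))
        utils::write.csv(as.data.frame(sim), f, row.names = FALSE)
        outputs <- c(outputs, f)
      }
    } else if (command == "fixtures") {
      ds <- generate_synthetic_dataset(kp, cfg$calibration$T_S_grid,
                                       noise_cv = cfg$calibration$noise_cv,
                                       seed = seed)
      f <- file.path(out_dir, "fixtures.csv")
      write_tissue_dataset(ds, f)
      outputs <- c(outputs, f)
    } else if (command == "calibrate") {
      ds <- if (!is.null(cfg$calibration$dataset)) {
        read_tissue_dataset(cfg$calibration$dataset)
      } else {
        log_msg("info", "no dataset configured; calibrating against a ",
                "generated fixture", cfg_level = lvl)
        generate_synthetic_dataset(kp, cfg$calibration$T_S_grid,
                                   noise_cv = cfg$calibration$noise_cv,
                                   seed = seed)
      }
      tab <- infer_influx_table(ds, kp)
      f1 <- file.path(out_dir, "influx_table.csv")
      utils::write.csv(tab, f1, row.names = FALSE)
      infl <- fit_influx_function(tab)
      fit <- fit_reductase(ds, infl, kp)
      f2 <- file.path(out_dir, "calibration_fit.json")
      jsonlite::write_json(
        list(influx = list(u_max = infl$u_max, u_half = infl$u_half,
                           fit = attr(infl, "fit")),
             reductase = list(params = as.list(fit$params),
                              rss = fit$rss, converged = fit$converged,
                              identifiable = fit$identifiable)),
        f2, auto_unbox = TRUE, digits = NA, na = "null")
      outputs <- c(outputs, f1, f2)
    }
    TRUE
  }, error = function(e) {
    err <<- conditionMessage(e)
    ok <<- FALSE
    log_msg("error", err, cfg_level = lvl)
    FALSE
  })

  manifest <- list(
    command = command,
    package = "androscape",
    version = as.character(utils::packageVersion("androscape")),
    model_hash = model_hash(),
    config_hash = rlang::hash(jsonlite::toJSON(
      unclass(cfg)[setdiff(names(unclass(cfg)),
                           c("kinetic_params", "growth_params"))],
      auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)),
    seed = seed,
    wall_time_s = proc.time()[["elapsed"]] - t0,
    outputs = basename(outputs),
    success = ok,
    error = if (is.null(err)) NULL else err
  )
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (!ok) stop("run_scenario failed: ", err, call. = FALSE)
  invisible(c(outputs, mf))
}

## one steady-state evaluation per sweep row
.sweep_rows <- function(rows, kp, g) {
  vals <- t(vapply(seq_len(nrow(rows)), function(i) {
    kpe <- .kp_with_eta(kp, rows$eta[i])
    kpe$R_t <- rows$R_t_nM[i]
    ss <- kinetics_steady_state(kpe, rows$T_S_nM[i])
    ct <- effective_complex(ss[["C_TR"]], ss[["C_DR"]], g$w_dht)
    c(ct, ros_level(ct, g), growth_steady_state(ct, g),
      turnover_rate(ct, g))
  }, numeric(4)))
  rows$C_t_nM <- vals[, 1]
  rows$S <- vals[, 2]
  rows$P_star_cells <- vals[, 3]
  rows$turnover_per_h <- vals[, 4]
  rows
}

#' Hash of the model right-hand sides
#'
#' A short stable hash of the deparsed kinetics, growth and evolution
#' equations, so a run manifest records exactly which reconstruction of
#' the model equations produced it.
#'
#' @return character scalar.
#' @export
model_hash <- function() {
  src <- paste(c(deparse(.kin_rhs), deparse(ros_level),
                 deparse(proliferation_signal), deparse(death_rate),
                 deparse(growth_rhs), deparse(mutation_fluxes),
                 deparse(evolution_rhs)), collapse = "\n")
  rlang::hash(src)
}
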