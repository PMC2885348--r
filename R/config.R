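## YAML scenario configuration: defaults are the baseline kinetics and
## growth tables; unknown keys are rejected so typos cannot silently fall
## back to defaults.

.config_defaults <- function() {
  list(
    kinetics = list(
      ka_T = 0.14, kd_T = 0.069, ka_D = 0.053, kd_D = 0.018,
      beta_R = log(2) / 3, beta_T = log(2) / 3, beta_D = log(2) / 9,
      alpha = 5, k_cat = 18, K_M = 75, K_I = 0.46, inhibitor_I = 0,
      R_t = 45, beta_R_norm = log(2) / 3,
      influx = list(form = "saturating", u_max = 1.4078, u_half = 4)
    ),
    growth = list(
      theta1 = 30, theta2 = 225, mu = 0.05, n = 4, m = 4,
      phi1 = 110, phi2 = 40, varphi = 4, omega = 1, q = 8,
      sigma = 1.5e-10, delta0 = 0.004, delta = log(2) / 24,
      r = log(2) / 24, w_dht = 2.4, k_apop = 2
    ),
    evolution = list(
      Q = 100L, Rt_min = 15, step = 1, gamma = 1e-5, t_end = 175200,
      init_mode = "point", init_state_Rt = 45, output_stride = 720
    ),
    scenarios = list(list(T_S = 5, eta = 1)),
    sweep = list(T_S = c(1, 2, 3, 5, 7, 10), R_t = c(25, 35, 45, 60),
                 eta = c(1, 2, 5, 10)),
    simulation = list(t_end_h = 2000, n_out = 201),
    calibration = list(T_S_grid = c(0.25, 0.5, 1, 2, 3, 5, 7, 10),
                       noise_cv = 0, dataset = NULL),
    seed = 1L,
    log_level = "info"
  )
}

## overlay user values onto defaults, rejecting unknown keys
.merge_config <- function(def, usr, path = "") {
  if (is.null(usr) || (is.list(usr) && length(usr) == 0)) return(def)
  if (!is.list(usr)) {
    stop("config error: section '", path, "' must be a mapping",
         call. = FALSE)
  }
  if (is.null(names(usr)) || any(names(usr) == "")) {
    stop("config error: unnamed entries under '", path, "'",
         call. = FALSE)
  }
  unknown <- setdiff(names(usr), names(def))
  if (length(unknown)) {
    stop("config error: unknown key(s) ",
         paste0("'", path, unknown, "'", collapse = ", "), call. = FALSE)
  }
  for (k in names(usr)) {
    if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
      def[[k]] <- .merge_config(def[[k]], usr[[k]],
                                paste0(path, k, "."))
    } else {
      def[[k]] <- usr[[k]]
    }
  }
  def
}

.check_positive <- function(cfg, keys, section) {
  for (k in keys) {
    v <- cfg[[k]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0)) {
      stop("config error: '", section, ".", k,
           "' must be non-negative and finite", call. = FALSE)
    }
  }
}

#' Parse and validate a scenario configuration
#'
#' Reads a YAML file, overlays it on the baseline defaults (kinetics and
#' growth parameter tables, evolution settings, sweep grids), validates
#' ranges, and materializes the parameter objects. An empty file (or
#' `path = NULL`) yields pure defaults. Unknown keys and out-of-range
#' values are rejected with the offending key path.
#'
#' @param path path to a YAML config file, or `NULL` for defaults.
#' @return object of class `scenario_config`: the validated list plus
#'   ready-built `$kinetic_params` and `$growth_params`.
#' @export
parse_config <- function(path = NULL) {
  usr <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop("config error: file not found: ", path, call. = FALSE)
    }
    usr <- yaml::read_yaml(path)
    if (is.null(usr)) usr <- list()  # empty file
  }
  cfg <- .merge_config(.config_defaults(), usr)

  ## YAML arrays mixing ints and floats arrive as lists; flatten the
  ## numeric-vector fields
  for (k in c("T_S", "R_t", "eta")) {
    cfg$sweep[[k]] <- as.numeric(unlist(cfg$sweep[[k]]))
    if (any(!is.finite(cfg$sweep[[k]])) || any(cfg$sweep[[k]] < 0)) {
      stop("config error: 'sweep.", k, "' must be non-negative numbers",
           call. = FALSE)
    }
  }
  cfg$calibration$T_S_grid <- as.numeric(unlist(cfg$calibration$T_S_grid))

  .check_positive(cfg$kinetics,
                  setdiff(names(cfg$kinetics), "influx"), "kinetics")
  .check_positive(cfg$growth, names(cfg$growth), "growth")
  .check_positive(cfg$evolution,
                  setdiff(names(cfg$evolution), "init_mode"), "evolution")
  if (!cfg$evolution$init_mode %in% c("point", "uniform")) {
    stop("config error: 'evolution.init_mode' must be 'point' or ",
         "'uniform'", call. = FALSE)
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 ||
      cfg$seed != round(cfg$seed)) {
    stop("config error: 'seed' must be a single integer", call. = FALSE)
  }
  if (!cfg$log_level %in% c("debug", "info", "warn", "error")) {
    stop("config error: 'log_level' must be one of debug, info, warn, ",
         "error", call. = FALSE)
  }
  for (i in seq_along(cfg$scenarios)) {
    sc <- cfg$scenarios[[i]]
    if (!is.list(sc) || !all(c("T_S", "eta") %in% names(sc)) ||
        sc$T_S < 0 || sc$eta < 1) {
      stop("config error: 'scenarios[", i, "]' needs T_S >= 0 and ",
           "eta >= 1", call. = FALSE)
    }
  }
  if (!is.null(cfg$calibration$noise_cv) && cfg$calibration$noise_cv < 0) {
    stop("config error: 'calibration.noise_cv' must be >= 0",
         call. = FALSE)
  }

  inf <- cfg$kinetics$influx
  influx_obj <- if (identical(inf$form, "tabulated")) {
    influx_params(form = "tabulated",
                  table = as.data.frame(inf$table))
  } else {
    influx_params(u_max = inf$u_max, u_half = inf$u_half)
  }
  kin_args <- cfg$kinetics
  kin_args$influx <- influx_obj
  cfg$kinetic_params <- do.call(kinetic_params, kin_args)
  cfg$growth_params <- do.call(growth_params, cfg$growth)
  structure(cfg, class = "scenario_config")
}

## leveled logging to stderr; numeric formatting is locale-independent
.log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)
log_msg <- function(level, ..., cfg_level = "info") {
  if (.log_levels[[level]] >= .log_levels[[cfg_level]]) {
    message(sprintf("[%s] %s", toupper(level), paste0(...)))
  }
  invisible(NULL)
}
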