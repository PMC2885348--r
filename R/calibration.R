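## Steady-state parameter inference. The influx U(T_S) is identified from
## finasteride-condition tissue data (reductase blocked, so at steady state
## the binding fluxes net zero and influx balances first-order free-T
## degradation: U = beta_T * T_free, with T_free recovered from the total-T
## binding equilibrium at imposed R_t). The reductase level alpha and DHT
## degradation rate beta_D are then fit to the uninhibited arm. All fitting
## is validated by parameter recovery on synthetic datasets; no digitized
## literature data ship with the package.

#' Convert receptor content to intracellular concentration
#'
#' `fmol per mg cytosol protein x g protein per L / 1000 = nM`. At the
#' cited 200-300 g/L intracellular protein, 1 fmol/mg corresponds to
#' 0.2-0.3 nM, and measured AR contents of 80-150 fmol/mg give 16-45 nM.
#'
#' @param content receptor content (fmol per mg protein), >= 0.
#' @param protein_conc intracellular protein concentration (g/L), >= 0.
#' @return concentration in nM.
#' @export
#' @examples
#' fmol_per_mg_to_nM(80, 200)  # 16 nM
fmol_per_mg_to_nM <- function(content, protein_conc) {
  if (any(content < 0) || any(protein_conc < 0)) {
    stop("invalid-parameter: inputs must be >= 0", call. = FALSE)
  }
  content * protein_conc / 1000
}

#' Free testosterone from a total-testosterone measurement
#'
#' Solves the single-ligand binding equilibrium
#' `total_T = T_f + R_t * T_f / (K_D + T_f)` for the free concentration
#' `T_f` (the bound complex being `R_t * T_f / (K_D + T_f)` at imposed
#' total receptor `R_t`). The unique non-negative root of the underlying
#' quadratic is returned in a numerically stable form.
#'
#' @param total_T total (free + bound) testosterone (nM), >= 0.
#' @param R_t imposed total AR concentration (nM), >= 0.
#' @param K_D equilibrium dissociation constant (nM), > 0.
#' @return free testosterone (nM), in `[0, total_T]`. Vectorized.
#' @export
free_from_total_T <- function(total_T, R_t, K_D) {
  if (any(total_T < 0) || any(R_t < 0)) {
    stop("invalid-parameter: concentrations must be >= 0", call. = FALSE)
  }
  if (any(K_D <= 0)) {
    stop("invalid-parameter: K_D must be > 0", call. = FALSE)
  }
  ## T_f^2 + (K_D + R_t - total_T) T_f - K_D total_T = 0, positive root
  b <- K_D + R_t - total_T
  2 * K_D * total_T / (b + sqrt(b^2 + 4 * K_D * total_T))
}

#' Validate a tissue concentration dataset
#'
#' Rows of steady-state measurements: serum testosterone, total
#' intraprostatic T, total intraprostatic DHT, and a finasteride flag.
#'
#' @param data data.frame with columns `serum_T_nM`, `total_T_nM`,
#'   `total_DHT_nM`, `finasteride` (0/1 or logical).
#' @return the validated data.frame (flag coerced to logical), invisibly
#'   classed `tissue_dataset`.
#' @export
as_tissue_dataset <- function(data) {
  need <- c("serum_T_nM", "total_T_nM", "total_DHT_nM", "finasteride")
  if (!is.data.frame(data) || !all(need %in% names(data))) {
    stop("data error: tissue dataset needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  data$finasteride <- as.logical(data$finasteride)
  conc <- c("serum_T_nM", "total_T_nM", "total_DHT_nM")
  if (any(unlist(data[conc]) < 0, na.rm = FALSE) ||
      any(!is.finite(unlist(data[conc])))) {
    stop("data error: concentrations must be finite and >= 0",
         call. = FALSE)
  }
  for (fl in unique(data$finasteride)) {
    if (anyDuplicated(data$serum_T_nM[data$finasteride == fl])) {
      stop("data error: serum_T_nM must be unique within each ",
           "finasteride condition", call. = FALSE)
    }
  }
  class(data) <- c("tissue_dataset", "data.frame")
  data
}

#' Infer the influx table from finasteride-condition data
#'
#' With the reductase blocked (`alpha = 0`) and total AR imposed at `R_t`,
#' the steady state requires the influx to balance free-T degradation:
#' `U = beta_T * T_free`, where `T_free` follows from the binding
#' equilibrium [free_from_total_T()]. Larger `R_t` binds more of the
#' measured total, implying a smaller inferred `U`.
#'
#' @param data a tissue dataset ([as_tissue_dataset()]) containing at
#'   least 2 finasteride rows.
#' @param kp a [kinetic_params()] object supplying `beta_T`, `R_t`, and
#'   the T:AR dissociation constant.
#' @return data.frame with columns `T_S` and `U` (nM/h), sorted by `T_S`.
#' @export
infer_influx_table <- function(data, kp) {
  stopifnot(inherits(kp, "kinetic_params"))
  data <- as_tissue_dataset(as.data.frame(data))
  fin <- data[data$finasteride, , drop = FALSE]
  if (nrow(fin) < 2) {
    stop("data error: need at least 2 finasteride rows to infer influx",
         call. = FALSE)
  }
  KD_T <- dissociation_constant(kp$ka_T, kp$kd_T)
  Tf <- free_from_total_T(fin$total_T_nM, kp$R_t, KD_T)
  out <- data.frame(T_S = fin$serum_T_nM, U = kp$beta_T * Tf)
  out[order(out$T_S), , drop = FALSE]
}

#' Fit a saturating influx curve to an inferred influx table
#'
#' Ordinary least squares fit of `U = u_max * T_S / (u_half + T_S)` (which
#' passes through the origin by construction). Degenerate tables with no
#' variation in `U` are flagged as a poor fit rather than fitted.
#'
#' @param table data.frame with columns `T_S` and `U`, >= 2 points.
#' @param form only `"saturating"` is supported.
#' @return an [influx_params()] object with attribute `fit`, a list
#'   `(rss, converged, poor_fit, n_obs)`.
#' @export
fit_influx_function <- function(table, form = "saturating") {
  form <- match.arg(form, "saturating")
  if (!is.data.frame(table) || !all(c("T_S", "U") %in% names(table)) ||
      nrow(table) < 2) {
    stop("data error: need a (T_S, U) table with at least 2 points",
         call. = FALSE)
  }
  tab <- table[table$T_S > 0, , drop = FALSE]
  if (nrow(tab) < 2 || stats::sd(tab$U) == 0) {
    p <- influx_params(u_max = max(table$U, 0), u_half = 1)
    attr(p, "fit") <- list(rss = NA_real_, converged = FALSE,
                           poor_fit = TRUE, n_obs = nrow(table))
    return(p)
  }
  u_max0 <- max(tab$U) * 1.5
  u_half0 <- tab$T_S[which.min(abs(tab$U - max(tab$U) / 2))]
  if (u_half0 <= 0) u_half0 <- stats::median(tab$T_S)
  obj <- function(par) {
    um <- exp(par[1]); uh <- exp(par[2])
    sum((tab$U - um * tab$T_S / (uh + tab$T_S))^2)
  }
  opt <- stats::optim(log(c(u_max0, u_half0)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  p <- influx_params(u_max = exp(opt$par[1]), u_half = exp(opt$par[2]))
  attr(p, "fit") <- list(rss = opt$value,
                         converged = opt$convergence == 0,
                         poor_fit = FALSE, n_obs = nrow(table))
  p
}

## model-predicted steady-state totals for one serum level
.model_totals <- function(T_S, kp) {
  ss <- kinetics_steady_state(kp, T_S)
  c(ss[["T"]] + ss[["C_TR"]], ss[["D"]] + ss[["C_DR"]])
}

#' Fit reductase level and DHT degradation to uninhibited tissue data
#'
#' Minimizes the summed squared residuals between model steady-state
#' (total T, total DHT) and the no-finasteride rows, over
#' `(alpha, beta_D)`, with all other kinetic parameters (including the
#' influx function) held fixed. Both totals are weighted equally, in nM.
#'
#' If the data contain essentially no DHT, `alpha` is driven to 0 and
#' `beta_D` is structurally unidentifiable; the result is flagged.
#'
#' @param data a tissue dataset with >= 2 no-finasteride rows.
#' @param influx an [influx_params()] object (typically from
#'   [fit_influx_function()]).
#' @param kp a [kinetic_params()] object for the fixed parameters.
#' @param start positive initial guesses, named `alpha` and `beta_D`.
#' @return object of class `fit_result`: list with `params` (named:
#'   `alpha`, `beta_D`), `rss`, `converged`, `identifiable`, `n_obs`.
#' @export
fit_reductase <- function(data, influx, kp,
                          start = c(alpha = 1, beta_D = 0.05)) {
  stopifnot(inherits(influx, "influx_params"),
            inherits(kp, "kinetic_params"))
  data <- as_tissue_dataset(as.data.frame(data))
  nofin <- data[!data$finasteride, , drop = FALSE]
  if (nrow(nofin) < 2) {
    stop("data error: need at least 2 no-finasteride rows", call. = FALSE)
  }
  if (any(start <= 0)) {
    stop("invalid-parameter: start values must be > 0", call. = FALSE)
  }
  kp_fix <- kp
  kp_fix$influx <- influx

  identifiable <- max(nofin$total_DHT_nM) > 1e-6 * max(1, nofin$total_T_nM)
  if (!identifiable) {
    res <- structure(list(params = c(alpha = 0, beta_D = NA_real_),
                          rss = NA_real_, converged = TRUE,
                          identifiable = FALSE, n_obs = nrow(nofin)),
                     class = "fit_result")
    return(res)
  }

  obj <- function(par) {
    kp_try <- kp_fix
    kp_try$alpha <- exp(par[1])
    kp_try$beta_D <- exp(par[2])
    ## degenerate corners (e.g. beta_D -> 0 with DHT production on) have
    ## no steady state; penalize instead of erroring out of the search
    pred <- tryCatch(
      vapply(nofin$serum_T_nM, .model_totals, numeric(2), kp = kp_try),
      error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred))) return(1e12)
    sum((pred[1, ] - nofin$total_T_nM)^2 +
          (pred[2, ] - nofin$total_DHT_nM)^2)
  }
  opt <- stats::optim(unname(log(start[c("alpha", "beta_D")])), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 3000, reltol = 1e-14))
  if (opt$convergence != 0) {
    warning("fit error: reductase fit did not converge (code ",
            opt$convergence, ")", call. = FALSE)
  }
  structure(list(params = c(alpha = unname(exp(opt$par[1])),
                            beta_D = unname(exp(opt$par[2]))),
                 rss = opt$value, converged = opt$convergence == 0,
                 identifiable = TRUE, n_obs = nrow(nofin)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Steady-state fit:", x$n_obs, "rows, rss =", signif(x$rss, 5), "\n")
  print(x$params)
  if (!x$identifiable) cat("  (beta_D structurally unidentifiable)\n")
  invisible(x)
}

#' Serialize a fit result to JSON
#'
#' @param fit a `fit_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  jsonlite::write_json(
    list(params = as.list(fit$params), rss = fit$rss,
         converged = fit$converged, identifiable = fit$identifiable,
         n_obs = fit$n_obs),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Generate a synthetic steady-state tissue dataset
#'
#' Emulates the design of the classic castrated-rat infusion experiments:
#' for each serum testosterone level, one arm with the reductase active
#' (`alpha` as given) and, optionally, one arm with it fully blocked
#' (`alpha = 0`, the idealized finasteride limit, in which no DHT is
#' made). Totals are the kinetics steady-state values, optionally
#' perturbed by multiplicative log-normal noise with coefficient of
#' variation `noise_cv` (mean-preserving). The result is deterministic
#' given `seed`.
#'
#' @param true_params a [kinetic_params()] object (ground truth).
#' @param T_S_grid serum testosterone levels (nM), non-empty.
#' @param noise_cv coefficient of variation of the multiplicative noise;
#'   0 gives exact model output.
#' @param seed integer seed used for the noise draws.
#' @param include_finasteride include the blocked arm (default TRUE).
#' @return a `tissue_dataset` data.frame.
#' @export
generate_synthetic_dataset <- function(true_params, T_S_grid,
                                       noise_cv = 0, seed = 1L,
                                       include_finasteride = TRUE) {
  stopifnot(inherits(true_params, "kinetic_params"))
  if (!length(T_S_grid)) {
    stop("invalid-input: T_S_grid must be non-empty", call. = FALSE)
  }
  if (noise_cv < 0) {
    stop("invalid-parameter: noise_cv must be >= 0", call. = FALSE)
  }
  arms <- if (include_finasteride) c(FALSE, TRUE) else FALSE
  rows <- do.call(rbind, lapply(arms, function(fin) {
    kp <- true_params
    if (fin) kp$alpha <- 0
    tt <- vapply(T_S_grid, function(ts) {
      ss <- kinetics_steady_state(kp, ts)
      state_totals(ss)[c("total_T", "total_DHT")]
    }, numeric(2))
    data.frame(serum_T_nM = T_S_grid, total_T_nM = tt[1, ],
               total_DHT_nM = tt[2, ], finasteride = fin)
  }))
  if (noise_cv > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(as.integer(seed))
    sdlog <- sqrt(log(1 + noise_cv^2))
    noisy <- function(x) {
      eps <- stats::rlnorm(length(x), meanlog = -sdlog^2 / 2,
                           sdlog = sdlog)
      x * eps  # zero stays exactly zero
    }
    rows$total_T_nM <- noisy(rows$total_T_nM)
    rows$total_DHT_nM <- noisy(rows$total_DHT_nM)
  }
  rownames(rows) <- NULL
  as_tissue_dataset(rows)
}

#' Read / write tissue datasets as CSV
#'
#' @param path file path.
#' @return for the reader, a `tissue_dataset`; the writer returns `path`
#'   invisibly.
#' @export
read_tissue_dataset <- function(path) {
  as_tissue_dataset(utils::read.csv(path))
}

#' @param data a `tissue_dataset`.
#' @rdname read_tissue_dataset
#' @export
write_tissue_dataset <- function(data, path) {
  data <- as_tissue_dataset(as.data.frame(data))
  data$finasteride <- as.integer(data$finasteride)
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}
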