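config_defaults <- function() {
  list(
    kind = "trajectory",
    model = list(r = 0.61, c0 = 0.04, n = 1.6, T = 0.01, hill = TRUE),
    stimulus = list(type = "poisson", rate = 8, duration = 100,
                    tau_c = 0.03, delta_c = 0.5,
                    alpha = 0.02, phi = 2, tau = 0.2,
                    n_pulses = 30),
    noise = NULL,
    integrator = list(dt = 0.001, x0 = NULL),
    analysis = list(sigma_grid = NULL, trials = 10, sr_duration = 200,
                    r_values = 0.59),
    seed = 1L
  )
}

merge_config <- function(defaults, user, path = character()) {
  for (nm in names(user)) {
    if (!nm %in% names(defaults)) {
      abort(paste0("unknown config field: ",
                   paste(c(path, nm), collapse = "$")))
    }
    if (is.list(defaults[[nm]]) && !is.null(defaults[[nm]]) &&
        is.list(user[[nm]])) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], c(path, nm))
    } else {
      # defaults[nm] <- list(...) keeps explicit NULLs instead of dropping them
      defaults[nm] <- list(user[[nm]])
    }
  }
  defaults
}

#' Validate and complete a run configuration
#'
#' Fills every omitted field with its documented default (no silent
#' defaults: the returned object carries the complete configuration),
#' rejects unknown keys, and checks parameter ranges, including the
#' discretization guard `dt < tau_eta` when noise is enabled and the
#' physiological warning `alpha > c0` for sinusoidal drive.
#'
#' @param config A named list; see [run_config()] for the recognized
#'   fields. An empty list yields the fully defaulted configuration.
#' @return A validated configuration of class `run_config`.
#' @export
validate_config <- function(config = list()) {
  stopifnot(is.list(config))
  cfg <- merge_config(config_defaults(), config)
  m <- cfg$model
  if (m$r < 0) abort("invalid config: `model$r` must be >= 0")
  if (m$c0 < 0) abort("invalid config: `model$c0` must be >= 0")
  if (m$n <= 0) abort("invalid config: `model$n` must be > 0")
  if (m$T <= 0) abort("invalid config: `model$T` must be > 0")
  s <- cfg$stimulus
  if (!s$type %in% c("poisson", "regular", "sinusoid", "exp_decay", "none"))
    abort("invalid config: unknown `stimulus$type`")
  if (s$rate < 0) abort("invalid config: `stimulus$rate` must be >= 0")
  if (s$duration <= 0) abort("invalid config: `stimulus$duration` must be > 0")
  if (cfg$integrator$dt <= 0) abort("invalid config: `integrator$dt` must be > 0")
  if (!is.null(cfg$noise)) {
    if (is.null(cfg$noise$tau_eta)) cfg$noise$tau_eta <- 0.01
    if (is.null(cfg$noise$bound)) cfg$noise$bound <- 5
    if (is.null(cfg$noise$sigma)) abort("invalid config: `noise$sigma` missing")
    if (cfg$noise$sigma < 0) abort("invalid config: `noise$sigma` must be >= 0")
    if (cfg$integrator$dt >= cfg$noise$tau_eta)
      abort("invalid config: `integrator$dt` must be < `noise$tau_eta`")
  }
  if (s$type == "sinusoid" && s$alpha > m$c0)
    warn("config: `stimulus$alpha` > `model$c0`; drive will be floored at 0")
  if (!cfg$kind %in% c("trajectory", "sr_sweep", "discrepancy", "dekoninck",
                       "chang"))
    abort("invalid config: unknown `kind`")
  class(cfg) <- "run_config"
  cfg
}

config_stimulus <- function(cfg) {
  s <- cfg$stimulus
  dt <- cfg$integrator$dt
  switch(s$type,
    poisson = {
      tr <- poisson_pulse_train(s$rate, s$duration, seed = cfg$seed)
      pulses_to_calcium(tr, s$tau_c, s$delta_c, cfg$model$c0, dt)
    },
    regular = {
      tr <- regular_pulse_train(s$rate, s$n_pulses, duration = s$duration)
      pulses_to_calcium(tr, s$tau_c, s$delta_c, cfg$model$c0, dt)
    },
    sinusoid = sinusoidal_input(cfg$model$c0, s$alpha, s$phi, s$duration, dt),
    exp_decay = {
      tr <- regular_pulse_train(s$rate, s$n_pulses, duration = s$duration)
      exp_decay_calcium(tr, s$tau, s$delta_c, cfg$model$c0, dt)
    },
    none = sinusoidal_input(cfg$model$c0, 0, 0, s$duration, dt)
  )
}

#' Execute a validated configuration
#'
#' Dispatches on `config$kind`:
#' \describe{
#'   \item{`"trajectory"`}{build the stimulus, integrate (with OU noise if
#'     `noise` is set), return the trajectory.}
#'   \item{`"sr_sweep"`}{run [sr_sweep()] with the configured grid/trials.}
#'   \item{`"discrepancy"`}{run [discrepancy_experiment()] at
#'     `analysis$r_values`.}
#'   \item{`"dekoninck"` / `"chang"`}{run the corresponding protocol.}
#' }
#' All randomness derives from `config$seed`; re-running the same
#' configuration reproduces the numbers exactly. When `out_dir` is given
#' the result table is written as CSV next to a JSON manifest recording the
#' full configuration, seed, package version and an MD5 checksum of the
#' CSV.
#'
#' @param config A list (validated via [validate_config()] if not already).
#' @param out_dir Optional output directory.
#' @return A list with elements `result` (a tibble) and `manifest` (a list).
#' @export
run_config <- function(config = list(), out_dir = NULL) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  params <- switch_params(r = cfg$model$r, c0 = cfg$model$c0, n = cfg$model$n,
                          T = cfg$model$T, hill = cfg$model$hill)
  result <- switch(cfg$kind,
    trajectory = {
      sig <- config_stimulus(cfg)
      if (is.null(cfg$noise)) {
        simulate_switch(params, sig, x0 = cfg$integrator$x0)
      } else {
        simulate_switch_noisy(params, sig, cfg$noise$sigma, cfg$noise$tau_eta,
                              cfg$noise$bound, seed = cfg$seed,
                              x0 = cfg$integrator$x0)
      }
    },
    sr_sweep = {
      a <- cfg$analysis
      grid <- a$sigma_grid %||% exp(seq(log(0.005), log(1), length.out = 30))
      sr_sweep(params, sigma_grid = grid, trials = a$trials,
               duration = a$sr_duration, alpha = cfg$stimulus$alpha,
               phi = cfg$stimulus$phi,
               tau_eta = if (is.null(cfg$noise)) 0.01 else cfg$noise$tau_eta,
               dt = cfg$integrator$dt, seed = cfg$seed)
    },
    discrepancy = discrepancy_experiment(cfg$analysis$r_values, n = cfg$model$n,
                                         T = cfg$model$T,
                                         rate = cfg$stimulus$rate,
                                         duration = cfg$stimulus$duration,
                                         trials = cfg$analysis$trials,
                                         dt = cfg$integrator$dt,
                                         seed = cfg$seed),
    dekoninck = dekoninck_protocol(params = params, dt = cfg$integrator$dt),
    chang = chang_protocol(n = cfg$model$n, T = cfg$model$T,
                           dt = cfg$integrator$dt)
  )
  manifest <- list(config = unclass(cfg), seed = cfg$seed,
                   package = "switchdyn",
                   version = as.character(utils::packageVersion("switchdyn")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    csv <- file.path(out_dir, paste0(cfg$kind, ".csv"))
    utils::write.csv(as.data.frame(result), csv, row.names = FALSE)
    manifest$outputs <- list(list(file = basename(csv),
                                  md5 = unname(tools::md5sum(csv))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(result = result, manifest = manifest)
}

#' Named figure-style presets
#'
#' Ready-made configurations for the package's reference simulations:
#' `"fig2a"` (8 Hz Poisson-driven tracking example: n = 1.6, r = 0.61,
#' c0 = 0.04, T = 0.01, alpha-kernel calcium with delta_c = 0.5),
#' `"fig3a"` (noisy sinusoid-driven trajectory, n = 1.6, r = 0.61,
#' sigma = 0.09), `"fig3b-n2"` and `"fig3b-n16"` (stochastic-resonance
#' sweeps for n = 2, r = 0.65 and n = 1.6, r = 0.61), `"fig2d-ii"`
#' (paired-arm discrepancy at r = 0.59), `"fig3e"` (frequency/duration
#' decoding grid) and `"fig3f"` (wild-type vs mutant 1 Hz protocol).
#'
#' @param name Preset name.
#' @param seed Master seed recorded in the configuration.
#' @param scale Factor in `(0, 1]` shrinking durations and trial counts for
#'   quick runs.
#' @return A validated `run_config`.
#' @export
preset_config <- function(name, seed = 1L, scale = 1) {
  stopifnot(scale > 0, scale <= 1)
  base <- switch(name,
    "fig2a" = list(kind = "trajectory",
                   model = list(r = 0.61, c0 = 0.04, n = 1.6, T = 0.01),
                   stimulus = list(type = "poisson", rate = 8,
                                   duration = max(10 * scale, 1))),
    "fig3a" = list(kind = "trajectory",
                   model = list(r = 0.61, c0 = 0.04, n = 1.6, T = 0.01),
                   stimulus = list(type = "sinusoid",
                                   duration = max(200 * scale, 10)),
                   noise = list(sigma = 0.09, tau_eta = 0.01)),
    "fig3b-n2" = list(kind = "sr_sweep",
                      model = list(r = 0.65, c0 = 0.04, n = 2, T = 0.01),
                      stimulus = list(type = "sinusoid", duration = 200),
                      analysis = list(trials = max(2, round(10 * scale)),
                                      sr_duration = max(20, 200 * scale))),
    "fig3b-n16" = list(kind = "sr_sweep",
                       model = list(r = 0.61, c0 = 0.04, n = 1.6, T = 0.01),
                       stimulus = list(type = "sinusoid", duration = 200),
                       analysis = list(trials = max(2, round(10 * scale)),
                                       sr_duration = max(20, 200 * scale))),
    "fig2d-ii" = list(kind = "discrepancy",
                      model = list(r = 0.59, c0 = 0.04, n = 2, T = 0.01),
                      stimulus = list(type = "poisson", rate = 8,
                                      duration = max(10, 100 * scale)),
                      analysis = list(r_values = 0.59,
                                      trials = max(2, round(10 * scale)))),
    "fig3e" = list(kind = "dekoninck",
                   model = list(r = 0.61, c0 = 0, n = 1.6, T = 0.4)),
    "fig3f" = list(kind = "chang",
                   model = list(r = 0.58, c0 = 0, n = 1.6, T = 0.1)),
    abort(paste0("unknown preset: ", name))
  )
  base$seed <- seed
  validate_config(base)
}
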