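#' Default experiment configuration
#'
#' Complete configuration of a simulation experiment with every model
#' constant at its reference value: neuron blocks (`gpe`, `stn`), the
#' conductance set for the chosen `n_stn_gpe`, network type, stimulation
#' protocol, engine settings and analysis windows. [load_config()] merges a
#' user file over these defaults.
#'
#' @param n_stn_gpe STN->GPe out-degree preset (3 or 30).
#' @return Nested named list.
#' @export
default_config <- function(n_stn_gpe = 3) {
  list(
    neurons = list(gpe = unclass(gpe_params()), stn = unclass(stn_params())),
    network = list(type = "N", n_stn_gpe = n_stn_gpe, P = 0.1, d = 0.15,
                   n_ctx = 1000, n_msn = 1000, n_stn = 100, n_gpe = 300,
                   mu_scale = 1, msn_gpe_variant = "text"),
    conductances = conductance_preset(n_stn_gpe),
    rates = list(ctx = 4, msn = 0.67),
    protocol = list(mode = "one-site", period = 1700, n_stimuli = 500,
                    s0 = 0, delta_s = 0, delta_t = 0,
                    sigma_s = 0.05 / pi, warmup = 40000),
    engine = list(dt = 0.05, duration = NA, structure_seed = 1, seed = 1,
                  n_trials = 1, noise = "membrane",
                  record = c("stn", "gpe")),
    analysis = list(bin = 1, window = c(-100, 300),
                    rate_window = c(31000, 40000),
                    T_minus = 190, T_plus = 200, A = 0.045)
  )
}

#' Load and validate an experiment configuration
#'
#' Reads a YAML or JSON file, merges it over [default_config()] and
#' validates it. Unknown keys are rejected with their path, so typos fail
#' loudly rather than silently running the defaults.
#'
#' @param path file path (`.yaml`/`.yml`/`.json`), or `NULL` for pure
#'   defaults.
#' @return A validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    if (length(user) > 0) {
      check_known_keys(user, cfg, "")
      if (!is.null(user$network$n_stn_gpe) &&
          is.null(user$conductances))
        cfg$conductances <- conductance_preset(user$network$n_stn_gpe)
      cfg <- modify_deep(cfg, user)
    }
  }
  validate_config(cfg)
  cfg
}

modify_deep <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- modify_deep(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

check_known_keys <- function(user, base, path) {
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0)
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (nm in names(user))
    if (is.list(user[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(base[[nm]])) && length(names(user[[nm]])) > 0)
      check_known_keys(user[[nm]], base[[nm]], paste0(path, nm, "$"))
}

validate_config <- function(cfg) {
  if (!is.numeric(cfg$engine$dt) || cfg$engine$dt <= 0)
    stop("engine$dt must be positive")
  if (!cfg$network$type %in% c("N", "D", "S"))
    stop("network$type must be one of N, D, S")
  if (!cfg$protocol$mode %in% c("one-site", "two-site"))
    stop("protocol$mode must be 'one-site' or 'two-site'")
  stopifnot(cfg$protocol$period > 0, cfg$protocol$n_stimuli >= 1)
  invisible(cfg)
}

#' Instantiate circuit and protocol from a configuration
#'
#' @param cfg a [load_config()] list.
#' @return List with `circuit` and `protocol`.
#' @export
config_to_model <- function(cfg) {
  cond <- lapply(cfg$conductances, function(g) g * cfg$network$mu_scale)
  circuit <- build_circuit(
    n_stn_gpe = cfg$network$n_stn_gpe, network = cfg$network$type,
    conductances = cond, seed = cfg$engine$structure_seed,
    P = cfg$network$P, d = cfg$network$d,
    n_ctx = cfg$network$n_ctx, n_msn = cfg$network$n_msn,
    n_stn = cfg$network$n_stn, n_gpe = cfg$network$n_gpe,
    r_ctx = cfg$rates$ctx, r_msn = cfg$rates$msn,
    gpe = do.call(gpe_params, cfg$neurons$gpe[names(cfg$neurons$gpe) %in%
                                                names(gpe_params())]),
    stn = do.call(stn_params, cfg$neurons$stn[names(cfg$neurons$stn) %in%
                                                names(stn_params())]))
  protocol <- do.call(stimulation_protocol, cfg$protocol)
  list(circuit = circuit, protocol = protocol)
}

#' Run a configured experiment and write its artifacts
#'
#' Orchestrates build -> simulate -> analyse for one configuration: writes
#' the spike record (`spikes.csv`), the stimulus schedule
#' (`schedule.csv`), per-neuron rates (`rates.csv`), a centre-subset PSTH
#' (`psth.csv`, when the protocol has stimuli) and a `manifest.json` with
#' the resolved configuration, seeds and file checksums.
#'
#' @param cfg a configuration list from [load_config()].
#' @param out_dir output directory (created if missing).
#' @param stimulate if `FALSE`, run without stimulation for
#'   `engine$duration` ms.
#' @return Invisibly, the manifest list.
#' @export
run_experiment <- function(cfg, out_dir, stimulate = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- config_to_model(cfg)
  duration <- if (!stimulate) {
    if (is.na(cfg$engine$duration)) stop("engine$duration required")
    cfg$engine$duration
  } else NULL
  rec <- run_trials(model$circuit, n_trials = cfg$engine$n_trials,
                    seed = cfg$engine$seed, duration = duration,
                    protocol = if (stimulate) model$protocol else NULL,
                    dt = cfg$engine$dt,
                    record = cfg$engine$record, noise = cfg$engine$noise)

  utils::write.csv(rec$spikes, file.path(out_dir, "spikes.csv"),
                   row.names = FALSE)
  utils::write.csv(rec$schedule, file.path(out_dir, "schedule.csv"),
                   row.names = FALSE)
  win <- if (stimulate) c(0, rec$schedule$time[1]) else if
    (duration >= cfg$analysis$rate_window[2]) cfg$analysis$rate_window else
    c(duration / 2, duration)
  rates <- do.call(rbind, lapply(intersect(cfg$engine$record,
                                           c("stn", "gpe")), function(nuc) {
    r <- neuron_rates(rec, nuc, win)
    r$nucleus <- nuc
    r
  }))
  utils::write.csv(rates, file.path(out_dir, "rates.csv"), row.names = FALSE)
  if (stimulate && nrow(rec$schedule) > 0) {
    psth <- compute_psth(rec, "stn", bin = cfg$analysis$bin,
                         window = cfg$analysis$window)
    out <- data.frame(lag = psth$lag, t(psth$prob))
    utils::write.csv(out, file.path(out_dir, "psth.csv"), row.names = FALSE)
  }

  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                               null = "null", na = "null")
  files <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
  manifest <- list(config = cfg,
                   config_hash = unname(tools::md5sum(
                     writeLines_tmp(cfg_json))),
                   seeds = list(structure = cfg$engine$structure_seed,
                                dynamics = cfg$engine$seed),
                   package_version = as.character(
                     utils::packageVersion("stngpe")),
                   files = stats::setNames(as.list(unname(
                     tools::md5sum(files))), basename(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

writeLines_tmp <- function(x) {
  f <- tempfile(fileext = ".json")
  writeLines(x, f)
  f
}
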