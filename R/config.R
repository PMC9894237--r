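#' Default run configuration
#'
#' A nested list mirroring the model's parameter groups, with units spelled
#' out in the key names (the model is unit-landmine-dense). Serializable to
#' YAML with [write_run_config()] and validated strictly on read: unknown
#' keys are rejected rather than ignored.
#'
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    chemistry = list(
      k_h_per_s = 0.037, pK1_eff = 6.35, K_H_M_per_atm = 0.034,
      temperature_C = 25
    ),
    environment = list(
      pCO2 = 0.0004, pH_out = 7.0, pH_in = 7.0, total_pressure_atm = 1.0
    ),
    cell = list(
      P_C_cm_per_s = 0.3, P_H_cm_per_s = 3e-8, sa_v_per_cm = 1e4 / 0.3,
      gamma_per_s = 90, delta_per_s = 0, chi_per_s = 0, phi_per_s = 1,
      f_H = 0.02, volume_L = 1e-15, uptake_substrate = "CO2",
      q_C_uM = 1e10 / (.N_AVOGADRO * 1e-15) * 1e6, mu_max_per_h = Inf
    ),
    sweep = list(type = "leakage_heatmap", n_points = 25),
    fitness = list(counts_file = NULL, pseudocount = 0.5, min_t0_reads = 3,
                   t0_label = "T0"),
    simulate = list(n_genes = 100, reads_per_sample = 1e6, n_replicates = 2),
    seed = 1,
    verbosity = 1
  ), class = "run_config")
}

check_config_keys <- function(cfg, template, path = "") {
  unknown <- setdiff(names(cfg), names(template))
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s)%s: %s",
                  if (nzchar(path)) paste0(" under '", path, "'") else "",
                  paste(unknown, collapse = ", ")))
  }
  for (nm in names(cfg)) {
    if (is.list(template[[nm]]) && !is.null(cfg[[nm]])) {
      if (!is.list(cfg[[nm]])) {
        abort(sprintf("Config key '%s%s' must be a mapping.", path, nm))
      }
      check_config_keys(cfg[[nm]], template[[nm]],
                        paste0(path, nm, "."))
    }
  }
  invisible(TRUE)
}

#' Read and validate a YAML run configuration
#'
#' Missing keys fall back to [default_run_config()]; unknown keys and
#' invalid parameter values fail fast with the offending key named.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: '%s'", path))
  }
  raw <- yaml::read_yaml(path)
  template <- default_run_config()
  check_config_keys(raw, template)
  cfg <- utils::modifyList(unclass(template), raw)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  # constructing the parameter objects runs their own validation, which
  # names the offending parameter
  config_chem(cfg)
  config_env(cfg)
  config_cell(cfg)
  invisible(cfg)
}

#' Write a run configuration to YAML
#'
#' @param cfg A `run_config` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(drop_null(unclass(cfg)), path, precision = 15)
  invisible(path)
}

drop_null <- function(x) {
  if (!is.list(x)) return(x)
  x <- x[!vapply(x, is.null, logical(1))]
  lapply(x, drop_null)
}

#' @rdname default_run_config
#' @param cfg A `run_config` list.
#' @export
config_chem <- function(cfg) {
  ch <- cfg$chemistry
  carbonate_params(k_h = ch$k_h_per_s, pK1_eff = ch$pK1_eff,
                   K_H = ch$K_H_M_per_atm, temperature = ch$temperature_C)
}

#' @rdname default_run_config
#' @export
config_env <- function(cfg) {
  e <- cfg$environment
  ci_environment(pCO2 = e$pCO2, pH_out = e$pH_out, pH_in = e$pH_in,
                 total_pressure = e$total_pressure_atm)
}

#' @rdname default_run_config
#' @export
config_cell <- function(cfg) {
  cl <- cfg$cell
  cell_params(P_C = cl$P_C_cm_per_s, P_H = cl$P_H_cm_per_s,
              sa_v = cl$sa_v_per_cm, gamma = cl$gamma_per_s,
              delta = cl$delta_per_s, chi = cl$chi_per_s,
              phi = cl$phi_per_s, f_H = cl$f_H, volume = cl$volume_L,
              uptake_substrate = cl$uptake_substrate, q_C = cl$q_C_uM,
              mu_max = if (is.null(cl$mu_max_per_h)) Inf else cl$mu_max_per_h)
}

#' Run a pipeline stage from a configuration
#'
#' Dispatches one of the package's analysis stages on a validated
#' configuration and writes its artifacts (a versioned JSON report echoing
#' the inputs, plus tidy TSV tables) into `out_dir`. Deterministic for a
#' fixed config: stochastic stages are seeded from `cfg$seed`.
#'
#' @param cfg A `run_config` list (or path to a YAML file).
#' @param subcommand One of `"steady-state"`, `"sweep"`, `"trajectory"`,
#'   `"fitness"`, `"simulate"`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the computed result and the paths
#'   written.
#' @export
run_pipeline <- function(cfg, subcommand = c("steady-state", "sweep",
                                             "trajectory", "fitness",
                                             "simulate"),
                         out_dir = ".") {
  subcommand <- match.arg(subcommand)
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  chem <- config_chem(cfg)
  env <- config_env(cfg)
  cell <- config_cell(cfg)

  paths <- character(0)
  result <- switch(
    subcommand,
    "steady-state" = {
      res <- model_growth(cell, env, chem)
      paths <- write_report(cfg, res, "steady_state", out_dir,
                            units = list(concentrations = "uM",
                                         fluxes = "uM/s",
                                         growth_rate = "1/h"))
      res
    },
    "sweep" = {
      n <- cfg$sweep$n_points %||% 25
      res <- switch(
        cfg$sweep$type %||% "leakage_heatmap",
        leakage_heatmap = leakage_heatmap(
          log_axis(1e-1, 1e5, n), log_axis(1, 1e6, n),
          cell = cell, env = env, chem = chem),
        growth_vs_ca = growth_vs_ca(
          delta_axis = log_axis(1e-2, 1e4, n),
          cell = cell, env = env, chem = chem),
        depletion_scan = depletion_scan(
          log_axis(10, 1e5, n), log_axis(1e-3, 1, n),
          cell = cell, env = env, chem = chem),
        pump_scenario = pump_scenario(cell = cell, env = env, chem = chem),
        abort(sprintf("Unknown sweep type '%s'.", cfg$sweep$type))
      )
      paths <- write_report(cfg, res, paste0("sweep_", attr(res, "sweep_type")),
                            out_dir,
                            units = list(activities = "1/s",
                                         fluxes = "uM/s"))
      res
    },
    "trajectory" = {
      res <- enumerate_trajectories(base = update_cell(cell, mu_max = 0.25),
                                    chem = chem)
      paths <- write_report(cfg, res, "trajectories", out_dir,
                            units = list(growth_rate = "1/h"))
      res
    },
    "fitness" = {
      f <- cfg$fitness$counts_file
      if (is.null(f)) abort("Config key 'fitness.counts_file' is not set.")
      if (!file.exists(f)) {
        abort(sprintf("Counts file not found: '%s'", f), class = "colimitr_missing_input")
      }
      counts <- read_poolcount(f)
      st <- strain_fitness(counts, t0 = cfg$fitness$t0_label,
                           pseudocount = cfg$fitness$pseudocount)
      gn <- gene_fitness(st, min_t0_reads = cfg$fitness$min_t0_reads)
      p1 <- file.path(out_dir, "strain_fitness.tsv")
      p2 <- file.path(out_dir, "gene_fitness.tsv")
      readr::write_tsv(st, p1)
      readr::write_tsv(gn, p2)
      paths <- c(p1, p2,
                 write_report(cfg, fitness_summary(gn), "fitness_summary",
                              out_dir, units = list(fitness = "log2")))
      list(strains = st, genes = gn)
    },
    "simulate" = {
      sp <- library_spec(n_genes = cfg$simulate$n_genes,
                         reads_per_sample = cfg$simulate$reads_per_sample,
                         n_replicates = cfg$simulate$n_replicates,
                         seed = cfg$seed)
      lib <- simulate_library(sp)
      p1 <- file.path(out_dir, "simulated_counts.tsv")
      p2 <- file.path(out_dir, "simulated_truth.tsv")
      readr::write_tsv(lib$counts, p1)
      readr::write_tsv(lib$truth, p2)
      paths <- c(p1, p2)
      lib
    }
  )
  invisible(list(result = result, paths = paths))
}

write_report <- function(cfg, result, name, out_dir, units = list()) {
  tsv <- file.path(out_dir, paste0(name, ".tsv"))
  json <- file.path(out_dir, paste0(name, ".json"))
  if (is.data.frame(result)) readr::write_tsv(result, tsv)
  report <- list(
    report = name,
    package_version = as.character(utils::packageVersion("colimitr")),
    seed = cfg$seed,
    units = units,
    config = drop_null(unclass(cfg)),
    result = if (is.data.frame(result)) {
      as.list(utils::head(result, 1000))
    } else result
  )
  jsonlite::write_json(report, json, auto_unbox = TRUE, digits = 9,
                       pretty = TRUE, null = "null")
  c(if (is.data.frame(result)) tsv, json)
}
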