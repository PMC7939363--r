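sim_config_defaults <- function() {
  list(
    # geometry / model size
    sheet_rings = 9L, n_genes = 10L, gradient_gene = 1L,
    # integrator: 4th-order Runge-Kutta with step-doubling error control
    rk_tolerance = 1e-3, dt_init = 0.02, dt_min = 1e-4, dt_max = 0.2,
    control_every = 5L, max_steps = 1000L, max_nodes = 5000L,
    # developmental noise: per-step isotropic Gaussian displacement (length
    # units per accepted step), applied to all cell nodes
    noise_amplitude = 0.005,
    # mechanics (stiffnesses of the piecewise force laws)
    k_rep = 5, k_adh = 5, k_spring = 10, k_bend = 2, k_tors = 1,
    # behaviors
    min_radius = 0.1, division_offset = 0.2,
    ecm_radius = 0.25, ecm_add = 0.35,
    default_division_rate = 0.001,
    # maintained morphogen input: the gradient gene is clamped
    maintained_gradient = TRUE,
    # stop conditions
    steady_window = 10L, steady_pos_tol = 1e-3, steady_expr_tol = 1e-4,
    rupture_multiple = 4, antialign_threshold = -0.9,
    snapshot_every = 0L,
    # signaling-only screen: a pattern transformation must change expression
    # and leave a spatially structured stable pattern; expression-only steps
    # are cheap, so the screen gets a larger step budget
    pattern_change_threshold = 0.05, pattern_spatial_threshold = 0.02,
    screen_max_steps = 1500L,
    # random-network sampler
    p_interact = 0.2, p_couple = 0.5, t_max = 1,
    mu_range = c(0.05, 0.5), D_range = c(0.2, 1),
    rate_coupling_log10_range = c(-2.5, -0.5), prop_coupling_max = 0.15,
    broad_ensemble = FALSE,
    # screens (prune_twins: candidate twin count during pruning; 0 means
    # use n_twins)
    n_twins = 10L, prune_patience = 40L, prune_twins = 0L,
    cmd_margin = 0.01,
    n_walks = 10L, walk_steps = 200L, walk_twins = 5L,
    walk_eligibility_emd = 0.3, walk_mode = "compound",
    # RNG
    seed = 1L
  )
}

#' Simulation and screening configuration
#'
#' Builds a validated configuration with all defaults resolved.  Unknown
#' keys are rejected.  The defaults define the study conditions: a
#' hexagonal sheet of `sheet_rings` rings, 10-gene networks, RK4
#' integration with step-doubling error control, per-step positional noise,
#' and the published screen settings (10 twins, 0.01 convexity-distance
#' acceptance margin, walks of 200 steps with 5 twins per step, walk
#' eligibility below 0.3 twin distance).
#'
#' @param ... Named overrides of the defaults (see
#'   `morphozoo:::sim_config_defaults()` for the full list).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(...) {
  defaults <- sim_config_defaults()
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]])) {
    over <- over[[1]]
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, over)
  int_keys <- c("sheet_rings", "n_genes", "gradient_gene", "max_steps",
                "max_nodes", "control_every", "screen_max_steps",
                "steady_window",
                "snapshot_every", "n_twins",
                "prune_patience", "prune_twins", "n_walks", "walk_steps",
                "walk_twins", "seed")
  for (k in int_keys) cfg[[k]] <- as.integer(cfg[[k]])
  pos <- c("rk_tolerance", "dt_init", "dt_min", "dt_max", "max_steps",
           "max_nodes", "sheet_rings", "n_genes", "k_rep", "k_adh",
           "k_spring", "min_radius", "t_max", "n_twins", "walk_twins")
  for (k in pos) {
    if (any(!is.finite(cfg[[k]])) || any(cfg[[k]] <= 0)) {
      abort(paste0("config key '", k, "' must be positive"))
    }
  }
  if (cfg$noise_amplitude < 0) abort("noise_amplitude must be >= 0")
  if (!cfg$walk_mode %in% c("compound", "reset")) {
    abort("walk_mode must be 'compound' or 'reset'")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (k in names(x)) {
    cat(sprintf("  %s: %s\n", k, paste(format(x[[k]]), collapse = ", ")))
  }
  invisible(x)
}

#' Load / save a configuration file
#'
#' Configurations are stored as YAML.  Loading validates every key and
#' resolves all defaults; unknown keys are rejected with their key path.
#' An empty file yields the full default configuration.
#'
#' @param path File path.
#' @return `load_config` returns a `sim_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) abort("config file must contain a YAML mapping")
  sim_config(raw)
}

#' @rdname load_config
#' @param config A `sim_config`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

# derive a reproducible child seed (kept below 2^31) from a base seed and a
# stream counter, so twins/mutants get independent deterministic streams
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 7919 + 12345) %%
               2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
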