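#' Packaged default configuration
#'
#' The default scenario shipped with the package: a coastal typhoon
#' evacuation with 200 households on a small-world kin network, a strike
#' probability of 0.5, total assets 10, abandoned fixed assets 8 (1
#' recoverable through government action), evacuation cost 4 and stay cost
#' 2 on a common value scale, neutral imitation noise `k = 1`, 20 rounds
#' and 200 Monte-Carlo repetitions. Both groups share the same economics.
#' The baseline policy profile is `beta = 0.45`, `theta = 0.45`,
#' `delta = 0.3`, `epsilon = 0.7`, `eta = 0.5` (see the methods vignette
#' for the calibration rationale).
#'
#' @return A nested named list of class `evac_config` with blocks
#'   `economics` (`group1`, `group2`), `policy`, `network`, `simulation`,
#'   `sweep`.
#' @export
default_config <- function() {
  econ <- list(P = 10, C = 8, Cprime = 1, D = 4, E = 2)
  structure(list(
    economics = list(group1 = econ, group2 = econ),
    policy = list(alpha = 0.5, beta = 0.45, theta = 0.45,
                  delta = 0.3, epsilon = 0.7, eta = 0.5),
    network = list(n_nodes = 200, k_ring = 4, p_rewire = 0.1, seed = 1),
    simulation = list(rounds = 20, n_reps = 200, noise_k = 1,
                      init_evac_fraction = 0.5,
                      update_scheme = "synchronous",
                      fermi_variant = "standard",
                      payoff_aggregation = "sum",
                      master_seed = 1, regenerate_graph = FALSE),
    sweep = list(parameter = "beta",
                 grid = c(0.05, 0.25, 0.45, 0.65, 0.85))
  ), class = "evac_config")
}

# The grids over which each policy lever is swept by default.
default_grids <- list(
  alpha = c(0.1, 0.3, 0.5, 0.7, 0.9),
  beta = c(0.05, 0.25, 0.45, 0.65, 0.85),
  theta = c(0.05, 0.25, 0.45, 0.65, 0.85),
  delta = c(0.1, 0.2, 0.3, 0.4, 0.5),
  epsilon = c(0.5, 0.6, 0.7, 0.8, 0.9),
  eta = c(0.5, 0.6, 0.7, 0.8, 0.9)
)

# Recursive merge of user values over defaults, rejecting unknown keys.
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user))
    stop("load_config: block '", path, "' must be a mapping", call. = FALSE)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop("load_config: unknown key(s) ",
         paste0("'", path, unknown, "'", collapse = ", "),
         "; valid keys here: ", paste(names(defaults), collapse = ", "),
         call. = FALSE)
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]],
                                     paste0(path, nm, "."))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load and resolve a run configuration
#'
#' Reads a YAML (or JSON) document with any subset of the blocks
#' `economics`, `policy`, `network`, `simulation`, `sweep`, fills every
#' omitted key from [default_config()], rejects unknown keys, and validates
#' all values through the type constructors. An empty or missing document
#' resolves to the packaged defaults.
#'
#' @param path Path to a YAML/JSON config file, or `NULL` for the defaults.
#' @return A fully resolved `evac_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop("load_config: no such file: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    cfg <- merge_config(unclass(cfg), user)
    class(cfg) <- "evac_config"
  }
  validate_config(cfg)
  cfg
}

# Builds the typed objects, erroring on any invalid value.
validate_config <- function(cfg) {
  config_objects(cfg)
  if (!cfg$sweep$parameter %in% names(default_grids))
    stop("load_config: sweep.parameter must be one of ",
         paste(names(default_grids), collapse = ", "), call. = FALSE)
  if (length(cfg$sweep$grid) < 2 || anyDuplicated(cfg$sweep$grid) ||
      any(cfg$sweep$grid < 0 | cfg$sweep$grid > 1))
    stop("load_config: sweep.grid needs >= 2 distinct values in [0, 1]",
         call. = FALSE)
  invisible(cfg)
}

#' Materialise the typed objects described by a configuration
#'
#' @param cfg An `evac_config` from [load_config()] or [default_config()].
#' @return List with `econ1`, `econ2`, `policy`, `netspec`, `simcfg`.
#' @export
config_objects <- function(cfg) {
  list(econ1 = do.call(group_economics, cfg$economics$group1),
       econ2 = do.call(group_economics, cfg$economics$group2),
       policy = do.call(policy_params, cfg$policy),
       netspec = do.call(network_spec, cfg$network),
       simcfg = do.call(sim_config, cfg$simulation))
}

#' Write a resolved configuration to YAML
#'
#' Round-trips with [load_config()]: dumping and reloading yields an
#' identical resolved configuration.
#'
#' @param cfg An `evac_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.evac_config <- function(x, ...) {
  cat("Resolved evacuation-game configuration:\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}
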