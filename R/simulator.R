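#' Simulation configuration
#'
#' Controls for the networked imitation dynamic.
#'
#' @param rounds Number of game rounds `T` (default 20).
#' @param n_reps Monte-Carlo repetitions averaged into the ensemble
#'   (default 200).
#' @param noise_k Fermi noise intensity `k > 0` (default 1, neutral noise).
#' @param init_evac_fraction Probability that a node starts as an evacuator
#'   (default 0.5).
#' @param update_scheme `"synchronous"` (all nodes revise simultaneously
#'   from the round-start state; default) or `"asynchronous"` (nodes revise
#'   one at a time in a random permutation).
#' @param fermi_variant `"standard"` (adoption probability increases with
#'   the neighbour's payoff advantage; default) or `"as_printed"` (the
#'   opposite sign convention; see [fermi_adopt_prob()]).
#' @param payoff_aggregation `"sum"` (default) or `"mean"` of the per-pair
#'   payoffs over a node's neighbourhood.
#' @param master_seed Integer master seed; per-repetition child seeds are
#'   derived from it so repetitions are independent and reproducible.
#' @param regenerate_graph If `TRUE` a fresh graph is drawn for every
#'   repetition; by default one fixed graph is shared (the network is
#'   generated once, strategies are re-randomised each repetition).
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(rounds = 20, n_reps = 200, noise_k = 1,
                       init_evac_fraction = 0.5,
                       update_scheme = c("synchronous", "asynchronous"),
                       fermi_variant = c("standard", "as_printed"),
                       payoff_aggregation = c("sum", "mean"),
                       master_seed = 1, regenerate_graph = FALSE) {
  if (!is.numeric(rounds) || length(rounds) != 1L || rounds < 1 ||
      rounds != round(rounds))
    stop("sim_config: 'rounds' must be an integer >= 1", call. = FALSE)
  if (!is.numeric(n_reps) || length(n_reps) != 1L || n_reps < 1 ||
      n_reps != round(n_reps))
    stop("sim_config: 'n_reps' must be an integer >= 1", call. = FALSE)
  if (!is.numeric(noise_k) || length(noise_k) != 1L || !is.finite(noise_k) ||
      noise_k <= 0)
    stop("sim_config: 'noise_k' must be a positive number", call. = FALSE)
  check_unit_interval(init_evac_fraction, "init_evac_fraction")
  if (!is.numeric(master_seed) || length(master_seed) != 1L ||
      master_seed != round(master_seed))
    stop("sim_config: 'master_seed' must be an integer", call. = FALSE)
  structure(list(rounds = as.integer(rounds), n_reps = as.integer(n_reps),
                 noise_k = noise_k,
                 init_evac_fraction = init_evac_fraction,
                 update_scheme = match.arg(update_scheme),
                 fermi_variant = match.arg(fermi_variant),
                 payoff_aggregation = match.arg(payoff_aggregation),
                 master_seed = as.integer(master_seed),
                 regenerate_graph = isTRUE(regenerate_graph)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("Simulation config: T=%d reps=%d k=%.3g init=%.3g ",
                     "%s/%s/%s seed=%d%s\n"),
              x$rounds, x$n_reps, x$noise_k, x$init_evac_fraction,
              x$update_scheme, x$fermi_variant, x$payoff_aggregation,
              x$master_seed,
              if (x$regenerate_graph) " regen-graph" else ""))
  invisible(x)
}

#' Random initial strategy assignment
#'
#' Assigns Evacuate (1) independently to each node with probability `frac`,
#' Stay (0) otherwise, using the current RNG state.
#'
#' @param n Number of nodes.
#' @param frac Probability of starting as an evacuator, in \[0, 1\].
#' @return Integer vector of 0/1 strategies of length `n`.
#' @export
init_strategies <- function(n, frac) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  check_unit_interval(frac, "frac")
  as.integer(stats::runif(n) < frac)
}

#' Per-node game payoff
#'
#' Payoff of node `i` given the current strategy profile: the Table-style
#' cell payoff against each neighbour, aggregated by sum or mean. Every node
#' reads the matrix as the row player by default; an optional `groups`
#' vector (values 1/2) assigns column-player roles for asymmetric
#' economics.
#'
#' @param graph An [igraph::igraph] graph.
#' @param strategies 0/1 vector (1 = Evacuate), one entry per node.
#' @param pm A [compute_payoff_matrix()] result.
#' @param i Node id.
#' @param aggregation `"sum"` or `"mean"`.
#' @param groups Optional integer vector of group labels (1 or 2) per node.
#' @return The scalar payoff of node `i`.
#' @export
node_payoff <- function(graph, strategies, pm, i,
                        aggregation = c("sum", "mean"), groups = NULL) {
  stopifnot(igraph::is_igraph(graph), inherits(pm, "payoff_matrix"))
  aggregation <- match.arg(aggregation)
  if (length(strategies) != igraph::vcount(graph))
    stop("node_payoff: 'strategies' length must equal the node count",
         call. = FALSE)
  nbrs <- as.integer(igraph::neighbors(graph, i))
  if (length(nbrs) == 0)
    stop("node_payoff: node ", i, " is isolated", call. = FALSE)
  grp <- if (is.null(groups)) 1L else groups[i]
  vals <- vapply(nbrs, function(j)
    payoff_cell(pm, strategies[i], strategies[j], grp), numeric(1))
  if (aggregation == "sum") sum(vals) else mean(vals)
}

#' Fermi adoption probability
#'
#' Probability that a focal individual with payoff `pr_i` adopts the
#' strategy of a compared neighbour with payoff `pr_j`, under noise
#' intensity `k`:
#' \deqn{W = \frac{1}{1 + \exp[(pr_i - pr_j)/k]} \quad \textrm{(standard)},}
#' increasing in the neighbour's payoff advantage. The `"as_printed"`
#' variant flips the sign in the exponent (adoption becomes less likely the
#' better the neighbour does) and is retained for fidelity experiments.
#' Overflow-safe: saturates to the 0/1 limits for large payoff gaps.
#'
#' @param pr_i,pr_j Payoffs of the focal node and the compared neighbour.
#' @param noise_k Positive noise intensity.
#' @param variant `"standard"` (default) or `"as_printed"`.
#' @return Adoption probability in (0, 1) (limits attained only by
#'   saturation).
#' @examples
#' fermi_adopt_prob(0, 1, 1)  # 1 / (1 + exp(-1)) ~ 0.731
#' @export
fermi_adopt_prob <- function(pr_i, pr_j, noise_k,
                             variant = c("standard", "as_printed")) {
  variant <- match.arg(variant)
  stopifnot(is.numeric(noise_k), noise_k > 0)
  z <- (pr_i - pr_j) / noise_k
  if (variant == "as_printed") z <- -z
  stats::plogis(-z)  # 1 / (1 + exp(z)), overflow-safe
}

# Internal: flat neighbour representation + sparse adjacency for fast
# vectorised payoff evaluation. Built once per ensemble.
build_sim_graph <- function(graph) {
  n <- igraph::vcount(graph)
  adj <- igraph::as_adj_list(graph, mode = "all")
  nbr <- unlist(lapply(adj, as.integer), use.names = FALSE)
  deg <- lengths(adj)
  if (any(deg == 0))
    stop("simulation requires every node to have at least one neighbour",
         call. = FALSE)
  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  list(n = n, nbr = nbr, deg = deg, ptr = c(0L, cumsum(deg)), A = A)
}

# Vectorised payoffs of all nodes under the current profile.
all_payoffs <- function(sg, strategies, pm, aggregation, groups = NULL) {
  nE <- as.numeric(sg$A %*% strategies)  # evacuating neighbours per node
  nS <- sg$deg - nE
  pe <- pm$U11 * nE + pm$U12 * nS  # payoff if Evacuate (row player)
  ps <- pm$U21 * nE + pm$U22 * nS  # payoff if Stay
  if (!is.null(groups) && any(groups == 2L)) {
    g2 <- groups == 2L
    pe[g2] <- (pm$V11 * nE + pm$V21 * nS)[g2]
    ps[g2] <- (pm$V12 * nE + pm$V22 * nS)[g2]
  }
  pr <- ifelse(strategies == 1L, pe, ps)
  if (aggregation == "mean") pr <- pr / sg$deg
  pr
}

#' One imitation round
#'
#' Advances the strategy profile by one round of the networked game. Each
#' node draws one neighbour from its [neighbor_choice_distribution()],
#' compares payoffs computed on the current profile, keeps its strategy when
#' not worse off, and otherwise adopts the neighbour's strategy with the
#' [fermi_adopt_prob()] probability. Under the synchronous scheme all
#' comparisons use the round-start state and updates land simultaneously;
#' under the asynchronous scheme nodes revise one at a time in a random
#' permutation, each seeing the partially updated profile.
#'
#' @inheritParams node_payoff
#' @param config A [sim_config()] (only `noise_k`, `update_scheme`,
#'   `fermi_variant`, `payoff_aggregation` are used).
#' @return The successor 0/1 strategy vector.
#' @export
step_imitation <- function(graph, strategies, pm, config, groups = NULL) {
  stopifnot(inherits(config, "sim_config"))
  sg <- build_sim_graph(graph)
  step_imitation_impl(sg, strategies, pm, config, groups)
}

step_imitation_impl <- function(sg, strategies, pm, config, groups = NULL) {
  n <- sg$n
  if (config$update_scheme == "synchronous") {
    pr <- all_payoffs(sg, strategies, pm, config$payoff_aggregation, groups)
    # one uniformly chosen neighbour per node (graphs are unweighted)
    pick <- sg$ptr[seq_len(n)] + 1L +
      as.integer(floor(stats::runif(n) * sg$deg))
    j <- sg$nbr[pick]
    w <- fermi_adopt_prob(pr, pr[j], config$noise_k, config$fermi_variant)
    adopt <- (pr < pr[j]) & (stats::runif(n) < w)
    out <- strategies
    out[adopt] <- strategies[j[adopt]]
    out
  } else {
    out <- strategies
    for (i in sample.int(n)) {
      d <- sg$deg[i]
      j <- sg$nbr[sg$ptr[i] + 1L + as.integer(floor(stats::runif(1) * d))]
      pr2 <- all_payoffs(sg, out, pm, config$payoff_aggregation, groups)
      if (pr2[i] < pr2[j] &&
          stats::runif(1) < fermi_adopt_prob(pr2[i], pr2[j], config$noise_k,
                                             config$fermi_variant)) {
        out[i] <- out[j]
      }
    }
    out
  }
}

# Counter-based child seed derivation: independent, reproducible streams
# per repetition, kept below 2^31.
child_seed <- function(master_seed, r) {
  m <- as.double(master_seed) %% 2147483647
  as.integer((m * 48271 + as.double(r) * 16807) %% 2147483647)
}

#' Run a Monte-Carlo ensemble of the networked evacuation game
#'
#' Protocol: generate the interaction network, then for each repetition
#' re-randomise the initial strategies, play `rounds` imitation rounds, and
#' record the evacuation response rate (fraction of evacuators) after every
#' round; the ensemble mean and standard deviation over repetitions are
#' reported per round. By default one fixed graph is shared across
#' repetitions; set `regenerate_graph = TRUE` in the config to redraw it.
#'
#' @param netspec A [network_spec()].
#' @param pm A [compute_payoff_matrix()] result.
#' @param config A [sim_config()].
#' @param groups Optional per-node group labels (1/2) for asymmetric
#'   economics.
#' @return An object of class `ensemble_result` with elements
#'   `series` (data.frame `round, mean_rate, sd_rate`, rounds 0..T),
#'   `final_rate` (mean rate at round T), `final_rates` (per-repetition
#'   finals), `rates` (n_reps x (T+1) matrix), and `metadata` echoing the
#'   resolved configuration and seeds.
#' @examples
#' econ <- group_economics(10, 8, 1, 4, 2)
#' pm <- compute_payoff_matrix(econ, econ, policy_params(0.5, 0.45, 0.45, 0.3, 0.7, 0.5))
#' res <- run_ensemble(network_spec(50, 4, 0.1, seed = 1), pm,
#'                     sim_config(rounds = 5, n_reps = 10, master_seed = 42))
#' res$final_rate
#' @export
run_ensemble <- function(netspec, pm, config, groups = NULL) {
  stopifnot(inherits(netspec, "network_spec"),
            inherits(pm, "payoff_matrix"),
            inherits(config, "sim_config"))
  graph0 <- if (config$regenerate_graph) NULL else generate_small_world(netspec)
  sg0 <- if (is.null(graph0)) NULL else build_sim_graph(graph0)

  rates <- matrix(NA_real_, nrow = config$n_reps, ncol = config$rounds + 1L)
  for (r in seq_len(config$n_reps)) {
    sg <- sg0
    if (is.null(sg)) {
      spec_r <- netspec
      spec_r$seed <- child_seed(netspec$seed, r)
      sg <- build_sim_graph(generate_small_world(spec_r))
    }
    withr::with_seed(child_seed(config$master_seed, r), {
      s <- init_strategies(sg$n, config$init_evac_fraction)
      rates[r, 1L] <- mean(s)
      for (t in seq_len(config$rounds)) {
        s <- step_imitation_impl(sg, s, pm, config, groups)
        rates[r, t + 1L] <- mean(s)
      }
    })
  }
  series <- data.frame(round = 0:config$rounds,
                       mean_rate = colMeans(rates),
                       sd_rate = apply(rates, 2, stats::sd))
  structure(list(series = series,
                 final_rate = series$mean_rate[config$rounds + 1L],
                 final_rates = rates[, config$rounds + 1L],
                 rates = rates,
                 metadata = list(network = unclass(netspec),
                                 payoff = unclass(pm)[1:8],
                                 sim = unclass(config))),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  md <- x$metadata$sim
  cat(sprintf("Ensemble of %d repetitions, %d rounds, N=%d nodes\n",
              md$n_reps, md$rounds, x$metadata$network$n_nodes))
  cat(sprintf("  initial rate %.3f -> final evacuation response rate %.3f (sd %.3f)\n",
              x$series$mean_rate[1], x$final_rate,
              x$series$sd_rate[nrow(x$series)]))
  invisible(x)
}

#' Write an ensemble result to CSV with a JSON metadata sidecar
#'
#' The CSV holds the per-round ensemble series (`round, mean_rate,
#' sd_rate`, 6 significant digits); `<path>.meta.json` records the fully
#' resolved configuration and seeds for provenance.
#'
#' @param result An `ensemble_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(result, path) {
  stopifnot(inherits(result, "ensemble_result"))
  ser <- result$series
  ser$mean_rate <- signif(ser$mean_rate, 6)
  ser$sd_rate <- signif(ser$sd_rate, 6)
  utils::write.csv(ser, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(result$metadata, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
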