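# Shared fixtures: the default scenario economics, a mid-grid policy profile,
# and random parameter draws for property-style tests.

econ_default <- function() group_economics(P = 10, C = 8, Cprime = 1, D = 4, E = 2)

policy_mid <- function() {
  policy_params(alpha = 0.5, beta = 0.45, theta = 0.45,
                delta = 0.3, epsilon = 0.7, eta = 0.7)
}

pm_mid <- function() compute_payoff_matrix(econ_default(), econ_default(), policy_mid())

rand_policy <- function() {
  v <- stats::runif(6)
  policy_params(v[1], v[2], v[3], v[4], v[5], v[6])
}

rand_econ <- function() {
  C <- stats::runif(1, 0, 10)
  group_economics(P = stats::runif(1, 0, 20), C = C,
                  Cprime = stats::runif(1, 0, C),
                  D = stats::runif(1, 0, 5), E = stats::runif(1, 0, 5))
}

# Draws (econ1, econ2, policy, coeffs) until the replicator system admits an
# interior fixed point in (0,1)^2.
rand_interior_draw <- function(max_tries = 10000) {
  for (k in seq_len(max_tries)) {
    e1 <- rand_econ(); e2 <- rand_econ(); pol <- rand_policy()
    co <- field_coefficients(e1, e2, pol)
    if (co$A1 != 0 && co$B1 != 0) {
      xs <- -co$B2 / co$B1; ys <- -co$A2 / co$A1
      if (xs > 1e-6 && xs < 1 - 1e-6 && ys > 1e-6 && ys < 1 - 1e-6)
        return(list(econ1 = e1, econ2 = e2, policy = pol, coeffs = co,
                    xs = xs, ys = ys))
    }
  }
  stop("no interior draw found")
}

# Direct field evaluation, tolerant of the +/- h excursions outside [0, 1]
# used by finite-difference checks.
replicator_field_num <- function(co, x, y) {
  c(x * (1 - x) * (co$A1 * y + co$A2),
    y * (1 - y) * (co$B1 * x + co$B2))
}

# Hand-built payoff matrix from arbitrary cell values (symmetric game),
# bypassing the economics parameterisation.
pm_cells <- function(U11, U12, U21, U22) {
  structure(list(U11 = U11, U12 = U12, U21 = U21, U22 = U22,
                 V11 = U11, V12 = U21, V21 = U12, V22 = U22),
            class = "payoff_matrix")
}

# Exact one-round successor distribution of the synchronous imitation rule,
# by direct enumeration: per-node flip probabilities from uniform neighbour
# choice and the Fermi coin, payoffs recomputed by a plain double loop.
enumerate_step_distribution <- function(graph, strategies, pm, noise_k,
                                        aggregation = "sum") {
  n <- igraph::vcount(graph)
  cell <- function(a, b) pm[[paste0("U", 2 - a, 2 - b)]]
  pr <- vapply(seq_len(n), function(i) {
    nbrs <- as.integer(igraph::neighbors(graph, i))
    tot <- sum(vapply(nbrs, function(j)
      cell(strategies[i], strategies[j]), numeric(1)))
    if (aggregation == "mean") tot / length(nbrs) else tot
  }, numeric(1))
  flip <- vapply(seq_len(n), function(i) {
    nbrs <- as.integer(igraph::neighbors(graph, i))
    p <- 0
    for (j in nbrs) {
      if (pr[i] < pr[j] && strategies[j] != strategies[i]) {
        w <- 1 / (1 + exp((pr[i] - pr[j]) / noise_k))
        p <- p + w / length(nbrs)
      }
    }
    p
  }, numeric(1))
  combos <- as.matrix(expand.grid(rep(list(0:1), n)))  # flip indicator rows
  probs <- apply(combos, 1, function(fl)
    prod(ifelse(fl == 1, flip, 1 - flip)))
  succ <- t(apply(combos, 1, function(fl)
    ifelse(fl == 1, 1L - strategies, strategies)))
  keys <- apply(succ, 1, paste, collapse = "")
  tapply(probs, keys, sum)
}
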