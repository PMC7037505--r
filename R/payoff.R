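#' Policy parameter set
#'
#' Bundles the six dimensionless knobs through which the hazard and the
#' government enter the evacuation game. All lie in \[0, 1\].
#'
#' @param alpha Perceived probability that the typhoon actually strikes.
#' @param beta Evacuation-cost reduction rate obtained when the counterpart
#'   stays home and frees road/shelter resources.
#' @param theta Stay-cost reduction rate obtained when the counterpart
#'   evacuates and frees emergency supplies.
#' @param delta Government coefficient reducing the evacuation-process cost
#'   (traffic guidance, transport provision).
#' @param epsilon Government coefficient multiplying the stay cost when
#'   exactly one party stays (partial guarantee).
#' @param eta Government coefficient multiplying the stay cost when both
#'   parties stay (maximum-effort guarantee).
#'
#' @return An object of class `policy_params`.
#' @examples
#' policy_params(alpha = 0.5, beta = 0.45, theta = 0.45,
#'               delta = 0.3, epsilon = 0.7, eta = 0.7)
#' @export
policy_params <- function(alpha, beta, theta, delta, epsilon, eta) {
  p <- list(alpha = alpha, beta = beta, theta = theta,
            delta = delta, epsilon = epsilon, eta = eta)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1) {
      stop("policy_params: field '", nm,
           "' must be a single finite number in [0, 1], got ",
           deparse(v), call. = FALSE)
    }
  }
  structure(p, class = "policy_params")
}

#' Group economics
#'
#' Per-group asset and cost quantities, on a common abstract value scale.
#'
#' @param P Total assets (material plus life property).
#' @param C Fixed assets abandoned when evacuating.
#' @param Cprime Fixed-asset loss recovered through government action;
#'   must not exceed `C`.
#' @param D Evacuation-process cost (congestion time, transport,
#'   accommodation).
#' @param E Stay cost (emergency supplies, time, housing reinforcement).
#'
#' @return An object of class `group_economics`.
#' @examples
#' group_economics(P = 10, C = 8, Cprime = 1, D = 4, E = 2)
#' @export
group_economics <- function(P, C, Cprime, D, E) {
  e <- list(P = P, C = C, Cprime = Cprime, D = D, E = E)
  for (nm in names(e)) {
    v <- e[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("group_economics: field '", nm,
           "' must be a single finite number >= 0, got ",
           deparse(v), call. = FALSE)
    }
  }
  if (Cprime > C) {
    stop("group_economics: field 'Cprime' (recovered loss) cannot exceed ",
         "'C' (abandoned assets)", call. = FALSE)
  }
  structure(e, class = "group_economics")
}

#' @export
print.policy_params <- function(x, ...) {
  cat("Policy parameters:\n")
  cat(sprintf("  alpha=%.3g beta=%.3g theta=%.3g delta=%.3g epsilon=%.3g eta=%.3g\n",
              x$alpha, x$beta, x$theta, x$delta, x$epsilon, x$eta))
  invisible(x)
}

#' @export
print.group_economics <- function(x, ...) {
  cat(sprintf("Group economics: P=%.4g C=%.4g C'=%.4g D=%.4g E=%.4g\n",
              x$P, x$C, x$Cprime, x$D, x$E))
  invisible(x)
}

#' Compute the two-player evacuation payoff matrix
#'
#' Builds the eight cell payoffs of the Evacuate/Stay game between two
#' (possibly asymmetric) groups under a given policy. Strategy index 1 is
#' Evacuate, 2 is Stay; the first subscript is Group 1's strategy and the
#' second Group 2's. `U` cells are Group 1 (row player) payoffs, `V` cells
#' Group 2 (column player) payoffs:
#' \deqn{U_{11} = P_1 - \alpha (C_1 - C_1') - (1-\delta) D_1}
#' \deqn{U_{12} = P_1 - \alpha (C_1 - C_1') - (1-\delta)(1-\beta) D_1}
#' \deqn{U_{21} = (1-\alpha) P_1 - \epsilon (1-\theta) E_1}
#' \deqn{U_{22} = (1-\alpha) P_1 - \eta E_1}
#' and symmetrically for `V` with Group 2 quantities.
#'
#' @param econ1,econ2 [group_economics()] for Group 1 and Group 2.
#' @param policy A [policy_params()] object.
#'
#' @return An object of class `payoff_matrix`: a named list with fields
#'   `U11, U12, U21, U22, V11, V12, V21, V22`.
#' @examples
#' econ <- group_economics(10, 8, 1, 4, 2)
#' pol  <- policy_params(0.5, 0.45, 0.45, 0.3, 0.7, 0.7)
#' compute_payoff_matrix(econ, econ, pol)
#' @export
compute_payoff_matrix <- function(econ1, econ2, policy) {
  stopifnot(inherits(econ1, "group_economics"),
            inherits(econ2, "group_economics"),
            inherits(policy, "policy_params"))
  a <- policy$alpha; b <- policy$beta; th <- policy$theta
  d <- policy$delta; ep <- policy$epsilon; et <- policy$eta

  evac_both  <- function(e) e$P - a * (e$C - e$Cprime) - (1 - d) * e$D
  evac_alone <- function(e) e$P - a * (e$C - e$Cprime) - (1 - d) * (1 - b) * e$D
  stay_mixed <- function(e) (1 - a) * e$P - ep * (1 - th) * e$E
  stay_both  <- function(e) (1 - a) * e$P - et * e$E

  pm <- list(
    U11 = evac_both(econ1),  V11 = evac_both(econ2),
    U12 = evac_alone(econ1), V12 = stay_mixed(econ2),
    U21 = stay_mixed(econ1), V21 = evac_alone(econ2),
    U22 = stay_both(econ1),  V22 = stay_both(econ2)
  )
  structure(pm, class = "payoff_matrix",
            econ1 = econ1, econ2 = econ2, policy = policy)
}

#' @export
print.payoff_matrix <- function(x, ...) {
  cat("Payoff matrix (row = Group 1; 1 = Evacuate, 2 = Stay):\n")
  cat(sprintf("            Evacuate              Stay\n"))
  cat(sprintf("  Evacuate  U11=%-7.4g V11=%-7.4g U12=%-7.4g V12=%-7.4g\n",
              x$U11, x$V11, x$U12, x$V12))
  cat(sprintf("  Stay      U21=%-7.4g V21=%-7.4g U22=%-7.4g V22=%-7.4g\n",
              x$U21, x$V21, x$U22, x$V22))
  invisible(x)
}

#' Flatten a payoff matrix to a one-row data frame
#'
#' Convenience export of the eight cells as a flat record, suitable for a
#' CSV row or JSON object.
#'
#' @param pm A `payoff_matrix`.
#' @return A one-row `data.frame` with columns `U11..V22`.
#' @export
payoff_record <- function(pm) {
  stopifnot(inherits(pm, "payoff_matrix"))
  as.data.frame(unclass(pm)[c("U11", "U12", "U21", "U22",
                              "V11", "V12", "V21", "V22")])
}

# Internal: the 2x2 cell value earned by a focal node with strategy `own`
# (1 = Evacuate, 0 = Stay) against a neighbour with strategy `other`,
# given the focal node's group (1 = row player, 2 = column player).
payoff_cell <- function(pm, own, other, group = 1L) {
  i <- 2L - own; j <- 2L - other  # strategy 1 -> index 1 (Evacuate)
  if (group == 1L) {
    pm[[paste0("U", i, j)]]
  } else {
    # column player: first subscript is the neighbour's (row) strategy
    pm[[paste0("V", j, i)]]
  }
}
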