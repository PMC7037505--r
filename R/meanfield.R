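#' Expected payoffs under mixed population states
#'
#' Given the payoff matrix and the current evacuation shares `x` (Group 1)
#' and `y` (Group 2), returns the expected payoff of each pure strategy and
#' the group averages:
#' \deqn{U_{E1} = y U_{11} + (1-y) U_{12}, \quad
#'       U_{S1} = y U_{21} + (1-y) U_{22}, \quad
#'       \bar U_1 = x U_{E1} + (1-x) U_{S1}}
#' and symmetrically for Group 2 with `x` as the mixing weight:
#' `UE2` mixes the two cells in which Group 2 evacuates (`V11`, `V21`) and
#' `US2` the two in which it stays (`V12`, `V22`), so that
#' `UE2 - US2 = B1 x + B2` (see [field_coefficients()]).
#'
#' @param pm A [compute_payoff_matrix()] result.
#' @param x,y Fractions of Group 1 / Group 2 choosing Evacuate, in \[0, 1\].
#'
#' @return Named list with `UE1, US1, Ubar1, UE2, US2, Ubar2`.
#' @export
expected_payoffs <- function(pm, x, y) {
  stopifnot(inherits(pm, "payoff_matrix"))
  check_unit_interval(x, "x")
  check_unit_interval(y, "y")
  UE1 <- y * pm$U11 + (1 - y) * pm$U12
  US1 <- y * pm$U21 + (1 - y) * pm$U22
  UE2 <- x * pm$V11 + (1 - x) * pm$V21
  US2 <- x * pm$V12 + (1 - x) * pm$V22
  list(UE1 = UE1, US1 = US1, Ubar1 = x * UE1 + (1 - x) * US1,
       UE2 = UE2, US2 = US2, Ubar2 = y * UE2 + (1 - y) * US2)
}

check_unit_interval <- function(v, nm) {
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
    stop("'", nm, "' must be a single finite number in [0, 1]", call. = FALSE)
  invisible(v)
}

#' Replicator field coefficients
#'
#' The payoff advantage of Evacuate over Stay is linear in the opposing
#' group's evacuation share. For Group 1,
#' \deqn{U_{E1} - U_{S1} = A_1 y + A_2,}
#' with
#' \deqn{A_1 = (\delta-1)\beta D_1 + E_1[(1-\theta)\epsilon - \eta], \quad
#'       A_2 = \alpha P_1 - \alpha(C_1 - C_1') - (1-\delta)(1-\beta)D_1 + \eta E_1,}
#' and `B1`, `B2` are the Group 2 analogues (slope in `x`). These four
#' numbers fully determine the replicator dynamics and its stability.
#'
#' @inheritParams compute_payoff_matrix
#' @return Object of class `field_coefficients` with fields `A1, A2, B1, B2`.
#' @examples
#' econ <- group_economics(10, 8, 1, 4, 2)
#' pol  <- policy_params(0.5, 0.45, 0.45, 0.3, 0.7, 0.7)
#' field_coefficients(econ, econ, pol)
#' @export
field_coefficients <- function(econ1, econ2, policy) {
  stopifnot(inherits(econ1, "group_economics"),
            inherits(econ2, "group_economics"),
            inherits(policy, "policy_params"))
  a <- policy$alpha; b <- policy$beta; th <- policy$theta
  d <- policy$delta; ep <- policy$epsilon; et <- policy$eta
  slope <- function(e) (d - 1) * b * e$D + e$E * ((1 - th) * ep - et)
  icept <- function(e) a * e$P - a * (e$C - e$Cprime) -
    (1 - d) * (1 - b) * e$D + et * e$E
  structure(list(A1 = slope(econ1), A2 = icept(econ1),
                 B1 = slope(econ2), B2 = icept(econ2)),
            class = "field_coefficients")
}

#' @export
print.field_coefficients <- function(x, ...) {
  cat(sprintf("Replicator field coefficients: A1=%.6g A2=%.6g B1=%.6g B2=%.6g\n",
              x$A1, x$A2, x$B1, x$B2))
  invisible(x)
}

#' Replicator vector field
#'
#' The two-group replicator dynamics of the evacuation game:
#' \deqn{\dot x = f(x,y) = x(1-x)(A_1 y + A_2), \qquad
#'       \dot y = g(x,y) = y(1-y)(B_1 x + B_2).}
#'
#' @param coeffs A [field_coefficients()] object.
#' @param x,y Evacuation shares of the two groups, in \[0, 1\].
#' @return Named list `f` (dx/dt) and `g` (dy/dt).
#' @export
replicator_field <- function(coeffs, x, y) {
  stopifnot(inherits(coeffs, "field_coefficients"))
  check_unit_interval(x, "x")
  check_unit_interval(y, "y")
  list(f = x * (1 - x) * (coeffs$A1 * y + coeffs$A2),
       g = y * (1 - y) * (coeffs$B1 * x + coeffs$B2))
}

#' Jacobian of the replicator system
#'
#' Analytic Jacobian of `(f, g)` from [replicator_field()]:
#' \deqn{J = \begin{pmatrix} (1-2x)(A_1 y + A_2) & x(1-x)A_1 \\
#'                           y(1-y)B_1 & (1-2y)(B_1 x + B_2)\end{pmatrix}.}
#' The off-diagonal entries are the partial derivatives of `f` in `y` and of
#' `g` in `x`; a finite-difference check of all four entries is part of the
#' package's test suite.
#'
#' @inheritParams replicator_field
#' @return A 2x2 numeric matrix.
#' @export
replicator_jacobian <- function(coeffs, x, y) {
  stopifnot(inherits(coeffs, "field_coefficients"))
  check_unit_interval(x, "x")
  check_unit_interval(y, "y")
  matrix(c((1 - 2 * x) * (coeffs$A1 * y + coeffs$A2),
           y * (1 - y) * coeffs$B1,
           x * (1 - x) * coeffs$A1,
           (1 - 2 * y) * (coeffs$B1 * x + coeffs$B2)),
         nrow = 2, ncol = 2,
         dimnames = list(c("f", "g"), c("x", "y")))
}

# Sign classification of one equilibrium from Det and Tr of the Jacobian.
classify_equilibrium <- function(det, tr, tol) {
  if (abs(det) < tol) return("degenerate")
  if (det < 0) return("saddle")
  if (abs(tr) < tol) return("center")
  if (tr < 0) "stable_node" else "unstable_node"
}

#' Enumerate and classify the equilibria of the replicator system
#'
#' The four corner states (all-Stay, all-Evacuate and the two mixed corners)
#' are always rest points. An interior rest point
#' \eqn{(x^*, y^*) = (-B_2/B_1,\; -A_2/A_1)} exists when both slopes are
#' non-zero and both coordinates lie strictly inside (0, 1). Each point is
#' labelled from the determinant and trace of the Jacobian:
#' saddle (`Det < 0`), stable node (`Det > 0, Tr < 0`), unstable node
#' (`Det > 0, Tr > 0`), center (`Det > 0, Tr = 0`), degenerate (`Det = 0`),
#' with tolerance-based sign comparisons scaled by the coefficient magnitude.
#'
#' @param coeffs A [field_coefficients()] object.
#' @return An object of class `equilibrium_report`: a `data.frame` with
#'   columns `x, y, detJ, trJ, label`, plus attributes `interior_exists`
#'   and (when absent) `interior_reason`.
#' @examples
#' econ <- group_economics(10, 8, 1, 4, 2)
#' pol  <- policy_params(0.5, 0.45, 0.45, 0.3, 0.7, 0.7)
#' find_equilibria(field_coefficients(econ, econ, pol))
#' @export
find_equilibria <- function(coeffs) {
  stopifnot(inherits(coeffs, "field_coefficients"))
  scale <- max(abs(coeffs$A1), abs(coeffs$A2),
               abs(coeffs$B1), abs(coeffs$B2), 1)^2
  tol <- 1e-9 * scale

  pts <- list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  interior_exists <- FALSE
  interior_reason <- NA_character_
  if (coeffs$A1 == 0 || coeffs$B1 == 0) {
    interior_reason <- "zero_slope_coefficient"
  } else {
    xs <- -coeffs$B2 / coeffs$B1
    ys <- -coeffs$A2 / coeffs$A1
    margin <- 1e-9
    if (xs > margin && xs < 1 - margin && ys > margin && ys < 1 - margin) {
      interior_exists <- TRUE
      pts <- c(pts, list(c(xs, ys)))
    } else {
      interior_reason <- "interior_candidate_outside_unit_square"
    }
  }

  rows <- lapply(pts, function(p) {
    J <- replicator_jacobian(coeffs, p[1], p[2])
    det <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
    tr <- J[1, 1] + J[2, 2]
    data.frame(x = p[1], y = p[2], detJ = det, trJ = tr,
               label = classify_equilibrium(det, tr, tol),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  structure(report, class = c("equilibrium_report", "data.frame"),
            interior_exists = interior_exists,
            interior_reason = interior_reason,
            coeffs = coeffs)
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat("Equilibria of the replicator system (", nrow(x), " points):\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 6)
  if (!isTRUE(attr(x, "interior_exists")))
    cat("Interior point absent:", attr(x, "interior_reason"), "\n")
  invisible(x)
}

#' Serialize an equilibrium report to JSON
#'
#' @param report An `equilibrium_report`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
equilibria_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "equilibrium_report"))
  obj <- list(points = as.data.frame(report),
              interior_exists = isTRUE(attr(report, "interior_exists")),
              interior_reason = attr(report, "interior_reason"),
              coefficients = unclass(attr(report, "coeffs")))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "rows", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Integrate the replicator dynamics
#'
#' Fixed-step classical Runge-Kutta (4th order) integration of the
#' replicator field from an initial state, for phase portraits and
#' convergence checks. States are confined to the unit square; only
#' accumulated round-off (magnitude below 1e-12) is clipped.
#'
#' @param coeffs A [field_coefficients()] object.
#' @param x0,y0 Initial evacuation shares, in \[0, 1\].
#' @param horizon Total integration time.
#' @param step Fixed time step (default 0.01).
#' @return A `data.frame` with columns `t, x, y`.
#' @export
integrate_replicator <- function(coeffs, x0, y0, horizon, step = 0.01) {
  stopifnot(inherits(coeffs, "field_coefficients"))
  check_unit_interval(x0, "x0")
  check_unit_interval(y0, "y0")
  stopifnot(is.numeric(horizon), horizon > 0, is.numeric(step), step > 0)
  deriv <- function(t, state, parms) {
    fg <- replicator_field_raw(coeffs, state[1], state[2])
    list(c(fg$f, fg$g))
  }
  times <- seq(0, horizon, by = step)
  sol <- deSolve::ode(y = c(x = x0, y = y0), times = times, func = deriv,
                      parms = NULL, method = "rk4")
  out <- as.data.frame(sol)
  names(out) <- c("t", "x", "y")
  if (any(!is.finite(out$x)) || any(!is.finite(out$y)))
    stop("integrate_replicator: non-finite state encountered; ",
         "integration aborted", call. = FALSE)
  clip <- function(v) {
    bad <- v < -1e-12 | v > 1 + 1e-12
    if (any(bad))
      stop("integrate_replicator: state left the unit square by more than ",
           "round-off", call. = FALSE)
    pmin(pmax(v, 0), 1)
  }
  out$x <- clip(out$x)
  out$y <- clip(out$y)
  out
}

# Field evaluation without unit-interval checks: RK4 stages may step a hair
# outside [0,1] transiently.
replicator_field_raw <- function(coeffs, x, y) {
  list(f = x * (1 - x) * (coeffs$A1 * y + coeffs$A2),
       g = y * (1 - y) * (coeffs$B1 * x + coeffs$B2))
}
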