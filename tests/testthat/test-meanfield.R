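test_that("expected payoffs are the correct mixtures of the cells", {
  pm <- pm_mid()
  # y = 1: mixtures collapse to the Evacuate column
  ep <- expected_payoffs(pm, x = 0.4, y = 1)
  expect_equal(ep$UE1, pm$U11)
  expect_equal(ep$US1, pm$U21)
  # midpoint mixture
  pmh <- pm_cells(4, 6, 1, 2)
  expect_equal(expected_payoffs(pmh, 0.5, 0.5)$UE1, 5)
  # brute-force weighted-sum oracle at (0.3, 0.6)
  x <- 0.3; y <- 0.6
  ep <- expected_payoffs(pm, x, y)
  expect_equal(ep$UE1, sum(c(y, 1 - y) * c(pm$U11, pm$U12)))
  expect_equal(ep$US1, sum(c(y, 1 - y) * c(pm$U21, pm$U22)))
  # Group 2 evacuating earns V11 against an evacuating Group 1, V21 against
  # a staying one (first subscript is Group 1's strategy)
  expect_equal(ep$UE2, sum(c(x, 1 - x) * c(pm$V11, pm$V21)))
  expect_equal(ep$US2, sum(c(x, 1 - x) * c(pm$V12, pm$V22)))
  expect_equal(ep$Ubar1, x * ep$UE1 + (1 - x) * ep$US1)
  expect_equal(ep$Ubar2, y * ep$UE2 + (1 - y) * ep$US2)
})

test_that("field coefficients match hand substitution and the payoff identity", {
  co <- field_coefficients(econ_default(), econ_default(), policy_mid())
  # A1 = -0.7*0.45*4 + 2*(0.55*0.7 - 0.7); A2 = 5 - 3.5 - 0.7*0.55*4 + 1.4
  expect_equal(co$A1, -1.89)
  expect_equal(co$A2, 1.36)
  expect_equal(co$B1, co$A1)
  expect_equal(co$B2, co$A2)

  # the linear form A1*y + A2 reproduces UE1 - US1 for random draws
  withr::with_seed(31, {
    for (rep in 1:50) {
      e1 <- rand_econ(); e2 <- rand_econ(); pol <- rand_policy()
      co <- field_coefficients(e1, e2, pol)
      pm <- compute_payoff_matrix(e1, e2, pol)
      x <- runif(1); y <- runif(1)
      ep <- expected_payoffs(pm, x, y)
      sc <- max(1, abs(ep$UE1 - ep$US1))
      expect_lt(abs(co$A1 * y + co$A2 - (ep$UE1 - ep$US1)), 1e-10 * sc)
      sc2 <- max(1, abs(ep$UE2 - ep$US2))
      expect_lt(abs(co$B1 * x + co$B2 - (ep$UE2 - ep$US2)), 1e-10 * sc2)
    }
  })
})

test_that("the slope coefficient vanishes when both resource channels cancel", {
  # beta = 0 and epsilon(1-theta) = eta: the counterpart's choice is payoff-neutral
  pol <- policy_params(alpha = 0.4, beta = 0, theta = 0.5,
                       delta = 0.3, epsilon = 0.8, eta = 0.4)
  co <- field_coefficients(econ_default(), econ_default(), pol)
  expect_equal(co$A1, 0)
  expect_equal(co$B1, 0)
})

test_that("replicator field vanishes on the boundary and matches both printed forms", {
  co <- field_coefficients(econ_default(), econ_default(), policy_mid())
  for (y in c(0, 0.3, 1)) {
    expect_identical(replicator_field(co, 0, y)$f, 0)
    expect_identical(replicator_field(co, 1, y)$f, 0)
    expect_identical(replicator_field(co, y, 0)$g, 0)
    expect_identical(replicator_field(co, y, 1)$g, 0)
  }
  expect_equal(replicator_field(co, 0.5, 0.5)$f, 0.25 * (-1.89 * 0.5 + 1.36))

  # payoff form x(1-x)(UE1-US1) equals the coefficient form
  withr::with_seed(37, {
    for (rep in 1:30) {
      e1 <- rand_econ(); e2 <- rand_econ(); pol <- rand_policy()
      co <- field_coefficients(e1, e2, pol)
      pm <- compute_payoff_matrix(e1, e2, pol)
      x <- runif(1); y <- runif(1)
      ep <- expected_payoffs(pm, x, y)
      fg <- replicator_field(co, x, y)
      expect_equal(fg$f, x * (1 - x) * (ep$UE1 - ep$US1), tolerance = 1e-10)
      expect_equal(fg$g, y * (1 - y) * (ep$UE2 - ep$US2), tolerance = 1e-10)
    }
  })
})

test_that("analytic Jacobian matches central finite differences", {
  withr::with_seed(41, {
    for (rep in 1:100) {
      co <- field_coefficients(rand_econ(), rand_econ(), rand_policy())
      x <- runif(1, 0.05, 0.95); y <- runif(1, 0.05, 0.95)
      J <- replicator_jacobian(co, x, y)
      h <- 1e-6
      fd <- matrix(c(
        (replicator_field(co, x + h, y)$f - replicator_field(co, x - h, y)$f),
        (replicator_field(co, x + h, y)$g - replicator_field(co, x - h, y)$g),
        (replicator_field(co, x, y + h)$f - replicator_field(co, x, y - h)$f),
        (replicator_field(co, x, y + h)$g - replicator_field(co, x, y - h)$g)),
        nrow = 2) / (2 * h)
      expect_lt(max(abs(J - fd)), 1e-5)
    }
  })
})

test_that("corner determinants and traces reduce to the symbolic coefficient forms", {
  withr::with_seed(43, {
    for (rep in 1:25) {
      co <- field_coefficients(rand_econ(), rand_econ(), rand_policy())
      J <- function(x, y) replicator_jacobian(co, x, y)
      dt <- function(m) m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
      tr <- function(m) m[1, 1] + m[2, 2]
      with(co, {
        expect_equal(dt(J(0, 0)), A2 * B2)
        expect_equal(tr(J(0, 0)), A2 + B2)
        expect_equal(dt(J(0, 1)), -(A1 + A2) * B2)
        expect_equal(tr(J(0, 1)), (A1 + A2) - B2)
        expect_equal(dt(J(1, 0)), -A2 * (B1 + B2))
        expect_equal(tr(J(1, 0)), -A2 + (B1 + B2))
        expect_equal(dt(J(1, 1)), (A1 + A2) * (B1 + B2))
        # the (1,1) trace is the negated sum: both diagonal entries carry
        # the (1-2x) sign flip
        expect_equal(tr(J(1, 1)), -((A1 + A2) + (B1 + B2)))
      })
    }
  })
})

test_that("equilibrium enumeration finds the five rest points of the default scenario", {
  co <- field_coefficients(econ_default(), econ_default(), policy_mid())
  rep <- find_equilibria(co)
  expect_equal(nrow(rep), 5)
  expect_true(attr(rep, "interior_exists"))
  interior <- rep[5, ]
  expect_equal(interior$x, 1.36 / 1.89, tolerance = 1e-12)
  expect_equal(interior$y, 1.36 / 1.89, tolerance = 1e-12)
  expect_equal(interior$trJ, 0, tolerance = 1e-12)
  expect_identical(interior$label, "saddle")
  # corners are always present
  expect_equal(rep$x[1:4], c(0, 0, 1, 1))
  expect_equal(rep$y[1:4], c(0, 1, 0, 1))
})

test_that("stability labels follow the sign logic of Det and Tr", {
  # A2 > 0, B2 > 0: origin is a source (both groups gain by evacuating
  # when nobody does)
  co <- field_coefficients(econ_default(), econ_default(), policy_mid())
  rep <- find_equilibria(co)
  expect_identical(rep$label[rep$x == 0 & rep$y == 0], "unstable_node")
  # A1+A2 > 0 and B1+B2 > 0 with positive determinant: all-evacuate attracts
  pol <- policy_params(alpha = 0.5, beta = 0.45, theta = 0.45,
                       delta = 0.5, epsilon = 0.7, eta = 0.5)
  co2 <- field_coefficients(econ_default(), econ_default(), pol)
  expect_gt(co2$A1 + co2$A2, 0)
  rep2 <- find_equilibria(co2)
  expect_identical(rep2$label[rep2$x == 1 & rep2$y == 1], "stable_node")
  expect_false(attr(rep2, "interior_exists"))
})

test_that("zero slope coefficients report the interior as absent with a reason", {
  pol <- policy_params(alpha = 0.4, beta = 0, theta = 0.5,
                       delta = 0.3, epsilon = 0.8, eta = 0.4)
  co <- field_coefficients(econ_default(), econ_default(), pol)
  expect_identical(co$A1, 0)
  rep <- find_equilibria(co)
  expect_equal(nrow(rep), 4)
  expect_false(attr(rep, "interior_exists"))
  expect_identical(attr(rep, "interior_reason"), "zero_slope_coefficient")
})

test_that("equilibrium report serializes to JSON", {
  co <- field_coefficients(econ_default(), econ_default(), policy_mid())
  js <- equilibria_json(find_equilibria(co))
  parsed <- jsonlite::fromJSON(js)
  expect_equal(nrow(parsed$points), 5)
  expect_true(parsed$interior_exists)
  expect_equal(parsed$coefficients$A1, -1.89)
})

test_that("replicator integration is invariant at corners and converges to a stable node", {
  co <- field_coefficients(econ_default(), econ_default(), policy_mid())
  traj <- integrate_replicator(co, 1, 1, horizon = 5)
  expect_true(all(traj$x == 1) && all(traj$y == 1))

  # profile where all-evacuate is attracting
  pol <- policy_params(0.5, 0.45, 0.45, 0.5, 0.7, 0.5)
  co2 <- field_coefficients(econ_default(), econ_default(), pol)
  traj2 <- integrate_replicator(co2, 0.99, 0.99, horizon = 50)
  expect_true(all(traj2$x >= 0 & traj2$x <= 1))
  n <- nrow(traj2)
  expect_lt(abs(traj2$x[n] - 1), 1e-4)
  expect_lt(abs(traj2$y[n] - 1), 1e-4)

  # time reversal (negated field) repels from the same node
  co_rev <- co2
  co_rev$A1 <- -co2$A1; co_rev$A2 <- -co2$A2
  co_rev$B1 <- -co2$B1; co_rev$B2 <- -co2$B2
  traj3 <- integrate_replicator(co_rev, 0.99, 0.99, horizon = 50)
  n3 <- nrow(traj3)
  expect_gt(abs(traj3$x[n3] - 1), abs(0.99 - 1))
})
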