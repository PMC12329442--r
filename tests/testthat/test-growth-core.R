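test_that("constructors enforce parameter constraints", {
  expect_error(component_params(H = 0, K = 1, q = 0.5, i = 0), "H")
  expect_error(component_params(H = 1, K = -1, q = 0.5, i = 0), "K")
  expect_error(component_params(H = 1, K = 1, q = 1, i = 0), "q")
  expect_error(component_params(H = 1, K = 1, q = 0, i = 0), "q")
  expect_error(component_params(H = 1, K = 1, q = 0.5, i = -0.1), "i")
  p <- fix_component()
  expect_s3_class(p, "component_params")

  comps <- lapply(c(0, 0.5, 1.5, 3, 11), function(i)
    component_params(1, 0.5, 0.5, i))
  cp <- composite_params(comps)
  expect_s3_class(cp, "composite_params")
  # first component must initiate at conception
  expect_error(composite_params(lapply(c(0.1, 0.5, 1.5, 3, 11), function(i)
    component_params(1, 0.5, 0.5, i))), "conception")
  # components get ordered by initiation age
  cp2 <- composite_params(comps[c(3, 1, 5, 2, 4)])
  expect_equal(param_matrix(cp2)[, "i"], param_matrix(cp)[, "i"])
  expect_error(composite_params(comps[1:4]), "5")
})

test_that("component height matches the hand-checked special cases", {
  p <- fix_component(H = 1, K = 0.5, q = 0.7, i = 0)
  expect_equal(component_height(p, 0), 0)          # bracket zero at t = i
  expect_equal(component_height(p, 1e6), 4^(1 / 0.7))  # forced asymptote
  expect_equal(asymptotic_height(p), 4^(1 / 0.7))
  expect_equal(asymptotic_height(component_params(0.5, 1, 0.3, 0)), 1)
  expect_equal(asymptotic_height(component_params(1, 0.5, 0.5, 0)), 16)
  # large-t evaluation agrees with the closed-form limit
  for (pp in random_components(20)) {
    expect_equal(component_height(pp, 1e6), asymptotic_height(pp),
                 tolerance = 1e-9)
  }
})

test_that("closed forms match adaptive ODE integration (height and mass)", {
  skip_if_not_installed("deSolve")
  for (p in random_components(100)) {
    # anchor the initial-value problem a little after initiation (where the
    # saturating bracket reaches 0.01) so the integrator is not started at
    # the degenerate h = 0 fixed point with an astronomically small state
    rate <- p$K * p$q / (1 + 2 * p$q)
    t0 <- p$i - log(0.99) / rate
    tgrid <- t0 + seq(0.5, 50, length.out = 12)
    rhs_h <- function(t, y, parms)
      list(ode_growth_rates(p, max(y[1], 0))$dhdt)
    h0 <- component_height(p, t0)
    num <- deSolve::ode(y = c(h = h0), times = c(t0, tgrid),
                        func = rhs_h, parms = NULL, method = "lsoda",
                        rtol = 1e-10, atol = h0 * 1e-8)
    expect_equal(num[-1, "h"], component_height(p, tgrid),
                 tolerance = 1e-6, ignore_attr = TRUE)
    # mass-form ODE reproduces the closed-form mass
    rhs_m <- function(t, y, parms) {
      h <- (max(y[1], 0) / pi)^(1 / (1 + 2 * p$q))
      list(ode_growth_rates(p, h)$dmdt)
    }
    m0 <- component_mass(p, t0)
    numm <- deSolve::ode(y = c(m = m0), times = c(t0, tgrid),
                         func = rhs_m, parms = NULL, method = "lsoda",
                         rtol = 1e-10, atol = m0 * 1e-8)
    expect_equal(numm[-1, "m"], component_mass(p, tgrid),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("mass is exactly D pi h^(1+2q) and composite sums its components", {
  for (p in random_components(30)) {
    tt <- p$i + c(0.1, 1, 5, 20)
    expect_equal(component_mass(p, tt),
                 pi * component_height(p, tt)^(1 + 2 * p$q),
                 tolerance = 1e-12)
  }
  p <- component_params(1, 0.5, 0.5, 0)
  expect_equal(component_mass(p, 0), 0)
  # when h = 1 cm and q = 0.5, m = pi g regardless of the rate parameters
  t1 <- uniroot(function(t) component_height(p, t) - 1, c(1e-3, 10),
                tol = 1e-12)$root
  expect_equal(component_mass(p, t1), pi, tolerance = 1e-9)

  cp <- reference_composite("female")
  tt <- c(0, 0.75, 2, 10, 26.75)
  expect_equal(composite_height(cp, tt),
               Reduce(`+`, lapply(cp$components, component_height, t = tt)))
  expect_equal(composite_mass(cp, tt),
               Reduce(`+`, lapply(cp$components, component_mass, t = tt)))
  expect_equal(composite_height(cp, 0), 0)
  expect_equal(composite_mass(cp, 0), 0)
})

test_that("components are gated: zero before initiation, degenerate sums collapse", {
  comps <- lapply(c(0, 0.5, 1.5, 3, 11), function(i)
    component_params(2, 0.6, 0.55, i))
  cp <- composite_params(comps)
  for (x in 2:5) {
    i_x <- comps[[x]]$i
    expect_equal(component_height(comps[[x]], i_x - 1e-9), 0)
    expect_equal(component_height(comps[[x]], i_x), 0)
  }
  # silencing processes 2..5 (H -> 0) leaves just the first component
  tiny <- composite_params(c(comps[1], lapply(comps[2:5], function(p)
    component_params(1e-12, p$K, p$q, p$i))))
  tt <- seq(0, 30, by = 0.5)
  expect_equal(composite_height(tiny, tt), component_height(comps[[1]], tt),
               tolerance = 1e-6)
})

test_that("composite trajectories are nondecreasing and bounded", {
  set.seed(11)
  for (rep in 1:5) {
    ii <- sort(c(0, runif(4, 0.2, 14)))
    cp <- composite_params(lapply(ii, function(i)
      component_params(exp(runif(1, 0, 2)), exp(runif(1, -1, 1)),
                       runif(1, 0.3, 0.7), i)))
    tt <- seq(0, 60, by = 0.1)
    h <- composite_height(cp, tt)
    m <- composite_mass(cp, tt)
    expect_true(all(diff(h) >= -1e-10))
    expect_true(all(diff(m) >= -1e-10))
    bound <- sum(vapply(cp$components, asymptotic_height, numeric(1)))
    expect_true(all(h <= bound + 1e-9))
  }
})

test_that("height velocity matches finite differences and decays", {
  p <- fix_component(H = 1, K = 0.5, q = 0.7, i = 0)
  cp1 <- composite_params(c(list(p), lapply(1:4, function(k)
    component_params(1e-12, 0.5, 0.5, k))))
  # velocity is zero at initiation (limit value)
  expect_equal(height_velocity(cp1, 0), 0, tolerance = 1e-12)
  # central finite difference of the closed form at t = 5
  fd <- (component_height(p, 5 + 1e-5) - component_height(p, 5 - 1e-5)) / 2e-5
  expect_equal(height_velocity(cp1, 5), fd, tolerance = 1e-5)
  # far beyond the asymptote the velocity is numerically zero
  expect_lt(height_velocity(cp1, 500), 1e-8)

  cpref <- reference_composite("female")
  tt <- seq(0.1, 40, by = 0.1)
  expect_true(all(height_velocity(cpref, tt) >= -1e-10))
})

test_that("ode_growth_rates is consistent with the allometric coupling", {
  p <- fix_component(H = 1.3, K = 0.8, q = 0.45, i = 0)
  expect_equal(ode_growth_rates(p, 0), list(dhdt = 0, dmdt = 0))
  astar <- asymptotic_height(p)
  r <- ode_growth_rates(p, astar)
  expect_equal(r$dhdt, 0, tolerance = 1e-10)
  expect_equal(r$dmdt, 0, tolerance = 1e-10)
  expect_error(ode_growth_rates(p, -1), "nonnegative")
  # chain rule through m = D pi h^(1+2q)
  for (pp in random_components(20)) {
    h <- runif(1, 0.1, 0.9) * asymptotic_height(pp)
    rr <- ode_growth_rates(pp, h)
    expect_equal(rr$dmdt, pi * (1 + 2 * pp$q) * h^(2 * pp$q) * rr$dhdt,
                 tolerance = 1e-9)
  }
})

test_that("radius follows the allometric power law", {
  expect_equal(radius_from_height(1, 0.37), 1)
  expect_equal(radius_from_height(4, 0.5), 2)
  expect_equal(radius_from_height(0, 0.5), 0)
  expect_error(radius_from_height(-1, 0.5))
})

test_that("transform round-trip preserves parameters", {
  cp <- reference_composite("male")
  th <- natural_to_transformed(cp)
  cp2 <- transformed_to_composite(th)
  expect_equal(param_matrix(cp2), param_matrix(cp), tolerance = 1e-12)
  expect_equal(length(th), 19L)
})
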