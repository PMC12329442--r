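test_that("process weights are normalized height shares", {
  comps <- lapply(c(0, 0.5, 1.5, 3, 11), function(i)
    component_params(2, 0.6, 0.55, i))
  cp <- composite_params(comps)
  # before any later process initiates, only process 1 carries weight
  expect_equal(process_weights(cp, 0.4), c(1, 0, 0, 0, 0))
  w <- process_weights(cp, c(2, 10, 20))
  expect_equal(rowSums(w), c(1, 1, 1), tolerance = 1e-12)
  expect_true(all(w >= 0))
  # five identical always-on components share the weight equally
  same <- composite_params(lapply(1:5, function(x)
    component_params(2, 0.6, 0.55, 0)))
  expect_equal(process_weights(same, 3), rep(0.2, 5))
  expect_error(process_weights(cp, 0), "zero")
})

test_that("metabolic activity interpolates from 1 to 1 - rho", {
  p <- fix_component(H = 2, K = 0.8, q = 0.5, i = 1)
  expect_equal(metabolic_activity(p, 1), 1)           # h = 0 at initiation
  expect_equal(metabolic_activity(p, 1e6, rho = 0.75), 0.25)
  expect_equal(metabolic_activity(p, c(2, 5, 50), rho = 0), c(1, 1, 1))
  tt <- seq(1, 40, by = 0.5)
  a <- metabolic_activity(p, tt, rho = 0.6)
  expect_true(all(diff(a) <= 1e-12))
  expect_true(all(a >= 0.4 - 1e-9 & a <= 1))
})

test_that("weighted trajectories collapse correctly in degenerate cases", {
  fit <- fixture_fit(S = 40)
  # identical parameters across processes: weighted value equals the shared one
  qq <- 0.55
  th_same <- natural_to_transformed(
    cbind(rep(2, 5), rep(0.6, 5), rep(qq, 5), c(0, 0.5, 1.5, 3, 11)))
  same_fit <- fit
  same_fit$beta0 <- matrix(rep(th_same, each = 10), 10, 19)
  colnames(same_fit$beta0) <- transformed_names()
  same_fit$g <- array(0, c(10, 1, 19),
                      dimnames = list(NULL, "reference", transformed_names()))
  same_fit$chain <- rep(1:2, each = 5)
  wq <- weighted_parameter_trajectory(same_fit, "q", ages = c(2, 8, 15))
  expect_equal(unname(wq$mean), rep(qq, 3), tolerance = 1e-10)
  wK <- weighted_parameter_trajectory(same_fit, "K", ages = c(2, 8, 15))
  expect_equal(unname(wK$mean), rep(0.6, 3), tolerance = 1e-10)
})

test_that("rho = 0 reduces the metabolic weighting to pure height weighting", {
  fit <- fixture_fit(S = 20)
  ages <- c(3, 9, 16)
  w0 <- weighted_parameter_trajectory(fit, "K", ages = ages, rho = 0,
                                      max_draws = 20)
  # manual pure height-weighted mean per draw
  gm <- group_mean_draws(fit, "reference")
  manual <- sapply(seq_len(20), function(s) {
    cp <- transformed_to_composite(gm[s, ])
    Ks <- param_matrix(cp)[, "K"]
    w <- process_weights(cp, ages)
    as.vector(w %*% Ks)
  })
  expect_equal(w0$draws[1:20, ], t(manual), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("a hand-built 2-process, 3-draw posterior matches explicit arithmetic", {
  # two active processes; the other three silenced with negligible H
  mk_theta <- function(H1, H2, K1, K2) {
    m <- cbind(c(H1, H2, 1e-9, 1e-9, 1e-9), c(K1, K2, 1, 1, 1),
               rep(0.5, 5), c(0, 1, 2, 3, 4))
    natural_to_transformed(m)
  }
  draws <- rbind(mk_theta(2.0, 1.0, 0.5, 0.8),
                 mk_theta(2.2, 0.9, 0.6, 0.7),
                 mk_theta(1.8, 1.2, 0.4, 0.9))
  fit <- fixture_fit(S = 3)
  fit$beta0 <- draws
  colnames(fit$beta0) <- transformed_names()
  fit$g <- array(0, c(3, 1, 19),
                 dimnames = list(NULL, "ref", transformed_names()))
  fit$chain <- c(1, 1, 2)
  age <- 6; rho <- 0.75
  wt <- weighted_parameter_trajectory(fit, "H", ages = age, rho = rho,
                                      max_draws = 3)
  for (s in 1:3) {
    nat <- compgrowth:::.transformed_to_natural(draws[s, ])
    hx <- sapply(1:5, function(x)
      compgrowth:::.vb_height(nat$H[1, x], nat$K[1, x], nat$q[1, x],
                              nat$i[1, x], age))
    w <- hx / sum(hx)
    a <- 1 - rho * hx / sapply(1:5, function(x)
      (2 * nat$H[1, x] / nat$K[1, x])^(1 / nat$q[1, x]))
    expected <- sum(w * a * nat$H[1, ]) / sum(w * a)
    expect_equal(wt$draws[s, 1], expected, tolerance = 1e-9)
  }
})

test_that("weighted values stay inside the convex hull of the parameters", {
  fit <- fixture_fit(S = 30)
  ages <- seq(1, 26, by = 1)
  gm <- group_mean_draws(fit, "focal")
  for (fam in c("q", "K", "H")) {
    wt <- weighted_parameter_trajectory(fit, fam, "focal", ages = ages,
                                        max_draws = 30)
    for (s in c(1, 15, 30)) {
      nat <- compgrowth:::.transformed_to_natural(gm[s, ])
      vals <- switch(fam, q = nat$q[1, ], K = nat$K[1, ], H = nat$H[1, ])
      ok <- wt$draws[s, ] >= min(vals) - 1e-9 &
        wt$draws[s, ] <= max(vals) + 1e-9
      expect_true(all(ok[!is.na(wt$draws[s, ])]))
    }
  }
})

test_that("metabolic trajectories decline from infancy toward a late plateau", {
  fit <- fixture_fit(S = 30)
  ages <- seq(2, 22, by = 0.5)
  for (fam in c("K", "H")) {
    wt <- weighted_parameter_trajectory(fit, fam, ages = ages, max_draws = 30)
    m <- wt$mean
    # monotone decline through childhood (the pubertal process carries a
    # higher catabolic rate on this fixture, so a small bump is expected
    # once it gains weight; the overall high-early / low-late pattern and
    # the late plateau are what is asserted)
    childhood <- m[ages <= 11]
    expect_true(all(diff(childhood) <= 1e-6))
    expect_gt(m[1], 1.5 * m[ages == 20])
    late <- m[ages >= 14]
    expect_lt(max(late) - min(late), 0.10 * m[1])
  }
})

test_that("HPDI bands are stable under posterior thinning", {
  fit <- fixture_fit(S = 400)
  ages <- seq(2, 24, by = 2)
  width_at <- function(S) {
    sub <- fit
    keep <- seq_len(S)
    sub$beta0 <- fit$beta0[keep, , drop = FALSE]
    sub$g <- fit$g[keep, , , drop = FALSE]
    sub$sigma <- fit$sigma[keep, , drop = FALSE]
    sub$chain <- fit$chain[keep]
    wt <- weighted_parameter_trajectory(sub, "K", ages = ages, max_draws = S)
    mean(wt$upper - wt$lower)
  }
  w_full <- width_at(400)
  # thinned bands stay within 25% of the full-draw bands (shortest-window
  # empirical HPDIs shrink slightly at small draw counts because the
  # minimum over candidate windows is selected)
  expect_lt(abs(width_at(40) - w_full), 0.25 * w_full)
  expect_lt(abs(width_at(10) - w_full), 0.25 * w_full)
})

test_that("trajectory descriptives match a dense-grid oracle", {
  fit <- fixture_fit(S = 12)
  de <- trajectory_descriptives(fit, "reference", max_draws = 12)
  expect_true(all(de$draws$peak_velocity > 0))
  expect_true(all(de$draws$age_at_peak_velocity >= 5 &
                  de$draws$age_at_peak_velocity <= 20))
  expect_equal(de$degenerate_fraction, 0)
  gm <- group_mean_draws(fit, "reference")
  for (s in c(1, 7)) {
    cp <- transformed_to_composite(gm[s, ])
    # independent fine-grid scan
    tg <- seq(5.75, 20.75, by = 0.002)
    v <- height_velocity(cp, tg)
    expect_equal(de$draws$peak_velocity[s], max(v), tolerance = 1e-4)
    expect_equal(de$draws$age_at_peak_velocity[s], tg[which.max(v)] - 0.75,
                 tolerance = 0.01)
    # max height is the height at the reference adult age and tops all
    # measured ages
    expect_equal(de$draws$max_height[s], composite_height(cp, 26.75))
    expect_true(all(composite_height(cp, seq(0.75, 26.75, 0.5)) <=
                    de$draws$max_height[s] + 1e-9))
  }
})

test_that("a single-process trajectory is flagged degenerate in the window", {
  # only the conception process: velocity decreasing everywhere after birth
  th <- natural_to_transformed(cbind(
    c(30, 1e-9, 1e-9, 1e-9, 1e-9), c(1, 1, 1, 1, 1), rep(0.5, 5),
    c(0, 1, 2, 3, 4)))
  fit <- fixture_fit(S = 4)
  fit$beta0 <- matrix(rep(th, each = 4), 4, 19)
  colnames(fit$beta0) <- transformed_names()
  fit$g <- array(0, c(4, 1, 19),
                 dimnames = list(NULL, "ref", transformed_names()))
  fit$chain <- rep(1:2, each = 2)
  de <- trajectory_descriptives(fit, max_draws = 4)
  expect_equal(de$degenerate_fraction, 1)
})
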