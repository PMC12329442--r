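test_that("log likelihood matches an independent elementwise oracle", {
  sim <- quick_sim(n_ref = 3, n_focal = 2, seed = 17)
  prep <- prepare_dataset(sim$records)
  se <- 0.04; sm <- 0.09
  ll <- log_likelihood(prep, sim$population$theta, se, sm)

  # brute force: loop over records, recomputing each trajectory directly
  df <- prep$records
  oracle <- 0
  for (r in seq_len(nrow(df))) {
    th <- sim$population$theta[df$person_id[r], ]
    cp <- transformed_to_composite(th)
    if (!is.na(df$height_cm[r]))
      oracle <- oracle + dnorm(log(df$height_cm[r]),
                               log(0.012 + composite_height(cp, df$t[r])),
                               se, log = TRUE)
    if (!is.na(df$weight_g[r]))
      oracle <- oracle + dnorm(log(df$weight_g[r]),
                               log(1.02e-6 + composite_mass(cp, df$t[r])),
                               sm, log = TRUE)
  }
  expect_equal(ll, oracle, tolerance = 1e-10)
})

test_that("log likelihood has the exact zero-residual value and is additive", {
  cp <- reference_composite("female")
  h10 <- 0.012 + composite_height(cp, 10.75)
  one <- data.frame(person_id = "A", group = "g", sex = "F", t = 10.75,
                    height_cm = h10, weight_g = NA_real_,
                    provenance = "observed")
  class(one) <- c("cg_records", "data.frame")
  prep1 <- prepare_dataset(one, add_conception = FALSE,
                           carry_forward_to = NULL)
  th <- matrix(natural_to_transformed(cp), 1)
  expect_equal(log_likelihood(prep1, th, 0.03, 0.08),
               -log(0.03) - 0.5 * log(2 * pi))
  two <- rbind(one, one)
  class(two) <- c("cg_records", "data.frame")
  prep2 <- prepare_dataset(two, add_conception = FALSE,
                           carry_forward_to = NULL)
  expect_equal(log_likelihood(prep2, th, 0.03, 0.08),
               2 * log_likelihood(prep1, th, 0.03, 0.08))
})

test_that("model construction rejects unusable data", {
  sim <- quick_sim(n_ref = 2, n_focal = 2, seed = 3)
  rec <- sim$records
  rec$weight_g <- NA_real_
  prep <- prepare_dataset(rec, add_conception = FALSE,
                          carry_forward_to = NULL)
  expect_error(build_model(prep), "weight")
})

test_that("hpdi finds the shortest window (brute-force cross-check)", {
  expect_equal(unname(hpdi(rep(3.7, 10), 0.9)), c(3.7, 3.7))
  iv <- hpdi(1:100, 0.9)
  expect_equal(unname(iv[2] - iv[1]), 90)   # earliest 91-point window
  expect_equal(unname(iv[1]), 1)

  set.seed(1)
  x <- rnorm(1e6)
  iv <- hpdi(x, 0.9)
  expect_lt(abs(iv[1] + 1.645), 0.02)
  expect_lt(abs(iv[2] - 1.645), 0.02)

  # enumeration oracle on small skewed samples
  set.seed(2)
  for (rep in 1:20) {
    y <- sort(rexp(sample(10:40, 1)))
    mass <- runif(1, 0.5, 0.95)
    n <- length(y); k <- ceiling(mass * n)
    if (k >= n) next
    widths <- sapply(1:(n - k), function(j) y[j + k] - y[j])
    jbest <- which.min(widths)
    expect_equal(unname(hpdi(y, mass)), c(y[jbest], y[jbest + k]))
  }
  expect_error(hpdi(1, 0.9))
  expect_error(hpdi(1:10, 1.2))
})

test_that("contrasts flag separations correctly", {
  set.seed(4)
  a <- rnorm(1e4, 0.3, 0.1)
  b <- rnorm(1e4, 0, 0.1)
  same <- contrast_draws(a, a)
  expect_true(all(same$draws == 0))
  expect_false(same$excludes_zero)
  shifted <- contrast_draws(a + 10, a)
  expect_true(shifted$excludes_zero)
  cc <- contrast_draws(a, b)
  expect_true(cc$excludes_zero)
  expect_lt(abs(cc$hpdi[1] - 0.07), 0.03)
  expect_lt(abs(cc$hpdi[2] - 0.53), 0.03)
  expect_message(contrast_draws(rnorm(100), rnorm(50)), "common draw count")
})

test_that("a prior-only run reproduces the prior on the baseline means", {
  sim <- quick_sim(n_ref = 3, n_focal = 3, seed = 13)
  prep <- prepare_dataset(sim$records, carry_forward_to = NULL)
  pr <- cg_priors()
  fit <- fit_growth(build_model(prep, pr), chains = 2, iter = 300,
                    warmup = 200, seed = 77, likelihood_weight = 0)
  # beta0 marginals should match Normal(means0, tau0) within MC error
  expect_lt(mean(abs(colMeans(fit$beta0) - pr$means0)), 0.2)
  sds <- apply(fit$beta0, 2, sd)
  expect_true(all(sds > 0.5 * pr$tau0 & sds < 1.6 * pr$tau0))
  # sigma samples its half-normal prior (median of |N(0, s)|)
  expect_lt(abs(median(fit$sigma[, 2]) - 0.25 * qnorm(0.75)), 0.06)
})

test_that("near-noiseless dense data recovers person trajectories within 1%", {
  cfg <- population_config(group_sizes = c(ref = 8), sigma_eta = 1e-12,
                           sigma_mu = 1e-12)
  sim <- simulate_growth_data(cfg, "dense", seed = 31)
  prep <- prepare_dataset(sim$records, carry_forward_to = NULL)
  fit <- fit_growth(build_model(prep), chains = 2, iter = 250, warmup = 250,
                    seed = 8, fix_sigma = c(0.01, 0.02))
  ages <- dense_design_ages()
  for (p in 1:8) {
    truth <- composite_height(
      transformed_to_composite(sim$population$theta[p, ]), ages)
    est <- rowMeans(sapply(seq(1, 500, by = 10), function(s)
      composite_height(transformed_to_composite(fit$theta[s, p, ]), ages)))
    expect_lt(max(abs(est - truth) / truth), 0.01)
  }
})

test_that("every stored draw respects the parameter constraints", {
  sf <- shared_fit()
  fit <- sf$fit
  S <- nrow(fit$beta0)
  take <- seq(1, S, by = 7)
  for (s in take) {
    nat <- compgrowth:::.transformed_to_natural(fit$theta[s, , ])
    expect_true(all(nat$H > 0))
    expect_true(all(nat$K > 0))
    expect_true(all(nat$q > 0 & nat$q < 1))
    expect_true(all(nat$i[, 1] == 0))
    expect_true(all(apply(nat$i, 1, function(v) all(diff(v) > 0))))
  }
  expect_true(all(fit$sigma > 0))
  # covariance draws stay symmetric positive definite
  for (f in names(fit$Sigma))
    for (s in c(1, S))
      expect_true(all(eigen(fit$Sigma[[f]][s, , ],
                            symmetric = TRUE)$values > 0))
})

test_that("posterior predictive intervals bracket the observed heights", {
  sf <- shared_fit()
  pp <- posterior_predict(sf$fit, ndraws = 120, seed = 9)
  obsd <- pp$records
  sel <- which(!is.na(obsd$height_cm) & obsd$provenance == "observed")
  lo <- apply(pp$heights[sel, ], 1, quantile, 0.25, na.rm = TRUE)
  hi <- apply(pp$heights[sel, ], 1, quantile, 0.75, na.rm = TRUE)
  cover <- mean(obsd$height_cm[sel] >= lo & obsd$height_cm[sel] <= hi)
  expect_gte(cover, 0.30)
})

test_that("sparse-design posterior uncertainty stays within 3x of dense", {
  # the estimator's sparse-data workflow: fit the dense reference first,
  # derive informative priors from it, then fit the sparse population with
  # those priors (sparse data alone carry no early-life information beyond
  # the conception anchors, so diffuse-prior sparse fits cannot match dense
  # precision on in-utero and allometry parameters)
  n <- 16
  cfgd <- population_config(group_sizes = c(ref = n))
  simd <- simulate_growth_data(cfgd, "dense", seed = 51)
  sims <- simulate_growth_data(cfgd, "sparse", seed = 52)
  fd <- fit_growth(build_model(prepare_dataset(simd$records,
                                               carry_forward_to = NULL)),
                   chains = 2, iter = 250, warmup = 250, seed = 61)
  fs <- fit_growth(build_model(prepare_dataset(sims$records,
                                               carry_forward_to = NULL),
                               priors_from_fit(fd)),
                   chains = 2, iter = 250, warmup = 250, seed = 62)
  sd_d <- apply(fd$beta0, 2, sd)
  sd_s <- apply(fs$beta0, 2, sd)
  ratio <- sd_s / sd_d
  expect_true(all(ratio < 3))
})
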