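# Shared fixtures built in code.

# a generic well-behaved single component
fix_component <- function(H = 1, K = 0.5, q = 0.7, i = 0) {
  component_params(H = H, K = K, q = q, i = i)
}

# 100 seeded random valid parameter sets for oracle-equivalence checks
random_components <- function(n = 100, seed = 404) {
  set.seed(seed)
  lapply(seq_len(n), function(k)
    component_params(H = exp(runif(1, -1, 3)),
                     K = exp(runif(1, -1.5, 1.5)),
                     q = runif(1, 0.2, 0.8),
                     i = runif(1, 0, 12)))
}

# small two-group fixture posterior with draws differing ONLY in the
# metabolic (H, K) families between groups: used by intervention tests
fixture_fit <- function(S = 200, seed = 99, metab_shift = 0.25) {
  set.seed(seed)
  tn <- transformed_names()
  m <- reference_transformed_means("female")
  beta0 <- matrix(rep(m, each = S), S, 19) + matrix(rnorm(S * 19, 0, 0.02), S, 19)
  colnames(beta0) <- tn
  g <- array(0, c(S, 2, 19), dimnames = list(NULL, c("reference", "focal"), tn))
  # focal group: higher catabolism, lower anabolism in mid processes
  g[, 2, .family_cols_test("K")[2:4]] <- metab_shift
  g[, 2, .family_cols_test("H")[3]] <- -metab_shift
  Sigma <- lapply(c(H = 5, K = 5, q = 5, i = 4), function(d) {
    a <- array(0, c(S, d, d)); for (s in 1:S) a[s, , ] <- diag(0.02, d); a
  })
  structure(list(beta0 = beta0, g = g, theta = NULL, Sigma = Sigma,
                 sigma = cbind(rep(0.03, S), rep(0.08, S)),
                 lp = numeric(S), chain = rep(1:2, each = S / 2),
                 chains = 2, iter = S / 2, warmup = 0, seed = seed,
                 model = NULL,
                 diagnostics = data.frame(parameter = character(),
                                          rhat = numeric(), ess = numeric())),
            class = "cg_fit")
}

.family_cols_test <- function(f)
  switch(f, H = 1:5, K = 6:10, q = 11:15, i = 16:19)

# small dense two-group synthetic dataset + model, reused by several tests
quick_sim <- function(n_ref = 4, n_focal = 4, seed = 7,
                      design = c(reference = "dense", focal = "sparse")) {
  goff <- matrix(0, 2, 19,
                 dimnames = list(c("reference", "focal"), transformed_names()))
  cfg <- population_config(group_sizes = c(reference = n_ref, focal = n_focal),
                           group_offsets = goff)
  simulate_growth_data(cfg, design = design, seed = seed)
}

# one moderately sized two-group fit shared across test files (cached)
.fixture_cache <- new.env(parent = emptyenv())
shared_fit <- function() {
  if (is.null(.fixture_cache$shared)) {
    sim <- quick_sim(n_ref = 6, n_focal = 10, seed = 42)
    prep <- prepare_dataset(sim$records, carry_forward_to = NULL)
    fit <- fit_growth(build_model(prep), chains = 2, iter = 300,
                      warmup = 300, seed = 5)
    .fixture_cache$shared <- list(fit = fit, sim = sim, prep = prep)
  }
  .fixture_cache$shared
}
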