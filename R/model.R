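# Multilevel model specification.
#
# Transformed person parameters decompose as
#   theta_j = beta0 + g[group(j)] + u_j,   u_j ~ MVN(0, Sigma_family)
# family by family (H, K, q, i), with the person offsets of a family
# covarying across the five growth processes but independent between
# families.  The first group is the reference (offset fixed at zero).
# Measurement error SDs sigma_eta and sigma_mu close the model.

#' Prior hyperparameters for the multilevel growth model
#'
#' Weakly informative priors centred on the reference-like preset:
#' \itemize{
#'   \item baseline transformed means: independent Normal(`means0`, `tau0`);
#'   \item group offsets: independent Normal(0, `tau_group`);
#'   \item person-offset covariances: per-family inverse-Wishart with
#'     `cov_df = d + 2` degrees of freedom and scale `cov_scale * I`
#'     (prior mean `cov_scale/(cov_df - d - 1) * I`), chosen conjugate so the
#'     sampler can update covariances exactly;
#'   \item measurement SDs: half-Normal scales `sigma_eta_scale` and
#'     `sigma_mu_scale`.  The height scale is deliberately much tighter than
#'     the weight scale so that height dominates fit quality, reflecting the
#'     unequal measurement-error constraint between the two data types.
#' }
#'
#' @param means0 Prior centre for the 19 transformed baseline means
#'   (default the female reference preset).
#' @param tau0 Prior SD of each baseline mean (scalar, or one SD per
#'   parameter as produced by [priors_from_fit()]).
#' @param tau_group Prior SD of each group-offset entry.
#' @param cov_scale Inverse-Wishart scale multiplier.
#' @param cov_df_extra Degrees of freedom above the family dimension
#'   (df = d + cov_df_extra; must exceed d + 1 for a finite prior mean).
#' @param sigma_eta_scale,sigma_mu_scale Half-normal prior scales of the
#'   log-scale measurement SDs for height and weight.
#' @return A `cg_priors` object.
#' @export
cg_priors <- function(means0 = reference_transformed_means("female"),
                      tau0 = 0.5, tau_group = 0.5,
                      cov_scale = 0.02, cov_df_extra = 2,
                      sigma_eta_scale = 0.05, sigma_mu_scale = 0.25) {
  stopifnot(length(means0) == N_TRANSFORMED, all(tau0 > 0), tau_group > 0,
            length(tau0) %in% c(1L, N_TRANSFORMED),
            cov_scale > 0, cov_df_extra > 1,
            sigma_eta_scale > 0, sigma_mu_scale > 0)
  structure(list(means0 = stats::setNames(as.numeric(means0),
                                          transformed_names()),
                 tau0 = rep(as.numeric(tau0), length.out = N_TRANSFORMED),
                 tau_group = tau_group,
                 cov_scale = cov_scale, cov_df_extra = cov_df_extra,
                 sigma_eta_scale = sigma_eta_scale,
                 sigma_mu_scale = sigma_mu_scale),
            class = "cg_priors")
}

#' Derive informative priors from a reference-population fit
#'
#' The estimator's intended workflow for temporally sparse data: fit the
#' densely measured reference population first, then centre the baseline-mean
#' priors for the sparse-population fit on the reference posterior means,
#' with prior SDs set to a multiple of the reference posterior SDs (floored
#' to avoid degenerate priors).  This is how a sparse design attains
#' population-mean uncertainties comparable to a dense design despite
#' carrying far less early-life information of its own.
#'
#' @param fit A `cg_fit` of the reference population.
#' @param inflate Multiplier on the reference posterior SDs (default 2).
#' @param floor_sd Lower bound on each prior SD (default 0.05).
#' @param ... Further arguments passed to [cg_priors()] (e.g. the
#'   measurement-SD scales).
#' @return A `cg_priors` object with vector-valued baseline-mean SDs.
#' @export
priors_from_fit <- function(fit, inflate = 2, floor_sd = 0.05, ...) {
  stopifnot(inherits(fit, "cg_fit"), inflate > 0, floor_sd >= 0)
  cg_priors(means0 = colMeans(fit$beta0),
            tau0 = pmax(inflate * apply(fit$beta0, 2, stats::sd), floor_sd),
            ...)
}

#' Build the multilevel growth model for a prepared dataset
#'
#' Validates the data, binds it to the priors and returns a model object
#' exposing the unnormalized log posterior over the constrained
#' parameterization (all parameters live on the transformed scale, so every
#' constraint — positivity of H and K, q in (0,1), ordered initiation ages —
#' holds by construction).
#'
#' @param prep A `cg_prepared` dataset.
#' @param priors A [cg_priors()] object.
#' @return A `cg_model` object.  `$log_posterior(state)` evaluates the joint
#'   unnormalized log density for a state list with elements `theta`
#'   (n x 19), `beta0` (19), `g` (groups x 19), `Sigma` (per-family list),
#'   `sigma_eta`, `sigma_mu`.
#' @export
build_model <- function(prep, priors = cg_priors()) {
  stopifnot(inherits(prep, "cg_prepared"), inherits(priors, "cg_priors"))
  obs <- .build_obs(prep)
  if (obs$n_person < 1) stop("model needs at least one person")
  if (!any(obs$hs)) stop("no height measurements present in the dataset")
  if (!any(obs$ws)) stop("no weight measurements present in the dataset")

  model <- structure(list(data = prep, obs = obs, priors = priors,
                          n_person = obs$n_person,
                          groups = names(prep$group_index)),
                     class = "cg_model")
  model$log_posterior <- function(state) .log_posterior(model, state)
  model
}

.ldmvn0 <- function(U, Sigma) {
  # sum of MVN(0, Sigma) log densities over rows of U
  R <- chol(Sigma)
  z <- U %*% backsolve(R, diag(ncol(U)))
  -0.5 * sum(z^2) - nrow(U) * (sum(log(diag(R))) + 0.5 * ncol(U) * log(2 * pi))
}

.log_posterior <- function(model, state) {
  obs <- model$obs
  pr <- model$priors
  nat <- .transformed_to_natural(state$theta)
  mu <- .traj_mu(nat, obs$pid, obs$t)
  ll <- sum(.person_loglik(obs, mu, state$sigma_eta, state$sigma_mu))
  lp <- 0
  for (f in names(.family_cols)) {
    cols <- .family_cols[[f]]
    lvl <- state$beta0[cols] + state$g[obs$person_group, cols, drop = FALSE]
    U <- state$theta[, cols, drop = FALSE] - lvl
    lp <- lp + .ldmvn0(U, state$Sigma[[f]])
    d <- length(cols)
    # inverse-Wishart prior (unnormalized)
    df <- d + pr$cov_df_extra
    S0 <- diag(pr$cov_scale, d)
    Sf <- state$Sigma[[f]]
    lp <- lp - 0.5 * (df + d + 1) * determinant(Sf)$modulus -
      0.5 * sum(diag(S0 %*% chol2inv(chol(Sf))))
  }
  lp <- lp + sum(stats::dnorm(state$beta0, pr$means0, pr$tau0, log = TRUE))
  if (nrow(state$g) > 1)
    lp <- lp + sum(stats::dnorm(state$g[-1, ], 0, pr$tau_group, log = TRUE))
  lp <- lp + stats::dnorm(state$sigma_eta, 0, pr$sigma_eta_scale, log = TRUE) +
    stats::dnorm(state$sigma_mu, 0, pr$sigma_mu_scale, log = TRUE)
  as.numeric(ll + lp)
}
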