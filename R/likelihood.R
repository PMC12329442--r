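# Measurement likelihood.
#
# Observed height and weight are lognormal around the model trajectory plus
# the egg-cell offsets:
#   ln(h_jt) ~ Normal( ln(0.012    + h(t; params_j)), sigma_eta )
#   ln(m_jt) ~ Normal( ln(1.02e-6  + m(t; params_j)), sigma_mu  )
# Conception anchors participate in the likelihood exactly like observed
# records; a missing modality contributes nothing.

# Flatten a prepared dataset into parallel record vectors keyed by person
# index.  pid/grp are contiguous integer codes.
.build_obs <- function(prep) {
  stopifnot(inherits(prep, "cg_prepared"))
  df <- prep$records
  pid <- unname(prep$person_index[df$person_id])
  pgroup_tab <- tapply(unname(prep$group_index[df$group]), pid, function(g) g[1])
  list(pid = pid,
       t = df$t,
       lh = log(df$height_cm),
       lw = log(df$weight_g),
       hs = !is.na(df$height_cm),
       ws = !is.na(df$weight_g),
       n_person = length(prep$person_index),
       n_group = length(prep$group_index),
       person_group = as.integer(pgroup_tab))
}

# Trajectory means on the log scale for every record, given natural-scale
# parameter matrices (n_person x 5).
.traj_mu <- function(nat, pid, t) {
  h <- m <- 0
  for (x in 1:5) {
    hx <- .vb_height(nat$H[pid, x], nat$K[pid, x], nat$q[pid, x],
                     nat$i[pid, x], t)
    h <- h + hx
    m <- m + pi * hx^(1 + 2 * nat$q[pid, x])
  }
  list(mu_h = log(EGG_HEIGHT_CM + h), mu_w = log(EGG_WEIGHT_G + m))
}

# Per-person log likelihood given record means.
.person_loglik <- function(obs, mu, sigma_eta, sigma_mu, weight = 1) {
  llrec <- numeric(length(obs$t))
  llrec[obs$hs] <- stats::dnorm(obs$lh[obs$hs], mu$mu_h[obs$hs],
                                sigma_eta, log = TRUE)
  llrec[obs$ws] <- llrec[obs$ws] +
    stats::dnorm(obs$lw[obs$ws], mu$mu_w[obs$ws], sigma_mu, log = TRUE)
  as.vector(rowsum(llrec * weight, obs$pid))
}

#' Measurement log likelihood of a prepared dataset
#'
#' Sums, over all height records, the normal log density of `log(h_obs)` at
#' mean `log(0.012 + h(t))` with SD `sigma_eta`, plus the analogous weight
#' terms with offset `1.02e-6` g and SD `sigma_mu`.  A missing modality
#' contributes nothing.
#'
#' @param prep A `cg_prepared` dataset (see [prepare_dataset()]).
#' @param params Person parameters: a matrix (persons x 19) of
#'   transformed-scale parameters with rows ordered as
#'   `prep$person_index`, or a `cg_population` whose persons match, or a
#'   single [composite_params()] when the dataset has one person.
#' @param sigma_eta,sigma_mu Positive log-scale measurement SDs.
#' @return Total log likelihood (scalar).
#' @export
log_likelihood <- function(prep, params, sigma_eta, sigma_mu) {
  stopifnot(sigma_eta > 0, sigma_mu > 0)
  obs <- .build_obs(prep)
  if (inherits(params, "cg_population")) params <- params$theta
  if (inherits(params, "composite_params")) {
    if (obs$n_person != 1)
      stop("a single composite_params requires a single-person dataset")
    params <- matrix(natural_to_transformed(params), nrow = 1)
  }
  stopifnot(is.matrix(params), nrow(params) == obs$n_person,
            ncol(params) == N_TRANSFORMED)
  nat <- .transformed_to_natural(params)
  mu <- .traj_mu(nat, obs$pid, obs$t)
  sum(.person_loglik(obs, mu, sigma_eta, sigma_mu))
}
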