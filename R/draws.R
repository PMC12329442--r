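# Posterior-draw utilities: HPDI, contrasts, extractors, posterior
# prediction, and a text-based persistence format for fits.

#' Highest posterior density interval
#'
#' Shortest contiguous interval of sorted draws containing the requested
#' posterior mass: with `k = ceiling(mass * n)`, the window
#' `[x_(j), x_(j+k)]` of minimal width (the earliest window on ties).
#'
#' @param x Numeric draws (at least 2).
#' @param mass Probability mass in (0, 1); default 0.90.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' hpdi(rnorm(1e4), 0.9)
#' @export
hpdi <- function(x, mass = 0.9) {
  stopifnot(is.numeric(x), length(x) >= 2, mass > 0, mass < 1)
  x <- sort(x)
  n <- length(x)
  k <- ceiling(mass * n)
  if (k >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  j <- which.min(widths)
  c(lower = x[j], upper = x[j + k])
}

#' Posterior contrast between two sets of draws
#'
#' Elementwise difference `A - B` with a detection flag: the contrast is
#' flagged when its HPDI excludes zero.
#'
#' @param a,b Numeric draw vectors.  Unequal lengths are resampled (without
#'   replacement from the longer vector) to the common minimum, with a
#'   message.
#' @param mass HPDI mass used for the detection rule (default 0.90).
#' @return A list with `draws` (the differences), `hpdi`, and
#'   `excludes_zero` (logical detection flag).
#' @export
contrast_draws <- function(a, b, mass = 0.9) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) != length(b)) {
    message("contrast: resampling to common draw count ",
            min(length(a), length(b)))
    nn <- min(length(a), length(b))
    if (length(a) > nn) a <- sample(a, nn)
    if (length(b) > nn) b <- sample(b, nn)
  }
  d <- a - b
  iv <- hpdi(d, mass)
  list(draws = d, hpdi = iv,
       excludes_zero = unname(iv[1] > 0 | iv[2] < 0))
}

#' Posterior draws of a group's mean transformed parameters
#'
#' Baseline means plus the group's offset, per draw.
#'
#' @param fit A `cg_fit` (or text-restored fit) object.
#' @param group Group name (default the reference group).
#' @return Matrix (draws x 19) on the transformed scale.
#' @export
group_mean_draws <- function(fit, group = NULL) {
  gn <- dimnames(fit$g)[[2]]
  if (is.null(group)) group <- gn[1]
  k <- match(group, gn)
  if (is.na(k)) stop("unknown group '", group, "'; available: ",
                     paste(gn, collapse = ", "))
  out <- fit$beta0 + fit$g[, k, ]
  colnames(out) <- transformed_names()
  out
}

#' Posterior-mean composite parameters of a group
#'
#' Back-transforms the posterior mean of the group-level transformed
#' parameters into a [composite_params()] object.
#'
#' @inheritParams group_mean_draws
#' @export
group_mean_composite <- function(fit, group = NULL) {
  transformed_to_composite(colMeans(group_mean_draws(fit, group)))
}

#' Posterior predictive replicates of the observed records
#'
#' For randomly chosen posterior draws, regenerates noisy height and weight
#' observations at every observed record's age from that draw's person-level
#' parameters and measurement SDs.
#'
#' @param fit A `cg_fit` with person-level draws.
#' @param ndraws Number of replicate datasets.
#' @param seed Integer seed.
#' @return List with `heights` and `weights`: matrices
#'   (records x ndraws) of replicated observations (NA where the modality is
#'   missing), and `records` the observed record table.
#' @export
posterior_predict <- function(fit, ndraws = 100, seed = 1) {
  if (is.null(fit$theta)) stop("fit has no person-level draws")
  set.seed(seed)
  obs <- fit$model$obs
  take <- sample(dim(fit$theta)[1], ndraws, replace = ndraws > dim(fit$theta)[1])
  H <- matrix(NA_real_, length(obs$t), ndraws)
  W <- matrix(NA_real_, length(obs$t), ndraws)
  for (s in seq_along(take)) {
    nat <- .transformed_to_natural(fit$theta[take[s], , ])
    mu <- .traj_mu(nat, obs$pid, obs$t)
    H[obs$hs, s] <- exp(stats::rnorm(sum(obs$hs), mu$mu_h[obs$hs],
                                     fit$sigma[take[s], 1]))
    W[obs$ws, s] <- exp(stats::rnorm(sum(obs$ws), mu$mu_w[obs$ws],
                                     fit$sigma[take[s], 2]))
  }
  list(heights = H, weights = W, records = fit$model$data$records)
}

#' Tidy table of population-level posterior draws
#'
#' Long-format draws of all population-level quantities (baseline means,
#' group offsets, covariance entries, measurement SDs), suitable for CSV
#' persistence.
#'
#' @param fit A `cg_fit` object.
#' @return Data frame with columns `draw`, `chain`, `parameter`, `value`.
#' @export
draws_table <- function(fit) {
  S <- nrow(fit$beta0)
  tn <- transformed_names()
  pieces <- list()
  add <- function(name, value)
    pieces[[length(pieces) + 1]] <<- data.frame(
      draw = seq_len(S), chain = fit$chain, parameter = name, value = value)
  for (j in seq_len(N_TRANSFORMED))
    add(paste0("beta0[", tn[j], "]"), fit$beta0[, j])
  gn <- dimnames(fit$g)[[2]]
  for (k in seq_along(gn))
    for (j in seq_len(N_TRANSFORMED))
      add(paste0("g[", gn[k], "][", tn[j], "]"), fit$g[, k, j])
  for (f in names(fit$Sigma)) {
    d <- dim(fit$Sigma[[f]])[2]
    for (r in seq_len(d)) for (cc in seq_len(d))
      add(sprintf("Sigma[%s][%d,%d]", f, r, cc), fit$Sigma[[f]][, r, cc])
  }
  add("sigma_eta", fit$sigma[, 1])
  add("sigma_mu", fit$sigma[, 2])
  do.call(rbind, pieces)
}

#' Persist a fit's population-level draws as text
#'
#' Writes `draws.csv` (long format, see [draws_table()]), `groups.json` and
#' `diagnostics.json` into a directory.  The person-level draws are not
#' persisted; a restored fit supports group-level summaries and
#' interventions.
#'
#' @param fit A `cg_fit`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fit_dir <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(draws_table(fit), file.path(dir, "draws.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(groups = dimnames(fit$g)[[2]], chains = fit$chains, iter = fit$iter,
         warmup = fit$warmup, seed = fit$seed),
    file.path(dir, "groups.json"), auto_unbox = TRUE)
  jsonlite::write_json(fit$diagnostics, file.path(dir, "diagnostics.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}

#' Restore a fit written by [write_fit_dir()]
#'
#' @param dir Directory containing `draws.csv` and `groups.json`.
#' @return A `cg_fit`-like object (class `cg_fit`) without person-level
#'   draws.
#' @export
read_fit_dir <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "groups.json"),
                              simplifyVector = TRUE)
  tab <- utils::read.csv(file.path(dir, "draws.csv"), stringsAsFactors = FALSE)
  tn <- transformed_names()
  S <- max(tab$draw)
  grab <- function(name) tab$value[tab$parameter == name]
  beta0 <- sapply(tn, function(p) grab(paste0("beta0[", p, "]")))
  G <- length(meta$groups)
  g <- array(0, c(S, G, N_TRANSFORMED),
             dimnames = list(NULL, meta$groups, tn))
  for (k in seq_len(G)) for (j in seq_len(N_TRANSFORMED))
    g[, k, j] <- grab(paste0("g[", meta$groups[k], "][", tn[j], "]"))
  Sigma <- lapply(stats::setNames(names(.family_cols), names(.family_cols)),
                  function(f) {
    d <- length(.family_cols[[f]])
    a <- array(NA_real_, c(S, d, d))
    for (r in seq_len(d)) for (cc in seq_len(d))
      a[, r, cc] <- grab(sprintf("Sigma[%s][%d,%d]", f, r, cc))
    a
  })
  structure(list(beta0 = beta0, g = g, theta = NULL, Sigma = Sigma,
                 sigma = cbind(grab("sigma_eta"), grab("sigma_mu")),
                 chain = tab$chain[tab$parameter == "sigma_eta"],
                 chains = meta$chains, iter = meta$iter,
                 warmup = meta$warmup, seed = meta$seed, model = NULL),
            class = "cg_fit")
}
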