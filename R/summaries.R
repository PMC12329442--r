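# Posterior-derived scientific summaries: age-weighted parameter
# trajectories, trajectory descriptives, and group comparisons.

#' Contribution of each growth process to overall height
#'
#' At a given age, each process's weight is its share of composite height:
#' `w_x(t) = h_x(t) / sum_y h_y(t)`.  Weights are nonnegative and sum to 1.
#'
#' @param cp A [composite_params()] object.
#' @param t Total age(s) since conception; composite height must be positive
#'   at every requested age.
#' @return For scalar `t`, a length-5 vector; for vector `t`, a matrix
#'   (ages x 5).
#' @export
process_weights <- function(cp, t) {
  stopifnot(inherits(cp, "composite_params"))
  hx <- vapply(cp$components, function(p) component_height(p, t, cp$D),
               numeric(length(t)))
  hx <- matrix(hx, nrow = length(t))
  tot <- rowSums(hx)
  if (any(tot <= 0))
    stop("composite height is zero at some requested age(s); weights undefined")
  w <- hx / tot
  if (length(t) == 1) as.vector(w) else w
}

#' Relative metabolic activity of a component process
#'
#' Metabolic rates are assumed to decline as a process approaches its
#' asymptote (replacement of metabolically active red marrow by marrow fat):
#' `a_x(t) = 1 - rho * h_x(t) / h_x(Inf)`, a monotone interpolation from 1
#' at initiation to `1 - rho` at the asymptote.  The decline fraction `rho`
#' defaults to 0.75.
#'
#' @param p A [component_params()] object.
#' @param t Total age(s).
#' @param rho Fraction of metabolic activity lost at the asymptote, in
#'   `[0, 1)`.
#' @param D Density.
#' @return Activity value(s) in `[1 - rho, 1]`.
#' @export
metabolic_activity <- function(p, t, rho = 0.75, D = 1) {
  stopifnot(rho >= 0, rho < 1)
  1 - rho * component_height(p, t, D) / asymptotic_height(p, D)
}

# height-weighted (and, for K/H, activity-weighted) parameter value(s) for a
# single parameter set; ages with zero composite height yield NA.
.weighted_param_value <- function(cp, family, ages, rho) {
  pm <- param_matrix(cp)
  hx <- vapply(cp$components, function(p) component_height(p, ages, cp$D),
               numeric(length(ages)))
  hx <- matrix(hx, nrow = length(ages))
  tot <- rowSums(hx)
  w <- hx / ifelse(tot > 0, tot, NA_real_)
  if (family == "q") {
    val <- rowSums(w * rep(pm[, "q"], each = length(ages)))
  } else {
    asym <- vapply(cp$components, asymptotic_height, numeric(1), D = cp$D)
    act <- 1 - rho * hx / rep(asym, each = length(ages))
    wa <- w * act
    val <- rowSums(wa * rep(pm[, family], each = length(ages))) / rowSums(wa)
  }
  val
}

#' Age-weighted posterior parameter trajectories
#'
#' For each posterior draw of a group's mean parameters and each age,
#' computes the across-process summary of a parameter family, weighted by
#' the contribution of each process to overall height at that age
#' (`w_x = h_x / sum h_y`); the metabolic families K and H are further
#' weighted by the expected decline in metabolic activity toward the
#' asymptote ([metabolic_activity()]):
#' \deqn{\bar q(t) = \sum_x w_x q_x, \qquad
#'       \bar K(t) = \frac{\sum_x w_x a_x K_x}{\sum_x w_x a_x}}
#' (and analogously for H).  Ages where the composite height is zero are
#' reported as missing.
#'
#' @param fit A `cg_fit` object.
#' @param family `"q"`, `"K"` or `"H"`.
#' @param group Group name (default reference).
#' @param ages Total-age grid (yr, > 0).
#' @param rho Metabolic decline fraction at the asymptote (default 0.75).
#' @param mass HPDI mass for the bands.
#' @param max_draws Cap on the number of posterior draws used.
#' @return A `cg_wtraj` object: list with `ages`, per-draw matrix `draws`
#'   (draws x ages), `mean`, `lower`, `upper`, and metadata.
#' @export
weighted_parameter_trajectory <- function(fit, family = c("q", "K", "H"),
                                          group = NULL,
                                          ages = seq(0.25, 26.75, by = 0.25),
                                          rho = 0.75, mass = 0.9,
                                          max_draws = 500) {
  family <- match.arg(family)
  stopifnot(all(ages > 0))
  gm <- group_mean_draws(fit, group)
  S <- min(nrow(gm), max_draws)
  take <- if (nrow(gm) > S) round(seq(1, nrow(gm), length.out = S)) else seq_len(S)
  vals <- matrix(NA_real_, length(take), length(ages))
  for (s in seq_along(take)) {
    cp <- transformed_to_composite(gm[take[s], ])
    vals[s, ] <- .weighted_param_value(cp, family, ages, rho)
  }
  bands <- apply(vals, 2, function(v)
    if (all(is.na(v))) c(NA_real_, NA_real_) else hpdi(v[!is.na(v)], mass))
  structure(list(ages = ages, family = family,
                 group = if (is.null(group)) dimnames(fit$g)[[2]][1] else group,
                 rho = rho, draws = vals,
                 mean = colMeans(vals), lower = bands[1, ], upper = bands[2, ]),
            class = "cg_wtraj")
}

#' @export
print.cg_wtraj <- function(x, ...) {
  cat(sprintf("weighted %s trajectory for group '%s' (%d draws, %d ages, rho = %g)\n",
              x$family, x$group, nrow(x$draws), length(x$ages), x$rho))
  invisible(x)
}

#' @export
as.data.frame.cg_wtraj <- function(x, ...) {
  data.frame(age = x$ages, group = x$group, family = x$family,
             mean = x$mean, hpdi_lo = x$lower, hpdi_hi = x$upper)
}

# descriptives of a single trajectory
.descriptives_one <- function(cp, window, adult_age, step) {
  tg <- seq(window[1], window[2], by = step) + GESTATION_YR
  v <- height_velocity(cp, tg)
  jj <- which.max(v)  # earliest maximum on ties
  lo <- max(tg[1], tg[jj] - step)
  hi <- min(tg[length(tg)], tg[jj] + step)
  op <- stats::optimize(function(tt) height_velocity(cp, tt),
                        lower = lo, upper = hi, maximum = TRUE,
                        tol = 1e-6)
  peak_t <- if (op$objective >= v[jj]) op$maximum else tg[jj]
  peak_v <- max(op$objective, v[jj])
  c(max_height = composite_height(cp, adult_age + GESTATION_YR),
    peak_velocity = peak_v,
    age_at_peak_velocity = peak_t - GESTATION_YR,
    degenerate = as.numeric(jj == 1))
}

#' Posterior trajectory descriptives
#'
#' Per posterior draw of a group's mean trajectory: maximum achieved height
#' (composite height at a reference adult age), maximum growth velocity
#' within a pubertal search window, and the age (since birth) at that
#' maximum.  The velocity maximum is located on a fine age grid and refined
#' locally; ties take the earliest age.  Draws whose maximum sits at the
#' window's lower edge (no pubertal peak inside the window) are flagged
#' degenerate.
#'
#' @param fit A `cg_fit` object.
#' @param group Group name (default reference).
#' @param window Search window for peak velocity, years since birth.
#' @param adult_age Reference adult age (years since birth) at which maximum
#'   height is read.
#' @param step Search grid resolution (yr).
#' @param mass HPDI mass.
#' @param max_draws Cap on posterior draws used.
#' @return A `cg_descriptives` object: per-draw data frame `draws` plus a
#'   `summary` data frame of posterior means and HPDIs.
#' @export
trajectory_descriptives <- function(fit, group = NULL, window = c(5, 20),
                                    adult_age = 26, step = 0.01, mass = 0.9,
                                    max_draws = 500) {
  stopifnot(length(window) == 2, window[1] < window[2])
  gm <- group_mean_draws(fit, group)
  S <- min(nrow(gm), max_draws)
  take <- if (nrow(gm) > S) round(seq(1, nrow(gm), length.out = S)) else seq_len(S)
  rows <- t(vapply(take, function(s)
    .descriptives_one(transformed_to_composite(gm[s, ]), window, adult_age,
                      step),
    numeric(4)))
  draws <- as.data.frame(rows)
  summ <- do.call(rbind, lapply(
    c("max_height", "peak_velocity", "age_at_peak_velocity"),
    function(v) {
      iv <- hpdi(draws[[v]], mass)
      data.frame(quantity = v, mean = mean(draws[[v]]),
                 hpdi_lo = iv[1], hpdi_hi = iv[2], row.names = NULL)
    }))
  structure(list(draws = draws, summary = summ,
                 group = if (is.null(group)) dimnames(fit$g)[[2]][1] else group,
                 window = window, adult_age = adult_age,
                 degenerate_fraction = mean(draws$degenerate)),
            class = "cg_descriptives")
}

#' @export
print.cg_descriptives <- function(x, ...) {
  cat(sprintf("trajectory descriptives for group '%s' (adult age %g, window [%g, %g] yr since birth)\n",
              x$group, x$adult_age, x$window[1], x$window[2]))
  print(x$summary, row.names = FALSE)
  if (x$degenerate_fraction > 0)
    cat(sprintf("  note: %.0f%% of draws had no interior velocity peak\n",
                100 * x$degenerate_fraction))
  invisible(x)
}
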