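# Synthetic-data generator.
#
# Generates populations of true growth parameters with the multilevel
# structure the estimator assumes (transformed-scale baseline means, group
# offsets, person offsets covarying across the five processes within each
# parameter family), measurement schedules emulating a temporally dense and a
# temporally sparse design, and lognormal measurement noise around the
# model-generated trajectories.

.default_sigma_list <- function(scale = 0.02) {
  s <- lapply(.family_cols, function(cols) diag(scale, length(cols)))
  names(s) <- names(.family_cols)
  s
}

.check_psd <- function(S, name) {
  if (!isSymmetric(unname(S), tol = 1e-8))
    stop("covariance for family ", name, " is not symmetric")
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10))
    stop("covariance for family ", name, " is not positive semi-definite")
  invisible(S)
}

#' Configuration of a synthetic study population
#'
#' Describes the data-generating multilevel model: transformed-scale baseline
#' means, per-group offset vectors, per-family covariance of person-level
#' offsets across the five growth processes, and log-scale measurement-error
#' SDs.
#'
#' @param means Named numeric vector of length 19: transformed baseline
#'   means (default [reference_transformed_means()] for females).
#' @param group_sizes Named integer vector: persons per group.  The first
#'   group is the reference (zero offset unless given).
#' @param group_offsets Optional matrix (groups x 19, rownames = group
#'   names) of transformed-scale group offsets; default all zero.
#' @param offset_cov List of per-family covariance matrices for person-level
#'   offsets, names `H`, `K`, `q` (5 x 5) and `i` (4 x 4).  Default
#'   `0.02 * I`, i.e. person SDs of about 0.14 on the transformed scale.
#' @param sigma_eta,sigma_mu Log-scale measurement-error SDs for height and
#'   weight (defaults 0.03 and 0.08; package fixture choices).
#' @param sex `"female"` or `"male"` (selects the preset means default and
#'   is stamped on generated records).
#' @return A `cg_popconfig` object.
#' @export
population_config <- function(means = NULL,
                              group_sizes = c(reference = 30),
                              group_offsets = NULL,
                              offset_cov = .default_sigma_list(),
                              sigma_eta = 0.03, sigma_mu = 0.08,
                              sex = c("female", "male")) {
  sex <- match.arg(sex)
  if (is.null(means)) means <- reference_transformed_means(sex)
  stopifnot(length(means) == N_TRANSFORMED, sigma_eta > 0, sigma_mu > 0,
            length(group_sizes) >= 1, all(group_sizes >= 1))
  if (is.null(names(group_sizes)))
    names(group_sizes) <- paste0("group", seq_along(group_sizes))
  if (is.null(group_offsets)) {
    group_offsets <- matrix(0, length(group_sizes), N_TRANSFORMED,
                            dimnames = list(names(group_sizes),
                                            transformed_names()))
  }
  stopifnot(nrow(group_offsets) == length(group_sizes),
            ncol(group_offsets) == N_TRANSFORMED)
  stopifnot(identical(sort(names(offset_cov)), sort(names(.family_cols))))
  for (f in names(.family_cols)) {
    stopifnot(nrow(offset_cov[[f]]) == length(.family_cols[[f]]))
    .check_psd(offset_cov[[f]], f)
  }
  # implied initiation ages must be ordered at the mean (automatic under the
  # increment parameterization, checked for safety)
  i_mean <- .transformed_to_natural(means)$i[1, ]
  stopifnot(all(diff(i_mean) > 0))
  structure(list(means = stats::setNames(as.numeric(means), transformed_names()),
                 group_sizes = group_sizes,
                 group_offsets = group_offsets, offset_cov = offset_cov,
                 sigma_eta = sigma_eta, sigma_mu = sigma_mu, sex = sex),
            class = "cg_popconfig")
}

# one MVN draw matrix (n x d) with covariance S; eigendecomposition square
# root so that positive semi-definite (including zero) covariances are
# handled exactly
.rmvn <- function(n, S) {
  d <- nrow(S)
  e <- eigen(S, symmetric = TRUE)
  A <- sqrt(pmax(e$values, 0)) * t(e$vectors)
  matrix(stats::rnorm(n * d), n, d) %*% A
}

#' Draw a population of true growth parameters
#'
#' For each person, transformed parameters are baseline mean + group offset +
#' person offset, where person offsets are drawn from the per-family
#' multivariate normal; back-transformation yields each person's natural
#' (H, K, q, i) parameters with `i1` forced to 0.
#'
#' @param cfg A [population_config()] object.
#' @param seed Integer seed (required; generation is deterministic given it).
#' @return A `cg_population` object: list with `persons` (data frame of
#'   `person_id`, `group`, `sex`), `theta` (n x 19 matrix of transformed
#'   parameters), `natural` (list of n x 5 matrices H, K, q, i) and the
#'   generating `config`.
#' @export
draw_population <- function(cfg, seed) {
  stopifnot(inherits(cfg, "cg_popconfig"))
  set.seed(seed)
  groups <- rep(names(cfg$group_sizes), cfg$group_sizes)
  n <- length(groups)
  theta <- matrix(rep(cfg$means, each = n), n, N_TRANSFORMED)
  theta <- theta + cfg$group_offsets[groups, , drop = FALSE]
  for (f in names(.family_cols)) {
    cols <- .family_cols[[f]]
    theta[, cols] <- theta[, cols] + .rmvn(n, cfg$offset_cov[[f]])
  }
  colnames(theta) <- transformed_names()
  persons <- data.frame(
    person_id = sprintf("%s_%03d", groups, stats::ave(seq_len(n), groups,
                                                      FUN = seq_along)),
    group = groups, sex = cfg$sex, stringsAsFactors = FALSE)
  rownames(theta) <- persons$person_id
  structure(list(persons = persons, theta = theta,
                 natural = .transformed_to_natural(theta), config = cfg,
                 seed = seed),
            class = "cg_population")
}

#' Dense-design measurement ages
#'
#' The fixed measurement grid of the temporally dense design, on the
#' total-age scale: birth, then quarterly up to (not including) total age
#' 2.75, then annually to 18.75 (ages since birth 0 to 18) — 25 ages, and,
#' when `carry_forward = TRUE` (the default), annual ages through 26.75
#' emulating the densified adult horizon of the design (about 33 ages in
#' total, i.e. an average of about 30 childhood measurements plus the adult
#' plateau).
#'
#' @param carry_forward Include the annual ages 19.75..26.75?
#' @return Numeric vector of total ages (yr).
#' @export
dense_design_ages <- function(carry_forward = TRUE) {
  ages <- c(seq(0.75, 2.5, by = 0.25), seq(2.75, 18.75, by = 1))
  if (carry_forward) ages <- c(ages, seq(19.75, 26.75, by = 1))
  ages
}

#' Generate per-person measurement schedules
#'
#' `"dense"` gives every person the deterministic [dense_design_ages()]
#' grid.  `"sparse"` draws, per person, a measurement count from the mixture
#' P(1, 2, 3) = (0.70, 0.29, 0.01) — matching a 70% singleton share, a
#' maximum of 3 and a mean of about 1.3 — and distinct integer ages since
#' birth uniform on 1..24.
#'
#' @param design `"dense"` or `"sparse"`.
#' @param n_persons Number of persons.
#' @param seed Integer seed (required for the sparse design).
#' @param count_probs Sparse count-mixture probabilities for 1, 2, 3
#'   measurements.
#' @param age_range Sparse integer age range since birth.
#' @param carry_forward Dense design only: include the annual adult-horizon
#'   ages (see [dense_design_ages()]).
#' @return List of length `n_persons` of sorted total-age vectors, with the
#'   design stored in attribute `"design"`.
#' @export
make_schedule <- function(design = c("dense", "sparse"), n_persons,
                          seed = NULL, count_probs = c(0.70, 0.29, 0.01),
                          age_range = c(1L, 24L), carry_forward = TRUE) {
  design <- match.arg(design)
  stopifnot(n_persons >= 1)
  if (design == "dense") {
    ages <- dense_design_ages(carry_forward)
    sched <- rep(list(ages), n_persons)
  } else {
    if (is.null(seed)) stop("sparse schedules require a seed")
    set.seed(seed)
    stopifnot(length(count_probs) == 3, all(count_probs >= 0))
    counts <- sample.int(3L, n_persons, replace = TRUE, prob = count_probs)
    pool <- seq.int(age_range[1], age_range[2])
    sched <- lapply(counts, function(k)
      sort(sample(pool, k)) + GESTATION_YR)
  }
  attr(sched, "design") <- design
  sched
}

#' Simulate noisy height and weight measurements
#'
#' Observations follow the lognormal measurement model around each person's
#' model-generated trajectory:
#' `h_obs = exp(Normal(log(0.012 + h(t)), sigma_eta))` and analogously for
#' weight with the egg-cell offset 1.02e-6 g.  Both modalities are measured
#' at every scheduled age.
#'
#' @param pop A `cg_population` from [draw_population()].
#' @param schedule Per-person total-age lists from [make_schedule()] (length
#'   must equal the number of persons).
#' @param sigma_eta,sigma_mu Log-scale measurement SDs; default from the
#'   population config.
#' @param seed Integer seed.
#' @return A `cg_records` data frame of observed measurements.
#' @export
simulate_measurements <- function(pop, schedule,
                                  sigma_eta = pop$config$sigma_eta,
                                  sigma_mu = pop$config$sigma_mu, seed) {
  stopifnot(inherits(pop, "cg_population"),
            length(schedule) == nrow(pop$persons),
            sigma_eta > 0, sigma_mu > 0)
  set.seed(seed)
  n_per <- lengths(schedule)
  pid_row <- rep(seq_along(schedule), n_per)
  t <- unlist(schedule, use.names = FALSE)
  nat <- pop$natural
  h <- m <- 0
  for (x in 1:5) {
    hx <- .vb_height(nat$H[pid_row, x], nat$K[pid_row, x], nat$q[pid_row, x],
                     nat$i[pid_row, x], t)
    h <- h + hx
    m <- m + pi * hx^(1 + 2 * nat$q[pid_row, x])
  }
  h_obs <- exp(stats::rnorm(length(t), log(EGG_HEIGHT_CM + h), sigma_eta))
  w_obs <- exp(stats::rnorm(length(t), log(EGG_WEIGHT_G + m), sigma_mu))
  .as_records(data.frame(
    person_id = pop$persons$person_id[pid_row],
    group = pop$persons$group[pid_row],
    sex = pop$persons$sex[pid_row],
    t = t, height_cm = h_obs, weight_g = w_obs,
    provenance = "observed", stringsAsFactors = FALSE))
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: draw a population, build per-group schedules and
#' simulate measurements.
#'
#' @param cfg A [population_config()].
#' @param design Either a single design name applied to all groups, or a
#'   named character vector mapping group names to `"dense"`/`"sparse"`.
#' @param seed Integer seed governing all randomness.
#' @return List with `records` (a `cg_records` data frame), `population`
#'   (the true parameters) and `schedule`.
#' @export
simulate_growth_data <- function(cfg, design = "dense", seed) {
  stopifnot(inherits(cfg, "cg_popconfig"))
  pop <- draw_population(cfg, seed = seed)
  if (length(design) == 1 && is.null(names(design)))
    design <- stats::setNames(rep(design, length(cfg$group_sizes)),
                              names(cfg$group_sizes))
  sched <- vector("list", nrow(pop$persons))
  for (gi in seq_along(cfg$group_sizes)) {
    g <- names(cfg$group_sizes)[gi]
    rows <- which(pop$persons$group == g)
    sched[rows] <- make_schedule(design[[g]], length(rows),
                                 seed = seed + 7919L * gi)
  }
  records <- simulate_measurements(pop, sched, seed = seed + 104729L)
  list(records = records, population = pop, schedule = sched)
}
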