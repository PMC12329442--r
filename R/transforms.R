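# Transformed-scale parameterization used by the generator and the estimator.
#
# Each person's 20 component-level parameters reduce to 19 free quantities on
# an unconstrained scale (i1 is fixed at conception):
#   log H_x   (x = 1..5)   anabolic rates
#   log K_x   (x = 1..5)   catabolic rates
#   logit q_x (x = 1..5)   allometric exponents, kept in (0, 1)
#   log d_x   (x = 2..5)   positive initiation-age increments,
#                          i_x = d_2 + ... + d_x, enforcing i2 < i3 < i4 < i5
# Population means, group offsets and person offsets all live on this scale.

N_TRANSFORMED <- 19L

.family_cols <- list(H = 1:5, K = 6:10, q = 11:15, i = 16:19)

#' Names of the transformed model parameters
#'
#' @return Character vector of length 19 naming the transformed-scale
#'   parameters in package order: `log_H_1..5`, `log_K_1..5`,
#'   `logit_q_1..5`, `log_di_2..5`.
#' @export
transformed_names <- function() {
  c(paste0("log_H_", 1:5), paste0("log_K_", 1:5),
    paste0("logit_q_", 1:5), paste0("log_di_", 2:5))
}

#' Map natural component parameters to the transformed scale
#'
#' @param cp A [composite_params()] object (or a 5 x 4 matrix with columns
#'   H, K, q, i and strictly increasing `i` for processes 2..5).
#' @return Named numeric vector of length 19.
#' @export
natural_to_transformed <- function(cp) {
  m <- if (inherits(cp, "composite_params")) param_matrix(cp) else cp
  stopifnot(is.matrix(m), nrow(m) == 5, ncol(m) == 4)
  di <- diff(c(0, m[2:5, 4]))
  if (any(di <= 0))
    stop("initiation ages must be strictly increasing for processes 2..5")
  th <- c(log(m[, 1]), log(m[, 2]), stats::qlogis(m[, 3]), log(di))
  names(th) <- transformed_names()
  th
}

# Back-transform a matrix (n x 19) or vector of transformed parameters to
# natural-scale matrices H, K, q, i (each n x 5).
.transformed_to_natural <- function(theta) {
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1)
  E <- exp(theta[, 16:19, drop = FALSE])
  i <- cbind(0, E[, 1], E[, 1] + E[, 2], E[, 1] + E[, 2] + E[, 3],
             E[, 1] + E[, 2] + E[, 3] + E[, 4])
  list(H = exp(theta[, 1:5, drop = FALSE]),
       K = exp(theta[, 6:10, drop = FALSE]),
       q = stats::plogis(theta[, 11:15, drop = FALSE]),
       i = i)
}

#' Build a composite model from a transformed parameter vector
#'
#' @param theta Numeric vector of length 19 on the transformed scale.
#' @param D Density (g/cm^3).
#' @return A [composite_params()] object.
#' @export
transformed_to_composite <- function(theta, D = 1) {
  stopifnot(is.numeric(theta), length(theta) == N_TRANSFORMED)
  nat <- .transformed_to_natural(theta)
  composite_params(lapply(1:5, function(x)
    component_params(nat$H[1, x], nat$K[1, x], nat$q[1, x], nat$i[1, x])), D = D)
}

#' Construct a component from trajectory shape quantities
#'
#' Parameterizes a component by its asymptotic height `A`, exponential
#' approach rate `lambda = Kq/(1+2q)` (yr^-1), allometric exponent and
#' initiation age, and converts to the (H, K, q, i) rate parameters:
#' `K = lambda (1+2q)/q`, `H = K A^q / 2`.  Convenient for building fixture
#' trajectories with a prescribed size and tempo.
#'
#' @param A Asymptotic height contribution (cm).
#' @param lambda Approach rate (yr^-1).
#' @param q Allometric exponent in (0, 1).
#' @param i Initiation age (total years since conception).
#' @param label Optional label.
#' @return A [component_params()] object.
#' @export
component_from_shape <- function(A, lambda, q, i, label = NULL) {
  stopifnot(A > 0, lambda > 0)
  K <- lambda * (1 + 2 * q) / q
  component_params(H = K * A^q / 2, K = K, q = q, i = i, label = label)
}
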