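#' compgrowth: composite von Bertalanffy growth models for human height and weight
#'
#' Models human height and weight growth as the sum of five gated
#' Putter/von Bertalanffy-type component processes.  Each component describes
#' one tissue-group growth cycle: anabolism scales with the absorbing
#' (intestinal) surface of a stylised cylindrical body, catabolism scales with
#' mass, and radius is tied to height by the allometric power law r = h^q.
#' The package provides the closed-form trajectories, a synthetic-data
#' generator, a Bayesian multilevel estimator for dense and sparse
#' longitudinal anthropometry, posterior summaries, and counterfactual
#' metabolic-intervention simulation.
#'
#' @keywords internal
#' @aliases compgrowth-package
"_PACKAGE"

# Diameter of a human egg cell (cm) and its weight (g): every trajectory is
# anchored at this size at conception (total age 0).
EGG_HEIGHT_CM <- 0.012
EGG_WEIGHT_G <- 1.02e-6

# Gestation length on the total-age scale: birth occurs 0.75 yr after
# conception, so age-since-birth a maps to total age a + 0.75.
GESTATION_YR <- 0.75

#' Parameters of one component growth process
#'
#' A single Putter/von Bertalanffy-type growth process for a cylindrical body
#' segment whose radius follows the allometric law \eqn{r = h^q}.  Growth in
#' mass is the balance of anabolism (rate `H` per unit absorbing surface) and
#' catabolism (rate `K` per unit mass); the process switches on at total age
#' `i` (years since conception).
#'
#' @param H Anabolic rate, synthesized mass per unit absorbing surface per
#'   year (g cm^-2 yr^-1). Must be strictly positive; degenerate
#'   "absent" processes are represented by a very small `H`.
#' @param K Catabolic rate, destructed mass per unit mass per year (yr^-1).
#'   Strictly positive.
#' @param q Allometric exponent linking radius to height, in the open
#'   interval (0, 1).
#' @param i Initiation age: total age since conception (years, >= 0) at which
#'   the process switches on.
#' @param label Optional descriptive label (e.g. "infancy").
#' @return An object of class `component_params`.
#' @examples
#' p <- component_params(H = 1, K = 0.5, q = 0.7, i = 0)
#' asymptotic_height(p)
#' @export
component_params <- function(H, K, q, i, label = NULL) {
  stopifnot(is.numeric(H), is.numeric(K), is.numeric(q), is.numeric(i),
            length(H) == 1, length(K) == 1, length(q) == 1, length(i) == 1)
  if (!is.finite(H) || H <= 0) stop("H must be a finite positive number")
  if (!is.finite(K) || K <= 0) stop("K must be a finite positive number")
  if (!is.finite(q) || q <= 0 || q >= 1) stop("q must lie in the open interval (0, 1)")
  if (!is.finite(i) || i < 0) stop("i must be a finite nonnegative number")
  structure(list(H = H, K = K, q = q, i = i, label = label),
            class = "component_params")
}

#' @export
print.component_params <- function(x, ...) {
  cat(sprintf("component growth process%s: H = %.4g, K = %.4g, q = %.4g, i = %.4g\n",
              if (is.null(x$label)) "" else paste0(" (", x$label, ")"),
              x$H, x$K, x$q, x$i))
  invisible(x)
}

#' Parameters of a five-component composite growth model
#'
#' The full 20-parameter growth trajectory of one individual: five additive
#' component processes, ordered by nondecreasing initiation age, the first of
#' which initiates at conception (`i = 0`).  Components are conventionally
#' labelled in-utero, infancy, early childhood, mid-childhood and puberty by
#' position; labels are descriptive only.
#'
#' @param components List of exactly 5 [component_params()] objects.
#' @param D Tissue density in g cm^-3 (default 1).
#' @return An object of class `composite_params`.
#' @examples
#' cp <- reference_composite("female")
#' composite_height(cp, c(0.75, 10.75, 26.75))
#' @export
composite_params <- function(components, D = 1) {
  if (!is.list(components) || length(components) != 5 ||
      !all(vapply(components, inherits, logical(1), "component_params")))
    stop("components must be a list of exactly 5 component_params objects")
  if (!is.numeric(D) || length(D) != 1 || !is.finite(D) || D <= 0)
    stop("D must be a finite positive density (g/cm^3)")
  ii <- vapply(components, `[[`, numeric(1), "i")
  # stable ordering by initiation age; ties keep original index order
  ord <- order(ii)
  components <- components[ord]
  ii <- ii[ord]
  if (ii[1] != 0)
    stop("the first component must initiate at conception (i = 0)")
  default_labels <- c("in utero", "infancy", "early childhood",
                      "mid-childhood", "puberty")
  for (x in seq_along(components))
    if (is.null(components[[x]]$label)) components[[x]]$label <- default_labels[x]
  structure(list(components = components, D = D), class = "composite_params")
}

#' @export
print.composite_params <- function(x, ...) {
  cat(sprintf("composite growth model: 5 components, D = %g g/cm^3\n", x$D))
  for (p in x$components) print(p)
  invisible(x)
}

#' Extract the 5 x 4 parameter matrix of a composite model
#'
#' @param cp A [composite_params()] object.
#' @return Numeric matrix with rows = processes 1..5 and columns H, K, q, i.
#' @export
param_matrix <- function(cp) {
  stopifnot(inherits(cp, "composite_params"))
  m <- t(vapply(cp$components,
                function(p) c(H = p$H, K = p$K, q = p$q, i = p$i),
                numeric(4)))
  rownames(m) <- paste0("process_", 1:5)
  m
}

# Closed-form component height kernel, vectorised over all arguments.
# h(t) = [ 2H/(D K) * (1 - exp(Kq/(1+2q) (i - t))) ]^{1/q} for t >= i, else 0.
# The bracket is clamped at >= 0 to absorb floating-point underflow at t ~ i.
.vb_height <- function(H, K, q, i, t, D = 1) {
  rate <- K * q / (1 + 2 * q)
  br <- 1 - exp(rate * (i - t))
  br[br < 0] <- 0
  h <- (2 * H / (D * K) * br)^(1 / q)
  h[t < i] <- 0
  h
}

.check_finite <- function(h, p) {
  if (any(!is.finite(h)))
    stop(sprintf(
      "non-finite trajectory value (overflow in power) for H=%g, K=%g, q=%g, i=%g",
      p$H, p$K, p$q, p$i))
  h
}

#' Component height trajectory (closed form)
#'
#' Height contributed by a single component process at total age `t`:
#' \deqn{h(t) = [\,(2H/(DK))\,(1 - e^{Kq(i-t)/(1+2q)})\,]^{1/q}}
#' for `t >= i`, and 0 before initiation.  Monotone nondecreasing in `t`,
#' bounded above by the asymptote \eqn{(2H/(DK))^{1/q}}.
#'
#' @param p A [component_params()] object.
#' @param t Total age(s) in years since conception (nonnegative).
#' @param D Density (g/cm^3), default 1.
#' @return Height(s) in cm.
#' @export
component_height <- function(p, t, D = 1) {
  stopifnot(inherits(p, "component_params"), is.numeric(t), all(t >= 0))
  .check_finite(.vb_height(p$H, p$K, p$q, p$i, t, D), p)
}

#' Component mass trajectory (closed form)
#'
#' Mass of a single cylindrical component, \eqn{m(t) = D \pi h(t)^{1+2q}},
#' equivalently \eqn{\pi[\ldots]^{1/q + 2}} when D = 1.
#'
#' @inheritParams component_height
#' @return Mass(es) in g.
#' @export
component_mass <- function(p, t, D = 1) {
  h <- component_height(p, t, D)
  .check_finite(D * pi * h^(1 + 2 * p$q), p)
}

#' Composite height trajectory
#'
#' Sum of the five gated component heights: a component contributes exactly 0
#' before its initiation age (Iverson gating).
#'
#' @param cp A [composite_params()] object.
#' @param t Total age(s) in years since conception.
#' @return Height(s) in cm.
#' @export
composite_height <- function(cp, t) {
  stopifnot(inherits(cp, "composite_params"), is.numeric(t), all(t >= 0))
  out <- 0
  for (p in cp$components) out <- out + component_height(p, t, cp$D)
  out
}

#' Composite mass trajectory
#'
#' Sum of the five gated component masses.
#'
#' @inheritParams composite_height
#' @return Mass(es) in g.
#' @export
composite_mass <- function(cp, t) {
  stopifnot(inherits(cp, "composite_params"), is.numeric(t), all(t >= 0))
  out <- 0
  for (p in cp$components) out <- out + component_mass(p, t, cp$D)
  out
}

# per-component longitudinal growth rate at component height h
.vb_velocity <- function(H, K, q, h, D = 1) {
  h^(1 - q) * (2 * H / (D * (1 + 2 * q)) - K / (1 + 2 * q) * h^q)
}

#' Composite height growth velocity
#'
#' Sum over active components of the longitudinal growth rate
#' \deqn{dh/dt = h^{1-q}\left(\frac{2H}{D(1+2q)} - \frac{K}{1+2q} h^{q}\right),}
#' evaluated at each component's current height.  At initiation (`h = 0`) the
#' velocity is the limit value 0 (valid because `1 - q > 0`); it tends to 0
#' again as each component approaches its asymptote.
#'
#' @inheritParams composite_height
#' @return Velocity(ies) in cm/yr (nonnegative).
#' @export
height_velocity <- function(cp, t) {
  stopifnot(inherits(cp, "composite_params"), is.numeric(t), all(t >= 0))
  out <- 0
  for (p in cp$components) {
    h <- component_height(p, t, cp$D)
    out <- out + .vb_velocity(p$H, p$K, p$q, h, cp$D)
  }
  out
}

#' Asymptotic height of a component process
#'
#' The upper bound \eqn{(2H/(DK))^{1/q}} the component height approaches as
#' \eqn{t \to \infty}.
#'
#' @inheritParams component_height
#' @return Asymptotic height in cm.
#' @export
asymptotic_height <- function(p, D = 1) {
  stopifnot(inherits(p, "component_params"))
  a <- (2 * p$H / (D * p$K))^(1 / p$q)
  .check_finite(a, p)
}

#' Body radius implied by height under the allometric power law
#'
#' @param h Height(s) in cm, nonnegative.
#' @param q Allometric exponent in (0, 1).
#' @return Radius(es) in cm, \eqn{r = h^q}.
#' @export
radius_from_height <- function(h, q) {
  stopifnot(is.numeric(h), all(h >= 0), is.numeric(q), all(q > 0), all(q < 1))
  h^q
}

#' Instantaneous growth rates of one component (ODE right-hand sides)
#'
#' Evaluates the height- and mass-form differential equations of a component
#' process at component height `h`, with mass tied to height through
#' \eqn{m = D \pi h^{1+2q}}:
#' \deqn{dm/dt = (2H/D)(D\pi)^{q/(2q+1)} m^{(q+1)/(2q+1)} - K m.}
#' Used by the numerical-integration oracle that cross-checks the closed
#' forms.
#'
#' @param p A [component_params()] object.
#' @param h Component height(s) in cm, nonnegative.
#' @param D Density (g/cm^3).
#' @return List with elements `dhdt` (cm/yr) and `dmdt` (g/yr).
#' @export
ode_growth_rates <- function(p, h, D = 1) {
  stopifnot(inherits(p, "component_params"), is.numeric(h))
  if (any(h < 0)) stop("h must be nonnegative")
  q <- p$q
  dh <- .vb_velocity(p$H, p$K, q, h, D)
  m <- D * pi * h^(1 + 2 * q)
  dm <- (2 * p$H / D) * (D * pi)^(q / (2 * q + 1)) * m^((q + 1) / (2 * q + 1)) -
    p$K * m
  list(dhdt = dh, dmdt = dm)
}
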