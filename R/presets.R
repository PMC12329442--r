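# Reference-like parameter presets.
#
# These are package fixtures: synthetic parameter sets whose composite
# trajectories have the broad shape of growth-reference curves (female adult
# height about 165 cm with a pubertal velocity peak near age 12 since birth;
# male about 176 cm peaking near 13.5).  They seed the synthetic-data
# generator and centre the default priors.  They are not estimates from any
# real population.

.preset_shapes <- list(
  # columns: asymptote A (cm), approach rate lambda (yr^-1), q, i (total yr)
  female = rbind(
    c(50, 4.00, 0.50, 0.00),
    c(32, 0.80, 0.50, 0.50),
    c(38, 0.24, 0.55, 1.25),
    c(26, 0.14, 0.60, 3.00),
    c(21, 0.55, 0.60, 11.75)),
  male = rbind(
    c(52, 4.00, 0.50, 0.00),
    c(34, 0.80, 0.50, 0.50),
    c(40, 0.24, 0.55, 1.25),
    c(28, 0.14, 0.60, 3.00),
    c(24, 0.55, 0.60, 13.50))
)

#' Reference-like composite growth parameters
#'
#' A synthetic five-component parameter set producing a realistic
#' reference-shaped height curve (see the package vignette for the shape
#' targets).  Used as the default centre of the synthetic-data generator and
#' of the estimator's priors.
#'
#' @param sex `"female"` or `"male"`.
#' @return A [composite_params()] object.
#' @examples
#' cp <- reference_composite("female")
#' composite_height(cp, 26.75)  # adult height, cm
#' @export
reference_composite <- function(sex = c("female", "male")) {
  sex <- match.arg(sex)
  s <- .preset_shapes[[sex]]
  labels <- c("in utero", "infancy", "early childhood", "mid-childhood",
              "puberty")
  composite_params(lapply(1:5, function(x)
    component_from_shape(s[x, 1], s[x, 2], s[x, 3], s[x, 4], labels[x])))
}

#' Reference-like transformed population means
#'
#' The [reference_composite()] preset mapped to the transformed scale used by
#' the generator and estimator.
#'
#' @inheritParams reference_composite
#' @return Named numeric vector of length 19.
#' @export
reference_transformed_means <- function(sex = c("female", "male")) {
  natural_to_transformed(reference_composite(match.arg(sex)))
}
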