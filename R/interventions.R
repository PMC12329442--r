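# Counterfactual metabolic-intervention simulation.
#
# An intervention replaces some of a target group's group-level metabolic
# parameters (H's and/or K's, on the transformed scale) with the reference
# group's posterior estimates, holding allometry (q), timing (i), the
# person-level offsets and the measurement SDs fixed, then regenerates all
# downstream trajectories and summaries from the modified draws.

#' Specify a counterfactual metabolic intervention
#'
#' @param target_group Group whose parameters are modified.
#' @param reference_group Group providing the replacement estimates.
#' @param substitutions Which metabolic parameter slots to substitute:
#'   either a character vector of slot names like `c("K2", "H3")`, or a
#'   data frame with columns `family` (`"H"`/`"K"`), `process` (1..5) and
#'   optionally `mode` (`"set_to_reference_mean"`, the default, or
#'   `"scale_by"`) and `factor` (for `scale_by`).  Only H and K are
#'   substitutable; allometry and timing are excluded by construction.
#' @param label Optional label.
#' @return A `cg_intervention` object.
#' @export
intervention_spec <- function(target_group, reference_group, substitutions,
                              label = NULL) {
  if (is.character(substitutions)) {
    m <- regmatches(substitutions, regexec("^([HK])([1-5])$", substitutions))
    if (any(lengths(m) != 3))
      stop("substitution names must look like 'K2' or 'H3' (families H/K, process 1-5)")
    substitutions <- data.frame(
      family = vapply(m, `[`, character(1), 2),
      process = as.integer(vapply(m, `[`, character(1), 3)),
      stringsAsFactors = FALSE)
  }
  subs <- as.data.frame(substitutions)
  if (nrow(subs)) {
    if (!all(c("family", "process") %in% names(subs)))
      stop("substitutions need columns 'family' and 'process'")
    if (!all(subs$family %in% c("H", "K")))
      stop("only metabolic families H and K are substitutable; got: ",
           paste(setdiff(subs$family, c("H", "K")), collapse = ", "))
    if (!all(subs$process %in% 1:5))
      stop("process indices must be in 1..5")
    if (is.null(subs$mode)) subs$mode <- "set_to_reference_mean"
    if (!all(subs$mode %in% c("set_to_reference_mean", "scale_by")))
      stop("mode must be 'set_to_reference_mean' or 'scale_by'")
    if (any(subs$mode == "scale_by") &&
        (is.null(subs$factor) || any(is.na(subs$factor[subs$mode == "scale_by"])) ||
         any(subs$factor[subs$mode == "scale_by"] <= 0)))
      stop("scale_by substitutions need a positive 'factor'")
  }
  structure(list(target_group = target_group,
                 reference_group = reference_group,
                 substitutions = subs, label = label),
            class = "cg_intervention")
}

#' @export
print.cg_intervention <- function(x, ...) {
  cat(sprintf("intervention%s: %s <- %s, %d substitution(s)\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              x$target_group, x$reference_group, nrow(x$substitutions)))
  if (nrow(x$substitutions))
    cat(" ", paste0(x$substitutions$family, x$substitutions$process,
                    collapse = ", "), "\n")
  invisible(x)
}

#' Apply a counterfactual intervention to posterior draws
#'
#' Per draw, the listed target-group metabolic parameters are replaced on
#' the transformed (log) scale: under `"reference_mean"` each substituted
#' group-level value is set to the reference group's posterior mean for that
#' slot; under `"paired_draws"` it is set to the reference group's value in
#' the same draw, propagating reference uncertainty.  Person-level offsets
#' of the target group are retained, so the substitution shifts every target
#' person's implied baseline by the same amount.  q, i, covariances and
#' measurement SDs are untouched.  The input fit is not modified.
#'
#' @param fit A `cg_fit` object.
#' @param spec A [intervention_spec()] object.
#' @param how `"reference_mean"` (default) or `"paired_draws"`.
#' @return A new `cg_fit` with modified group-level (and implied
#'   person-level) draws; the substitutions performed are recorded in
#'   attribute `"intervention"`.
#' @export
apply_intervention <- function(fit, spec,
                               how = c("reference_mean", "paired_draws")) {
  how <- match.arg(how)
  stopifnot(inherits(spec, "cg_intervention"))
  gn <- dimnames(fit$g)[[2]]
  kt <- match(spec$target_group, gn)
  kr <- match(spec$reference_group, gn)
  if (is.na(kt) || is.na(kr))
    stop("unknown group; available groups: ", paste(gn, collapse = ", "))
  out <- fit
  subs <- spec$substitutions
  if (nrow(subs) == 0) return(out)
  target_rows <- if (!is.null(fit$theta) && !is.null(fit$model))
    which(fit$model$obs$person_group == kt) else integer()
  applied <- list()
  for (r in seq_len(nrow(subs))) {
    col <- .family_cols[[subs$family[r]]][subs$process[r]]
    old_level <- out$beta0[, col] + out$g[, kt, col]
    if (subs$mode[r] == "scale_by") {
      delta <- rep(log(subs$factor[r]), nrow(out$beta0))
    } else {
      ref_level <- out$beta0[, col] + out$g[, kr, col]
      new_level <- if (how == "reference_mean") mean(ref_level) else ref_level
      delta <- new_level - old_level
    }
    out$g[, kt, col] <- out$g[, kt, col] + delta
    if (length(target_rows))
      out$theta[, target_rows, col] <- out$theta[, target_rows, col] + delta
    applied[[r]] <- data.frame(
      slot = paste0(subs$family[r], subs$process[r]), mode = subs$mode[r],
      mean_shift = mean(delta))
  }
  attr(out, "intervention") <- list(spec = spec, how = how,
                                    applied = do.call(rbind, applied))
  out
}

#' Preset intervention specifications
#'
#' Two presets mirroring idealized healthcare scenarios:
#' \itemize{
#'   \item `full_metabolic`: all ten metabolic parameters (H and K of all
#'     five processes) set to the reference group's estimates, isolating the
#'     contribution of allometry to remaining group differences;
#'   \item `targeted`: a two-slot infancy / early-childhood intervention —
#'     `K2` and `H3` for females, `K2` and `K3` for males.
#' }
#'
#' @param target_group,reference_group Group names.
#' @param sex `"female"` or `"male"` (selects the targeted preset slots).
#' @return Named list of [intervention_spec()] objects.
#' @export
intervention_presets <- function(target_group, reference_group,
                                 sex = c("female", "male")) {
  sex <- match.arg(sex)
  full <- intervention_spec(
    target_group, reference_group,
    paste0(rep(c("H", "K"), each = 5), rep(1:5, 2)),
    label = "full_metabolic")
  targeted <- intervention_spec(
    target_group, reference_group,
    if (sex == "female") c("K2", "H3") else c("K2", "K3"),
    label = paste0("targeted_", sex))
  list(full_metabolic = full, targeted = targeted)
}
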