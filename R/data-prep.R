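# Reading, validating and preparing anthropometric measurement records.
#
# All internal ages are *total* ages in years since conception; birth sits at
# 0.75 yr on this scale.  Measurement tables are plain CSV with columns
# person_id, group, sex, age, age_basis, height_cm, weight_g, provenance
# (missing values as empty fields).

.record_cols <- c("person_id", "group", "sex", "t", "height_cm", "weight_g",
                  "provenance")

.as_records <- function(df) {
  df <- df[.record_cols]
  df$person_id <- as.character(df$person_id)
  df$group <- as.character(df$group)
  df$sex <- as.character(df$sex)
  rownames(df) <- NULL
  class(df) <- c("cg_records", "data.frame")
  df
}

#' Load anthropometric measurements from a delimited text file
#'
#' Reads a CSV of measurement records, validates each row, converts ages to
#' the total-age-since-conception scale and weights to grams.  Rows failing
#' validation (nonpositive or missing measurements on both modalities,
#' unparseable or negative ages) are dropped; an itemized report with file
#' line numbers is attached as attribute `"load_report"` and surfaced as a
#' warning.
#'
#' @param path Path to a CSV file with header columns `person_id`, `group`,
#'   `sex`, `age` and at least one of `height_cm`, `weight_g` (or
#'   `weight_kg` with `weight_unit = "kg"`).  An optional `age_basis` column
#'   (`"birth"` or `"conception"`) overrides the `age_basis` argument per
#'   row; an optional `provenance` column is preserved.
#' @param age_basis Default interpretation of the `age` column: `"birth"`
#'   (age since birth; converted by `t = age + gestation`) or
#'   `"conception"` (already total age).
#' @param weight_unit Unit of the weight column: `"g"` (column `weight_g`)
#'   or `"kg"` (column `weight_kg`, converted to grams).
#' @param gestation Gestation length in years used for the birth-to-total
#'   age conversion (default 0.75, i.e. nine months).
#' @return A `cg_records` data frame with columns `person_id`, `group`,
#'   `sex`, `t`, `height_cm`, `weight_g`, `provenance`.
#' @export
load_measurements <- function(path, age_basis = c("birth", "conception"),
                              weight_unit = c("g", "kg"),
                              gestation = GESTATION_YR) {
  age_basis <- match.arg(age_basis)
  weight_unit <- match.arg(weight_unit)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("empty measurement file: ", path)
    out <- .as_records(data.frame(person_id = character(), group = character(),
                                  sex = character(), t = numeric(),
                                  height_cm = numeric(), weight_g = numeric(),
                                  provenance = character()))
    attr(out, "load_report") <- character()
    return(out)
  }
  wcol <- if (weight_unit == "kg") "weight_kg" else "weight_g"
  need <- c("person_id", "group", "sex", "age")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  if (!any(c("height_cm", wcol) %in% names(df)))
    stop("need at least one measurement column: height_cm or ", wcol)
  h <- if ("height_cm" %in% names(df)) suppressWarnings(as.numeric(df$height_cm)) else rep(NA_real_, nrow(df))
  w <- if (wcol %in% names(df)) suppressWarnings(as.numeric(df[[wcol]])) else rep(NA_real_, nrow(df))
  if (weight_unit == "kg") w <- w * 1000
  age <- suppressWarnings(as.numeric(df$age))
  basis <- if ("age_basis" %in% names(df)) {
    b <- as.character(df$age_basis)
    b[is.na(b) | b == ""] <- age_basis
    b
  } else rep(age_basis, nrow(df))
  t_total <- ifelse(basis == "birth", age + gestation, age)

  report <- character()
  bad <- function(rows, why) {
    if (any(rows))
      # +1 for the header line
      report <<- c(report, sprintf("line %d: %s", which(rows) + 1L, why))
    rows
  }
  drop <- bad(is.na(age) | !is.finite(t_total), "unparseable age")
  drop <- drop | bad(!is.na(age) & t_total < 0, "negative total age")
  drop <- drop | bad(!is.na(h) & h <= 0, "nonpositive height")
  drop <- drop | bad(!is.na(w) & w <= 0, "nonpositive weight")
  drop <- drop | bad(is.na(h) & is.na(w), "no height or weight measurement")
  if (length(report))
    warning("dropped ", sum(drop), " invalid record(s):\n  ",
            paste(report, collapse = "\n  "))
  prov <- if ("provenance" %in% names(df)) {
    p <- as.character(df$provenance); p[is.na(p) | p == ""] <- "observed"; p
  } else rep("observed", nrow(df))
  out <- data.frame(person_id = df$person_id, group = df$group, sex = df$sex,
                    t = t_total, height_cm = h, weight_g = w,
                    provenance = prov, stringsAsFactors = FALSE)[!drop, ]
  out <- .as_records(out)
  attr(out, "load_report") <- report
  out
}

#' Write measurement records to CSV
#'
#' Writes the package's standard measurement dialect (ages on the
#' total-age-since-conception scale, weights in grams, empty fields for
#' missing values); the result round-trips through [load_measurements()].
#'
#' @param records A `cg_records` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  df <- as.data.frame(records)
  out <- data.frame(person_id = df$person_id, group = df$group, sex = df$sex,
                    age = df$t, age_basis = "conception",
                    height_cm = df$height_cm, weight_g = df$weight_g,
                    provenance = df$provenance)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Prepare a measurement dataset for model fitting
#'
#' Applies the data conventions the estimator expects:
#' \itemize{
#'   \item \strong{Conception anchoring}: each person receives a
#'     pseudo-observation at total age 0 fixing height at 0.012 cm and weight
#'     at 1.02e-6 g (egg-cell size), tagged `conception_anchor`.  A modality
#'     the person was never measured on is left missing in the anchor.
#'   \item \strong{Carry-forward densification}: each person's last observed
#'     height and weight are duplicated at integer ages since birth up to
#'     `carry_forward_to`, tagged `carried_forward`.
#' }
#' Observed records are never modified, and the function is idempotent:
#' preparing an already-prepared dataset adds nothing.
#'
#' @param records A `cg_records` data frame (see [load_measurements()]).
#' @param add_conception Insert conception anchors? (default TRUE)
#' @param carry_forward_to Age since birth (years) up to which last
#'   measurements are carried forward yearly, or `NULL` to disable.
#'   Persons already measured beyond this age are skipped.
#' @param gestation Gestation length (yr) separating the birth and
#'   conception age scales.
#' @return A `cg_prepared` object: list with elements `records` (the
#'   augmented `cg_records`), `person_index` and `group_index` (named
#'   contiguous integer codings) and `options`.
#' @export
prepare_dataset <- function(records, add_conception = TRUE,
                            carry_forward_to = 26,
                            gestation = GESTATION_YR) {
  stopifnot(inherits(records, "cg_records") || is.data.frame(records))
  df <- as.data.frame(records)
  if (nrow(df) == 0) stop("cannot prepare an empty dataset")
  obs <- df[df$provenance == "observed", , drop = FALSE]
  extra <- list()

  if (!is.null(carry_forward_to)) {
    for (pid in unique(obs$person_id)) {
      prs <- obs[obs$person_id == pid, , drop = FALSE]
      if (any(df$person_id == pid & df$provenance == "carried_forward")) next
      last_t <- max(prs$t)
      last_birth_age <- last_t - gestation
      from <- floor(last_birth_age) + 1
      if (from > carry_forward_to) {
        message("carry-forward skipped for person ", pid,
                ": already measured beyond age ", carry_forward_to)
        next
      }
      ages <- seq(from, carry_forward_to)
      hh <- prs$height_cm[!is.na(prs$height_cm)]
      ww <- prs$weight_g[!is.na(prs$weight_g)]
      last_h <- if (length(hh)) hh[which.max(prs$t[!is.na(prs$height_cm)])] else NA_real_
      last_w <- if (length(ww)) ww[which.max(prs$t[!is.na(prs$weight_g)])] else NA_real_
      extra[[length(extra) + 1]] <- data.frame(
        person_id = pid, group = prs$group[1], sex = prs$sex[1],
        t = ages + gestation, height_cm = last_h, weight_g = last_w,
        provenance = "carried_forward", stringsAsFactors = FALSE)
    }
  }

  if (add_conception) {
    for (pid in unique(df$person_id)) {
      if (any(df$person_id == pid & df$provenance == "conception_anchor")) next
      prs <- df[df$person_id == pid, , drop = FALSE]
      extra[[length(extra) + 1]] <- data.frame(
        person_id = pid, group = prs$group[1], sex = prs$sex[1], t = 0,
        height_cm = if (any(!is.na(prs$height_cm))) EGG_HEIGHT_CM else NA_real_,
        weight_g = if (any(!is.na(prs$weight_g))) EGG_WEIGHT_G else NA_real_,
        provenance = "conception_anchor", stringsAsFactors = FALSE)
    }
  }

  all_rec <- rbind(df, do.call(rbind, extra))
  # person and group codings follow first appearance in the input, so the
  # first group of the input is the model's reference group
  persons <- unique(df$person_id)
  groups <- unique(df$group)
  all_rec <- all_rec[order(match(all_rec$person_id, persons), all_rec$t), ,
                     drop = FALSE]
  structure(list(
    records = .as_records(all_rec),
    person_index = stats::setNames(seq_along(persons), persons),
    group_index = stats::setNames(seq_along(groups), groups),
    options = list(add_conception = add_conception,
                   carry_forward_to = carry_forward_to,
                   gestation = gestation)),
    class = "cg_prepared")
}

#' @export
print.cg_prepared <- function(x, ...) {
  tab <- table(x$records$provenance)
  cat(sprintf("prepared growth dataset: %d records, %d persons, %d group(s)\n",
              nrow(x$records), length(x$person_index), length(x$group_index)))
  cat("  provenance:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
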