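#' @title Lifespan cohorts
#' @name cohort
#' @description
#' A cohort is a validated table of per-animal lifespan records from a
#' longevity experiment: one row per animal, with the age at death (or
#' censoring) in days, the factor labels of the 2 x 2 x 2 design
#' (genotype, treatment, sex) and an event flag. Every downstream
#' estimator in the package assumes the contract enforced here:
#' positive ages, known factor labels, unique animal ids.
NULL

# Factor levels of the study design; unknown labels are rejected.
GENOTYPES  <- c("dwarf", "control")
TREATMENTS <- c("GH", "saline")
SEXES      <- c("male", "female")

LIFESPAN_COLUMNS <- c("animal_id", "age_days", "genotype", "treatment",
                      "sex", "event")

stop_schema <- function(msg) {
  stop(errorCondition(msg, class = c("lifespanr_schema_error",
                                     "lifespanr_error")))
}

stop_validation <- function(msg) {
  stop(errorCondition(msg, class = c("lifespanr_validation_error",
                                     "lifespanr_error")))
}

# Total validation of a record frame: either every rule passes or a typed
# error is raised; no partially-valid cohort is ever returned.
check_cohort_frame <- function(df) {
  if (!is.data.frame(df)) stop_schema("cohort records must be a data frame")
  missing_cols <- setdiff(setdiff(LIFESPAN_COLUMNS, "event"), names(df))
  if (length(missing_cols) > 0L) {
    stop_schema(sprintf("missing required column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0L) stop_validation("cohort must contain at least one record")

  age <- df$age_days
  if (!is.numeric(age)) stop_validation("age_days must be numeric")
  bad <- which(!is.finite(age) | age <= 0)
  if (length(bad) > 0L) {
    stop_validation(sprintf("non-positive or non-finite age_days in row %s",
                            paste(bad, collapse = ", ")))
  }
  check_enum <- function(x, levels, what) {
    bad <- which(!(as.character(x) %in% levels))
    if (length(bad) > 0L) {
      stop_validation(sprintf(
        "unknown %s label '%s' in row %s (expected one of: %s)",
        what, as.character(x)[bad[1L]], bad[1L],
        paste(levels, collapse = ", ")))
    }
  }
  check_enum(df$genotype,  GENOTYPES,  "genotype")
  check_enum(df$treatment, TREATMENTS, "treatment")
  check_enum(df$sex,       SEXES,      "sex")

  ev <- df$event
  if (!is.logical(ev)) {
    if (is.numeric(ev) && all(ev %in% c(0, 1))) ev <- as.logical(ev)
    else stop_validation("event must be logical (or 0/1)")
  }
  if (anyNA(ev)) stop_validation("event contains missing values")

  id <- as.character(df$animal_id)
  if (anyNA(id) || any(!nzchar(id))) {
    stop_validation("animal_id must be non-missing and non-empty")
  }
  dup <- duplicated(id)
  if (any(dup)) {
    stop_validation(sprintf("duplicate animal_id: %s",
                            paste(unique(id[dup]), collapse = ", ")))
  }

  data.frame(animal_id = id,
             age_days  = as.numeric(age),
             genotype  = as.character(df$genotype),
             treatment = as.character(df$treatment),
             sex       = as.character(df$sex),
             event     = ev,
             stringsAsFactors = FALSE)
}

#' Construct a lifespan cohort
#'
#' Builds a validated cohort from per-animal fields. `genotype` must be one
#' of `"dwarf"`/`"control"`, `treatment` one of `"GH"`/`"saline"`, `sex` one
#' of `"male"`/`"female"`. `event = TRUE` marks an observed death (the
#' default; fully uncensored data are the common case in lifespan studies
#' where every animal is followed to death).
#'
#' @param animal_id character vector of unique animal identifiers.
#' @param age_days positive ages at death (or censoring), in days.
#' @param genotype,treatment,sex design factor labels, recycled if scalar.
#' @param event logical death indicator, default `TRUE` for all animals.
#' @param protocol_label free-text label for the treatment protocol
#'   (e.g. `"week1"`).
#' @return An object of class `cohort`: a data frame with one row per
#'   animal and a `protocol_label` attribute.
#' @examples
#' co <- cohort(animal_id = paste0("m", 1:4),
#'              age_days  = c(810, 950, 1004, 620),
#'              genotype  = "dwarf", treatment = "saline",
#'              sex = c("male", "male", "female", "female"))
#' validate_cohort(co)
#' @export
cohort <- function(animal_id, age_days, genotype, treatment, sex,
                   event = TRUE, protocol_label = "") {
  n <- length(age_days)
  df <- data.frame(animal_id = animal_id,
                   age_days  = age_days,
                   genotype  = rep_len(genotype, n),
                   treatment = rep_len(treatment, n),
                   sex       = rep_len(sex, n),
                   event     = rep_len(event, n),
                   stringsAsFactors = FALSE)
  as_cohort(df, protocol_label = protocol_label)
}

#' Coerce a data frame to a validated cohort
#'
#' @param df data frame with columns `animal_id`, `age_days`, `genotype`,
#'   `treatment`, `sex` and optionally `event` (assumed `TRUE` when absent).
#' @param protocol_label free-text protocol label attached to the cohort.
#' @return A `cohort` object.
#' @export
as_cohort <- function(df, protocol_label = "") {
  if (is.data.frame(df) && !("event" %in% names(df)))
    df$event <- rep(TRUE, nrow(df))
  out <- check_cohort_frame(df)
  attr(out, "protocol_label") <- as.character(protocol_label)[1L]
  class(out) <- c("cohort", "data.frame")
  out
}

#' @export
print.cohort <- function(x, ...) {
  lab <- attr(x, "protocol_label")
  cat(sprintf("Lifespan cohort: %d animals%s\n", nrow(x),
              if (nzchar(lab)) paste0(" (protocol: ", lab, ")") else ""))
  cat(sprintf("  deaths observed: %d, censored: %d\n",
              sum(x$event), sum(!x$event)))
  print.data.frame(utils::head(as.data.frame(x), 6L), row.names = FALSE)
  if (nrow(x) > 6L) cat(sprintf("  ... and %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Read a lifespan table from CSV
#'
#' Reads a comma-separated, UTF-8, headered lifespan table and returns a
#' validated [cohort]. Required columns are `animal_id`, `age_days`,
#' `genotype`, `treatment` and `sex`; `event` is optional and defaults to
#' `TRUE` (uncensored). Row order is preserved. Malformed input raises a
#' typed condition (`lifespanr_schema_error` for a missing column,
#' `lifespanr_validation_error` for a bad value, citing the row).
#'
#' @param path path to a CSV file.
#' @param protocol_label protocol label attached to the returned cohort.
#' @return A `cohort` object.
#' @seealso [write_lifespan_table()] for the exact inverse.
#' @export
read_lifespan_table <- function(path, protocol_label = "") {
  if (!file.exists(path)) stop_schema(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  as_cohort(df, protocol_label = protocol_label)
}

#' Write a lifespan table to CSV
#'
#' Writes a cohort to the on-disk CSV contract used by
#' [read_lifespan_table()]. Ages are formatted with 17 significant digits so
#' that a write/read round trip reproduces the cohort exactly, including
#' sub-day simulated lifespans.
#'
#' @param cohort a [cohort] object.
#' @param path target file path; the parent directory must be writable.
#' @return Invisibly, `path`.
#' @export
write_lifespan_table <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  out <- as.data.frame(cohort)
  out$age_days <- vapply(out$age_days, function(a) sprintf("%.17g", a), "")
  ok <- tryCatch({
    suppressWarnings(
      utils::write.csv(out, file = path, row.names = FALSE, quote = FALSE,
                       fileEncoding = "UTF-8"))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop(errorCondition(sprintf("cannot write lifespan table to '%s': %s",
                                path, conditionMessage(ok)),
                        class = c("lifespanr_io_error", "lifespanr_error")))
  }
  invisible(path)
}

#' Summarise a cohort by design cell
#'
#' Re-validates the cohort and returns the animal count in every
#' (genotype, treatment, sex) cell of the factorial design, including
#' empty cells. Duplicate animal ids or any other contract violation raise
#' a typed error.
#'
#' @param cohort a [cohort] object (or a data frame coercible to one).
#' @return A data frame of class `cohort_summary` with columns `genotype`,
#'   `treatment`, `sex` and `n`.
#' @export
validate_cohort <- function(cohort) {
  if (!inherits(cohort, "cohort")) cohort <- as_cohort(cohort)
  df <- check_cohort_frame(cohort)
  counts <- as.data.frame(table(
    genotype  = factor(df$genotype,  levels = GENOTYPES),
    treatment = factor(df$treatment, levels = TREATMENTS),
    sex       = factor(df$sex,       levels = SEXES)),
    responseName = "n", stringsAsFactors = FALSE)
  counts$n <- as.integer(counts$n)
  class(counts) <- c("cohort_summary", "data.frame")
  attr(counts, "n_total") <- nrow(df)
  counts
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort design summary (%d animals):\n", attr(x, "n_total")))
  print.data.frame(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
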