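#' Derive early-life deprivation from the parental indicators
#'
#' Deprivation is the conjunction of short maternal education (left school
#' at 15) and a manual social class of the other parent at the cohort
#' member's birth; every other combination is non-deprived. A missing
#' conjunct only leaves the result undetermined when the other conjunct is
#' 1: one observed 0 settles the conjunction at 0.
#'
#' @param mother_short_education 0/1 (or `NA`) vector.
#' @param parent_manual_class 0/1 (or `NA`) vector.
#' @return Integer 0/1 vector with `NA` where undeterminable.
#' @export
#' @examples
#' derive_deprivation(c(1, 1, 0, NA), c(1, 0, NA, 1))
derive_deprivation <- function(mother_short_education, parent_manual_class) {
  check_binary <- function(x, nm) {
    if (!all(x %in% c(0, 1) | is.na(x))) {
      stop("derive_deprivation: ", nm, " must be 0, 1 or NA", call. = FALSE)
    }
  }
  check_binary(mother_short_education, "mother_short_education")
  check_binary(parent_manual_class, "parent_manual_class")
  out <- ifelse(
    !is.na(mother_short_education) & mother_short_education == 0, 0L,
    ifelse(!is.na(parent_manual_class) & parent_manual_class == 0, 0L,
           ifelse(is.na(mother_short_education) | is.na(parent_manual_class),
                  NA_integer_, 1L)))
  as.integer(out)
}

#' Log-transform the right-skewed biomarkers
#'
#' Adds natural-log columns (`log_triglycerides`, `log_crp`,
#' `log_cortisol`) for the three markers whose distributions are too
#' asymmetric for a linear model on the native scale; all other biomarkers
#' are left untouched. Re-applying the transform is rejected, guarding
#' against double logging.
#'
#' @param table Cohort table.
#' @return The table with the log columns appended.
#' @export
transform_outcomes <- function(table) {
  breg <- biomarker_registry()
  targets <- breg$name[breg$log_transform]
  already <- intersect(paste0("log_", targets), names(table))
  if (length(already) > 0) {
    stop("transform_outcomes: log columns already present (",
         paste(already, collapse = ", "), "); refusing to log twice",
         call. = FALSE)
  }
  for (nm in intersect(targets, names(table))) {
    x <- table[[nm]]
    bad <- which(!is.na(x) & x <= 0)
    if (length(bad) > 0) {
      ids <- if ("id" %in% names(table)) table$id[bad] else bad
      stop("transform_outcomes: non-positive ", nm, " at row(s) ",
           paste(utils::head(ids, 5), collapse = ", "),
           "; log transform undefined", call. = FALSE)
    }
    table[[paste0("log_", nm)]] <- log(x)
  }
  table
}

#' Z-standardize a value against given moments
#'
#' `z = (y - mu) / sigma`. In the pipeline `mu` and `sigma` are always the
#' mean and SD of the outcome in the current (imputed, bootstrapped)
#' dataset, so a column standardized against its own moments has mean 0 and
#' SD 1 and every effect reads in SD units.
#'
#' @param y Numeric vector.
#' @param mu Centre.
#' @param sigma Scale, `> 0`.
#' @return `(y - mu) / sigma`.
#' @export
standardize_outcome <- function(y, mu, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || is.na(sigma) || sigma <= 0) {
    stop("standardize_outcome: sigma must be a single positive number",
         call. = FALSE)
  }
  (y - mu) / sigma
}

#' Restrict the mediator block to a variable set
#'
#' Returns a view of the cohort table keeping the identifier, exposure and
#' outcome columns and only the mediators in `varset`.
#'
#' @param table Cohort table.
#' @param varset A [variable_set()].
#' @return The restricted tibble.
#' @export
select_variable_set <- function(table, varset) {
  stopifnot(inherits(varset, "variable_set"))
  absent <- setdiff(varset$mediators, names(table))
  if (length(absent) > 0) {
    stop("select_variable_set: mediator column(s) not in table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  keep <- c(intersect(c("id", "sex", "mother_short_education",
                        "parent_manual_class", "deprived"), names(table)),
            varset$mediators,
            intersect(c(biomarker_registry()$name,
                        paste0("log_", biomarker_registry()$name),
                        "gender_score"), names(table)))
  table[, keep]
}

#' Data dictionary for the cohort CSV layout
#'
#' @return A tibble with columns `column`, `role`
#'   (`id`/`sex`/`environment`/`mediator`/`biomarker`), `type` and
#'   `allowed`.
#' @export
cohort_dictionary <- function() {
  reg <- mediator_registry()
  breg <- biomarker_registry()
  tibble::tibble(
    column = c("id", "sex", "mother_short_education", "parent_manual_class",
               "deprived", reg$name, breg$name),
    role = c("id", "sex", "environment", "environment", "environment",
             rep("mediator", nrow(reg)), rep("biomarker", nrow(breg))),
    type = c("integer", rep("binary", 4 + nrow(reg)),
             rep("numeric", nrow(breg))),
    allowed = c(NA, rep("0,1", 4 + nrow(reg)), rep(NA, nrow(breg)))
  )
}

#' Read a cohort CSV with strict dictionary validation
#'
#' @param path CSV file path.
#' @param dictionary Data dictionary, by default [cohort_dictionary()].
#' @return A validated cohort tibble.
#' @export
read_cohort_csv <- function(path, dictionary = cohort_dictionary()) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  absent <- setdiff(dictionary$column, names(tab))
  if (length(absent) > 0) {
    stop("read_cohort_csv: missing column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  for (i in seq_len(nrow(dictionary))) {
    col <- dictionary$column[i]
    x <- tab[[col]]
    if (identical(dictionary$type[i], "binary")) {
      bad <- which(!(x %in% c(0, 1) | is.na(x)))
      if (length(bad) > 0) {
        stop("read_cohort_csv: column '", col, "' not binary at data line(s) ",
             paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
      }
    } else if (!is.numeric(x)) {
      bad <- which(!is.na(x) & is.na(suppressWarnings(as.numeric(x))))
      if (length(bad) > 0) {
        stop("read_cohort_csv: column '", col,
             "' not numeric at data line(s) ",
             paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
      }
      tab[[col]] <- as.numeric(x)
    }
  }
  tab
}

#' Write a cohort CSV
#'
#' @param table Cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}
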