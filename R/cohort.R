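#' Longitudinal cohort container
#'
#' A `longitudinal_cohort` holds a complete participant x variable x visit
#' grid for the data-collection window, the visit schedule, a one-row-per-id
#' table of fixed covariates, and (for simulated cohorts) the latent truth.
#' The canonical tabular view is tidy long format
#' (`participant_id`, `variable`, `visit_year`, `value`); per-variable
#' id-by-visit matrices are kept alongside for fast featurization.
#'
#' @param long Tidy long tibble/data.frame with columns `participant_id`,
#'   `variable`, `visit_year`, `value`.
#' @param fixed Optional tibble with `participant_id` and numeric fixed
#'   covariates, one row per id.
#' @param visit_years Optional schedule; defaults to the sorted unique
#'   `visit_year` values present.
#' @param truth Optional latent-truth tibble (simulator use).
#'
#' @return A `longitudinal_cohort` object.
#' @export
as_longitudinal_cohort <- function(long, fixed = NULL, visit_years = NULL,
                                   truth = NULL) {
  need <- c("participant_id", "variable", "visit_year", "value")
  if (!all(need %in% names(long))) {
    stop("long data must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  long <- tibble::as_tibble(long)
  if (is.null(visit_years)) visit_years <- sort(unique(long$visit_year))
  ids <- unique(long$participant_id)
  vars <- unique(long$variable)
  grids <- lapply(vars, function(v) {
    sub <- long[long$variable == v, ]
    m <- matrix(NA_real_, length(ids), length(visit_years),
                dimnames = list(ids, visit_years))
    m[cbind(match(sub$participant_id, ids),
            match(sub$visit_year, visit_years))] <- sub$value
    m
  })
  names(grids) <- vars
  if (!is.null(fixed)) {
    fixed <- tibble::as_tibble(fixed)
    if (anyDuplicated(fixed$participant_id)) {
      stop("fixed must have one row per participant", call. = FALSE)
    }
    fixed <- fixed[match(ids, fixed$participant_id), ]
  }
  structure(list(ids = ids, visit_years = as.numeric(visit_years),
                 grids = grids, fixed = fixed, truth = truth),
            class = "longitudinal_cohort")
}

new_cohort_from_grids <- function(grids, visit_years, fixed = NULL,
                                  truth = NULL) {
  ids <- if (length(grids)) rownames(grids[[1]]) else character(0)
  structure(list(ids = ids, visit_years = as.numeric(visit_years),
                 grids = grids, fixed = fixed, truth = truth),
            class = "longitudinal_cohort")
}

#' @export
print.longitudinal_cohort <- function(x, ...) {
  cat("<longitudinal_cohort> ", length(x$ids), " participants, ",
      length(x$grids), " longitudinal variables, ",
      length(x$visit_years), " visits (",
      paste(x$visit_years, collapse = ", "), ")\n", sep = "")
  if (!is.null(x$fixed)) {
    cat("  fixed covariates: ",
        paste(setdiff(names(x$fixed), "participant_id"), collapse = ", "),
        "\n", sep = "")
  }
  if (!is.null(x$truth)) cat("  latent truth attached\n")
  invisible(x)
}

#' Tidy long view of a cohort
#'
#' @param x A `longitudinal_cohort`.
#' @param ... Unused.
#' @return Tibble with `participant_id`, `variable`, `visit_year`, `value`,
#'   ordered by variable then participant then visit.
#' @method as_tibble longitudinal_cohort
#' @export
as_tibble.longitudinal_cohort <- function(x, ...) {
  purrr::map_dfr(names(x$grids), function(v) {
    m <- x$grids[[v]]
    tibble::tibble(
      participant_id = rep(x$ids, times = length(x$visit_years)),
      variable = v,
      visit_year = rep(x$visit_years, each = length(x$ids)),
      value = as.vector(m)
    )
  }) |>
    dplyr::arrange(.data$variable, .data$participant_id, .data$visit_year)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Write / read a cohort as tidy CSV files
#'
#' `write_cohort()` writes `<stem>_long.csv` (participant_id, variable,
#' visit_year, value), `<stem>_fixed.csv`, and a small `<stem>_meta.json`
#' carrying the visit schedule. `read_cohort()` reverses it.
#'
#' @param cohort A `longitudinal_cohort`.
#' @param stem File path stem (directory must exist).
#' @return `write_cohort()` the stem, invisibly; `read_cohort()` a cohort.
#' @export
write_cohort <- function(cohort, stem) {
  utils::write.csv(as_tibble(cohort), paste0(stem, "_long.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$fixed)) {
    utils::write.csv(cohort$fixed, paste0(stem, "_fixed.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(list(visit_years = cohort$visit_years),
                       paste0(stem, "_meta.json"), auto_unbox = FALSE)
  invisible(stem)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(stem) {
  long <- utils::read.csv(paste0(stem, "_long.csv"),
                          colClasses = c(participant_id = "character"))
  fixed_path <- paste0(stem, "_fixed.csv")
  fixed <- if (file.exists(fixed_path)) {
    tibble::as_tibble(utils::read.csv(
      fixed_path, colClasses = c(participant_id = "character")))
  }
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"),
                              simplifyVector = TRUE)
  as_longitudinal_cohort(long, fixed = fixed,
                         visit_years = meta$visit_years)
}

#' Write / read a survival outcome table
#'
#' @param outcome Tibble with `participant_id`, `time_years`, `event`.
#' @param path CSV path.
#' @export
write_outcome <- function(outcome, path) {
  utils::write.csv(outcome, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_outcome
#' @export
read_outcome <- function(path) {
  tibble::as_tibble(utils::read.csv(
    path, colClasses = c(participant_id = "character")))
}
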