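#' Construct a feature table with column provenance
#'
#' A feature table is a tibble whose first column is `participant_id` and
#' whose remaining columns are numeric model inputs. Each column carries
#' provenance — the source variable, the statistic (or visit) it was derived
#' from, and the visit year where applicable — in the `"provenance"`
#' attribute, a tibble with columns `column`, `source_variable`,
#' `statistic`, `visit_year`.
#'
#' @param data Tibble with `participant_id` plus numeric columns.
#' @param provenance Provenance tibble; defaults to self-named columns.
#' @return A `feature_table` tibble.
#' @export
feature_table <- function(data, provenance = NULL) {
  data <- tibble::as_tibble(data)
  stopifnot("participant_id" %in% names(data))
  cols <- setdiff(names(data), "participant_id")
  if (is.null(provenance)) {
    provenance <- tibble::tibble(column = cols, source_variable = cols,
                                 statistic = "raw",
                                 visit_year = NA_real_)
  }
  stopifnot(identical(provenance$column, cols))
  structure(data, provenance = provenance,
            class = c("feature_table", class(data)))
}

#' @export
#' @rdname feature_table
#' @param x A `feature_table`.
provenance <- function(x) attr(x, "provenance")

ft_matrix <- function(x) {
  m <- as.matrix(x[setdiff(names(x), "participant_id")])
  rownames(m) <- x$participant_id
  storage.mode(m) <- "double"
  m
}

ft_select <- function(x, cols) {
  pv <- provenance(x)
  feature_table(x[c("participant_id", cols)],
                pv[match(cols, pv$column), ])
}

ft_rows <- function(x, ids) {
  idx <- match(ids, x$participant_id)
  if (anyNA(idx)) stop("unknown participant ids", call. = FALSE)
  feature_table(x[idx, ], provenance(x))
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x), " participants x ",
      ncol(x) - 1, " features\n", sep = "")
  NextMethod()
}

# append fixed covariates as pass-through columns with "fixed" provenance
append_fixed <- function(ft, cohort) {
  if (is.null(cohort$fixed)) return(ft)
  fx <- cohort$fixed[match(ft$participant_id, cohort$fixed$participant_id), ]
  fvars <- setdiff(names(fx), "participant_id")
  dat <- dplyr::bind_cols(ft[setdiff(names(ft), fvars)], fx[fvars])
  pv <- dplyr::bind_rows(
    provenance(ft),
    tibble::tibble(column = fvars, source_variable = fvars,
                   statistic = "fixed", visit_year = NA_real_))
  feature_table(dat, pv)
}
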