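#' Experimental condition keys
#'
#' Every column of a fold-change matrix is identified by a
#' (compartment, treatment, timepoint) triple rendered as a label of the form
#' `"proteome_LPS_6h"`. The triple-label SILAC design fixes the admissible
#' timepoints: the proteome time course runs 0/6/12 h and the secretome
#' 0/6/24 h (0 h is the reference channel and never appears as a column).
#'
#' @param compartment `"proteome"` or `"secretome"`.
#' @param treatment One of `"LPS"`, `"P3C"`, `"R848"`, `"basal"`.
#' @param hours Timepoint in hours: 6 or 12 for the proteome, 6 or 24 for the
#'   secretome.
#' @return A character label, vectorized over its arguments.
#' @examples
#' condition_key("proteome", "LPS", 6)
#' @export
condition_key <- function(compartment, treatment, hours) {
  n <- max(length(compartment), length(treatment), length(hours))
  compartment <- rep_len(as.character(compartment), n)
  treatment <- rep_len(as.character(treatment), n)
  hours <- rep_len(as.numeric(hours), n)
  for (i in seq_len(n)) {
    validate_condition(compartment[i], treatment[i], hours[i])
  }
  sprintf("%s_%s_%gh", compartment, treatment, hours)
}

COMPARTMENTS <- c("proteome", "secretome")
TREATMENTS <- c("LPS", "P3C", "R848", "basal")
STIM_TREATMENTS <- c("LPS", "P3C", "R848")

validate_condition <- function(compartment, treatment, hours) {
  if (!compartment %in% COMPARTMENTS) {
    stop("unknown compartment: '", compartment, "'", call. = FALSE)
  }
  if (!treatment %in% TREATMENTS) {
    stop("unknown treatment: '", treatment, "'", call. = FALSE)
  }
  allowed <- if (compartment == "proteome") c(6, 12) else c(6, 24)
  if (!hours %in% allowed) {
    stop(sprintf(
      "timepoint %g h is not valid for the %s (allowed: %s)",
      hours, compartment, paste(allowed, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' Parse condition labels back into their components
#'
#' @param labels Character vector of labels produced by [condition_key()].
#' @return A data frame with columns `label`, `compartment`, `treatment`,
#'   `hours`.
#' @export
parse_condition <- function(labels) {
  m <- regmatches(labels, regexec("^([a-z]+)_([A-Za-z0-9]+)_([0-9]+)h$", labels))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    stop("unparseable condition label: '", labels[bad][1], "'", call. = FALSE)
  }
  out <- data.frame(
    label = labels,
    compartment = vapply(m, `[`, character(1), 2L),
    treatment = vapply(m, `[`, character(1), 3L),
    hours = as.numeric(vapply(m, `[`, character(1), 4L)),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(out))) {
    validate_condition(out$compartment[i], out$treatment[i], out$hours[i])
  }
  out
}

#' Timepoint hours for a compartment
#'
#' The medium/light channel ratio is the early (6 h) fold change in both
#' compartments; the heavy/light ratio is the late fold change, 12 h for the
#' proteome and 24 h for the secretome.
#'
#' @param compartment `"proteome"` or `"secretome"`.
#' @return Named numeric vector `c(early = 6, late = 12 or 24)`.
#' @export
compartment_hours <- function(compartment) {
  compartment <- match.arg(compartment, COMPARTMENTS)
  c(early = 6, late = if (compartment == "proteome") 12 else 24)
}

#' Combine fold-change matrices over a shared protein universe
#'
#' Outer-joins the row sets (union of protein ids, sorted) and binds the
#' columns; cells absent from a contributing matrix become `NA`.
#'
#' @param matrices List of fold-change matrices with unique column labels.
#' @return A single matrix with the union of rows and all columns.
#' @export
combine_fold_changes <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1)
  all_cols <- unlist(lapply(matrices, colnames))
  if (anyDuplicated(all_cols)) {
    stop("duplicate condition labels across matrices: ",
         paste(unique(all_cols[duplicated(all_cols)]), collapse = ", "),
         call. = FALSE)
  }
  ids <- sort(unique(unlist(lapply(matrices, rownames))))
  out <- matrix(NA_real_, nrow = length(ids), ncol = length(all_cols),
                dimnames = list(ids, all_cols))
  for (m in matrices) {
    out[rownames(m), colnames(m)] <- m
  }
  out
}
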