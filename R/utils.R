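#' @importFrom rlang abort warn %||% .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n row_number desc across all_of
#' @importFrom tibble tibble as_tibble
NULL

# Canonical centromere-type order: most symmetric to most asymmetric.
TYPE_CLASSES <- c("M", "m", "sm", "st", "t", "T")

type_factor <- function(x) factor(x, levels = TYPE_CLASSES)

#' Coerce a named count vector to the canonical type-class order
#'
#' Unknown class names raise an error; absent classes become zero.
#'
#' @param counts named numeric/integer vector or list, names in
#'   `c("M","m","sm","st","t","T")`.
#' @return named integer vector over all six classes, canonical order.
#' @keywords internal
normalize_counts <- function(counts) {
  counts <- unlist(counts)
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    abort("`counts` must be named by type class.", class = "karyohybrid_input_error")
  }
  bad <- setdiff(names(counts), TYPE_CLASSES)
  if (length(bad) > 0) {
    abort(paste0("Unknown chromosome type class(es): ", paste(bad, collapse = ", ")),
          class = "karyohybrid_input_error")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Type counts must be non-negative integers.",
          class = "karyohybrid_input_error")
  }
  out <- stats::setNames(integer(length(TYPE_CLASSES)), TYPE_CLASSES)
  out[names(counts)] <- out[names(counts)] + as.integer(counts)
  out
}

drop_zero_counts <- function(counts) counts[counts > 0]

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
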