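#' Balanced haploid gamete from a diploid karyotype
#'
#' Under regular meiosis a euploid diploid contributes one chromosome of
#' each homolog pair, so every per-type count is halved and the gamete has
#' n = 2n/2 chromosomes. An odd per-type count means no balanced gamete
#' exists at type resolution (aneuploid or mis-typed input) and raises an
#' error; unreduced or aneuploid gametes are deliberately not modelled.
#'
#' @param karyotype a named per-type count vector, a karyotype formula
#'   string, or a single-taxon element of a `karyotype_summary`.
#' @return named list with `counts` (halved, zero classes dropped) and `n`.
#' @examples
#' balanced_gamete("2n = 22 = 10t + 12st")  # n = 11 = 5t + 6st
#' @export
balanced_gamete <- function(karyotype) {
  counts <- as_type_counts(karyotype)
  if (any(counts %% 2 != 0)) {
    odd <- names(counts)[counts %% 2 != 0]
    abort(paste0("Unbalanced parent: odd count for type(s) ",
                 paste(odd, collapse = ", "),
                 ". Only balanced (euploid) gametes are modelled."),
          class = "karyohybrid_unbalanced_error")
  }
  g <- counts %/% 2L
  list(counts = drop_zero_counts(g), n = sum(g))
}

as_type_counts <- function(x) {
  if (is.character(x) && length(x) == 1) {
    return(parse_karyotype_formula(x)$counts)
  }
  if (is.list(x) && !is.null(x$counts)) x <- x$counts
  normalize_counts(x)
}

#' Predict the F1 complement of a cross
#'
#' Unites one balanced gamete from each parent: the predicted F1 per-type
#' counts are the sums of the two halved parental counts, and its
#' chromosome number is (2n_A + 2n_B)/2. Commutative in its arguments.
#'
#' @param parent_a,parent_b per-type counts, formula strings, or
#'   karyotype summaries (see [balanced_gamete()]).
#' @return named list with `counts`, `two_n` and `formula`.
#' @examples
#' predict_f1("2n = 22 = 10t + 12st", "2n = 14 = 8m + 6T")
#' @export
predict_f1 <- function(parent_a, parent_b) {
  ga <- balanced_gamete(parent_a)
  gb <- balanced_gamete(parent_b)
  counts <- normalize_counts(ga$counts) + normalize_counts(gb$counts)
  list(counts = drop_zero_counts(counts), two_n = sum(counts),
       formula = karyotype_formula(counts))
}

#' Test an observed karyotype for parental additivity
#'
#' Compares an observed complement against the balanced-gamete F1
#' prediction for a candidate parent pair. The residual is observed minus
#' predicted per type; the pair is consistent with parentage exactly when
#' every residual is zero (additivity at type-count resolution).
#'
#' @param observed observed per-type counts or formula string.
#' @param parent_a,parent_b candidate parents (counts, formula, or summary).
#' @return object of class `additivity_result` with fields `consistent`,
#'   `predicted`, `observed`, `residual`; [tidy()] gives the per-type
#'   table, [glance()] a one-row summary.
#' @export
additivity_test <- function(observed, parent_a, parent_b) {
  obs <- normalize_counts(as_type_counts(observed))
  f1 <- predict_f1(parent_a, parent_b)
  pred <- normalize_counts(f1$counts)
  residual <- obs - pred
  structure(list(
    consistent = all(residual == 0L),
    predicted = pred,
    observed = obs,
    residual = residual,
    predicted_formula = f1$formula
  ), class = "additivity_result")
}

#' @export
print.additivity_result <- function(x, ...) {
  cat("Karyotype additivity: ",
      if (x$consistent) "CONSISTENT" else "inconsistent",
      "\n  predicted F1: ", x$predicted_formula,
      "\n  observed:     ", karyotype_formula(x$observed), "\n", sep = "")
  invisible(x)
}

#' @method tidy additivity_result
#' @export
tidy.additivity_result <- function(x, ...) {
  tibble(type_class = names(x$observed),
         observed = as.integer(x$observed),
         predicted = as.integer(x$predicted),
         residual = as.integer(x$residual)) |>
    filter(.data$observed > 0 | .data$predicted > 0)
}

#' @method glance additivity_result
#' @export
glance.additivity_result <- function(x, ...) {
  tibble(consistent = x$consistent,
         observed_two_n = sum(x$observed),
         predicted_two_n = sum(x$predicted),
         max_abs_residual = max(abs(x$residual)))
}

#' Screen a panel of candidate parents for additive pairs
#'
#' Evaluates every unordered pair from the panel (self-pairs included,
#' since selfing is a formally valid cross at type resolution) and returns
#' the pairs whose predicted F1 matches the observed complement exactly.
#'
#' @param observed observed per-type counts or formula string.
#' @param panel data frame with columns `taxon` and `formula`, or a named
#'   list/character vector of formulas.
#' @return tibble of consistent pairs, columns `parent_a`, `parent_b`
#'   (sorted labels, `parent_a <= parent_b`), ordered by labels.
#' @export
screen_parent_pairs <- function(observed, panel) {
  if (is.data.frame(panel)) {
    formulas <- stats::setNames(panel$formula, panel$taxon)
  } else {
    formulas <- unlist(panel)
  }
  if (length(formulas) < 2) {
    abort("Panel must contain at least two candidate taxa.",
          class = "karyohybrid_input_error")
  }
  taxa <- names(formulas)
  idx <- which(upper.tri(diag(length(taxa)), diag = TRUE), arr.ind = TRUE)
  hits <- purrr::map_lgl(seq_len(nrow(idx)), function(r) {
    a <- idx[r, "row"]; b <- idx[r, "col"]
    ok <- tryCatch(
      additivity_test(observed, formulas[[a]], formulas[[b]])$consistent,
      karyohybrid_unbalanced_error = function(e) FALSE
    )
    isTRUE(ok)
  })
  out <- tibble(
    parent_a = pmin(taxa[idx[, "row"]], taxa[idx[, "col"]])[hits],
    parent_b = pmax(taxa[idx[, "row"]], taxa[idx[, "col"]])[hits]
  )
  arrange(out, .data$parent_a, .data$parent_b)
}
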