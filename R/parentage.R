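#' Rank candidate maternal parents by plastome similarity
#'
#' The chloroplast genome is maternally inherited, so a hybrid's plastome
#' should match its seed parent almost exactly. Candidates are ranked by
#' the number of SNP sites shared with the hybrid (all variant sets called
#' against one common reference), descending; ties are broken by the
#' smaller symmetric difference of the full variant sets. The margin is
#' the shared-site difference between the top two candidates; a zero
#' margin means the plastome cannot discriminate.
#'
#' @param hybrid_variants `variant_set` of the hybrid vs the reference.
#' @param candidate_variants named list of candidate `variant_set`s vs the
#'   same reference (names = candidate taxa).
#' @return object of class `maternal_ranking`: tibble (`candidate`,
#'   `shared_sites`, `symdiff`, `rank`) with attribute `margin`.
#' @export
maternal_assignment <- function(hybrid_variants, candidate_variants) {
  if (length(candidate_variants) < 2) {
    abort("Maternal assignment needs at least two candidates.",
          class = "karyohybrid_input_error")
  }
  if (is.null(names(candidate_variants))) {
    names(candidate_variants) <- purrr::map_chr(candidate_variants,
                                                ~ attr(.x, "query_id"))
  }
  tb <- purrr::imap_dfr(candidate_variants, function(vs, nm) {
    tibble(candidate = nm,
           shared_sites = shared_snp_sites(hybrid_variants, vs),
           symdiff = variant_symdiff(hybrid_variants, vs))
  }) |>
    arrange(desc(.data$shared_sites), .data$symdiff, .data$candidate) |>
    mutate(rank = row_number())
  margin <- tb$shared_sites[1] - tb$shared_sites[2]
  structure(tb, class = c("maternal_ranking", class(tibble())), margin = margin)
}

#' @export
print.maternal_ranking <- function(x, ...) {
  cat("Maternal ranking (margin ", attr(x, "margin"), "):\n", sep = "")
  NextMethod()
}

#' Combine karyotype additivity and plastome evidence into a cross report
#'
#' The top-ranked plastome candidate is assigned as the maternal parent
#' and the other member of the additivity-tested parent pair as paternal.
#' The report is confident only when the karyotype additivity test is
#' consistent AND the plastome margin is positive (strict maternal
#' inheritance assumed; confidence is a margin-based boolean, since no
#' statistical model of the shared-site counts is attempted).
#'
#' @param hybrid label of the hybrid individual.
#' @param karyotype_result an `additivity_result` for the candidate pair.
#' @param maternal_ranking a `maternal_ranking` over the same two
#'   candidates (plus possibly others; the top pair members are used).
#' @param parents optional character vector of the two candidate labels
#'   tested for additivity; defaults to the two top-ranked candidates.
#' @return object of class `cross_report`.
#' @export
infer_cross <- function(hybrid, karyotype_result, maternal_ranking,
                        parents = NULL) {
  rk <- tibble::as_tibble(maternal_ranking)
  if (is.null(parents)) parents <- rk$candidate[1:2]
  if (length(parents) != 2) {
    abort("Exactly two candidate parents are required.",
          class = "karyohybrid_input_error")
  }
  rk <- filter(rk, .data$candidate %in% parents)
  if (nrow(rk) != 2) {
    abort("Ranking does not cover both candidate parents.",
          class = "karyohybrid_input_error")
  }
  rk <- arrange(rk, .data$rank)
  maternal <- rk$candidate[1]
  paternal <- rk$candidate[2]
  margin <- rk$shared_sites[1] - rk$shared_sites[2]
  consistent <- isTRUE(karyotype_result$consistent)
  confident <- consistent && margin > 0
  reason <- if (confident) NA_character_
    else if (!consistent) "karyotype additivity inconsistent"
    else "plastome evidence cannot discriminate the candidates (margin 0)"
  structure(list(
    hybrid = hybrid,
    maternal = maternal,
    paternal = paternal,
    cross = sprintf("%s (♀) × %s (♂)", maternal, paternal),
    cp_evidence = rk,
    margin = margin,
    karyotype_evidence = karyotype_result,
    confident = confident,
    reason = reason
  ), class = "cross_report")
}

#' @export
print.cross_report <- function(x, ...) {
  cat("Cross report for '", x$hybrid, "': ", x$cross,
      if (x$confident) "  [confident]" else paste0("  [NOT confident: ", x$reason, "]"),
      "\n", sep = "")
  invisible(x)
}

#' @method glance cross_report
#' @export
glance.cross_report <- function(x, ...) {
  tibble(hybrid = x$hybrid, maternal = x$maternal, paternal = x$paternal,
         margin = x$margin,
         karyotype_consistent = isTRUE(x$karyotype_evidence$consistent),
         confident = x$confident)
}

#' @method tidy cross_report
#' @export
tidy.cross_report <- function(x, ...) x$cp_evidence

#' Serialize a cross report to JSON
#'
#' @param x a `cross_report`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_cross_report <- function(x, path) {
  jsonlite::write_json(list(
    hybrid = x$hybrid, maternal = x$maternal, paternal = x$paternal,
    cross = x$cross, margin = x$margin, confident = x$confident,
    reason = x$reason,
    cp_evidence = purrr::transpose(as.list(x$cp_evidence)),
    karyotype = list(
      consistent = x$karyotype_evidence$consistent,
      predicted = as.list(drop_zero_counts(x$karyotype_evidence$predicted)),
      observed = as.list(drop_zero_counts(x$karyotype_evidence$observed)))
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
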