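#' Run the full hybrid-parentage pipeline
#'
#' Chains the stages end to end: karyotype summaries from the measurement
#' table, the balanced-gamete additivity test of the hybrid against the
#' candidate parent pair, quadripartite partitioning of every plastome,
#' collinear variant calling and SSR scanning of hybrid and candidates
#' against the common reference, maternal assignment, and the combined
#' cross report. All thresholds are echoed into the report for
#' provenance; outputs are JSON with TSV/VCF sidecars and re-running with
#' identical inputs produces identical files.
#'
#' @param measurements measurement table (tibble or TSV path) containing
#'   the hybrid and both candidate parents.
#' @param hybrid taxon label of the hybrid in `measurements`.
#' @param parents character vector of the two candidate parent labels.
#' @param reference reference plastome ([plastome_record()] or file path).
#' @param candidate_plastomes named list (names = the two parent labels)
#'   of plastomes.
#' @param hybrid_plastome the hybrid's plastome.
#' @param out_dir output directory (created); `NULL` skips file output.
#' @param min_ir,k see [detect_inverted_repeat()] and [call_variants()].
#' @param ssr_thresholds,compound_gap see [find_ssrs()].
#' @return invisibly, a list with `karyotype` (`karyotype_summary`),
#'   `additivity` (`additivity_result`), `partitions`, `variants`, `ssrs`,
#'   `ranking`, `cross` (`cross_report`).
#' @export
run_pipeline <- function(measurements, hybrid, parents,
                         reference, candidate_plastomes, hybrid_plastome,
                         out_dir = NULL, min_ir = 1000, k = 31,
                         ssr_thresholds = c(10, 5, 4, 3, 3, 3),
                         compound_gap = 100) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ", conditionMessage(e)),
            class = "karyohybrid_pipeline_error", parent = e)
    })
  }
  if (length(parents) != 2) {
    abort("`parents` must name exactly two candidate taxa.",
          class = "karyohybrid_input_error")
  }
  if (is.character(measurements) && length(measurements) == 1) {
    measurements <- stage("input", read_measurements(measurements))
  }
  as_record <- function(x) {
    if (inherits(x, "plastome_record")) x
    else stage("input", read_plastome(x))
  }
  relabel <- function(rec, nm) { rec$id <- nm; rec }
  reference <- relabel(as_record(reference), "reference")
  candidate_plastomes <- purrr::imap(purrr::map(candidate_plastomes, as_record),
                                     relabel)
  hybrid_plastome <- relabel(as_record(hybrid_plastome), hybrid)

  kar <- stage("karyotype", summarize_karyotype(measurements))
  kg <- glance(kar)
  missing_taxa <- setdiff(c(hybrid, parents), kg$taxon)
  if (length(missing_taxa) > 0) {
    abort(paste0("Taxa absent from measurements: ",
                 paste(missing_taxa, collapse = ", ")),
          class = "karyohybrid_input_error")
  }
  fm <- stats::setNames(kg$formula, kg$taxon)
  add <- stage("hybrid-test",
               additivity_test(fm[[hybrid]], fm[[parents[1]]], fm[[parents[2]]]))

  all_plastomes <- c(list(reference = reference), candidate_plastomes,
                     stats::setNames(list(hybrid_plastome), hybrid))
  parts <- stage("cp-structure",
                 purrr::map(all_plastomes, detect_inverted_repeat, min_ir = min_ir))
  ref_canon <- parts$reference$record

  queries <- parts[c(parents, hybrid)]
  vars <- stage("cp-compare", purrr::map(queries, function(p) {
    call_variants(p$record, ref_canon, k = k)
  }))
  ssrs <- stage("ssr", purrr::map(parts, function(p) {
    find_ssrs(p$record, thresholds = ssr_thresholds, compound_gap = compound_gap)
  }))

  ranking <- stage("parentage",
                   maternal_assignment(vars[[hybrid]], vars[parents]))
  cross <- stage("parentage", infer_cross(hybrid, add, ranking, parents = parents))

  res <- list(karyotype = kar, additivity = add, partitions = parts,
              variants = vars, ssrs = ssrs, ranking = ranking, cross = cross)
  if (!is.null(out_dir)) {
    write_pipeline_bundle(res, out_dir, hybrid, parents,
                          list(min_ir = min_ir, k = k,
                               ssr_thresholds = ssr_thresholds,
                               compound_gap = compound_gap))
  }
  invisible(res)
}

write_pipeline_bundle <- function(res, out_dir, hybrid, parents, params) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_karyotype(res$karyotype, out_dir)
  for (nm in names(res$partitions)) {
    write_quadripartite(res$partitions[[nm]], out_dir)
  }
  for (nm in names(res$variants)) {
    write_vcf(res$variants[[nm]], file.path(out_dir, paste0(nm, ".vcf")))
  }
  for (nm in names(res$ssrs)) {
    readr::write_tsv(dplyr::mutate(res$ssrs[[nm]], taxon = nm, .before = 1),
                     file.path(out_dir, paste0(nm, "_ssrs.tsv")))
  }
  write_cross_report(res$cross, file.path(out_dir, "cross_report.json"))
  jsonlite::write_json(list(
    hybrid = hybrid, parents = as.list(parents), parameters = params,
    additivity_consistent = res$additivity$consistent,
    maternal = res$cross$maternal, paternal = res$cross$paternal,
    confident = res$cross$confident,
    variant_counts = purrr::map(res$variants, ~ as.list(glance(.x))),
    ssr_counts = purrr::map(res$ssrs, nrow)
  ), file.path(out_dir, "report.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
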