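#' Classify a chromosome by centromere position
#'
#' Assigns the Levan/Stebbins centromere-position class from the long/short
#' arm ratio: `T` (terminal centromeric point, no short arm, ratio infinite),
#' `t` (ratio > 7.00), `st` (3.01-7.00), `sm` (1.71-3.00), `m` (1.01-1.70)
#' and `M` (median point, ratio 1.00). Arms are swapped internally so
#' short <= long. The `sm` band is not occupied by any of the study taxa but
#' is kept so the classifier is total over valid measurements; hitting it
#' triggers a warning.
#'
#' Band edges are applied at two-decimal precision (a ratio within 0.005 of
#' 1.00 counts as `M`, the `sm`/`st` cut sits at 3.005), matching ranges that
#' are conventionally printed to two decimals. `t` is strictly > 7.00 and
#' `st` includes 7.00.
#'
#' @param short_arm,long_arm numeric vectors of arm lengths (um), recycled.
#' @return character vector of type classes.
#' @examples
#' classify_chromosome(0, 6.2)   # "T"
#' classify_chromosome(3, 3)     # "M"
#' classify_chromosome(1, 5)     # "st"
#' @export
classify_chromosome <- function(short_arm, long_arm) {
  n <- max(length(short_arm), length(long_arm))
  short_arm <- rep_len(as.numeric(short_arm), n)
  long_arm <- rep_len(as.numeric(long_arm), n)
  if (any(is.na(short_arm) | is.na(long_arm))) {
    abort("Arm lengths must be non-missing.", class = "karyohybrid_measurement_error")
  }
  if (any(short_arm < 0 | long_arm < 0)) {
    abort("Arm lengths must be non-negative.", class = "karyohybrid_measurement_error")
  }
  s <- pmin(short_arm, long_arm)
  l <- pmax(short_arm, long_arm)
  if (any(l <= 0)) {
    abort("Both arms are zero: invalid measurement.",
          class = "karyohybrid_measurement_error")
  }
  r <- ifelse(s == 0, Inf, l / s)
  out <- character(n)
  out[s == 0] <- "T"
  out[s > 0 & r > 7] <- "t"
  out[s > 0 & r >= 3.005 & r <= 7] <- "st"
  out[s > 0 & r >= 1.705 & r < 3.005] <- "sm"
  out[s > 0 & r > 1.005 & r < 1.705] <- "m"
  out[s > 0 & r <= 1.005] <- "M"
  if (any(out == "sm")) {
    warn("Arm ratio in 1.71-3.00: classified `sm` (band unused by the reference taxa).",
         class = "karyohybrid_sm_warning")
  }
  out
}

arm_ratio <- function(short_arm, long_arm) {
  s <- pmin(short_arm, long_arm)
  l <- pmax(short_arm, long_arm)
  ifelse(s == 0, Inf, l / s)
}

#' Read a chromosome arm-measurement table
#'
#' Expects a UTF-8 TSV with header `taxon cell chrom short_um long_um`
#' (decimal point). Rows where the recorded short arm exceeds the long arm
#' are auto-swapped with a warning, so downstream code can rely on
#' `short_um <= long_um`.
#'
#' @param path path to the TSV file.
#' @return tibble with columns `taxon`, `cell`, `chrom`, `short_um`,
#'   `long_um`.
#' @export
read_measurements <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    taxon = readr::col_character(),
    cell = readr::col_character(),
    chrom = readr::col_integer(),
    short_um = readr::col_double(),
    long_um = readr::col_double()
  ))
  need <- c("taxon", "cell", "chrom", "short_um", "long_um")
  if (!all(need %in% names(x))) {
    abort(paste0("Measurement table must have columns: ", paste(need, collapse = " ")),
          class = "karyohybrid_input_error")
  }
  normalize_measurements(as_tibble(x))
}

normalize_measurements <- function(x) {
  swapped <- x$short_um > x$long_um
  if (any(swapped)) {
    warn(sprintf("%d measurement(s) had short arm > long arm; arms swapped.",
                 sum(swapped)),
         class = "karyohybrid_swap_warning")
    s <- pmin(x$short_um, x$long_um)
    l <- pmax(x$short_um, x$long_um)
    x$short_um <- s
    x$long_um <- l
  }
  if (any(x$long_um <= 0)) {
    abort("Chromosome with both arms zero: invalid measurement.",
          class = "karyohybrid_measurement_error")
  }
  x
}

#' Pair homologous chromosomes within a complement
#'
#' Within each type class, chromosomes are sorted by total length
#' (descending) and paired consecutively: a diploid complement of 2n
#' chromosomes yields n homolog pairs, each summarised by its mean short
#' arm `b` and mean long arm `B`. An odd within-type count means the
#' complement cannot be partitioned into homolog pairs at type resolution
#' and raises an error naming the offending type.
#'
#' @param complement data frame with columns `short_um`, `long_um` and
#'   optionally `type_class` (computed if absent).
#' @return tibble with one row per pair: `pair`, `type_class`, `b` (mean
#'   short arm, um), `B` (mean long arm, um), `total` (b + B).
#' @export
pair_homologs <- function(complement) {
  complement <- as_tibble(complement)
  if (!"type_class" %in% names(complement)) {
    complement$type_class <- classify_chromosome(complement$short_um, complement$long_um)
  }
  complement$total_um <- complement$short_um + complement$long_um
  odd <- table(complement$type_class) %% 2 != 0
  if (any(odd)) {
    abort(paste0("Odd chromosome count within type class(es): ",
                 paste(names(odd)[odd], collapse = ", "),
                 ". Homolog pairing needs an even count per type."),
          class = "karyohybrid_pairing_error")
  }
  complement |>
    arrange(type_factor(.data$type_class), desc(.data$total_um)) |>
    group_by(.data$type_class) |>
    mutate(.pair_in_type = (row_number() + 1L) %/% 2L) |>
    group_by(.data$type_class, .data$.pair_in_type) |>
    summarise(b = mean(.data$short_um), B = mean(.data$long_um),
              .groups = "drop") |>
    arrange(type_factor(.data$type_class), desc(.data$b + .data$B)) |>
    mutate(pair = row_number(), total = .data$b + .data$B) |>
    select("pair", "type_class", "b", "B", "total")
}

#' Karyotype asymmetry indices A1 and A2
#'
#' `A1` (intrachromosomal) is `1 - mean(b_i / B_i)` over the n homolog
#' pairs, with `b/B = 0` for T-type pairs (no short arm); it lies in
#' `[0, 1]`, 0 for a perfectly metacentric complement. `A2`
#' (interchromosomal) is the coefficient of variation (sd/mean, sample sd)
#' of the total lengths of all chromosomes in the complement. Both are
#' dimensionless and invariant under uniform scaling of all lengths.
#'
#' @param pairs tibble from [pair_homologs()].
#' @param lengths numeric vector of all 2n chromosome total lengths (um)
#'   used for A2; defaults to each pair's total repeated twice.
#' @return named list with elements `A1` and `A2`.
#' @export
asymmetry_indices <- function(pairs, lengths = NULL) {
  if (nrow(pairs) < 1) {
    abort("Need at least one homolog pair.", class = "karyohybrid_input_error")
  }
  ratio <- ifelse(pairs$B == 0, 1, pairs$b / pairs$B)
  A1 <- 1 - mean(ratio)
  if (is.null(lengths)) lengths <- rep(pairs$total, each = 2)
  A2 <- if (length(lengths) < 2) 0 else stats::sd(lengths) / mean(lengths)
  list(A1 = A1, A2 = A2)
}

#' Complement-level length statistics
#'
#' For each metaphase cell, the haploid total chromosome length is half the
#' summed lengths of the diploid complement; `TCL` is its mean over cells.
#' `LS` is the mean over cells of (longest chromosome) / (shortest
#' chromosome).
#'
#' @param cells data frame with columns `cell`, `short_um`, `long_um`.
#' @return list with `TCL`, `LS`, `n_cells`, and `per_cell` tibble.
#' @export
complement_stats <- function(cells) {
  cells <- as_tibble(cells)
  cells$total_um <- cells$short_um + cells$long_um
  sizes <- table(cells$cell)
  if (length(unique(sizes)) != 1) {
    abort("Inconsistent chromosome number (2n) across cells.",
          class = "karyohybrid_input_error")
  }
  per_cell <- cells |>
    group_by(.data$cell) |>
    summarise(tcl = sum(.data$total_um) / 2,
              ls = max(.data$total_um) / min(.data$total_um),
              .groups = "drop")
  list(TCL = mean(per_cell$tcl), LS = mean(per_cell$ls),
       n_cells = nrow(per_cell), per_cell = per_cell)
}

#' Stebbins karyotype asymmetry class
#'
#' Two-character class: a digit from the proportion `p` of chromosomes with
#' arm ratio > 2.00 (T-type counts as exceeding 2) - `p = 0` gives 1,
#' `0 < p <= 0.5` gives 2, `0.5 < p < 1` gives 3, `p = 1` gives 4 - and a
#' letter from the longest/shortest ratio: `< 2` A, `[2, 4]` B, `> 4` C.
#'
#' @param arm_ratios numeric vector of per-chromosome arm ratios (`Inf` for
#'   T-type), or `NULL` when `counts` is given.
#' @param ls_ratio longest/shortest chromosome length ratio.
#' @param counts alternatively, a named per-type count vector; `st`, `t`
#'   and `T` are taken as ratio > 2, `M`/`m` as below. `sm` straddles 2.00
#'   and is counted as above it, with a warning.
#' @return two-character class string, e.g. `"4A"`.
#' @examples
#' stebbins_class(counts = c(t = 10, st = 12), ls_ratio = 1.73)  # "4A"
#' @export
stebbins_class <- function(arm_ratios = NULL, ls_ratio, counts = NULL) {
  if (is.null(arm_ratios) && is.null(counts)) {
    abort("Provide `arm_ratios` or `counts`.", class = "karyohybrid_input_error")
  }
  if (is.null(arm_ratios)) {
    counts <- normalize_counts(counts)
    if (counts[["sm"]] > 0) {
      warn("`sm` chromosomes straddle the arm-ratio-2 cut; counted as > 2.",
           class = "karyohybrid_sm_warning")
    }
    p <- sum(counts[c("sm", "st", "t", "T")]) / sum(counts)
  } else {
    p <- mean(arm_ratios > 2)
  }
  digit <- if (p == 0) 1L else if (p <= 0.5) 2L else if (p < 1) 3L else 4L
  letter <- if (ls_ratio < 2) "A" else if (ls_ratio <= 4) "B" else "C"
  paste0(digit, letter)
}

#' Format and parse karyotype formulas
#'
#' A karyotype formula such as `"2n = 18 = 4m + 6st + 5t + 3T"` summarises
#' a complement as counts per centromere-position class. `karyotype_formula()`
#' emits the canonical form (terms ordered M, m, sm, st, t, T; zero counts
#' omitted); `parse_karyotype_formula()` accepts terms in any order,
#' optional spaces, and an optional ploidy segment (`"2n = 2x = 22 = ..."`),
#' and checks that the term counts sum to the stated 2n.
#'
#' @param counts named per-type count vector.
#' @param two_n total chromosome number; defaults to `sum(counts)`.
#' @return `karyotype_formula()`: the formula string.
#' @examples
#' karyotype_formula(c(m = 8, T = 6))               # "2n = 14 = 8m + 6T"
#' parse_karyotype_formula("2n = 2x = 22 = 10t + 12st")
#' @export
karyotype_formula <- function(counts, two_n = NULL) {
  counts <- normalize_counts(counts)
  if (is.null(two_n)) two_n <- sum(counts)
  if (sum(counts) != two_n) {
    abort(sprintf("Type counts sum to %d, not the stated 2n = %d.",
                  sum(counts), as.integer(two_n)),
          class = "karyohybrid_formula_error")
  }
  nz <- drop_zero_counts(counts)
  paste0("2n = ", two_n, " = ",
         paste0(nz, names(nz), collapse = " + "))
}

#' @rdname karyotype_formula
#' @param formula formula string to parse.
#' @return `parse_karyotype_formula()`: list with `two_n` (integer) and
#'   `counts` (named integer vector over the six classes).
#' @export
parse_karyotype_formula <- function(formula) {
  segs <- stringr::str_trim(strsplit(formula, "=", fixed = TRUE)[[1]])
  if (length(segs) < 3 || !identical(tolower(segs[1]), "2n")) {
    abort("Formula must look like '2n = [2x =] <count> = <terms>'.",
          class = "karyohybrid_formula_error")
  }
  i <- 2
  while (i < length(segs) && grepl("^\\d+x$", segs[i])) i <- i + 1
  if (!grepl("^\\d+$", segs[i]) || i == length(segs)) {
    abort("Could not locate the chromosome count segment.",
          class = "karyohybrid_formula_error")
  }
  two_n <- as.integer(segs[i])
  terms <- stringr::str_trim(strsplit(paste(segs[(i + 1):length(segs)], collapse = "="),
                                      "+", fixed = TRUE)[[1]])
  counts <- stats::setNames(integer(length(TYPE_CLASSES)), TYPE_CLASSES)
  for (tm in terms) {
    m <- stringr::str_match(gsub("[[:space:]]", "", tm), "^(\\d+)(sm|st|M|m|t|T)$")
    if (is.na(m[1, 1])) {
      abort(paste0("Unparseable formula term: '", tm, "'"),
            class = "karyohybrid_formula_error")
    }
    counts[m[1, 3]] <- counts[m[1, 3]] + as.integer(m[1, 2])
  }
  if (sum(counts) != two_n) {
    abort(sprintf("Formula terms sum to %d but state 2n = %d.",
                  sum(counts), two_n),
          class = "karyohybrid_formula_error")
  }
  list(two_n = two_n, counts = counts)
}

#' Summarise karyotypes from arm measurements
#'
#' The workhorse of the cytological side: takes a measurement table (one
#' row per chromosome per metaphase cell, possibly several taxa) and
#' returns per-taxon karyotype summaries - 2n, type counts and formula,
#' TCL (mean haploid total length, um), longest/shortest ratio, the
#' Romero Zarco asymmetry indices A1 and A2, and the Stebbins class.
#'
#' Aggregation across cells: within each cell chromosomes are ordered by
#' (type class, descending total length) and averaged position-wise across
#' cells, so each of the 2n karyotype positions gets mean arm lengths over
#' the cells measured. A1/A2 and the Stebbins digit are computed on this
#' averaged complement; TCL and the L/S ratio are per-cell values averaged
#' over cells. If per-cell type counts disagree (heavy noise), ordering
#' falls back to descending length with a warning.
#'
#' @param measurements data frame with columns `taxon`, `cell`, `chrom`,
#'   `short_um`, `long_um` (see [read_measurements()]).
#' @param strict_pairing if `TRUE`, odd within-type counts (as in a hybrid
#'   complement) raise a pairing error. The default `FALSE` evaluates A1
#'   over individual chromosomes when homologs cannot be paired - the two
#'   give identical A1 when homologs are exact copies, and a hybrid has no
#'   true homolog pairs to average anyway.
#' @return object of class `karyotype_summary`; see [tidy.karyotype_summary()]
#'   for the per-chromosome table and [glance.karyotype_summary()] for the
#'   one-row-per-taxon summary.
#' @export
summarize_karyotype <- function(measurements, strict_pairing = FALSE) {
  measurements <- normalize_measurements(as_tibble(measurements))
  taxa <- unique(measurements$taxon)
  res <- purrr::map(taxa, function(tx) {
    summarize_karyotype_one(dplyr::filter(measurements, .data$taxon == tx),
                            tx, strict_pairing)
  })
  names(res) <- taxa
  structure(list(taxa = res), class = "karyotype_summary")
}

summarize_karyotype_one <- function(m, taxon, strict_pairing) {
  m$total_um <- m$short_um + m$long_um
  sizes <- table(m$cell)
  if (length(unique(as.integer(sizes))) != 1) {
    abort(sprintf("Taxon '%s': inconsistent 2n across cells.", taxon),
          class = "karyohybrid_input_error")
  }
  two_n <- as.integer(sizes[1])

  # align chromosomes across cells: by their chromosome index when every
  # cell carries the same index set (karyotype tables number chromosomes
  # consistently), otherwise by (type class, descending length) rank
  ids_by_cell <- split(m$chrom, m$cell)
  same_ids <- all(purrr::map_lgl(ids_by_cell,
                                 ~ setequal(.x, ids_by_cell[[1]]))) &&
    !anyDuplicated(ids_by_cell[[1]])
  if (same_ids) {
    ordered <- mutate(m, position = .data$chrom)
  } else {
    warn(sprintf("Taxon '%s': chromosome indices differ across cells; aligning by type and length rank.",
                 taxon),
         class = "karyohybrid_alignment_warning")
    m$type_class <- classify_chromosome(m$short_um, m$long_um)
    ordered <- m |>
      group_by(.data$cell) |>
      arrange(type_factor(.data$type_class), desc(.data$total_um), .by_group = TRUE) |>
      mutate(position = row_number()) |>
      ungroup()
  }
  avg <- ordered |>
    group_by(.data$position) |>
    summarise(short_um = mean(.data$short_um), long_um = mean(.data$long_um),
              .groups = "drop") |>
    mutate(total_um = .data$short_um + .data$long_um,
           arm_ratio = arm_ratio(.data$short_um, .data$long_um),
           type_class = classify_chromosome(.data$short_um, .data$long_um),
           relative_pct = 100 * .data$total_um / (sum(.data$total_um) / 2)) |>
    arrange(type_factor(.data$type_class), desc(.data$total_um)) |>
    mutate(position = row_number())

  cs <- complement_stats(m)
  counts <- normalize_counts(table(avg$type_class))
  pairs <- NULL
  if (strict_pairing || all(table(avg$type_class) %% 2 == 0)) {
    pairs <- pair_homologs(avg)
    A1 <- asymmetry_indices(pairs, lengths = avg$total_um)$A1
  } else {
    # unpairable (hybrid) complement: average short/long over chromosomes
    A1 <- 1 - mean(ifelse(avg$long_um == 0, 1,
                          ifelse(avg$short_um == 0, 0,
                                 pmin(avg$short_um, avg$long_um) /
                                   pmax(avg$short_um, avg$long_um))))
  }
  A2 <- if (nrow(avg) < 2) 0 else stats::sd(avg$total_um) / mean(avg$total_um)

  list(
    taxon = taxon,
    two_n = two_n,
    counts = counts,
    formula = karyotype_formula(counts, two_n),
    TCL = cs$TCL,
    LS = cs$LS,
    A1 = A1,
    A2 = A2,
    stebbins = stebbins_class(avg$arm_ratio, cs$LS),
    n_cells = cs$n_cells,
    chromosomes = avg,
    pairs = pairs
  )
}

#' @export
print.karyotype_summary <- function(x, ...) {
  cat("Karyotype summary (", length(x$taxa), " taxa)\n", sep = "")
  print(glance(x), ...)
  invisible(x)
}

#' Per-chromosome karyotype table
#'
#' One row per karyotype position (cell-averaged chromosome) per taxon:
#' arm lengths, total, arm ratio, relative length (% of the haploid total)
#' and type class — mirroring a supplementary karyotype-parameter table.
#'
#' @param x a `karyotype_summary`.
#' @param ... unused.
#' @return tibble.
#' @method tidy karyotype_summary
#' @export
tidy.karyotype_summary <- function(x, ...) {
  purrr::map_dfr(x$taxa, function(s) {
    mutate(s$chromosomes, taxon = s$taxon, .before = 1)
  })
}

#' One-row-per-taxon karyotype summary
#'
#' @param x a `karyotype_summary`.
#' @param ... unused.
#' @return tibble with columns `taxon`, `two_n`, `formula`, `TCL_um`, `LS`,
#'   `A1`, `A2`, `stebbins`, `n_cells`.
#' @method glance karyotype_summary
#' @export
glance.karyotype_summary <- function(x, ...) {
  purrr::map_dfr(x$taxa, function(s) {
    tibble(taxon = s$taxon, two_n = s$two_n, formula = s$formula,
           TCL_um = s$TCL, LS = s$LS, A1 = s$A1, A2 = s$A2,
           stebbins = s$stebbins, n_cells = s$n_cells)
  })
}

#' Idiogram-style plot of a karyotype summary
#'
#' Stacked arm lengths per karyotype position, faceted by taxon.
#'
#' @param object a `karyotype_summary`.
#' @param ... unused.
#' @return ggplot object.
#' @method autoplot karyotype_summary
#' @export
autoplot.karyotype_summary <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("short_um", "long_um"),
                        names_to = "arm", values_to = "um")
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$position), y = .data$um,
                                  fill = .data$arm)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~taxon, scales = "free_x") +
    ggplot2::labs(x = "karyotype position", y = "arm length (um)", fill = NULL)
}

#' Write a karyotype summary bundle
#'
#' JSON summary (one object per taxon) plus a per-chromosome TSV.
#'
#' @param x a `karyotype_summary`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_karyotype <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  js <- purrr::map(x$taxa, function(s) {
    list(taxon = s$taxon, two_n = s$two_n, formula = s$formula,
         counts = as.list(drop_zero_counts(s$counts)),
         TCL_um = s$TCL, LS = s$LS, A1 = s$A1, A2 = s$A2,
         stebbins = s$stebbins, n_cells = s$n_cells)
  })
  jpath <- file.path(dir, "karyotype_summary.json")
  jsonlite::write_json(unname(js), jpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tpath <- file.path(dir, "karyotype_chromosomes.tsv")
  readr::write_tsv(tidy(x), tpath)
  invisible(c(jpath, tpath))
}
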