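#' Specification for a simulated karyotype
#'
#' Builds deterministic per-homolog-pair target arm lengths for a diploid
#' complement. Pair total lengths are spaced geometrically so the
#' longest/shortest ratio equals `ls_ratio`; arm-ratio targets per type are
#' evenly spread inside each classification band, kept away from the band
#' edges so noiseless measurements classify back to their own type
#' (T: short arm 0; t: 8-12; st: 3.5-6.5; m: 1.05-1.55).
#'
#' @param counts named per-type counts (each even: homologs come in pairs).
#' @param taxon taxon label for generated tables.
#' @param tcl_um target haploid total chromosome length (um).
#' @param ls_ratio target longest/shortest chromosome length ratio.
#' @param noise_cv coefficient of variation of per-cell multiplicative
#'   (log-normal) measurement noise; cytological measurement error scales
#'   with length.
#' @param n_cells metaphase cells to simulate per individual (default 5).
#' @return object of class `karyotype_sim_spec` with a `pairs` tibble of
#'   per-pair target arms.
#' @export
karyotype_sim_spec <- function(counts, taxon = "taxon", tcl_um = 120,
                               ls_ratio = 2, noise_cv = 0.05, n_cells = 5) {
  counts <- normalize_counts(counts)
  if (any(counts %% 2 != 0)) {
    abort("Simulated parents are euploid: per-type counts must be even.",
          class = "karyohybrid_input_error")
  }
  if (noise_cv < 0) {
    abort("noise_cv must be >= 0.", class = "karyohybrid_input_error")
  }
  n_pairs <- sum(counts) %/% 2L
  # band interiors kept clear of the classification cut-offs so that
  # cell-averaged noisy ratios stay in class with high probability
  bands <- list(M = c(1.0, 1.0), m = c(1.05, 1.55), sm = c(1.9, 2.8),
                st = c(3.5, 6.5), t = c(8, 12), T = c(Inf, Inf))
  pair_types <- rep(names(counts), counts %/% 2L)
  # geometric length spacing: longest/shortest = ls_ratio, scaled to TCL
  lens <- ls_ratio^seq(1, 0, length.out = n_pairs)
  lens <- lens * tcl_um / sum(lens)
  ratios <- unlist(purrr::imap(split(seq_len(n_pairs), type_factor(pair_types)),
                               function(ix, ty) {
    if (length(ix) == 0) return(numeric(0))
    b <- bands[[ty]]
    if (is.infinite(b[1])) rep(Inf, length(ix))
    else if (length(ix) == 1) rep(mean(b), 1)
    else seq(b[1], b[2], length.out = length(ix))
  }))
  ord <- order(type_factor(pair_types))
  pairs <- tibble(
    pair = seq_len(n_pairs),
    type = pair_types[ord],
    total_um = lens,
    ratio = unname(ratios)
  ) |>
    mutate(short_um = ifelse(is.infinite(.data$ratio), 0,
                             .data$total_um / (1 + .data$ratio)),
           long_um = .data$total_um - .data$short_um)
  structure(list(taxon = taxon, counts = counts, pairs = pairs,
                 noise_cv = noise_cv, n_cells = n_cells),
            class = "karyotype_sim_spec")
}

#' Canned parental karyotype specifications
#'
#' Two ready-made diploid specs shaped like the study system: a
#' 2n = 22 = 10t + 12st parent (TCL 115.61 um, L/S 1.73) and a
#' 2n = 14 = 8m + 6T parent (TCL 145.95 um, L/S 2.45).
#'
#' @param noise_cv,n_cells passed to [karyotype_sim_spec()].
#' @return a `karyotype_sim_spec`.
#' @export
radiata_like_spec <- function(noise_cv = 0.05, n_cells = 5) {
  karyotype_sim_spec(c(t = 10, st = 12), taxon = "radiata",
                     tcl_um = 115.61, ls_ratio = 1.73,
                     noise_cv = noise_cv, n_cells = n_cells)
}

#' @rdname radiata_like_spec
#' @export
aurea_like_spec <- function(noise_cv = 0.05, n_cells = 5) {
  karyotype_sim_spec(c(m = 8, T = 6), taxon = "aurea",
                     tcl_um = 145.95, ls_ratio = 2.45,
                     noise_cv = noise_cv, n_cells = n_cells)
}

#' Simulate a metaphase arm-measurement table
#'
#' For every cell, each chromosome's arms are the pair's target arms times
#' independent log-normal noise (`meanlog = 0`, `sdlog = noise_cv`);
#' homologs share targets. Deterministic given `seed`.
#'
#' @param spec a [karyotype_sim_spec()].
#' @param seed integer RNG seed.
#' @return measurement tibble (`taxon`, `cell`, `chrom`, `short_um`,
#'   `long_um`), two rows per pair per cell.
#' @export
simulate_karyotype_measurements <- function(spec, seed = 1) {
  withr::with_seed(seed, sim_measurements(spec))
}

sim_measurements <- function(spec) {
  targets <- spec$pairs[rep(seq_len(nrow(spec$pairs)), each = 2), ]
  two_n <- nrow(targets)
  purrr::map_dfr(seq_len(spec$n_cells), function(cell) {
    noise_s <- stats::rlnorm(two_n, 0, spec$noise_cv)
    noise_l <- stats::rlnorm(two_n, 0, spec$noise_cv)
    tibble(taxon = spec$taxon,
           cell = sprintf("cell%02d", cell),
           chrom = seq_len(two_n),
           short_um = round(targets$short_um * noise_s, 4),
           long_um = round(targets$long_um * noise_l, 4))
  })
}

#' Simulate measurements for an F1 hybrid of two parental specs
#'
#' The F1 complement takes one homolog (one target) from each parental
#' pair - the balanced-gamete union - and measurements are re-noised
#' around those targets. Noise and cell count come from `parent_a`'s spec.
#'
#' @param parent_a,parent_b [karyotype_sim_spec()]s.
#' @param seed integer RNG seed.
#' @param taxon label for the simulated hybrid.
#' @return measurement tibble as in [simulate_karyotype_measurements()].
#' @export
simulate_f1_measurements <- function(parent_a, parent_b, seed = 1,
                                     taxon = "F1") {
  gp <- bind_rows(parent_a$pairs, parent_b$pairs) |>
    arrange(type_factor(.data$type), desc(.data$total_um)) |>
    mutate(pair = row_number())
  f1 <- structure(list(taxon = taxon,
                       counts = normalize_counts(table(gp$type)),
                       pairs = gp,
                       noise_cv = parent_a$noise_cv,
                       n_cells = parent_a$n_cells),
                  class = "karyotype_sim_spec")
  # each F1 "pair" row stands for ONE chromosome from each parent; the
  # simulated complement keeps one homolog per parental pair
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(f1$n_cells), function(cell) {
      k <- nrow(gp)
      noise_s <- stats::rlnorm(k, 0, f1$noise_cv)
      noise_l <- stats::rlnorm(k, 0, f1$noise_cv)
      tibble(taxon = taxon,
             cell = sprintf("cell%02d", cell),
             chrom = seq_len(k),
             short_um = round(gp$short_um * noise_s, 4),
             long_um = round(gp$long_um * noise_l, 4))
    })
  })
}

#' Specification for a simulated quadripartite plastome
#'
#' Defaults give a reduced-scale (~5.8 kb) genome: LSC 3000, SSC 800 and
#' IR 1000 bp, with gene stubs straddling the junctions in the
#' conventional layout (rps19 across LSC-IRb with 176/34 bp sides, ndhF
#' across IRb-SSC with 107 bp in the IRb, ycf1 across SSC-IRa with 41 bp
#' in the IRa, psbA 86 bp into the LSC and an rps19 copy ending 3 bp
#' before the IRa-LSC border) and planted SSR loci. A
#' `scale = "lycoris"` preset uses real plastome dimensions (LSC 86597,
#' SSC 18342, IR 26733 bp) for stress testing.
#'
#' @param lsc_len,ssc_len,ir_len region lengths in bp; LSC must exceed SSC.
#' @param ssr_plants list of `list(motif=, repeats=, pos=)` to embed
#'   (positions on the final genome, LSC coordinates recommended).
#' @param scale `"reduced"` (default) or `"lycoris"`.
#' @return object of class `plastome_sim_spec`.
#' @export
plastome_sim_spec <- function(lsc_len = 3000, ssc_len = 800, ir_len = 1000,
                              ssr_plants = NULL,
                              scale = c("reduced", "lycoris")) {
  scale <- match.arg(scale)
  if (scale == "lycoris") {
    lsc_len <- 86597; ssc_len <- 18342; ir_len <- 26733
  }
  if (lsc_len <= ssc_len) {
    abort("LSC must be longer than SSC.", class = "karyohybrid_input_error")
  }
  if (is.null(ssr_plants)) {
    ssr_plants <- list(
      list(motif = "A", repeats = 10, pos = 500),
      list(motif = "T", repeats = 14, pos = 900),
      list(motif = "GGAAA", repeats = 3, pos = 1400)
    )
  }
  structure(list(lsc_len = lsc_len, ssc_len = ssc_len, ir_len = ir_len,
                 ssr_plants = ssr_plants),
            class = "plastome_sim_spec")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a circular quadripartite plastome
#'
#' Random sequence per region assembled as LSC + IRb + SSC + IRa with
#' IRa the exact reverse complement of IRb; junction-straddling gene stubs
#' and SSR plants from the spec are embedded at recorded positions (SSR
#' plants get non-motif flanking bases so the planted repeat count is
#' exact). Deterministic given `seed`.
#'
#' @param spec a [plastome_sim_spec()].
#' @param seed integer RNG seed.
#' @param id record label.
#' @return a [plastome_record()] with features; the ground-truth region
#'   table is attached as attribute `truth_regions`, planted SSRs as
#'   `truth_ssrs`.
#' @export
simulate_plastome <- function(spec, seed = 1, id = "synthetic_plastome") {
  withr::with_seed(seed, {
    lsc <- random_dna(spec$lsc_len)
    ssc <- random_dna(spec$ssc_len)
    irb <- random_dna(spec$ir_len)
    # single-copy termini are set to self-identical bases (A vs comp(A)=T)
    # so the planted IR cannot extend by chance across a junction and the
    # recovered partition equals the construction exactly
    substr(lsc, 1, 1) <- "A"
    substr(lsc, spec$lsc_len, spec$lsc_len) <- "A"
    substr(ssc, 1, 1) <- "A"
    substr(ssc, spec$ssc_len, spec$ssc_len) <- "A"

    for (pl in spec$ssr_plants) {
      run <- strrep(pl$motif, pl$repeats)
      u <- nchar(pl$motif)
      end <- pl$pos + nchar(run) - 1
      if (pl$pos < 2 || end > spec$lsc_len - 1) {
        abort("SSR plant must fit inside the LSC with 1 bp flanks.",
              class = "karyohybrid_input_error")
      }
      # flanks must break the repeat so the planted count is maximal
      lflank <- setdiff(c("A", "C", "G", "T"), substr(pl$motif, u, u))[1]
      rflank <- setdiff(c("A", "C", "G", "T"), substr(pl$motif, 1, 1))[1]
      lsc <- paste0(substr(lsc, 1, pl$pos - 2), lflank, run, rflank,
                    substr(lsc, end + 2, spec$lsc_len))
    }
    n <- spec$lsc_len + 2 * spec$ir_len + spec$ssc_len
    seq <- paste0(lsc, irb, ssc, revcomp(irb))

    Ll <- spec$lsc_len; Li <- spec$ir_len; Ls <- spec$ssc_len
    j1 <- Ll                 # LSC-IRb
    j2 <- Ll + Li            # IRb-SSC
    j3 <- Ll + Li + Ls       # SSC-IRa
    features <- tibble(
      gene = c("rps19", "ndhF", "ycf1", "psbA", "rps19"),
      strand = c("-", "-", "+", "-", "+"),
      start = c(j1 - 175L, j2 - 106L, j3 - 359L, 87L, n - 212L),
      end = c(j1 + 34L, j2 + 293L, j3 + 41L, 386L, n - 3L),
      part = 1L,
      feature_id = 1:5
    )
    truth <- tibble(region = c("LSC", "IRb", "SSC", "IRa"),
                    start = c(1L, Ll + 1L, j2 + 1L, j3 + 1L),
                    end = c(Ll, j2, j3, n),
                    length = c(Ll, Li, Ls, Li))
    rec <- plastome_record(seq, id = id, features = features)
    attr(rec, "truth_regions") <- truth
    attr(rec, "truth_ssrs") <- purrr::map_dfr(spec$ssr_plants, as_tibble)
    rec
  })
}

#' Derive a maternally inherited offspring plastome
#'
#' Copies the parent sequence and applies `n_subs` random substitutions
#' and `n_indels` short (1-3 bp) insertions/deletions at positions at
#' least `min_spacing` bp apart (and away from the sequence ends), the
#' strict-maternal-inheritance model: a hybrid's plastome is its seed
#' parent's plus a handful of private mutations. The edit log (positions
#' on the parent sequence) is attached as attribute `edits`.
#'
#' @param parent a [plastome_record()].
#' @param n_subs,n_indels numbers of substitutions and indels.
#' @param seed integer RNG seed.
#' @param id offspring record label.
#' @param min_spacing minimum spacing between edit positions in bp
#'   (default 100, comfortably above twice the variant caller's anchor
#'   k-mer so every edit sits in its own inter-anchor segment).
#' @param allowed optional integer vector of permitted edit positions
#'   (e.g. single-copy regions only, so the inverted repeats stay exact
#'   copies of each other as in real plastomes); default: anywhere
#'   `min_spacing` away from the sequence ends.
#' @return a [plastome_record()] with attribute `edits` (tibble:
#'   `parent_pos`, `kind`, `ref`, `alt`).
#' @export
derive_maternal_offspring <- function(parent, n_subs = 8, n_indels = 2,
                                      seed = 1, id = paste0(parent$id, "_offspring"),
                                      min_spacing = 100, allowed = NULL) {
  n_edit <- n_subs + n_indels
  s <- parent$sequence
  n <- nchar(s)
  if (n_edit == 0) {
    out <- plastome_record(s, id = id, features = parent$features)
    attr(out, "edits") <- tibble(parent_pos = integer(), kind = character(),
                                 ref = character(), alt = character())
    return(out)
  }
  withr::with_seed(seed, {
    if (is.null(allowed)) allowed <- (min_spacing + 1L):(n - min_spacing)
    pos <- integer(0)
    tries <- 0
    while (length(pos) < n_edit && tries < 10000) {
      cand <- sample(allowed, 1)
      if (all(abs(cand - pos) >= min_spacing)) pos <- c(pos, cand)
      tries <- tries + 1
    }
    if (length(pos) < n_edit) {
      abort("Could not place edits with the requested spacing.",
            class = "karyohybrid_input_error")
    }
    pos <- sort(pos)
    kind <- c(rep("substitution", n_subs), rep("indel", n_indels))
    kind <- sample(kind)
    edits <- purrr::map2_dfr(pos, kind, function(p, k) {
      ref_base <- substr(s, p, p)
      if (k == "substitution") {
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref_base), 1)
        tibble(parent_pos = p, kind = "substitution", ref = ref_base, alt = alt)
      } else if (stats::runif(1) < 0.5) {
        len <- sample(1:3, 1)
        tibble(parent_pos = p, kind = "insertion", ref = "",
               alt = random_dna(len))
      } else {
        len <- sample(1:3, 1)
        tibble(parent_pos = p, kind = "deletion",
               ref = substr(s, p, p + len - 1), alt = "")
      }
    })
    # apply right-to-left so earlier coordinates stay valid
    out <- s
    for (i in rev(seq_len(nrow(edits)))) {
      e <- edits[i, ]
      if (e$kind == "substitution") {
        substr(out, e$parent_pos, e$parent_pos) <- e$alt
      } else if (e$kind == "insertion") {
        out <- paste0(substr(out, 1, e$parent_pos), e$alt,
                      substr(out, e$parent_pos + 1, nchar(out)))
      } else {
        out <- paste0(substr(out, 1, e$parent_pos - 1),
                      substr(out, e$parent_pos + nchar(e$ref), nchar(out)))
      }
    }
    rec <- plastome_record(out, id = id)
    attr(rec, "edits") <- edits
    rec
  })
}

#' Simulate a plastome trio (two parents and a maternal offspring)
#'
#' A shared ancestral (reference) plastome is simulated, each parent
#' derives from it independently (`divergence_subs`/`divergence_indels`
#' edits each), and the hybrid derives from the designated maternal parent
#' with a few private mutations - so the hybrid shares essentially all of
#' the maternal parent's variants against the reference and almost none of
#' the paternal parent's.
#'
#' @param spec a [plastome_sim_spec()].
#' @param seed integer RNG seed.
#' @param maternal `"A"` or `"B"`: which parent is the seed parent.
#' @param divergence_subs,divergence_indels per-parent edits vs the
#'   reference (defaults 12 and 2, scaled to the reduced genome from the
#'   ~150 SNPs per 158 kb seen between congeneric plastomes).
#' @param private_subs,private_indels hybrid-private edits (defaults 3
#'   and 1).
#' @return list with records `reference`, `parent_A`, `parent_B`,
#'   `hybrid`, and `maternal` (the label of the true seed parent).
#' @export
simulate_cp_trio <- function(spec = plastome_sim_spec(), seed = 1,
                             maternal = c("A", "B"),
                             divergence_subs = 12, divergence_indels = 2,
                             private_subs = 3, private_indels = 1) {
  maternal <- match.arg(maternal)
  ref <- simulate_plastome(spec, seed = seed, id = "reference")
  # edits go in single-copy interiors only: the inverted repeats stay exact
  # mirror copies (as in real plastomes) so every genome remains
  # quadripartite, and a 50 bp margin absorbs indel coordinate drift
  tr <- attr(ref, "truth_regions")
  sc <- tr[tr$region %in% c("LSC", "SSC"), ]
  allowed <- unlist(purrr::map2(sc$start + 50L, sc$end - 50L, seq))
  pa <- derive_maternal_offspring(ref, divergence_subs, divergence_indels,
                                  seed = seed + 1L, id = "parent_A",
                                  allowed = allowed)
  pb <- derive_maternal_offspring(ref, divergence_subs, divergence_indels,
                                  seed = seed + 2L, id = "parent_B",
                                  allowed = allowed)
  mom <- if (maternal == "A") pa else pb
  hy <- derive_maternal_offspring(mom, private_subs, private_indels,
                                  seed = seed + 3L, id = "hybrid",
                                  allowed = allowed)
  list(reference = ref, parent_A = pa, parent_B = pb, hybrid = hy,
       maternal = paste0("parent_", maternal))
}

#' Synthetic trait table for the four-taxon study system
#'
#' Eight variables per taxon - leaf length and width, three ordinal
#' flower-colour stages, and the karyological A1, A2 and TCL - for two
#' parent-like taxa and two hybrids whose traits are intermediate but
#' biased toward their maternal side. The karyological values follow the
#' study system; the morphology and colour encodings are synthetic
#' choices, so absolute dissimilarities are not meaningful, only the
#' clustering structure.
#'
#' @return tibble, one row per taxon.
#' @export
lycoris_trait_fixture <- function() {
  tibble(
    taxon = c("radiata", "hybrid1", "aurea", "hybrid2"),
    leaf_length_cm = c(45, 48, 60, 57),
    leaf_width_cm = c(1.0, 1.3, 2.2, 2.0),
    color_bud = c(1, 2, 5, 4),
    color_early = c(1, 2, 5, 4),
    color_mid = c(1, 2, 5, 4),
    A1 = c(0.811, 0.719, 0.438, 0.723),
    A2 = c(0.063, 0.052, 0.041, 0.030),
    TCL_um = c(115.61, 128.88, 145.95, 129.69)
  )
}
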