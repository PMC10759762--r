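#' Shared unique k-mer anchors between two near-identical sequences
#'
#' Anchors are k-mers that occur exactly once in the query and exactly once
#' in the reference; the returned chain is the longest subsequence of
#' anchor matches that is strictly increasing in both coordinates (longest
#' increasing subsequence over reference positions after sorting by query
#' position), i.e. the maximal collinear backbone of the alignment. Both
#' sequences are assumed to be in the same rotation convention (rotate
#' plastomes to their LSC start first, see [detect_inverted_repeat()]).
#'
#' @param query,reference DNA strings or [plastome_record()]s.
#' @param k anchor k-mer size (default 31).
#' @return tibble with columns `qpos`, `rpos` (1-based starts), sorted by
#'   `qpos`, strictly increasing in both columns.
#' @export
anchor_chain <- function(query, reference, k = 31) {
  q <- as_sequence(query)
  r <- as_sequence(reference)
  qa <- unique_kmers(q, k)
  ra <- unique_kmers(r, k)
  anc <- dplyr::inner_join(qa, ra, by = "kmer") |>
    select(qpos = "pos.x", rpos = "pos.y") |>
    arrange(.data$qpos)
  if (nrow(anc) < 2) {
    abort("Fewer than 2 shared unique k-mer anchors: insufficient homology.",
          class = "karyohybrid_homology_error")
  }
  anc[lis_indices(anc$rpos), ]
}

as_sequence <- function(x) {
  if (inherits(x, "plastome_record")) x$sequence
  else if (inherits(x, "quadripartite")) x$record$sequence
  else toupper(as.character(x))
}

unique_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) {
    abort("Sequence shorter than k.", class = "karyohybrid_input_error")
  }
  starts <- seq_len(n - k + 1)
  km <- substring(s, starts, starts + k - 1)
  km[grepl("N", km, fixed = TRUE)] <- NA  # ambiguous bases never anchor
  tb <- tibble(kmer = km, pos = starts) |>
    filter(!is.na(.data$kmer)) |>
    dplyr::add_count(.data$kmer) |>
    filter(.data$n == 1L) |>
    select(-"n")
  tb
}

# indices of one longest strictly increasing subsequence (patience sorting)
lis_indices <- function(x) {
  m <- length(x)
  tails_val <- numeric(0)
  tails_idx <- integer(0)
  prev <- integer(m)
  for (i in seq_len(m)) {
    pos <- findInterval(x[i] - 0.5, tails_val) + 1L
    tails_val[pos] <- x[i]
    tails_idx[pos] <- i
    prev[i] <- if (pos > 1L) tails_idx[pos - 1L] else 0L
  }
  out <- integer(0)
  i <- tails_idx[length(tails_idx)]
  while (i > 0) {
    out <- c(i, out)
    i <- prev[i]
  }
  out
}

#' Call variants between two collinear plastomes
#'
#' Anchors the two sequences with [anchor_chain()], merges contiguous
#' anchors into exact-match blocks, and aligns each inter-block segment
#' pair globally (match +1, mismatch -1, N scored 0, gap of length L costs
#' 3 + L). Alignment columns become substitution, insertion and deletion
#' calls with 1-based positions on the reference; indels are left-aligned
#' (insertions anchored to the reference base they follow) and annotated
#' with the reference gene they fall in when features are available.
#'
#' @param query,reference [plastome_record()]s or DNA strings, in the same
#'   rotation convention.
#' @param k anchor k-mer size (default 31).
#' @return object of class `variant_set`: a tibble of calls (`ref_pos`,
#'   `kind`, `ref_allele`, `alt_allele`, `gene`) with attributes
#'   `reference_id`, `query_id`, `reference_seq`.
#' @export
call_variants <- function(query, reference, k = 31) {
  qs <- as_sequence(query)
  rs <- as_sequence(reference)
  qid <- record_id(query, "query")
  rid <- record_id(reference, "reference")
  chain <- anchor_chain(qs, rs, k)

  # merge anchors that continue the same exact diagonal into blocks
  dq <- diff(chain$qpos)
  dr <- diff(chain$rpos)
  newblock <- c(TRUE, !(dq == dr & dq <= k))
  bid <- cumsum(newblock)
  blocks <- tibble(qpos = chain$qpos, rpos = chain$rpos, bid = bid) |>
    group_by(.data$bid) |>
    summarise(q0 = min(.data$qpos), r0 = min(.data$rpos),
              len = max(.data$qpos) - min(.data$qpos) + k, .groups = "drop")

  # neighbouring blocks may overlap on one coordinate when an indel sits in
  # repetitive context (the same bases match on both sides); trim the later
  # block so segments between blocks are well-defined
  if (nrow(blocks) > 1) {
    keep <- rep(TRUE, nrow(blocks))
    qe <- blocks$q0[1] + blocks$len[1] - 1
    re <- blocks$r0[1] + blocks$len[1] - 1
    for (i in 2:nrow(blocks)) {
      delta <- max(0L, qe + 1L - blocks$q0[i], re + 1L - blocks$r0[i])
      if (delta >= blocks$len[i]) {
        keep[i] <- FALSE
        next
      }
      blocks$q0[i] <- blocks$q0[i] + delta
      blocks$r0[i] <- blocks$r0[i] + delta
      blocks$len[i] <- blocks$len[i] - delta
      qe <- blocks$q0[i] + blocks$len[i] - 1
      re <- blocks$r0[i] + blocks$len[i] - 1
    }
    blocks <- blocks[keep, ]
  }

  nb <- nrow(blocks)
  segs <- list()
  add_seg <- function(qa, qb, ra, rb) {
    qseg <- if (qb >= qa) substr(qs, qa, qb) else ""
    rseg <- if (rb >= ra) substr(rs, ra, rb) else ""
    if (nchar(qseg) > 0 || nchar(rseg) > 0) {
      segs[[length(segs) + 1]] <<- list(q = qseg, r = rseg, roffset = ra - 1L)
    }
  }
  add_seg(1L, blocks$q0[1] - 1L, 1L, blocks$r0[1] - 1L)
  if (nb > 1) {
    for (i in seq_len(nb - 1)) {
      add_seg(blocks$q0[i] + blocks$len[i], blocks$q0[i + 1] - 1L,
              blocks$r0[i] + blocks$len[i], blocks$r0[i + 1] - 1L)
    }
  }
  add_seg(blocks$q0[nb] + blocks$len[nb], nchar(qs),
          blocks$r0[nb] + blocks$len[nb], nchar(rs))

  calls <- purrr::map_dfr(segs, function(sg) align_segment(sg$q, sg$r, sg$roffset))
  calls <- normalize_calls(calls, rs)

  feats <- reference_features(reference)
  if (!is.null(feats) && nrow(calls) > 0) {
    calls$gene <- purrr::map_chr(calls$ref_pos, function(p) {
      hit <- feats$gene[feats$start <= p & feats$end >= p]
      if (length(hit)) hit[1] else NA_character_
    })
  } else if (nrow(calls) > 0) {
    calls$gene <- NA_character_
  }
  new_variant_set(calls, rid, qid, rs)
}

record_id <- function(x, default) {
  if (inherits(x, "plastome_record")) x$id
  else if (inherits(x, "quadripartite")) x$record$id
  else default
}

reference_features <- function(x) {
  if (inherits(x, "plastome_record")) x$features
  else if (inherits(x, "quadripartite")) x$record$features
  else NULL
}

new_variant_set <- function(calls, reference_id, query_id, reference_seq) {
  if (nrow(calls) == 0) {
    calls <- tibble(ref_pos = integer(), kind = character(),
                    ref_allele = character(), alt_allele = character(),
                    gene = character())
  }
  calls$ref_pos <- as.integer(calls$ref_pos)
  calls <- arrange(calls, .data$ref_pos, .data$kind)
  structure(calls, class = c("variant_set", class(tibble())),
            reference_id = reference_id, query_id = query_id,
            reference_seq = reference_seq)
}

# empty segments and mismatch-only segments shortcut the aligner
align_segment <- function(qseg, rseg, roffset) {
  empty <- tibble(ref_pos = integer(), kind = character(),
                  ref_allele = character(), alt_allele = character())
  if (nchar(qseg) == 0 && nchar(rseg) == 0) return(empty)
  if (nchar(rseg) == 0) {
    return(tibble(ref_pos = roffset, kind = "insertion",
                  ref_allele = "", alt_allele = qseg))
  }
  if (nchar(qseg) == 0) {
    return(tibble(ref_pos = roffset + 1L, kind = "deletion",
                  ref_allele = rseg, alt_allele = ""))
  }
  if (nchar(qseg) == nchar(rseg)) {
    qv <- strsplit(qseg, "")[[1]]
    rv <- strsplit(rseg, "")[[1]]
    if (nchar(qseg) <= 2 || sum(qv != rv) == nchar(qseg)) {
      mm <- which(qv != rv)
      return(tibble(ref_pos = roffset + mm, kind = "substitution",
                    ref_allele = rv[mm], alt_allele = qv[mm]))
    }
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  mat["N", ] <- 0
  mat[, "N"] <- 0
  al <- Biostrings::pairwiseAlignment(qseg, rseg, type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = 3, gapExtension = 1)
  qa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  ra <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  walk_alignment(qa, ra, roffset)
}

walk_alignment <- function(qa, ra, roffset) {
  calls <- list()
  rpos <- roffset
  i <- 1
  L <- length(qa)
  while (i <= L) {
    if (qa[i] != "-" && ra[i] != "-") {
      rpos <- rpos + 1
      if (qa[i] != ra[i]) {
        calls[[length(calls) + 1]] <- tibble(
          ref_pos = rpos, kind = "substitution",
          ref_allele = ra[i], alt_allele = qa[i])
      }
      i <- i + 1
    } else if (ra[i] == "-") {
      j <- i
      while (j <= L && ra[j] == "-") j <- j + 1
      calls[[length(calls) + 1]] <- tibble(
        ref_pos = rpos, kind = "insertion",
        ref_allele = "", alt_allele = paste(qa[i:(j - 1)], collapse = ""))
      i <- j
    } else {
      j <- i
      while (j <= L && qa[j] == "-") j <- j + 1
      calls[[length(calls) + 1]] <- tibble(
        ref_pos = rpos + 1L, kind = "deletion",
        ref_allele = paste(ra[i:(j - 1)], collapse = ""), alt_allele = "")
      rpos <- rpos + (j - i)
      i <- j
    }
  }
  bind_rows(calls) %||% tibble(ref_pos = integer(), kind = character(),
                               ref_allele = character(), alt_allele = character())
}

# shift indels to their leftmost equivalent placement on the reference
normalize_calls <- function(calls, ref_seq) {
  if (nrow(calls) == 0) return(calls)
  rv <- strsplit(ref_seq, "")[[1]]
  for (idx in which(calls$kind == "insertion")) {
    pos <- calls$ref_pos[idx]
    seqv <- strsplit(calls$alt_allele[idx], "")[[1]]
    while (pos >= 1 && rv[pos] == seqv[length(seqv)]) {
      seqv <- c(seqv[length(seqv)], seqv[-length(seqv)])
      pos <- pos - 1L
    }
    calls$ref_pos[idx] <- pos
    calls$alt_allele[idx] <- paste(seqv, collapse = "")
  }
  for (idx in which(calls$kind == "deletion")) {
    pos <- calls$ref_pos[idx]
    seqv <- strsplit(calls$ref_allele[idx], "")[[1]]
    while (pos > 1 && rv[pos - 1] == seqv[length(seqv)]) {
      seqv <- c(seqv[length(seqv)], seqv[-length(seqv)])
      pos <- pos - 1L
    }
    calls$ref_pos[idx] <- pos
    calls$ref_allele[idx] <- paste(seqv, collapse = "")
  }
  dplyr::distinct(calls)
}

#' @export
print.variant_set <- function(x, ...) {
  cat("Variant set: ", attr(x, "query_id"), " vs ", attr(x, "reference_id"),
      " (", sum(x$kind == "substitution"), " SNP, ",
      sum(x$kind == "insertion"), " ins, ",
      sum(x$kind == "deletion"), " del)\n", sep = "")
  NextMethod()
}

#' Per-category variant counts
#'
#' One-row summary in the style of a plastome variation table: SNP,
#' insertion ("Insert") and deletion ("Missing") counts, plus the number of
#' distinct genes carrying variants.
#'
#' @param x a `variant_set`.
#' @param ... unused.
#' @return tibble.
#' @method glance variant_set
#' @export
glance.variant_set <- function(x, ...) {
  tibble(query = attr(x, "query_id"), reference = attr(x, "reference_id"),
         snp = sum(x$kind == "substitution"),
         insert = sum(x$kind == "insertion"),
         missing = sum(x$kind == "deletion"),
         genes_hit = dplyr::n_distinct(x$gene[!is.na(x$gene)]))
}

#' Count shared substitution sites between two variant sets
#'
#' Two taxa share a SNP site when they carry the same alternate allele at
#' the same reference position: the count of substitution calls identical
#' in (position, reference allele, alternate allele). Both sets must have
#' been called against the same reference.
#'
#' @param a,b `variant_set`s with a common reference.
#' @return integer count.
#' @export
shared_snp_sites <- function(a, b) {
  if (!identical(attr(a, "reference_id"), attr(b, "reference_id"))) {
    abort("Variant sets were called against different references.",
          class = "karyohybrid_reference_error")
  }
  sa <- dplyr::filter(tibble::as_tibble(a), .data$kind == "substitution")
  sb <- dplyr::filter(tibble::as_tibble(b), .data$kind == "substitution")
  nrow(dplyr::inner_join(sa, sb, by = c("ref_pos", "ref_allele", "alt_allele")))
}

#' Symmetric difference size of two variant sets
#'
#' Number of calls (any kind, keyed by position/kind/alleles) present in
#' exactly one of the two sets; the tie-breaker used by maternal ranking.
#'
#' @param a,b `variant_set`s with a common reference.
#' @return integer.
#' @export
variant_symdiff <- function(a, b) {
  key <- c("ref_pos", "kind", "ref_allele", "alt_allele")
  ta <- dplyr::distinct(tibble::as_tibble(a)[key])
  tb <- dplyr::distinct(tibble::as_tibble(b)[key])
  both <- nrow(dplyr::inner_join(ta, tb, by = key))
  (nrow(ta) - both) + (nrow(tb) - both)
}

#' Write a minimal VCF
#'
#' VCF v4.2 with CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO columns; indels are
#' padded with the preceding reference base per VCF convention; INFO
#' carries `TYPE=` and, when known, `GENE=`.
#'
#' @param x a `variant_set`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(x, path) {
  ref_seq <- attr(x, "reference_seq")
  chrom <- attr(x, "reference_id")
  rows <- purrr::pmap_chr(tibble::as_tibble(x), function(ref_pos, kind, ref_allele,
                                                         alt_allele, gene, ...) {
    if (kind == "substitution") {
      pos <- ref_pos; ref <- ref_allele; alt <- alt_allele
    } else if (kind == "insertion") {
      pos <- max(1L, ref_pos)
      pad <- substr(ref_seq, pos, pos)
      ref <- pad; alt <- paste0(pad, alt_allele)
    } else {
      pos <- max(1L, ref_pos - 1L)
      pad <- substr(ref_seq, pos, pos)
      ref <- paste0(pad, ref_allele); alt <- pad
    }
    info <- paste0("TYPE=", kind,
                   if (!is.na(gene)) paste0(";GENE=", gene) else "")
    paste(chrom, pos, ".", ref, alt, ".", "PASS", info, sep = "\t")
  })
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chrom, nchar(ref_seq)),
    "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"Variant type\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Reference gene\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    rows), path)
  invisible(path)
}

#' Scan a sequence for simple sequence repeats (SSRs)
#'
#' MISA-style detection of maximal perfect tandem repeats of 1-6 bp motifs
#' meeting per-unit-size minimum repeat counts. Motifs that are themselves
#' repeats of a shorter unit (e.g. "AA", "ATAT") are reported at the
#' shorter unit size only. Motifs are reported as observed, not
#' cycle-canonicalized. Loci whose gap to a neighbour is at most
#' `compound_gap` are flagged compound.
#'
#' @param x a [plastome_record()] or DNA string.
#' @param thresholds minimum repeat count for unit sizes 1-6; the default
#'   `c(10, 5, 4, 3, 3, 3)` admits the mononucleotide (A)10 and
#'   pentanucleotide (GGAAA)3 loci typical of plastome catalogues.
#' @param compound_gap maximum gap (bp) between neighbouring loci for the
#'   compound flag (default 100).
#' @return tibble with columns `start` (1-based), `motif`, `repeats`,
#'   `unit_size`, `length`, `compound`, sorted by `start`.
#' @export
find_ssrs <- function(x, thresholds = c(10, 5, 4, 3, 3, 3), compound_gap = 100) {
  s <- as_sequence(x)
  if (length(thresholds) != 6 || any(thresholds < 1)) {
    abort("`thresholds` must give minimum repeats for unit sizes 1-6.",
          class = "karyohybrid_input_error")
  }
  loci <- purrr::map_dfr(1:6, function(u) {
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", u, thresholds[u] - 1L)
    m <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (m[1] == -1) return(tibble())
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    motifs <- substring(s, starts, starts + u - 1)
    keep <- purrr::map_lgl(motifs, is_primitive_motif)
    tibble(start = starts[keep], motif = motifs[keep],
           repeats = (lens %/% u)[keep], unit_size = u,
           length = lens[keep])
  })
  if (nrow(loci) == 0) {
    return(tibble(start = integer(), motif = character(), repeats = integer(),
                  unit_size = integer(), length = integer(), compound = logical()))
  }
  loci <- arrange(loci, .data$start, .data$unit_size)
  gap_prev <- c(Inf, loci$start[-1] - (loci$start[-nrow(loci)] + loci$length[-nrow(loci)] - 1) - 1)
  gap_next <- c(gap_prev[-1], Inf)
  loci$compound <- gap_prev <= compound_gap | gap_next <= compound_gap
  loci
}

# TRUE when the motif is not a whole-number repeat of a shorter unit
is_primitive_motif <- function(motif) {
  u <- nchar(motif)
  if (u == 1) return(TRUE)
  for (d in seq_len(u - 1)) {
    if (u %% d == 0 &&
        motif == strrep(substr(motif, 1, d), u %/% d)) {
      return(FALSE)
    }
  }
  TRUE
}

#' Compare two SSR catalogues
#'
#' Loci are matched one-to-one by motif and approximate start position
#' (within `pos_tol` bp) and classified as `identical` (same repeat
#' count), `length_changed` (same locus, different repeat count), or
#' private to either catalogue.
#'
#' @param a,b SSR tibbles from [find_ssrs()].
#' @param pos_tol start-position matching tolerance in bp (default 50;
#'   upstream indels shift downstream coordinates slightly).
#' @return tibble with columns `motif`, `start_a`, `start_b`, `repeats_a`,
#'   `repeats_b`, `status`.
#' @export
diff_ssr_catalogs <- function(a, b, pos_tol = 50) {
  a <- mutate(as_tibble(a), .ia = row_number())
  b <- mutate(as_tibble(b), .ib = row_number())
  used_b <- rep(FALSE, nrow(b))
  rows <- purrr::map_dfr(seq_len(nrow(a)), function(i) {
    cand <- which(!used_b & b$motif == a$motif[i] &
                    abs(b$start - a$start[i]) <= pos_tol)
    if (length(cand) == 0) {
      return(tibble(motif = a$motif[i], start_a = a$start[i],
                    start_b = NA_integer_, repeats_a = a$repeats[i],
                    repeats_b = NA_integer_, status = "private_a"))
    }
    j <- cand[which.min(abs(b$start[cand] - a$start[i]))]
    used_b[j] <<- TRUE
    tibble(motif = a$motif[i], start_a = a$start[i], start_b = b$start[j],
           repeats_a = a$repeats[i], repeats_b = b$repeats[j],
           status = if (a$repeats[i] == b$repeats[j]) "identical" else "length_changed")
  })
  leftover <- b[!used_b, ]
  if (nrow(leftover) > 0) {
    rows <- bind_rows(rows, tibble(
      motif = leftover$motif, start_a = NA_integer_, start_b = leftover$start,
      repeats_a = NA_integer_, repeats_b = leftover$repeats,
      status = "private_b"))
  }
  arrange(rows, dplyr::coalesce(.data$start_a, .data$start_b))
}
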