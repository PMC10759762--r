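#' @importFrom Biostrings DNAString reverseComplement
NULL

revcomp <- function(s) {
  as.character(reverseComplement(DNAString(s)))
}

rotate_left <- function(s, r) {
  n <- nchar(s)
  r <- r %% n
  if (r == 0) return(s)
  paste0(substr(s, r + 1, n), substr(s, 1, r))
}

# 1-based position after rotating the sequence left by r
pos_after_rot <- function(p, n, r) ((p - 1 - r) %% n) + 1

#' Construct a plastome record
#'
#' @param sequence DNA string over A/C/G/T/N (upper-cased on input).
#' @param id record label.
#' @param features optional tibble with columns `gene`, `strand` (`"+"` or
#'   `"-"`), `start`, `end`, `part` (1-based closed intervals; multi-part
#'   genes, e.g. GenBank `join(...)`, use one row per part).
#' @return object of class `plastome_record`.
#' @export
plastome_record <- function(sequence, id = "plastome", features = NULL) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0) abort("Empty sequence.", class = "karyohybrid_format_error")
  if (grepl("[^ACGTN]", sequence)) {
    abort("Sequence must be over A, C, G, T, N.", class = "karyohybrid_format_error")
  }
  if (!is.null(features)) {
    features <- as_tibble(features)
    need <- c("gene", "strand", "start", "end")
    if (!all(need %in% names(features))) {
      abort("Features need columns gene, strand, start, end.",
            class = "karyohybrid_format_error")
    }
    if (!"part" %in% names(features)) features$part <- 1L
    # distinct copies of a gene (e.g. the duplicated IR genes) are separate
    # feature entries; parts of one join() share a feature_id
    if (!"feature_id" %in% names(features)) {
      features$feature_id <- cumsum(features$part == 1L)
    }
    if (any(features$start < 1 | features$end > n | features$start > features$end)) {
      abort("Feature intervals must lie within [1, length].",
            class = "karyohybrid_format_error")
    }
  }
  structure(list(id = id, sequence = sequence, length = n, features = features),
            class = "plastome_record")
}

#' @export
print.plastome_record <- function(x, ...) {
  cat("Plastome record '", x$id, "': ", x$length, " bp, ",
      if (is.null(x$features)) "no features"
      else paste0(length(unique(x$features$gene)), " genes"), "\n", sep = "")
  invisible(x)
}

#' Read a plastome from FASTA or GenBank flat file
#'
#' FASTA reading goes through Biostrings; GenBank flat files are parsed for
#' the LOCUS id, the ORIGIN sequence and `gene` features (falling back to
#' CDS if the file annotates no `gene` keys), preserving strand and
#' `join(...)` multi-interval locations.
#'
#' @param path input file.
#' @param format `"auto"` (by extension/content), `"fasta"` or `"genbank"`.
#' @return a [plastome_record()].
#' @export
read_plastome <- function(path, format = c("auto", "fasta", "genbank")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("No such file: ", path), class = "karyohybrid_input_error")
  }
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (startsWith(first, ">")) "fasta" else "genbank"
  }
  if (format == "fasta") {
    ss <- Biostrings::readDNAStringSet(path)
    if (length(ss) == 0 || Biostrings::width(ss)[1] == 0) {
      abort("Empty FASTA record.", class = "karyohybrid_format_error")
    }
    return(plastome_record(as.character(ss[[1]]),
                           id = strsplit(names(ss)[1], "\\s+")[[1]][1]))
  }
  read_genbank(path)
}

read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  id <- if (length(locus)) strsplit(locus[1], "\\s+")[[1]][2] else "genbank"
  oi <- grep("^ORIGIN", lines)
  if (length(oi) == 0) {
    abort("GenBank record has no ORIGIN section.", class = "karyohybrid_format_error")
  }
  seq_lines <- lines[(oi[1] + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0) {
    abort("GenBank record has an empty sequence.", class = "karyohybrid_format_error")
  }
  fi <- grep("^FEATURES", lines)
  features <- NULL
  if (length(fi)) {
    block <- lines[(fi[1] + 1):(oi[1] - 1)]
    features <- parse_genbank_features(block)
  }
  plastome_record(sequence, id = id, features = features)
}

# Parse the FEATURES table: feature keys start at column 6, qualifiers
# with '/'; locations may continue over lines.
parse_genbank_features <- function(block) {
  is_key <- grepl("^ {5}\\S", block)
  idx <- which(is_key)
  if (length(idx) == 0) return(NULL)
  ends <- c(idx[-1] - 1L, length(block))
  feats <- purrr::map2(idx, ends, function(a, b) {
    key <- stringr::str_trim(substr(block[a], 6, 20))
    rest <- stringr::str_trim(substr(block[a], 21, nchar(block[a])))
    body <- stringr::str_trim(block[seq(a, b)][-1])
    # location may continue until the first qualifier line
    qual_start <- which(startsWith(body, "/"))[1]
    loc_extra <- if (is.na(qual_start)) body else body[seq_len(qual_start - 1)]
    loc <- paste0(rest, paste(loc_extra, collapse = ""))
    quals <- if (is.na(qual_start)) character() else body[qual_start:length(body)]
    gene <- stringr::str_match(quals, "^/gene=\"?([^\"]+)\"?")[, 2]
    gene <- gene[!is.na(gene)][1]
    if (is.na(gene) || is.null(gene)) {
      lt <- stringr::str_match(quals, "^/locus_tag=\"?([^\"]+)\"?")[, 2]
      gene <- lt[!is.na(lt)][1]
    }
    list(key = key, gene = gene, loc = loc)
  })
  keys <- purrr::map_chr(feats, "key")
  use <- feats[keys == "gene"]
  if (length(use) == 0) use <- feats[keys == "CDS"]
  if (length(use) == 0) return(NULL)
  purrr::imap_dfr(use, function(f, fid) {
    loc <- gsub("[<>]", "", f$loc)
    strand <- if (grepl("complement", loc)) "-" else "+"
    ivs <- stringr::str_match_all(loc, "(\\d+)\\.\\.(\\d+)")[[1]]
    if (nrow(ivs) == 0) {
      single <- stringr::str_match(loc, "^(\\d+)$")[, 2]
      if (is.na(single)) return(NULL)
      ivs <- cbind(NA, single, single)
    }
    tibble(gene = f$gene %||% NA_character_, strand = strand,
           start = as.integer(ivs[, 2]), end = as.integer(ivs[, 3]),
           part = seq_len(nrow(ivs)), feature_id = fid)
  })
}

#' Write a minimal GenBank flat file
#'
#' LOCUS/FEATURES/ORIGIN sections with `gene` features only; enough for
#' [read_plastome()] round-trips and for exchanging synthetic fixtures.
#'
#' @param record a [plastome_record()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_genbank <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     circular PLN",
                     record$id, record$length), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  if (!is.null(record$features)) {
    feats <- split(record$features, record$features$gene)
    for (g in names(feats)) {
      f <- arrange(feats[[g]], .data$part)
      ivs <- paste0(f$start, "..", f$end)
      loc <- if (nrow(f) > 1) paste0("join(", paste(ivs, collapse = ","), ")") else ivs
      if (f$strand[1] == "-") loc <- paste0("complement(", loc, ")")
      writeLines(sprintf("     gene            %s", loc), con)
      writeLines(sprintf("                     /gene=\"%s\"", g), con)
    }
  }
  writeLines("ORIGIN", con)
  s <- record$sequence
  for (i in seq(1, nchar(s), by = 60)) {
    chunk <- substr(s, i, min(i + 59, nchar(s)))
    parts <- substring(chunk, seq(1, nchar(chunk), 10),
                       pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", i, tolower(paste(parts, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

# Longest exact reverse-complement repeat pair on a *linear* string.
# Seeds: k-mers shared between s and revcomp(s) (each occurring <= 4 times
# per side); an exact inverted repeat lies on an anti-diagonal i + e = c
# (i: forward position, e: end of the reverse-complement partner), which is
# scanned base-wise for its longest true run.
find_ir_linear <- function(s, min_ir, k) {
  n <- nchar(s)
  if (n < 2 * k) return(NULL)
  starts <- seq_len(n - k + 1)
  kms <- substring(s, starts, starts + k - 1)
  rc <- revcomp(s)
  rkms <- substring(rc, starts, starts + k - 1)
  fwd <- tibble(kmer = kms, i = starts) |>
    dplyr::add_count(.data$kmer) |>
    filter(.data$n <= 4) |> select(-"n")
  rev <- tibble(kmer = rkms, p = starts) |>
    dplyr::add_count(.data$kmer) |>
    filter(.data$n <= 4) |> select(-"n")
  seeds <- dplyr::inner_join(fwd, rev, by = "kmer", relationship = "many-to-many")
  if (nrow(seeds) == 0) return(NULL)
  # rc position p mirrors the segment of s ending at e = n - p + 1; a seed
  # pairs base i+t with e-t for t in 0..k-1, so c = i + e is constant
  seeds$c <- seeds$i + (n - seeds$p + 1)
  diag_tab <- sort(table(seeds$c), decreasing = TRUE)
  cand <- as.integer(names(diag_tab))[seq_len(min(20, length(diag_tab)))]
  sv <- strsplit(s, "", fixed = TRUE)[[1]]
  csv <- strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]
  best <- NULL
  for (cc in cand) {
    i_lo <- max(1L, cc - n)
    i_hi <- (cc - 1L) %/% 2L
    if (i_hi < i_lo) next
    ii <- i_lo:i_hi
    m <- sv[ii] == csv[cc - ii] & sv[ii] != "N"
    r <- rle(m)
    ends_run <- cumsum(r$lengths)
    starts_run <- ends_run - r$lengths + 1L
    ok <- which(r$values & r$lengths >= min_ir)
    for (j in ok) {
      len <- r$lengths[j]
      if (is.null(best) || len > best$len) {
        a <- ii[starts_run[j]]
        b <- ii[ends_run[j]]
        best <- list(len = len, a = a, b = b, c = cc)
      }
    }
  }
  best
}

#' Detect the inverted repeat and partition a plastome
#'
#' Finds the maximal pair of disjoint exact reverse-complement repeats on
#' the circular sequence (k-mer seeding against the reverse complement plus
#' exact base-wise extension along the seed anti-diagonal; circularity is
#' handled by retrying the scan at four rotations of the origin), then
#' partitions the genome into LSC, IRb, SSC and IRa: the longer single-copy
#' gap is the LSC, and coordinates are rotated so it starts at position 1.
#' IRb is the IR copy immediately after the LSC in the rotated orientation.
#'
#' Strand orientation: when features include *rps19*, the orientation that
#' puts an *rps19* copy across (or nearest to) the LSC-IRb junction is
#' chosen, matching the conventional junction layout; otherwise the strand
#' giving the lexicographically smaller rotated sequence is used, so the
#' result is reproducible for any input orientation.
#'
#' @param record a [plastome_record()].
#' @param min_ir minimum IR length in bp (default 1000); sequences shorter
#'   than `4 * min_ir` are rejected.
#' @param k seed k-mer size (default 25).
#' @return object of class `quadripartite`: list with `record` (the
#'   rotated, strand-canonicalized [plastome_record()] with remapped
#'   features), `regions` (tibble: region, start, end, length),
#'   `ir_length`, `flipped`.
#' @export
detect_inverted_repeat <- function(record, min_ir = 1000, k = 25) {
  s0 <- record$sequence
  n <- record$length
  if (n < 4 * min_ir) {
    abort(sprintf("Sequence (%d bp) shorter than 4 x min_ir (%d bp).", n, 4 * min_ir),
          class = "karyohybrid_input_error")
  }
  offsets <- unique(c(0L, n %/% 4L, n %/% 2L, (3L * n) %/% 4L))
  best <- NULL
  for (t in offsets) {
    hit <- find_ir_linear(rotate_left(s0, t), min_ir, k)
    if (!is.null(hit) && (is.null(best) || hit$len > best$len)) {
      best <- c(hit, list(t = t))
    }
  }
  if (is.null(best)) {
    abort(sprintf("No inverted repeat of >= %d bp found: not a quadripartite genome?",
                  min_ir),
          class = "karyohybrid_no_ir_error")
  }
  st <- rotate_left(s0, best$t)
  a <- best$a; b <- best$b; cc <- best$c
  ir_len <- best$len
  # copies in the trial frame: ir1 = [a, b], ir2 = [cc - b, cc - a]
  g1_start <- b + 1; g1_end <- cc - b - 1          # between the copies
  g1 <- substr(st, g1_start, g1_end)
  g2 <- paste0(if (cc - a < n) substr(st, cc - a + 1, n) else "",
               if (a > 1) substr(st, 1, a - 1) else "")
  ir1 <- substr(st, a, b)
  ir2 <- substr(st, cc - b, cc - a)
  if (nchar(g1) >= nchar(g2)) {
    lsc <- g1; ssc <- g2; irb <- ir2; ira <- ir1
    r2 <- b                       # canonical start = g1_start in trial frame
  } else {
    lsc <- g2; ssc <- g1; irb <- ir1; ira <- ir2
    r2 <- (cc - a) %% n           # canonical start = cc - a + 1
  }
  canon <- paste0(lsc, irb, ssc, ira)
  Ll <- nchar(lsc); Ls <- nchar(ssc)
  stopifnot(nchar(canon) == n)

  map_unflipped <- function(p) pos_after_rot(pos_after_rot(p, n, best$t), n, r2)
  map_flipped <- function(p) pos_after_rot(n - map_unflipped(p) + 1, n, n - Ll)

  canon_f <- paste0(revcomp(lsc), revcomp(ira), revcomp(ssc), revcomp(irb))

  flipped <- choose_orientation(record$features, map_unflipped, map_flipped,
                                canon, canon_f, Ll, n)
  seq_out <- if (flipped) canon_f else canon
  mapper <- if (flipped) map_flipped else map_unflipped
  feats <- remap_features(record$features, mapper, n, flipped)

  regions <- tibble(
    region = c("LSC", "IRb", "SSC", "IRa"),
    start = c(1L, Ll + 1L, Ll + ir_len + 1L, Ll + ir_len + Ls + 1L),
    end = c(Ll, Ll + ir_len, Ll + ir_len + Ls, n),
    length = c(Ll, ir_len, Ls, ir_len)
  )
  structure(list(
    record = plastome_record(seq_out, id = record$id, features = feats),
    regions = regions,
    ir_length = ir_len,
    flipped = flipped
  ), class = "quadripartite")
}

choose_orientation <- function(features, map_u, map_f, canon, canon_f, Ll, n) {
  if (!is.null(features) && any(grepl("rps19", features$gene, ignore.case = TRUE))) {
    rps <- features[grepl("rps19", features$gene, ignore.case = TRUE), ]
    # prefer the orientation where an rps19 copy straddles the LSC-IRb
    # junction (the conventional layout); fall back to junction proximity.
    # a mapped interval is a circular arc of the gene's length starting at
    # the image of its 5'-most original coordinate (its end, when flipped)
    spans <- function(mapper, flipped) {
      purrr::some(seq_len(nrow(rps)), function(i) {
        L <- rps$end[i] - rps$start[i] + 1
        a <- mapper(if (flipped) rps$end[i] else rps$start[i])
        ((Ll - a) %% n) <= L - 2  # junction between Ll and Ll+1 inside arc
      })
    }
    su <- spans(map_u, FALSE); sf <- spans(map_f, TRUE)
    if (su != sf) return(sf)
    jdist <- function(mapper) {
      pos <- c(purrr::map_dbl(rps$start, mapper), purrr::map_dbl(rps$end, mapper))
      min(abs(pos - (Ll + 0.5)))
    }
    return(jdist(map_f) < jdist(map_u))
  }
  canon_f < canon
}

remap_features <- function(features, mapper, n, flipped) {
  if (is.null(features)) return(NULL)
  rows <- purrr::pmap_dfr(features,
                          function(gene, strand, start, end, part, feature_id, ...) {
    ms <- mapper(start); me <- mapper(end)
    if (flipped) {
      tmp <- ms; ms <- me; me <- tmp
      strand <- if (strand == "+") "-" else "+"
    }
    if (ms <= me) {
      tibble(gene = gene, strand = strand, start = ms, end = me,
             part = as.numeric(part), feature_id = feature_id)
    } else {  # interval crosses the new origin: split like a join()
      tibble(gene = gene, strand = strand,
             start = c(ms, 1L), end = c(n, me), part = c(part, part + 0.5),
             feature_id = feature_id)
    }
  })
  rows |>
    group_by(.data$feature_id) |>
    arrange(.data$part, .by_group = TRUE) |>
    mutate(part = row_number()) |>
    ungroup()
}

#' @export
print.quadripartite <- function(x, ...) {
  cat("Quadripartite plastome '", x$record$id, "' (", x$record$length, " bp, IR ",
      x$ir_length, " bp)\n", sep = "")
  print(x$regions)
  invisible(x)
}

#' @method tidy quadripartite
#' @export
tidy.quadripartite <- function(x, ...) x$regions

#' @method glance quadripartite
#' @export
glance.quadripartite <- function(x, ...) {
  tibble(id = x$record$id, length = x$record$length,
         lsc = x$regions$length[1], irb = x$regions$length[2],
         ssc = x$regions$length[3], ira = x$regions$length[4],
         gc_pct = gc_content(x$record), flipped = x$flipped)
}

#' GC content of a sequence
#'
#' Percent (G + C) / (A + C + G + T); ambiguous bases (N) are excluded from
#' the denominator. Reported to two decimals.
#'
#' @param x a [plastome_record()] or DNA string.
#' @return percent, rounded to 2 decimals.
#' @export
gc_content <- function(x) {
  s <- if (inherits(x, "plastome_record")) x$sequence else toupper(x)
  if (nchar(s) == 0) abort("Empty sequence.", class = "karyohybrid_input_error")
  counts <- Biostrings::letterFrequency(DNAString(s), c("A", "C", "G", "T"))
  round(100 * sum(counts[c("C", "G")]) / sum(counts), 2)
}

#' Report genes at the quadripartite junctions
#'
#' For each of the four junctions (LSC-IRb, IRb-SSC, SSC-IRa, IRa-LSC),
#' reports the gene spanning it with the number of bases on each side
#' (a gene ending exactly at the junction counts as spanning with a zero
#' far side); when no gene spans a junction, the nearest gene on each side
#' within the search window is reported with its distance from the border.
#'
#' @param x a `quadripartite` (from [detect_inverted_repeat()]) whose
#'   record carries features.
#' @param window nearest-gene search window, bp each side (default 1000).
#' @return tibble with columns `junction`, `gene`, `relation`
#'   (`"spans"`, `"nearest_left"`, `"nearest_right"`), `left_bp`,
#'   `right_bp`, `distance_bp`.
#' @export
junction_genes <- function(x, window = 1000) {
  if (!inherits(x, "quadripartite")) {
    abort("`x` must be a quadripartite partition.", class = "karyohybrid_input_error")
  }
  features <- x$record$features
  if (is.null(features) || nrow(features) == 0) {
    abort("Junction reporting needs gene features.", class = "karyohybrid_input_error")
  }
  n <- x$record$length
  reg <- x$regions
  junctions <- tibble(
    junction = c("LSC-IRb", "IRb-SSC", "SSC-IRa", "IRa-LSC"),
    left_end = c(reg$end[1], reg$end[2], reg$end[3], reg$end[4])
  )
  half <- n %/% 2L
  purrr::map_dfr(seq_len(nrow(junctions)), function(ji) {
    J <- junctions$left_end[ji]
    q <- function(p) ((p - 1 - J + half) %% n) + 1  # junction sits between q=half, half+1
    # per gene COPY (feature_id), so duplicated IR genes stay distinct;
    # parts that wrap the point opposite the junction are ~n/2 away and dropped
    per_gene <- features |>
      mutate(qs = q(.data$start), qe = q(.data$end)) |>
      filter(.data$qs <= .data$qe) |>
      group_by(.data$feature_id) |>
      summarise(
        gene = .data$gene[1],
        left_bp = sum(pmax(0, pmin(.data$qe, half) - pmin(.data$qs, half + 1) + 1)),
        total = sum(.data$end - .data$start + 1),
        qmin = min(.data$qs), qmax = max(.data$qe),
        .groups = "drop") |>
      mutate(right_bp = .data$total - .data$left_bp)
    spans <- per_gene |>
      filter((.data$left_bp > 0 & .data$right_bp > 0) |
               .data$qmax == half | .data$qmin == half + 1) |>
      arrange(desc(pmin(.data$left_bp, .data$right_bp)))
    if (nrow(spans) > 0) {
      g <- spans[1, ]
      return(tibble(junction = junctions$junction[ji], gene = g$gene,
                    relation = "spans", left_bp = g$left_bp,
                    right_bp = g$right_bp, distance_bp = 0L))
    }
    lefts <- per_gene |> filter(.data$qmax < half, half - .data$qmax <= window) |>
      arrange(desc(.data$qmax))
    rights <- per_gene |> filter(.data$qmin > half + 1, .data$qmin - half - 1 <= window) |>
      arrange(.data$qmin)
    out <- tibble()
    if (nrow(lefts) > 0) {
      out <- bind_rows(out, tibble(
        junction = junctions$junction[ji], gene = lefts$gene[1],
        relation = "nearest_left", left_bp = NA_integer_, right_bp = NA_integer_,
        distance_bp = as.integer(half - lefts$qmax[1])))
    }
    if (nrow(rights) > 0) {
      out <- bind_rows(out, tibble(
        junction = junctions$junction[ji], gene = rights$gene[1],
        relation = "nearest_right", left_bp = NA_integer_, right_bp = NA_integer_,
        distance_bp = as.integer(rights$qmin[1] - half - 1)))
    }
    out
  })
}

#' Write a quadripartite partition bundle
#'
#' JSON partition (region coordinates, IR length, GC) and, when features
#' are present, a TSV junction-gene table.
#'
#' @param x a `quadripartite`.
#' @param dir output directory.
#' @return invisibly, paths written.
#' @export
write_quadripartite <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jpath <- file.path(dir, paste0(x$record$id, "_partition.json"))
  jsonlite::write_json(list(
    id = x$record$id, length = x$record$length, ir_length = x$ir_length,
    gc_pct = gc_content(x$record),
    regions = purrr::transpose(as.list(x$regions))
  ), jpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- jpath
  if (!is.null(x$record$features)) {
    tpath <- file.path(dir, paste0(x$record$id, "_junctions.tsv"))
    readr::write_tsv(junction_genes(x), tpath)
    paths <- c(paths, tpath)
  }
  invisible(paths)
}
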