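# Independent oracles used to cross-check the implementation. These are
# deliberately naive re-derivations from the definitions, sharing no code
# with the package internals.

# O(n^3) UPGMA: clusters as index sets, cluster distance = arithmetic mean
# of all member pairwise distances; returns sorted merge distances and the
# cophenetic matrix.
naive_upgma <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  clusters <- lapply(seq_len(n), identity)
  coph <- matrix(0, n, n)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        dij <- mean(dm[clusters[[i]], clusters[[j]], drop = FALSE])
        if (dij < best[1]) best <- c(dij, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    heights <- c(heights, best[1])
    for (a in clusters[[i]]) for (b in clusters[[j]]) {
      coph[a, b] <- coph[b, a] <- best[1]
    }
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  list(merge_distances = heights, cophenetic = coph)
}

# brute-force SSR scan: for every start and unit size, extend the perfect
# tandem run directly, keep maximal primitive-motif runs meeting the
# threshold (maximality: not extendable left or right by a full period)
ssr_oracle <- function(s, thresholds = c(10, 5, 4, 3, 3, 3)) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  out <- list()
  for (u in 1:6) {
    i <- 1
    while (i + u * thresholds[u] - 1 <= n) {
      motif <- paste(chars[i:(i + u - 1)], collapse = "")
      # primitive motif check
      prim <- TRUE
      for (d in seq_len(u - 1)) {
        if (u %% d == 0 &&
            motif == strrep(paste(chars[i:(i + d - 1)], collapse = ""), u / d)) {
          prim <- FALSE
          break
        }
      }
      if (prim && !grepl("[^ACGT]", motif)) {
        reps <- 1
        while (i + (reps + 1) * u - 1 <= n &&
               all(chars[(i + reps * u):(i + (reps + 1) * u - 1)] ==
                     chars[i:(i + u - 1)])) {
          reps <- reps + 1
        }
        left_ext <- i - u >= 1 &&
          all(chars[(i - u):(i - 1)] == chars[i:(i + u - 1)])
        if (reps >= thresholds[u] && !left_ext) {
          out[[length(out) + 1]] <- data.frame(
            start = i, motif = motif, repeats = reps, unit_size = u)
          i <- i + reps * u - u  # continue past the run (allow phase overlaps)
          next
        }
      }
      i <- i + 1
    }
  }
  df <- do.call(rbind, out)
  if (is.null(df)) {
    return(data.frame(start = integer(), motif = character(),
                      repeats = integer(), unit_size = integer()))
  }
  df <- df[order(df$start, df$unit_size), ]
  rownames(df) <- NULL
  df
}

# independent parent-pair screen: counts parsed with a local regex parser,
# consistency = per-type equality of observed and halved-parent sums
oracle_screen_pairs <- function(observed_formula, panel_formulas) {
  parse_counts <- function(f) {
    terms <- regmatches(f, gregexpr("\\d+\\s*(sm|st|M|m|t|T)", f))[[1]]
    counts <- c(M = 0, m = 0, sm = 0, st = 0, t = 0, T = 0)
    for (tm in terms) {
      m <- regmatches(tm, regexec("(\\d+)\\s*(sm|st|M|m|t|T)", tm))[[1]]
      counts[m[3]] <- counts[m[3]] + as.integer(m[2])
    }
    counts
  }
  # drop the leading "2n = [2x =] NN =" before term extraction
  strip <- function(f) sub("^\\s*2n\\s*=\\s*(\\d+x\\s*=\\s*)?\\d+\\s*=", "", f)
  obs <- parse_counts(strip(observed_formula))
  taxa <- names(panel_formulas)
  hits <- list()
  for (i in seq_along(taxa)) {
    for (j in i:length(taxa)) {
      ca <- parse_counts(strip(panel_formulas[[i]]))
      cb <- parse_counts(strip(panel_formulas[[j]]))
      if (any(ca %% 2 != 0) || any(cb %% 2 != 0)) next
      if (all(ca / 2 + cb / 2 == obs)) {
        hits[[length(hits) + 1]] <- sort(c(taxa[i], taxa[j]))
      }
    }
  }
  hits
}

random_counts <- function(max_per_type = 8) {
  k <- sample(1:4, 1)
  types <- sample(c("M", "m", "sm", "st", "t", "T"), k)
  stats::setNames(sample(1:max_per_type, k, replace = TRUE), types)
}

random_balanced_counts <- function(max_pairs_per_type = 4) {
  k <- sample(1:4, 1)
  types <- sample(c("M", "m", "sm", "st", "t", "T"), k)
  stats::setNames(2L * sample(1:max_pairs_per_type, k, replace = TRUE), types)
}

random_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
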