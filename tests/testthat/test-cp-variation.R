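test_that("anchor chains tile identical sequences and break around a substitution", {
  withr::with_seed(41, s <- random_dna_string(500))
  ch <- anchor_chain(s, s, k = 31)
  expect_equal(nrow(ch), 500 - 31 + 1)
  expect_equal(ch$qpos, ch$rpos)
  # one substitution at p destroys the ~2k-1 anchors overlapping it
  p <- 250
  alt <- setdiff(c("A", "C", "G", "T"), substr(s, p, p))[1]
  q <- s
  substr(q, p, p) <- alt
  ch2 <- anchor_chain(q, s, k = 31)
  gap <- setdiff(ch$rpos, ch2$rpos)
  expect_equal(sort(gap), (p - 30):p)
  withr::with_seed(42, {
    a <- random_dna_string(500)
    b <- random_dna_string(500)
  })
  expect_error(anchor_chain(a, b, k = 31),
               class = "karyohybrid_homology_error")
})

test_that("variant calling is empty on identical sequences and exact on planted edits", {
  rec <- simulate_plastome(plastome_sim_spec(), seed = 6)
  expect_equal(nrow(call_variants(rec, rec)), 0)
  for (s in c(1, 7, 19)) {
    child <- derive_maternal_offspring(rec, n_subs = 5, n_indels = 2,
                                       seed = s, id = "child")
    ed <- attr(child, "edits")
    vs <- tibble::as_tibble(call_variants(child, rec))
    expect_equal(nrow(vs), nrow(ed))
    subs <- vs[vs$kind == "substitution", ]
    planted <- ed[ed$kind == "substitution", ]
    expect_equal(sort(subs$ref_pos), sort(planted$parent_pos))
    expect_equal(subs$alt_allele[order(subs$ref_pos)],
                 planted$alt[order(planted$parent_pos)])
    # indels recovered in kind and (left-aligned) position
    for (k in c("insertion", "deletion")) {
      got <- vs[vs$kind == k, ]
      want <- ed[ed$kind == k, ]
      expect_equal(nrow(got), nrow(want))
      if (nrow(got) > 0) {
        expect_true(all(abs(sort(got$ref_pos) - sort(want$parent_pos)) <= 5))
      }
    }
  }
})

test_that("a planted dinucleotide insertion is called with its full allele", {
  withr::with_seed(55, base <- random_dna_string(3000))
  p <- 1500
  # avoid ambiguity: make the insertion differ from its right context
  q <- paste0(substr(base, 1, p), "CA", substr(base, p + 1, 3000))
  vs <- tibble::as_tibble(call_variants(q, base))
  ins <- vs[vs$kind == "insertion", ]
  expect_equal(nrow(ins), 1)
  expect_equal(nchar(ins$alt_allele), 2)
  expect_lte(abs(ins$ref_pos - p), 2)  # left-alignment may shift slightly
})

test_that("deletions inside a homopolymer run are left-aligned", {
  left <- "ACGTCGGATCCTGACGGTACCGTATGCCAGT"
  right <- "CGATCCGGTTAACCGTTGCATCAGGTCCAAT"
  ref <- paste0(left, "GAAAAT", right)   # A-run at positions 33..36
  qry <- paste0(left, "GAAAT", right)    # one A deleted
  vs <- tibble::as_tibble(call_variants(qry, ref, k = 11))
  del <- vs[vs$kind == "deletion", ]
  expect_equal(nrow(del), 1)
  expect_equal(del$ref_pos, 33)  # leftmost A of the run
  expect_equal(del$ref_allele, "A")
})

test_that("shared SNP sites count identical substitutions only", {
  rec <- simulate_plastome(plastome_sim_spec(), seed = 9)
  a <- derive_maternal_offspring(rec, n_subs = 6, n_indels = 1, seed = 1, id = "a")
  b <- derive_maternal_offspring(rec, n_subs = 6, n_indels = 1, seed = 2, id = "b")
  va <- call_variants(a, rec)
  vb <- call_variants(b, rec)
  expect_equal(shared_snp_sites(va, va), sum(va$kind == "substitution"))
  expect_equal(shared_snp_sites(va, vb), shared_snp_sites(vb, va))
  expect_lte(shared_snp_sites(va, vb),
             min(sum(va$kind == "substitution"), sum(vb$kind == "substitution")))
  # maternal trio: hybrid shares all of the parent's substitution sites
  hy <- derive_maternal_offspring(a, n_subs = 3, n_indels = 0, seed = 3, id = "hy")
  vh <- call_variants(hy, rec)
  expect_gte(shared_snp_sites(va, vh), sum(va$kind == "substitution") - 1)
  other <- structure(tibble::as_tibble(vb), class = class(vb),
                     reference_id = "elsewhere", query_id = "b",
                     reference_seq = attr(vb, "reference_seq"))
  expect_error(shared_snp_sites(va, other),
               class = "karyohybrid_reference_error")
})

test_that("SSR scanning finds planted loci and honours thresholds", {
  rec <- simulate_plastome(plastome_sim_spec(), seed = 10)
  ssrs <- find_ssrs(rec)
  expect_true(any(ssrs$start == 500 & ssrs$motif == "A" & ssrs$repeats == 10))
  expect_true(any(ssrs$start == 900 & ssrs$motif == "T" & ssrs$repeats == 14))
  expect_true(any(ssrs$start == 1400 & ssrs$motif == "GGAAA" & ssrs$repeats == 3))
  # raising the penta threshold removes the penta locus and nothing gains
  high <- find_ssrs(rec, thresholds = c(10, 5, 4, 3, 4, 3))
  expect_false(any(high$motif == "GGAAA"))
  expect_true(all(paste(high$start, high$motif) %in% paste(ssrs$start, ssrs$motif)))
})

test_that("SSR scanner agrees with the brute-force oracle on random sequences", {
  withr::with_seed(61, {
    for (i in 1:20) {
      s <- random_dna_string(1000)
      got <- find_ssrs(s, thresholds = c(5, 3, 3, 3, 3, 3))
      want <- ssr_oracle(s, thresholds = c(5, 3, 3, 3, 3, 3))
      expect_equal(got$start, want$start)
      expect_equal(got$motif, want$motif)
      expect_equal(got$repeats, want$repeats)
    }
  })
})

test_that("SSR catalogue diffing classifies identical, changed and private loci", {
  a <- tibble::tibble(start = c(100, 500), motif = c("A", "AT"),
                      repeats = c(10, 6), unit_size = c(1, 2),
                      length = c(10, 12), compound = FALSE)
  expect_true(all(diff_ssr_catalogs(a, a)$status == "identical"))
  b <- dplyr::mutate(a, repeats = c(11, 6), length = c(11, 12))
  d <- diff_ssr_catalogs(a, b)
  expect_equal(d$status, c("length_changed", "identical"))
  empty <- a[0, ]
  expect_true(all(diff_ssr_catalogs(a, empty)$status == "private_a"))
  expect_true(all(diff_ssr_catalogs(empty, a)$status == "private_b"))
})

test_that("VCF output is well-formed with padded indel alleles", {
  rec <- simulate_plastome(plastome_sim_spec(), seed = 12)
  child <- derive_maternal_offspring(rec, n_subs = 3, n_indels = 2, seed = 2,
                                     id = "child")
  vs <- call_variants(child, rec)
  vcf <- tempfile(fileext = ".vcf")
  write_vcf(vs, vcf)
  lines <- readLines(vcf)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  body <- read.delim(text = lines[!startsWith(lines, "##")], check.names = FALSE)
  expect_equal(nrow(body), nrow(vs))
  expect_true(all(nchar(body$REF) >= 1 & nchar(body$ALT) >= 1))
  expect_true(all(grepl("^TYPE=", body$INFO)))
})
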