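test_that("planted quadripartite structure is recovered exactly", {
  rec <- simulate_plastome(plastome_sim_spec(), seed = 3)
  qp <- detect_inverted_repeat(rec, min_ir = 500)
  truth <- attr(rec, "truth_regions")
  expect_equal(qp$regions$region, truth$region)
  expect_equal(qp$regions$length, as.integer(truth$length))
  expect_equal(qp$ir_length, 1000L)
  # IRb is the exact reverse complement of IRa on the rotated sequence
  s <- qp$record$sequence
  irb <- substr(s, qp$regions$start[2], qp$regions$end[2])
  ira <- substr(s, qp$regions$start[4], qp$regions$end[4])
  expect_equal(karyohybrid:::revcomp(irb), ira)
  expect_equal(sum(qp$regions$length), rec$length)
})

test_that("partition is invariant to rotation and strand flip", {
  spec <- plastome_sim_spec(lsc_len = 900, ssc_len = 250, ir_len = 300,
                            ssr_plants = list(list(motif = "A", repeats = 10,
                                                   pos = 120)))
  rec <- simulate_plastome(spec, seed = 8)
  base <- detect_inverted_repeat(rec, min_ir = 250)
  n <- rec$length
  for (off in seq(0, n - 1, by = 97)) {
    rot <- plastome_record(
      paste0(substr(rec$sequence, off + 1, n), substr(rec$sequence, 1, off)),
      id = "rot")
    q <- detect_inverted_repeat(rot, min_ir = 250)
    expect_equal(q$regions$length, base$regions$length)
  }
  rc <- plastome_record(karyohybrid:::revcomp(rec$sequence), id = "rc")
  qrc <- detect_inverted_repeat(rc, min_ir = 250)
  expect_equal(qrc$regions$length, base$regions$length)
})

test_that("non-quadripartite input is refused", {
  withr::with_seed(2, {
    rnd <- plastome_record(random_dna_string(5000), id = "rnd")
  })
  expect_error(detect_inverted_repeat(rnd, min_ir = 500),
               class = "karyohybrid_no_ir_error")
  expect_error(detect_inverted_repeat(plastome_record("ACGT"), min_ir = 1000),
               class = "karyohybrid_input_error")
})

test_that("GC content excludes ambiguous bases", {
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("ATGC"), 50)
  expect_equal(gc_content("ATGCNN"), 50)
})

test_that("junction genes report spans and nearest genes like the border layout", {
  rec <- simulate_plastome(plastome_sim_spec(), seed = 1)
  qp <- detect_inverted_repeat(rec, min_ir = 500)
  jg <- junction_genes(qp)
  lscirb <- jg[jg$junction == "LSC-IRb", ]
  expect_equal(lscirb$gene, "rps19")
  expect_equal(lscirb$relation, "spans")
  expect_equal(lscirb$left_bp, 176)
  expect_equal(lscirb$right_bp, 34)
  irbssc <- jg[jg$junction == "IRb-SSC", ]
  expect_equal(irbssc$left_bp, 107)  # ndhF duplicated 107 bp into the IR
  sscira <- jg[jg$junction == "SSC-IRa", ]
  expect_equal(sscira$gene, "ycf1")
  expect_equal(sscira$right_bp, 41)
  iralsc <- jg[jg$junction == "IRa-LSC", ]
  expect_equal(iralsc$gene[iralsc$relation == "nearest_left"], "rps19")
  expect_equal(iralsc$distance_bp[iralsc$relation == "nearest_left"], 3L)
  expect_equal(iralsc$gene[iralsc$relation == "nearest_right"], "psbA")
  expect_equal(iralsc$distance_bp[iralsc$relation == "nearest_right"], 86L)
})

test_that("a gene ending exactly at a junction counts as spanning with a zero side", {
  rec <- simulate_plastome(plastome_sim_spec(), seed = 4)
  truth <- attr(rec, "truth_regions")
  j2 <- truth$end[2]  # IRb-SSC border
  rec2 <- plastome_record(rec$sequence, id = "zeroside", features = tibble::tibble(
    gene = c("rps19", "endgene"),
    strand = "+",
    start = c(truth$end[1] - 175L, j2 - 99L),
    end = c(truth$end[1] + 34L, j2),
    part = 1L, feature_id = 1:2))
  qp <- detect_inverted_repeat(rec2, min_ir = 500)
  jg <- junction_genes(qp)
  row <- jg[jg$junction == "IRb-SSC", ]
  expect_equal(row$gene, "endgene")
  expect_equal(row$relation, "spans")
  expect_equal(row$left_bp, 100)
  expect_equal(row$right_bp, 0)
  # the same gene is the nearest-left feature of the next junction,
  # one SSC-length away
  sscira <- jg[jg$junction == "SSC-IRa", ]
  expect_equal(sscira$relation, "nearest_left")
  expect_equal(sscira$distance_bp, 800L)
  # a junction with nothing inside the search window reports no rows
  expect_false("IRa-LSC" %in% jg$junction)
})

test_that("GenBank flat files round-trip including join() features", {
  rec <- simulate_plastome(plastome_sim_spec(), seed = 5, id = "GBTEST")
  gb <- tempfile(fileext = ".gb")
  write_genbank(rec, gb)
  back <- read_plastome(gb)
  expect_equal(back$sequence, rec$sequence)
  expect_setequal(unique(back$features$gene), unique(rec$features$gene))
  # hand-written record with a join() across two intervals
  txt <- c(
    "LOCUS       TOY 60 bp DNA circular",
    "FEATURES             Location/Qualifiers",
    "     gene            join(5..10,21..26)",
    "                     /gene=\"split\"",
    "     gene            complement(30..40)",
    "                     /gene=\"minus\"",
    "ORIGIN",
    "        1 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt",
    "//")
  f <- tempfile(fileext = ".gb")
  writeLines(txt, f)
  toy <- read_plastome(f)
  expect_equal(toy$length, 60)
  split <- toy$features[toy$features$gene == "split", ]
  expect_equal(nrow(split), 2)
  expect_equal(split$start, c(5L, 21L))
  expect_equal(toy$features$strand[toy$features$gene == "minus"][1], "-")
})

test_that("FASTA plastomes are read through Biostrings", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">rec1 test", "ACGTACGTAC", "GGCCA"), fa)
  rec <- read_plastome(fa)
  expect_equal(rec$id, "rec1")
  expect_equal(rec$length, 15)
  expect_error(read_plastome(tempfile()), class = "karyohybrid_input_error")
})
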