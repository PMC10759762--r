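test_that("chromosome classification follows the arm-ratio bands", {
  expect_equal(classify_chromosome(0, 6.2), "T")
  expect_equal(classify_chromosome(3, 3), "M")
  expect_equal(classify_chromosome(1, 5), "st")
  # swapped arms are normalized before classification
  expect_equal(classify_chromosome(5, 1), "st")
  # band edges: st includes both 3.01 and 7.00; t strictly above 7.00
  expect_equal(classify_chromosome(1, 3.01), "st")
  expect_equal(classify_chromosome(1, 7.00), "st")
  expect_equal(classify_chromosome(1, 7.01), "t")
  expect_equal(classify_chromosome(1, 1.01), "m")
  expect_equal(classify_chromosome(1, 1.70), "m")
  expect_warning(cl <- classify_chromosome(1, 2.5), class = "karyohybrid_sm_warning")
  expect_equal(cl, "sm")
  expect_error(classify_chromosome(0, 0), class = "karyohybrid_measurement_error")
})

test_that("classification is total and counts sum to 2n on random complements", {
  withr::with_seed(42, {
    for (i in 1:25) {
      two_n <- 2 * sample(3:12, 1)
      short <- round(runif(two_n, 0, 5), 2)
      long <- round(runif(two_n, 0.5, 8), 2)
      cl <- suppressWarnings(classify_chromosome(short, long))
      expect_true(all(cl %in% c("M", "m", "sm", "st", "t", "T")))
      expect_length(cl, two_n)
    }
  })
})

test_that("homolog pairing groups by type and length", {
  cells <- tibble::tibble(
    short_um = c(2, 2, 0.5, 0.4),
    long_um = c(2.5, 2.6, 4.5, 4.2),
    type_class = c("m", "m", "t", "t"))
  p <- pair_homologs(cells)
  expect_equal(nrow(p), 2)
  expect_equal(p$type_class, c("m", "t"))
  expect_equal(p$b, c(2, 0.45))
  # 2n = 22 = 10t + 12st pairs into 5 t-pairs and 6 st-pairs
  comp22 <- tibble::tibble(
    short_um = c(rep(0.8, 10), rep(1.5, 12)),
    long_um = c(8 * rep(0.8, 10) + seq(0, 0.9, length.out = 10),
                5 * rep(1.5, 12) + seq(0, 1.1, length.out = 12)))
  p22 <- pair_homologs(comp22)
  expect_equal(nrow(p22), 11)
  expect_equal(sum(p22$type_class == "t"), 5)
  expect_equal(sum(p22$type_class == "st"), 6)
  expect_error(pair_homologs(tibble::tibble(short_um = c(1, 1, 1),
                                            long_um = c(9, 9, 9))),
               class = "karyohybrid_pairing_error")
})

test_that("asymmetry indices match hand-computed values and are scale invariant", {
  # all pairs metacentric and equal: perfectly symmetric karyotype
  sym <- tibble::tibble(pair = 1:3, type_class = "M",
                        b = c(2, 2, 2), B = c(2, 2, 2), total = 4)
  expect_equal(asymmetry_indices(sym)$A1, 0)
  expect_equal(asymmetry_indices(sym)$A2, 0)
  # pairs (b,B) = (1,1) and (0,2): A1 = 1 - (1 + 0)/2
  two <- tibble::tibble(pair = 1:2, type_class = c("M", "T"),
                        b = c(1, 0), B = c(1, 2), total = c(2, 2))
  expect_equal(asymmetry_indices(two)$A1, 0.5)
  withr::with_seed(7, {
    for (i in 1:10) {
      n <- sample(3:8, 1)
      b <- runif(n, 0, 3)
      B <- b + runif(n, 0.1, 4)
      p <- tibble::tibble(pair = 1:n, type_class = "m", b = b, B = B,
                          total = b + B)
      a <- asymmetry_indices(p)
      expect_gte(a$A1, 0)
      expect_lte(a$A1, 1)
      expect_gte(a$A2, 0)
      cc <- runif(1, 0.1, 10)
      ps <- dplyr::mutate(p, b = b * cc, B = B * cc, total = total * cc)
      as <- asymmetry_indices(ps)
      expect_equal(as$A1, a$A1)
      expect_equal(as$A2, a$A2)
    }
  })
})

test_that("complement statistics: TCL is the mean haploid total, LS the mean ratio", {
  one <- tibble::tibble(cell = "c1", short_um = c(1, 1, 2, 2),
                        long_um = c(3, 3, 4, 4))
  cs <- complement_stats(one)
  expect_equal(cs$TCL, 10)
  expect_equal(cs$LS, 1.5)
  same <- tibble::tibble(cell = "c1", short_um = rep(2, 4), long_um = rep(3, 4))
  expect_equal(complement_stats(same)$LS, 1)
  two <- dplyr::bind_rows(one, dplyr::mutate(one, cell = "c2",
                                             short_um = short_um * 1.2,
                                             long_um = long_um * 1.2))
  expect_equal(complement_stats(two)$TCL, 11)
  bad <- dplyr::bind_rows(one, tibble::tibble(cell = "c3", short_um = 1,
                                              long_um = 2))
  expect_error(complement_stats(bad), class = "karyohybrid_input_error")
})

test_that("Stebbins classes reproduce the four printed karyotypes", {
  expect_equal(stebbins_class(counts = c(t = 10, st = 12), ls_ratio = 1.73), "4A")
  expect_equal(stebbins_class(counts = c(m = 8, T = 6), ls_ratio = 2.45), "2B")
  expect_equal(stebbins_class(counts = c(m = 4, st = 6, t = 5, T = 3),
                              ls_ratio = 3.50), "3B")
  expect_equal(stebbins_class(counts = c(m = 4, st = 6, t = 5, T = 3),
                              ls_ratio = 4.31), "3C")
  # digit boundaries on the ratio path: p = 0, 0.5, just above 0.5, 1
  expect_equal(stebbins_class(c(1.2, 1.5), ls_ratio = 1.5), "1A")
  expect_equal(stebbins_class(c(1.2, 3), ls_ratio = 1.5), "2A")
  expect_equal(stebbins_class(c(1.2, 3, 4), ls_ratio = 1.5), "3A")
  expect_equal(stebbins_class(c(3, 4), ls_ratio = 1.5), "4A")
  # letter boundaries: A strictly below 2, B closed [2, 4], C above 4
  expect_equal(stebbins_class(c(3, 4), ls_ratio = 2), "4B")
  expect_equal(stebbins_class(c(3, 4), ls_ratio = 4), "4B")
  expect_equal(stebbins_class(c(3, 4), ls_ratio = 4.01), "4C")
})

test_that("karyotype formulas format canonically and round-trip", {
  expect_equal(karyotype_formula(c(m = 8, T = 6), 14), "2n = 14 = 8m + 6T")
  p <- parse_karyotype_formula("2n = 18 = 4 m + 6st + 5t + 3 T")
  expect_equal(p$two_n, 18)
  expect_equal(p$counts[["m"]], 4)
  expect_equal(p$counts[["T"]], 3)
  # ploidy segment and arbitrary term order accepted
  p2 <- parse_karyotype_formula("2n = 2x = 22 = 12st + 10t")
  expect_equal(p2$two_n, 22)
  expect_equal(p2$counts[["t"]], 10)
  expect_error(parse_karyotype_formula("2n = 10 = 4m + 4t"),
               class = "karyohybrid_formula_error")
  expect_error(parse_karyotype_formula("22 = 10t + 12st"),
               class = "karyohybrid_formula_error")
  withr::with_seed(11, {
    for (i in 1:50) {
      counts <- random_counts()
      f <- karyotype_formula(counts)
      rt <- parse_karyotype_formula(f)
      expect_equal(rt$counts[rt$counts > 0],
                   karyohybrid:::normalize_counts(counts)[karyohybrid:::normalize_counts(counts) > 0])
      expect_equal(rt$two_n, sum(counts))
    }
  })
})

test_that("measurement tables are read with arm auto-swap", {
  tsv <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    taxon = "x", cell = "c1", chrom = 1:2,
    short_um = c(2, 5), long_um = c(4, 1)), tsv)
  expect_warning(m <- read_measurements(tsv), class = "karyohybrid_swap_warning")
  expect_true(all(m$short_um <= m$long_um))
})

test_that("summarize_karyotype recovers a noiseless simulated complement exactly", {
  sp <- radiata_like_spec(noise_cv = 0)
  g <- glance(summarize_karyotype(simulate_karyotype_measurements(sp, seed = 1)))
  expect_equal(g$formula, "2n = 22 = 12st + 10t")
  expect_equal(g$two_n, 22)
  # measurements are written to 4 decimals, so recovery is to ~1e-4
  expect_equal(g$TCL_um, 115.61, tolerance = 1e-4)
  expect_equal(g$LS, 1.73, tolerance = 1e-4)
  expect_equal(g$stebbins, "4A")
  ch <- tidy(summarize_karyotype(simulate_karyotype_measurements(sp, seed = 1)))
  # relative lengths: the diploid complement is two haploid sets of 100
  expect_equal(sum(ch$relative_pct), 200, tolerance = 1e-6)
  expect_error(
    summarize_karyotype(dplyr::bind_rows(
      simulate_karyotype_measurements(sp, seed = 1),
      tibble::tibble(taxon = "radiata", cell = "extra", chrom = 1,
                     short_um = 1, long_um = 2))),
    class = "karyohybrid_input_error")
})
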