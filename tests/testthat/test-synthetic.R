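test_that("generators are deterministic under a fixed seed", {
  expect_identical(simulate_karyotype_measurements(radiata_like_spec(), seed = 4),
                   simulate_karyotype_measurements(radiata_like_spec(), seed = 4))
  expect_false(identical(
    simulate_karyotype_measurements(radiata_like_spec(), seed = 4),
    simulate_karyotype_measurements(radiata_like_spec(), seed = 5)))
  r1 <- simulate_plastome(plastome_sim_spec(), seed = 2)
  r2 <- simulate_plastome(plastome_sim_spec(), seed = 2)
  expect_identical(r1$sequence, r2$sequence)
  o1 <- derive_maternal_offspring(r1, seed = 3)
  o2 <- derive_maternal_offspring(r1, seed = 3)
  expect_identical(o1$sequence, o2$sequence)
  expect_identical(attr(o1, "edits"), attr(o2, "edits"))
})

test_that("noiseless karyotype generation is exactly invertible", {
  for (spec in list(radiata_like_spec(noise_cv = 0), aurea_like_spec(noise_cv = 0))) {
    g <- glance(summarize_karyotype(simulate_karyotype_measurements(spec, seed = 1)))
    expect_equal(g$two_n, sum(spec$counts))
    expect_equal(g$formula, karyotype_formula(spec$counts))
  }
  expect_error(karyotype_sim_spec(c(t = 3)), class = "karyohybrid_input_error")
  expect_error(karyotype_sim_spec(c(t = 2), noise_cv = -0.1),
               class = "karyohybrid_input_error")
})

test_that("noisy karyotype generation keeps >= 99% of chromosomes in class", {
  a1 <- numeric(0)
  wrong <- 0L
  truth <- karyohybrid:::normalize_counts(c(t = 10, st = 12))
  for (s in 1:15) {
    g <- suppressWarnings(glance(summarize_karyotype(
      simulate_karyotype_measurements(radiata_like_spec(), seed = s))))
    got <- karyohybrid:::normalize_counts(parse_karyotype_formula(g$formula)$counts)
    wrong <- wrong + sum(abs(got - truth)) / 2
    a1 <- c(a1, g$A1)
  }
  expect_lte(wrong / (15 * 22), 0.01)
  expect_true(all(a1 > 0.7 & a1 < 0.9))
})

test_that("simulated F1 measurements are additive over their parents", {
  for (s in 1:5) {
    f1 <- simulate_f1_measurements(radiata_like_spec(), aurea_like_spec(),
                                   seed = s, taxon = "F1")
    g <- suppressWarnings(glance(summarize_karyotype(f1)))
    expect_equal(g$formula, "2n = 18 = 4m + 6st + 5t + 3T")
    expect_true(additivity_test(g$formula, "2n = 22 = 10t + 12st",
                                "2n = 14 = 8m + 6T")$consistent)
  }
  # selfing reproduces the parental formula
  self <- simulate_f1_measurements(radiata_like_spec(), radiata_like_spec(),
                                   seed = 1, taxon = "self")
  expect_equal(suppressWarnings(glance(summarize_karyotype(self)))$formula,
               "2n = 22 = 12st + 10t")
})

test_that("maternal offspring derivation plants recoverable edits", {
  rec <- simulate_plastome(plastome_sim_spec(), seed = 20)
  same <- derive_maternal_offspring(rec, n_subs = 0, n_indels = 0, seed = 1)
  expect_identical(same$sequence, rec$sequence)
  off <- derive_maternal_offspring(rec, n_subs = 5, n_indels = 0, seed = 21)
  ed <- attr(off, "edits")
  expect_equal(nrow(ed), 5)
  expect_true(all(diff(sort(ed$parent_pos)) >= 100))
  vs <- tibble::as_tibble(call_variants(off, rec))
  expect_equal(sort(vs$ref_pos[vs$kind == "substitution"]),
               sort(ed$parent_pos))
})

test_that("trio simulation separates maternal from paternal plastomes", {
  trio <- simulate_cp_trio(seed = 31, maternal = "B")
  va <- call_variants(trio$parent_A, trio$reference)
  vb <- call_variants(trio$parent_B, trio$reference)
  vh <- call_variants(trio$hybrid, trio$reference)
  expect_gt(shared_snp_sites(vh, vb), shared_snp_sites(vh, va))
  # all genomes keep the quadripartite structure
  for (r in trio[c("reference", "parent_A", "parent_B", "hybrid")]) {
    qp <- detect_inverted_repeat(r, min_ir = 500)
    expect_equal(qp$ir_length, 1000L)
  }
})

test_that("the trait fixture pairs each hybrid with its closer parent", {
  tr <- lycoris_trait_fixture()
  expect_equal(nrow(tr), 4)
  expect_equal(ncol(tr), 9)  # taxon + eight variables
  z <- suppressWarnings(standardize_traits(tr))
  vars <- setdiff(names(z), "taxon")
  expect_true(all(abs(colMeans(as.matrix(z[vars]))) < 1e-9))
})
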