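test_that("mutate_to_identity substitutes exactly the prescribed positions", {
  s100 <- strrep("A", 100)
  m <- mutate_to_identity(s100, 30, rng_seed = 7)
  expect_equal(oracle_identity(s100, m), 30)

  # round(L * (1 - id/100)) substitutions: L=50, id=25 -> 38 subs, 24% identity
  s50 <- paste(rep(c("A", "L"), 25), collapse = "")
  m50 <- mutate_to_identity(s50, 25, rng_seed = 1)
  expect_equal(oracle_identity(s50, m50), 100 * (50 - round(50 * 0.75)) / 50)
  expect_equal(oracle_identity(s50, m50), 24)

  expect_identical(mutate_to_identity(s100, 100, 99), s100)
  expect_identical(mutate_to_identity(s100, 30, 7), m)  # determinism
  expect_error(mutate_to_identity("", 50, 1), "empty")
})

test_that("plant_motif yields a scannable instance and is deterministic", {
  pat <- parse_motif("CXXCH")
  host <- strrep("A", 10)
  pl <- plant_motif(host, pat, position = 3L, rng_seed = 5)
  expect_equal(unname(pl$span), c(3L, 7L))
  expect_true(3L %in% scan_protein(pl$sequence, pat)$start)
  # untouched outside the span
  expect_equal(substr(pl$sequence, 1, 2), "AA")
  expect_equal(substr(pl$sequence, 8, 10), "AAA")
  pl2 <- plant_motif(host, pat, position = "random", rng_seed = 11)
  expect_identical(pl2, plant_motif(host, pat, position = "random", rng_seed = 11))
  expect_error(plant_motif("AAA", pat, 1L, 1), "longer than sequence")
})

test_that("planted motifs on a cysteine-free background are exactly recoverable", {
  pat <- parse_motif("CX{4,5}CX{1,50}CX{3}C", pattern_id = "fes")
  set.seed(3)
  n_plant <- 100L
  seqs <- vapply(1:n_plant, function(i) random_protein(80L, "cysteine_free"), "")
  planted <- vapply(seq_along(seqs), function(i)
    plant_motif(seqs[i], pat, position = "random", rng_seed = i,
                alphabet_policy = "cysteine_free")$sequence, "")
  prot <- proteome("G1", sprintf("p%03d", 1:n_plant), planted)
  sc <- scan_proteome(prot, list(pat))
  expect_equal(unname(sc$protein_counts[["fes"]]), n_plant)
})

test_that("dropout retains the exact count in original order", {
  prot <- proteome("G1", sprintf("p%d", 1:100),
                   vapply(1:100, function(i) strrep("A", 20), ""))
  dr <- apply_dropout(prot, 0.5, rng_seed = 3)
  expect_equal(nrow(dr$proteome$proteins), 50L)
  expect_equal(length(dr$dropped_ids), 50L)
  expect_identical(apply_dropout(prot, 1.0, rng_seed = 1)$proteome, prot)
  # relative order preserved under many seeds
  for (seed in 1:25) {
    kept <- apply_dropout(prot, 0.4, seed)$proteome$proteins$protein_id
    expect_identical(kept, intersect(prot$proteins$protein_id, kept))
  }
})

test_that("cohort generation honors degenerate carriage and is reproducible", {
  grpA <- group_profile("A", c(SufB = 1, SufC = 1))
  grpB <- group_profile("B", c(SufB = 0, SufC = 0))
  cfg <- cohort_config(list(grpA, grpB), n_genomes_per_group = 5L,
                       background_proteins_per_genome = 4L, rng_seed = 21L)
  ch <- generate_cohort(cfg)
  planted <- lapply(ch$truth$genomes, `[[`, "planted_families")
  a_ids <- grep("_A$", names(planted))
  b_ids <- grep("_B$", names(planted))
  expect_true(all(vapply(planted[a_ids], function(p)
    setequal(p, c("SufB", "SufC")), TRUE)))
  expect_true(all(lengths(planted[b_ids]) == 0L))

  # byte-identical FASTA and truth on rerun
  ch2 <- generate_cohort(cfg)
  d <- tempfile(); dir.create(d)
  write_fasta(ch$proteomes, file.path(d, "a.faa"))
  write_fasta(ch2$proteomes, file.path(d, "b.faa"))
  expect_identical(readBin(file.path(d, "a.faa"), "raw", 1e6),
                   readBin(file.path(d, "b.faa"), "raw", 1e6))
  expect_identical(ch$truth, ch2$truth)
})

test_that("carriage probabilities are recovered within binomial error", {
  p_true <- 0.6
  grp <- group_profile("A", c(FeoB = p_true))
  fams <- default_families()["FeoB"]
  cfg <- cohort_config(list(grp), families = fams, n_genomes_per_group = 250L,
                       background_proteins_per_genome = 1L,
                       background_length_range = c(30L, 40L), rng_seed = 5L)
  ch <- generate_cohort(cfg)
  carried <- mean(vapply(ch$truth$genomes, function(g)
    "FeoB" %in% g$planted_families, TRUE))
  tol <- 4 * sqrt(p_true * (1 - p_true) / 250)  # four binomial SEs
  expect_lt(abs(carried - p_true), tol)
})

test_that("undefined family references in a cohort config are rejected", {
  grp <- group_profile("A", c(NotAFamily = 1))
  expect_error(cohort_config(list(grp)), "undefined families")
})
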