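test_that("motif grammar compiles fixed, wildcard, alternation and gap elements", {
  p <- parse_motif("CXXCH")
  expect_length(p$elements, 5L)
  expect_equal(p$elements[[1L]], list(type = "fixed", aa = "C"))
  expect_equal(p$elements[[2L]]$type, "wildcard")
  expect_equal(p$elements[[4L]], list(type = "fixed", aa = "C"))
  expect_equal(p$elements[[5L]], list(type = "fixed", aa = "H"))
  expect_equal(c(p$min_len, p$max_len), c(5L, 5L))

  p <- parse_motif("GX(H/R)XCXGX")
  expect_length(p$elements, 8L)
  expect_equal(p$elements[[3L]], list(type = "alternation", set = c("H", "R")))
  expect_equal(c(p$min_len, p$max_len), c(8L, 8L))

  p <- parse_motif("CX{4,5}CX{1,50}CX{3}C")
  gaps <- Filter(function(e) e$type == "gap", p$elements)
  expect_equal(vapply(gaps, function(g) c(g$min, g$max), c(0L, 0L)),
               matrix(c(4L, 5L, 1L, 50L, 3L, 3L), nrow = 2L))
  expect_equal(c(p$min_len, p$max_len), c(12L, 62L))
})

test_that("open-length and numeric gap shorthands parse; render round-trips", {
  # Xn -> configurable open gap; X15 -> fixed 15-residue gap
  p <- parse_motif("CX{4}CXnCX{3}C")
  expect_equal(p$elements[[4L]][c("min", "max")], list(min = 1L, max = 50L))
  p2 <- parse_motif("CX{4}CXnCX{3}C", open_gap = c(2, 9))
  expect_equal(p2$elements[[4L]][c("min", "max")], list(min = 2L, max = 9L))
  p15 <- parse_motif("CX15CH")
  expect_equal(p15$elements[[2L]][c("min", "max")], list(min = 15L, max = 15L))
  expect_equal(c(p15$min_len, p15$max_len), c(18L, 18L))

  for (spec in c("CXXCH", "GX(H/R)XCXGX", "CX{4,5}CX{1,50}CX{3}C", "CPV")) {
    rendered <- render_motif(parse_motif(spec))
    reparsed <- parse_motif(rendered)
    expect_equal(reparsed$elements, parse_motif(spec)$elements, info = spec)
  }
})

test_that("malformed motif specs fail with a positioned parse error", {
  expect_error(parse_motif("CX{4,"), "position")
  expect_error(parse_motif("C(H/R"), "position")
  expect_error(parse_motif("C(h)C"), "alternation")
  expect_error(parse_motif("CX{a}"), "gap")
  expect_error(parse_motif("Cx"), "unexpected")
})

test_that("scanner reproduces hand-checked spans", {
  expect_equal(scan_protein("MACPPCHG", parse_motif("CXXCH"))[, c("start", "end")],
               data.frame(start = 3L, end = 7L))
  expect_equal(scan_protein("AGAHACAGA", parse_motif("GX(H/R)XCXGX"))[, c("start", "end")],
               data.frame(start = 2L, end = 9L))
  expect_equal(scan_protein("CAAAACAACAAAC",
                            parse_motif("CX{4,5}CX{1,50}CX{3}C"))[, c("start", "end")],
               data.frame(start = 1L, end = 13L))
  # empty / too-short input
  expect_equal(nrow(scan_protein("", parse_motif("CXXCH"))), 0L)
  expect_equal(nrow(scan_protein("CC", parse_motif("CXXCH"))), 0L)
})

test_that("overlapping matches at distinct starts are all reported", {
  hits <- scan_protein("CCACCHCH", parse_motif("CXXCH"))
  expect_equal(hits$start, c(2L, 4L))
})

test_that("ambiguity codes satisfy wildcards and gaps but never fixed anchors", {
  p <- parse_motif("CXXCH")
  expect_equal(scan_protein("CXXCH", p)$start, 1L)      # X at wildcard slots
  expect_equal(nrow(scan_protein("XAACH", p)), 0L)      # X cannot be anchor C
  expect_equal(nrow(scan_protein("CAAXH", p)), 0L)      # X cannot be anchor C
  alt <- parse_motif("G(H/R)C")
  expect_equal(nrow(scan_protein("GXC", alt)), 0L)      # X cannot satisfy (H/R)
  gap <- parse_motif("CX{2}C")
  expect_equal(scan_protein("CBZC", gap)$start, 1L)     # ambiguity inside gap
})

test_that("scanner agrees with the enumeration oracle and spans re-match", {
  pats <- list(parse_motif("CXXCH"), parse_motif("GX(H/R)XCXGX"),
               parse_motif("CX{1,4}CH"), parse_motif("CX{4,5}CX{1,50}CX{3}C"),
               parse_motif("CX{2}CX{2}CX{3}C"))
  set.seed(42)
  for (rep in 1:150) {
    s <- random_test_seq(sample(10:80, 1L))
    for (p in pats) {
      got <- scan_protein(s, p)
      exp <- oracle_scan(s, p)
      expect_equal(got$start, exp$start, info = paste(p$spec, s))
      expect_equal(got$end, exp$end, info = paste(p$spec, s))
      # self-verification: every reported span re-satisfies the pattern
      for (i in seq_len(nrow(got))) {
        sub <- substr(s, got$start[i], got$end[i])
        expect_true(nrow(scan_protein(sub, p)) >= 1L &&
                      scan_protein(sub, p)$start[1L] == 1L)
      }
    }
  }
})

test_that("exhaustive scan over all short sequences matches the oracle", {
  alpha <- c("C", "H", "A", "G")
  pats <- list(parse_motif("CXXCH"), parse_motif("CX{1,2}CH"),
               parse_motif("(C/H)XC"))
  for (len in 1:6) {
    grid <- do.call(expand.grid, rep(list(alpha), len))
    seqs <- do.call(paste0, grid)
    for (p in pats) {
      for (s in seqs) {
        expect_identical(scan_protein(s, p)$start, oracle_scan(s, p)$start,
                         info = paste(p$spec, s))
      }
    }
  }
})

test_that("proteome scan counts each protein once per pattern", {
  prot <- proteome("G1",
                   c("multi", "single", "none"),
                   c("ACAACHACAACHACAACH",   # three CXXCH matches
                     "AAACAACHAAA",          # one
                     "AAAAAAAAAA"))
  sc <- scan_proteome(prot, list(parse_motif("CXXCH", pattern_id = "cxxch")))
  expect_equal(unname(sc$protein_counts[["cxxch"]]), 2L)
  expect_error(scan_proteome(prot, list()), "non-empty")
})

test_that("fes_fraction is the motif-bearing protein share, order-invariant", {
  seqs <- c(sprintf("ONE%s", strrep("A", 20)), strrep("L", 20), strrep("K", 20))
  seqs[1] <- paste0("CAACAACAAAC", strrep("A", 12))  # FeS_ferredoxin instance
  prot <- proteome("G1", c("a", "b", "c"), seqs)
  expect_equal(fes_fraction(prot), 1 / 3)
  perm <- proteome("G1", c("c", "b", "a"), seqs[c(3, 2, 1)])
  expect_equal(fes_fraction(perm), fes_fraction(prot))
  none <- proteome("G2", "x", strrep("A", 30))
  expect_equal(fes_fraction(none), 0)
  expect_error(fes_fraction(proteome("G3", character(), character())), "equal length|empty")
})

test_that("required-motif verification gates families as declared", {
  fams <- default_families()
  dsr_seed <- fams$Dsr$seed_sequences[[1L]]
  expect_true(verify_required_motif(dsr_seed, fams$Dsr))
  expect_false(verify_required_motif(strrep("A", 100), fams$Dsr))
  expect_true(verify_required_motif(strrep("A", 100), fams$SufB))  # vacuous
})

test_that("minor heme c hits are annotated with companion evidence", {
  prot <- proteome("G1", c("with", "without"),
                   c(paste0("CAACH", strrep("A", 10), "CAACK"),  # CXXCH + CXXCK
                     paste0(strrep("A", 10), "CAACK")))          # CXXCK alone
  sc <- scan_proteome(prot, default_motif_library())
  ann <- annotate_heme_c_matches(sc$matches)
  k_with <- ann$pattern_id == "heme_c_CXXCK" & ann$protein_id == "with"
  k_without <- ann$pattern_id == "heme_c_CXXCK" & ann$protein_id == "without"
  expect_true(all(ann$companion_cxxch[k_with]))
  expect_false(any(ann$companion_cxxch[k_without]))
})
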