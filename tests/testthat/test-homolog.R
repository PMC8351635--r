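test_that("hit tables parse with correct coverage arithmetic", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("SufB\tp1\t45.0\t80\t40\t2\t1\t80\t5\t84\t1e-20\t150",
               "SufB\tp2\t100.0\t100\t0\t0\t1\t100\t1\t100\t0.0\t300"), tf)
  hits <- parse_hit_table(tf, c(SufB = 100L), genome_id = "G1")
  expect_equal(hits$percent_query_coverage, c(80, 100))
  expect_equal(hits$percent_identity, c(45, 100))
  expect_equal(hits$e_value, c(1e-20, 0))

  writeLines("NotAQuery\tp1\t45\t80\t40\t2\t1\t80\t5\t84\t1e-20\t150", tf)
  expect_error(parse_hit_table(tf, c(SufB = 100L)), "unknown query")
  writeLines("SufB\tp1\tabc\t80\t40\t2\t1\t80\t5\t84\t1e-20\t150", tf)
  expect_error(parse_hit_table(tf, c(SufB = 100L)), "non-numeric")
  writeLines("SufB\tp1\t45", tf)
  expect_error(parse_hit_table(tf, c(SufB = 100L)), "malformed.*line")
})

test_that("hit tables round-trip through the outfmt-6 writer", {
  set.seed(8)
  hits <- do.call(rbind, lapply(1:20, function(i)
    make_hit(e_value = 10^-sample(5:50, 1), identity = runif(1, 10, 100),
             coverage = sample(10:100, 1), subject = sprintf("p%02d", i))))
  tf <- tempfile(fileext = ".tsv")
  write_hit_table(hits, tf)
  back <- parse_hit_table(tf, c(SufB = 100L), genome_id = "G1")
  expect_equal(back$subject_protein_id, hits$subject_protein_id)
  expect_equal(back$e_value, hits$e_value)
  expect_equal(back$percent_identity, hits$percent_identity, tolerance = 1e-6)
  # coverage quantized to whole residues of a length-100 query
  expect_equal(back$percent_query_coverage, round(hits$percent_query_coverage))
})

test_that("classification reproduces the tier decision table at its boundaries", {
  pol <- acceptance_policy()
  cls <- function(e, id, cov, dom = FALSE, motif = TRUE)
    classify_hit(make_hit(e, id, cov), pol, dom, motif)
  # direct acceptance and the E screen
  expect_equal(cls(1e-6, 45, 80)$status, "accepted")
  expect_equal(cls(1e-3, 90, 95, dom = TRUE)[c("status", "reason")],
               list(status = "rejected", reason = "evalue"))
  expect_equal(cls(1e-5, 45, 80)$status, "accepted")     # E == cutoff passes
  # coverage: strictly greater than 30 required
  expect_equal(cls(1e-6, 45, 30)$reason, "coverage")
  expect_equal(cls(1e-6, 45, 30.1)$status, "accepted")
  # identity boundaries: >= 30 accepts; [20, 30) is the rescue band
  expect_equal(cls(1e-6, 30, 80)$status, "accepted")
  expect_equal(cls(1e-6, 29.99, 80, dom = TRUE)$status, "rescued")
  expect_equal(cls(1e-6, 25, 60, dom = TRUE)$status, "rescued")
  expect_equal(cls(1e-6, 25, 60, dom = FALSE)$reason, "no_domain_evidence")
  expect_equal(cls(1e-6, 20, 80, dom = TRUE)$status, "rescued")
  expect_equal(cls(1e-6, 19.99, 80, dom = TRUE)$reason, "identity")
  # required motif gates every acceptance path
  expect_equal(cls(1e-6, 45, 80, motif = FALSE)$reason, "motif_failed")
  expect_equal(cls(1e-6, 25, 80, dom = TRUE, motif = FALSE)$reason, "motif_failed")
})

test_that("the stringent siroheme-destination policy overrides the default", {
  pol <- siroheme_policy()
  hit <- make_hit(1e-20, 60, 70, family = "Dsr")
  expect_equal(classify_hit(hit, pol)[c("status", "reason")],
               list(status = "rejected", reason = "evalue"))
  expect_equal(classify_hit(make_hit(1e-31, 60, 70), pol)$status, "accepted")
  expect_equal(classify_hit(make_hit(1e-31, 49, 70), pol)$reason,
               "no_domain_evidence")  # below 50% identity, no rescue evidence
  expect_equal(classify_hit(make_hit(1e-31, 60, 50), pol)$reason, "coverage")
})

test_that("every call carries exactly one status and reason, consistently", {
  pol <- acceptance_policy()
  set.seed(13)
  for (i in 1:300) {
    h <- make_hit(10^runif(1, -40, 1), runif(1, 0, 100), runif(1, 0, 100))
    cl <- classify_hit(h, pol, domain_evidence = runif(1) < 0.5,
                       motif_ok = runif(1) < 0.8)
    expect_true(cl$status %in% c("accepted", "rescued", "rejected"))
    expect_identical(cl$status == "rejected", cl$reason != "ok")
    if (cl$status == "rescued")
      expect_true(h$percent_identity >= 20 && h$percent_identity < 30)
  }
})

test_that("acceptance is monotone in identity and E-value", {
  pol <- acceptance_policy()
  status_of <- function(e, id) classify_hit(make_hit(e, id, 80), pol, TRUE, TRUE)$status
  ids <- seq(5, 100, by = 2.5)
  ranks <- vapply(ids, function(id) switch(status_of(1e-10, id),
                                           rejected = 0L, rescued = 1L, accepted = 2L), 0L)
  expect_true(all(diff(ranks) >= 0))
  es <- 10^seq(-1, -40, by = -1)
  acc <- vapply(es, function(e) status_of(e, 50) == "accepted", TRUE)
  expect_true(all(diff(acc) >= 0))  # decreasing E never loses acceptance
})

test_that("the pairwise backend recovers planted separations", {
  fams <- default_families()
  seed <- fams$SufB$seed_sequences[[1L]]
  # self-hit: 100/100
  prot <- proteome("G1", "self", seed)
  hit <- pairwise_search(fams$SufB, prot)
  expect_equal(hit$percent_identity, 100)
  expect_equal(hit$percent_query_coverage, 100)
  expect_lt(hit$e_value, 1e-50)
  # planted homolog at 40% identity reports within +/- 5 points
  hom <- mutate_to_identity(seed, 40, rng_seed = 2)
  hit40 <- pairwise_search(fams$SufB, proteome("G1", "hom", hom))
  expect_equal(nrow(hit40), 1L)
  expect_lt(abs(hit40$percent_identity - 40), 5)
  expect_lt(hit40$e_value, 1e-5)
})

test_that("unrelated random proteins never pass the E-value screen", {
  fams <- default_families()
  set.seed(77)
  prot <- proteome("G0", sprintf("r%03d", 1:400),
                   vapply(1:400, function(i) random_protein(180L, "cysteine_free"), ""))
  hits <- pairwise_search(fams$SufB, prot)
  if (nrow(hits)) expect_true(all(hits$e_value > 1e-5))
})

test_that("operon synteny upgrades partial hits only with enough close support", {
  fams <- default_families()
  calls <- rbind(
    as.data.frame(unclass(classify_hit(make_hit(1e-10, 60, 80, family = "AhbA", locus = 10L))),
                  stringsAsFactors = FALSE),
    as.data.frame(unclass(classify_hit(make_hit(1e-10, 60, 80, family = "AhbC", locus = 12L))),
                  stringsAsFactors = FALSE),
    as.data.frame(unclass(classify_hit(make_hit(1e-10, 60, 20, family = "AhbB", locus = 11L))),
                  stringsAsFactors = FALSE))
  expect_equal(calls$status, c("accepted", "accepted", "rejected"))
  up <- apply_synteny(calls, fams)
  expect_equal(up$status[3L], "rescued")
  expect_true(up$synteny_support[3L])
  # outside the window: no upgrade
  far <- calls; far$locus[3L] <- 40L
  expect_equal(apply_synteny(far, fams)$status[3L], "rejected")
  # only one supporting neighbor (< k = 2): no upgrade
  one <- calls[c(1L, 3L), ]
  expect_equal(apply_synteny(one, fams)$status[2L], "rejected")
  # non-operon family is never upgraded
  solo <- as.data.frame(unclass(classify_hit(make_hit(1e-10, 60, 20, family = "SufS", locus = 11L))),
                        stringsAsFactors = FALSE)
  expect_equal(apply_synteny(rbind(calls[1:2, ], solo), fams)$status[3L], "rejected")
  # evalue rejections stay rejected even inside a supported operon
  ev <- calls
  ev$status[3L] <- "rejected"; ev$reason[3L] <- "evalue"
  expect_equal(apply_synteny(ev, fams)$status[3L], "rejected")
})

test_that("family presence requires at least one accepted or rescued call", {
  fams <- default_families()[c("SufB", "SufC", "SufS")]
  calls <- rbind(
    as.data.frame(unclass(classify_hit(make_hit(1e-10, 60, 80, family = "SufB"))),
                  stringsAsFactors = FALSE),
    as.data.frame(unclass(classify_hit(make_hit(1e-2, 60, 80, family = "SufC"))),
                  stringsAsFactors = FALSE))
  pres <- family_presence(calls, fams)
  expect_identical(pres, c(SufB = TRUE, SufC = FALSE, SufS = FALSE))
  expect_identical(family_presence(calls[2:1, ], fams), pres)  # order-invariant
})
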