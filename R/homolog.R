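# Tiered homolog classification.
#
# Hits from a protein similarity search (either the built-in desk-scale
# Smith-Waterman backend or an external BLASTp tabular file) are screened
# in tiers: an E-value cutoff first, then query coverage, then percent
# identity — with a 20-30% identity "rescue band" in which hits are kept
# only when independent domain evidence supports them. Required diagnostic
# motifs (when a family declares any) gate acceptance at every tier.
# Boundary conventions, which the tiered scheme needs stated explicitly:
# E <= e_max passes; coverage must be strictly greater than coverage_min;
# identity >= identity_min accepts directly; the rescue band is
# [rescue_low, identity_min).

# Gapped Karlin-Altschul parameters for BLOSUM62 with gap open 11 /
# extend 1 (the standard protein-search defaults). The built-in E-value is
# approximate; classification never depends on its absolute scale, only on
# the separation between genuine homologs and background.
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Acceptance policy for homolog classification
#'
#' @param e_max E-value cutoff (hits with E > `e_max` are rejected).
#' @param identity_min Percent identity for direct acceptance.
#' @param coverage_min Percent query coverage; coverage must exceed this
#'   strictly.
#' @param rescue_band Length-2 numeric: the half-open identity interval
#'   `[low, high)` in which hits are rescued given domain evidence.
#' @param require_domain_for_rescue If `FALSE`, rescue-band hits are kept
#'   without domain evidence (not recommended).
#' @return An `AcceptancePolicy` object.
#' @export
acceptance_policy <- function(e_max = 1e-5, identity_min = 30, coverage_min = 30,
                              rescue_band = c(20, 30),
                              require_domain_for_rescue = TRUE) {
  stopifnot(e_max > 0, rescue_band[1] >= 0, rescue_band[1] < rescue_band[2],
            rescue_band[2] <= identity_min)
  structure(list(e_max = e_max, identity_min = identity_min,
                 coverage_min = coverage_min, rescue_band = rescue_band,
                 require_domain_for_rescue = require_domain_for_rescue),
            class = "AcceptancePolicy")
}

#' Stringent policy for siroheme-destination searches
#'
#' Sulfite/nitrite reductase (Dsr/Fsr-type) searches use much stricter
#' thresholds than the general screen: E <= 1e-30, coverage > 50%,
#' identity >= 50%, with no rescue band.
#' @return An `AcceptancePolicy`.
#' @export
siroheme_policy <- function() {
  acceptance_policy(e_max = 1e-30, identity_min = 50, coverage_min = 50,
                    rescue_band = c(0, 50), require_domain_for_rescue = TRUE)
}

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Expects the default 12-column dialect: qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore. Percent query
#' coverage is computed as `100 * (qend - qstart + 1) / query_length`.
#'
#' @param path Path to the TSV file (no header row).
#' @param query_lengths Named integer vector mapping query/family id to
#'   query length in residues.
#' @param genome_id Genome the subject proteins belong to.
#' @param locus_map Optional named integer vector mapping subject protein
#'   id to locus index (needed for synteny support).
#' @return A data.frame of `HitRecord` rows: `family_name`, `genome_id`,
#'   `subject_protein_id`, `e_value`, `bit_score`, `percent_identity`,
#'   `percent_query_coverage`, `query_length`, `locus`.
#' @export
parse_hit_table <- function(path, query_lengths, genome_id = NA_character_,
                            locus_map = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12L)
  if (length(bad))
    stop("malformed hit-table rows (expected 12 columns) at line(s): ",
         paste(bad, collapse = ", "))
  m <- do.call(rbind, fields)
  qid <- m[, 1L]
  unknown <- setdiff(unique(qid), names(query_lengths))
  if (length(unknown))
    stop("unknown query id(s) in hit table: ", paste(unknown, collapse = ", "))
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v))
      stop("non-numeric ", what, " at line(s): ",
           paste(which(is.na(v)), collapse = ", "))
    v
  }
  pident <- num(3L, "pident"); qstart <- num(7L, "qstart"); qend <- num(8L, "qend")
  evalue <- num(11L, "evalue"); bits <- num(12L, "bitscore")
  qlen <- unname(query_lengths[qid])
  sid <- m[, 2L]
  data.frame(family_name = qid, genome_id = genome_id,
             subject_protein_id = sid,
             e_value = evalue, bit_score = bits,
             percent_identity = pident,
             percent_query_coverage = 100 * (qend - qstart + 1) / qlen,
             query_length = qlen,
             locus = if (is.null(locus_map)) NA_integer_ else
               unname(locus_map[sid]),
             stringsAsFactors = FALSE)
}

empty_hits <- function() {
  data.frame(family_name = character(), genome_id = character(),
             subject_protein_id = character(), e_value = numeric(),
             bit_score = numeric(), percent_identity = numeric(),
             percent_query_coverage = numeric(), query_length = integer(),
             locus = integer(), stringsAsFactors = FALSE)
}

#' Write a hit table in BLAST outfmt-6 layout
#'
#' Serialization inverse of [parse_hit_table()] for the fields the
#' classifier uses; alignment-bookkeeping columns it does not retain
#' (mismatch, gapopen, sstart, send) are written as zeros.
#' @param hits Hit data.frame (see [parse_hit_table()]).
#' @param path Output TSV path.
#' @export
write_hit_table <- function(hits, path) {
  qend <- round(hits$percent_query_coverage / 100 * hits$query_length)
  rows <- sprintf("%s\t%s\t%g\t%d\t0\t0\t1\t%d\t0\t0\t%g\t%g",
                  hits$family_name, hits$subject_protein_id,
                  hits$percent_identity, as.integer(qend), as.integer(qend),
                  hits$e_value, hits$bit_score)
  writeLines(rows, path)
  invisible(path)
}

#' Desk-scale pairwise homology search
#'
#' Smith-Waterman local alignment of each family seed against every
#' protein of a proteome (BLOSUM62, gap open 11 / extend 1). Identity is
#' identical columns over alignment columns; coverage is the aligned query
#' span over the query length; the E-value is the gapped Karlin-Altschul
#' estimate `K * m * n * exp(-lambda * S)` for the search space of one
#' seed against the proteome. This backend exists so the pipeline runs
#' without an external aligner; real BLASTp tabular output flows through
#' the identical downstream logic via [parse_hit_table()].
#'
#' @param family A [query_family()].
#' @param prot A `Proteome`.
#' @param e_report Hits with estimated E-value above this are not
#'   reported (keeps tables small; classification applies its own cutoff).
#' @return A `HitRecord` data.frame as in [parse_hit_table()]. With
#'   several seeds, only the best-scoring seed's hit per subject is kept.
#' @export
pairwise_search <- function(family, prot, e_report = 10) {
  stopifnot(inherits(family, "QueryFamily"), inherits(prot, "Proteome"))
  if (nrow(prot$proteins) == 0L) return(empty_hits())
  data("BLOSUM62", package = "Biostrings", envir = environment())
  subjects <- Biostrings::AAStringSet(prot$proteins$sequence)
  names(subjects) <- prot$proteins$protein_id
  search_n <- sum(nchar(prot$proteins$sequence))
  best <- NULL
  for (seed in family$seed_sequences) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = rep(Biostrings::AAStringSet(seed), length(subjects)),
      subject = subjects, type = "local",
      substitutionMatrix = BLOSUM62, gapOpening = 11, gapExtension = 1)
    sc <- Biostrings::score(aln)
    ev <- KA_K * nchar(seed) * search_n * exp(-KA_LAMBDA * sc)
    bits <- (KA_LAMBDA * sc - log(KA_K)) / log(2)
    pident <- Biostrings::pid(aln, type = "PID1")
    qr <- IRanges_of_pattern(aln)
    cov <- 100 * (qr[, 2L] - qr[, 1L] + 1) / nchar(seed)
    df <- data.frame(family_name = family$family_name,
                     genome_id = prot$genome_id,
                     subject_protein_id = prot$proteins$protein_id,
                     e_value = ev, bit_score = bits,
                     percent_identity = pident,
                     percent_query_coverage = cov,
                     query_length = nchar(seed),
                     locus = prot$proteins$locus,
                     stringsAsFactors = FALSE)
    best <- if (is.null(best)) df else {
      take <- df$bit_score > best$bit_score
      best[take, ] <- df[take, ]
      best
    }
  }
  best <- best[best$e_value <= e_report, , drop = FALSE]
  rownames(best) <- NULL
  best
}

IRanges_of_pattern <- function(aln) {
  r <- Biostrings::pattern(aln)
  cbind(Biostrings::start(r), Biostrings::end(r))
}

#' Classify one homology-search hit
#'
#' Applies the tiered decision procedure: (1) E-value screen, (2) coverage
#' screen, (3) direct acceptance at `identity >= identity_min` when any
#' required motif is present, (4) rescue in the identity band given domain
#' evidence and motif, (5) motif-failure rejection, (6) residual rejection
#' by identity or missing domain evidence.
#'
#' @param hit One-row `HitRecord` data.frame (or a list with the same
#'   fields).
#' @param policy An [acceptance_policy()].
#' @param domain_evidence Logical: independent functional-grouping
#'   evidence (COG/Pfam-style) supporting the hit. See
#'   [motif_domain_evidence()] for the built-in desk-scale provider.
#' @param motif_ok Logical: required diagnostic motifs present (vacuously
#'   `TRUE` for families without required motifs).
#' @return A `HomologCall`: list with `status` (`accepted` / `rescued` /
#'   `rejected`), `reason` (`ok`, `evalue`, `coverage`, `identity`,
#'   `no_domain_evidence`, `motif_failed`), `synteny_support = FALSE`, and
#'   the hit fields.
#' @export
classify_hit <- function(hit, policy = acceptance_policy(), domain_evidence = FALSE,
                         motif_ok = TRUE) {
  e <- hit$e_value; id <- hit$percent_identity; cov <- hit$percent_query_coverage
  call <- function(status, reason)
    structure(list(family_name = hit$family_name, genome_id = hit$genome_id,
                   subject_protein_id = hit$subject_protein_id,
                   e_value = e, percent_identity = id,
                   percent_query_coverage = cov, locus = hit$locus,
                   status = status, reason = reason, synteny_support = FALSE),
              class = "HomologCall")
  if (e > policy$e_max) return(call("rejected", "evalue"))
  if (cov <= policy$coverage_min) return(call("rejected", "coverage"))
  if (id >= policy$identity_min && motif_ok) return(call("accepted", "ok"))
  in_band <- id >= policy$rescue_band[1] && id < policy$rescue_band[2]
  if (in_band && motif_ok &&
      (domain_evidence || !policy$require_domain_for_rescue))
    return(call("rescued", "ok"))
  if (!motif_ok) return(call("rejected", "motif_failed"))
  if (in_band) return(call("rejected", "no_domain_evidence"))
  call("rejected", "identity")
}

#' Desk-scale domain-evidence provider
#'
#' Stands in for alignment against functional-grouping databases: a hit
#' has domain evidence when the subject sequence carries the family's
#' required diagnostic motifs. A user-supplied table of externally
#' computed domain hits can replace it (any function
#' `(family_name, protein_id, sequence) -> logical` slots in).
#'
#' @param family A `QueryFamily`.
#' @param sequence Subject protein sequence.
#' @param library Motif library resolving required pattern ids.
#' @return Logical.
#' @export
motif_domain_evidence <- function(family, sequence, library = default_motif_library()) {
  if (length(family$required_motifs) == 0L) return(FALSE)
  verify_required_motif(sequence, family, library)
}

#' Classify every hit of one genome for a set of families
#'
#' Convenience wrapper: selects the best hit per subject by bit score
#' (ties broken by lower E-value, then lexicographic subject id), computes
#' motif and domain evidence from the subject sequences, and applies
#' [classify_hit()] with each family's policy.
#'
#' @param hits `HitRecord` data.frame for one genome.
#' @param families Named list of `QueryFamily`.
#' @param prot The `Proteome` the subjects came from (for motif checks);
#'   may be `NULL` when no family requires motifs.
#' @param policy Default [acceptance_policy()] for families without an
#'   override.
#' @param library Motif library.
#' @param domain_provider Function `(family, sequence, library) -> logical`
#'   supplying rescue-band domain evidence.
#' @return A data.frame of calls: one row per classified hit with
#'   `family_name`, `genome_id`, `subject_protein_id`, `locus`, `status`,
#'   `reason`, `synteny_support`.
#' @export
classify_hits <- function(hits, families, prot = NULL,
                          policy = acceptance_policy(),
                          library = default_motif_library(),
                          domain_provider = motif_domain_evidence) {
  if (nrow(hits) == 0L) return(empty_calls())
  seqs <- if (!is.null(prot))
    stats::setNames(prot$proteins$sequence, prot$proteins$protein_id) else character()
  rows <- vector("list", 0L)
  for (fam_name in unique(hits$family_name)) {
    fam <- families[[fam_name]]
    if (is.null(fam)) stop("hits reference undefined family '", fam_name, "'")
    pol <- if (!is.null(fam$policy_override)) fam$policy_override else policy
    fh <- hits[hits$family_name == fam_name, , drop = FALSE]
    # best hit per subject by bit score; ties: lower E, then subject id
    o <- order(fh$subject_protein_id, -fh$bit_score, fh$e_value)
    fh <- fh[o, , drop = FALSE]
    fh <- fh[!duplicated(fh$subject_protein_id), , drop = FALSE]
    for (i in seq_len(nrow(fh))) {
      sid <- fh$subject_protein_id[i]
      s <- if (sid %in% names(seqs)) seqs[[sid]] else NULL
      motif_ok <- if (length(fam$required_motifs) == 0L) TRUE else
        !is.null(s) && verify_required_motif(s, fam, library)
      dom <- !is.null(s) && isTRUE(domain_provider(fam, s, library))
      cl <- classify_hit(fh[i, ], pol, domain_evidence = dom, motif_ok = motif_ok)
      rows[[length(rows) + 1L]] <- as.data.frame(unclass(cl), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_calls <- function() {
  data.frame(family_name = character(), genome_id = character(),
             subject_protein_id = character(), e_value = numeric(),
             percent_identity = numeric(), percent_query_coverage = numeric(),
             locus = integer(), status = character(), reason = character(),
             synteny_support = logical(), stringsAsFactors = FALSE)
}

#' Upgrade operon-member rejections using gene synteny
#'
#' Partial sequences in incomplete genomes often fail the coverage or
#' identity screens even though their gene neighborhood identifies them;
#' conserved-operon synteny restores those calls. A `rejected(coverage)`
#' or `rejected(identity)` call for a family belonging to an operon is
#' upgraded to `rescued` with `synteny_support = TRUE` iff at least `k`
#' *other* families of the same operon have accepted or rescued calls
#' within `w` loci of the hit. Accepted calls are never modified.
#'
#' @param calls Calls data.frame from [classify_hits()] (one genome).
#' @param families Named list of `QueryFamily` (supplies operon
#'   membership).
#' @param k Minimum number of supporting operon neighbors (default 2).
#' @param w Locus window (default 5).
#' @return The calls data.frame with qualifying rows upgraded.
#' @export
apply_synteny <- function(calls, families, k = 2L, w = 5L) {
  if (nrow(calls) == 0L) return(calls)
  operon_of <- vapply(calls$family_name, function(f) {
    fam <- families[[f]]
    if (is.null(fam)) stop("calls reference undefined family '", f, "'")
    if (is.na(fam$operon)) NA_character_ else fam$operon
  }, "")
  ok <- calls$status %in% c("accepted", "rescued")
  upgradable <- calls$status == "rejected" &
    calls$reason %in% c("coverage", "identity") & !is.na(operon_of)
  for (i in which(upgradable)) {
    same_op <- which(operon_of == operon_of[i] & ok &
                       calls$family_name != calls$family_name[i])
    if (length(same_op) == 0L || is.na(calls$locus[i])) next
    near <- abs(calls$locus[same_op] - calls$locus[i]) <= w
    n_support <- length(unique(calls$family_name[same_op][near]))
    if (n_support >= k) {
      calls$status[i] <- "rescued"
      calls$reason[i] <- "ok"
      calls$synteny_support[i] <- TRUE
    }
  }
  calls
}

#' Per-genome family presence from classified calls
#'
#' @param calls Calls data.frame for one genome.
#' @param families Named list of `QueryFamily`; families without any
#'   accepted/rescued call report `FALSE`.
#' @return Named logical vector over `names(families)`.
#' @export
family_presence <- function(calls, families) {
  present <- unique(calls$family_name[calls$status %in% c("accepted", "rescued")])
  stats::setNames(names(families) %in% present, names(families))
}
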