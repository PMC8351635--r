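# Synthetic proteome cohorts with planted ground truth.
#
# The generator emulates the structure of a mixed cultivar/MAG genome
# survey: taxon groups with characteristic per-family carriage
# probabilities, homologs planted at controlled percent identity from seed
# sequences, cofactor motifs planted into designated proteins, and MAG
# incompleteness simulated as random gene dropout. Background sequences
# are i.i.d. draws; a cysteine-free background gives a zero-false-positive
# regime for the C- and G-anchored cofactor motifs, separating scanner
# correctness from background-hit statistics.

#' Draw a random background protein sequence
#'
#' @param length Sequence length in residues.
#' @param alphabet_policy `"full20"` (uniform over the 20 standard
#'   residues) or `"cysteine_free"` (uniform over the 19 non-cysteine
#'   residues, with glycine also excluded so G-anchored motifs cannot
#'   arise by chance either).
#' @return A protein string.
#' @export
random_protein <- function(length, alphabet_policy = c("full20", "cysteine_free")) {
  alphabet_policy <- match.arg(alphabet_policy)
  alpha <- switch(alphabet_policy,
                  full20 = AA_STANDARD,
                  cysteine_free = setdiff(AA_STANDARD, c("C", "G", "H")))
  paste(sample(alpha, length, replace = TRUE), collapse = "")
}

#' Mutate a seed sequence to a target percent identity
#'
#' Substitution-only mutation (no indels), so identity and coverage of the
#' planted homolog are analytically controlled: exactly
#' `round(L * (1 - identity/100))` positions are substituted, each to a
#' residue different from the original.
#'
#' @param seed_sequence Protein string (length >= 10).
#' @param target_identity Percent identity in (0, 100].
#' @param rng_seed Integer seed; identical inputs and seed give identical
#'   output.
#' @param alphabet Residues substitutions are drawn from. Restricting this
#'   to a cysteine-free alphabet keeps mutated homologs of cysteine-free
#'   seeds free of accidental motif anchors.
#' @return The mutated protein string.
#' @examples
#' s <- strrep("A", 100)
#' m <- mutate_to_identity(s, 30, 7)
#' sum(strsplit(s, "")[[1]] == strsplit(m, "")[[1]])  # 30
#' @export
mutate_to_identity <- function(seed_sequence, target_identity, rng_seed,
                               alphabet = AA_STANDARD) {
  if (!nzchar(seed_sequence)) stop("empty seed sequence")
  L <- nchar(seed_sequence)
  stopifnot(L >= 10L, target_identity > 0, target_identity <= 100,
            length(alphabet) >= 2L)
  n_sub <- round(L * (1 - target_identity / 100))
  if (n_sub == 0L) return(seed_sequence)
  chars <- strsplit(seed_sequence, "")[[1]]
  with_seed(rng_seed, {
    pos <- sample.int(L, n_sub)
    for (p in pos) {
      chars[p] <- sample(setdiff(alphabet, chars[p]), 1L)
    }
  })
  paste(chars, collapse = "")
}

#' Plant a concrete motif instance into a sequence
#'
#' Overwrites a window of the sequence with one concrete instantiation of
#' the pattern (fixed residues as given; alternations take their first
#' member; wildcard and gap positions drawn from the background alphabet
#' policy, gaps at minimum length). Outside the window the sequence is
#' unchanged.
#'
#' @param sequence Host protein string.
#' @param pattern A `MotifPattern`.
#' @param position 1-based start index, or `"random"`.
#' @param rng_seed Integer seed (used for random position and gap/wildcard
#'   residues).
#' @param alphabet_policy Background alphabet for wildcard/gap residues.
#' @return A list with `sequence` (modified string) and `span`
#'   (c(start, end)).
#' @export
plant_motif <- function(sequence, pattern, position = "random", rng_seed = 1L,
                        alphabet_policy = c("full20", "cysteine_free")) {
  alphabet_policy <- match.arg(alphabet_policy)
  stopifnot(inherits(pattern, "MotifPattern"))
  L <- nchar(sequence)
  if (pattern$min_len > L) stop("pattern longer than sequence")
  alpha <- switch(alphabet_policy,
                  full20 = AA_STANDARD,
                  cysteine_free = setdiff(AA_STANDARD, c("C", "G", "H")))
  with_seed(rng_seed, {
    instance <- paste(vapply(pattern$elements, function(e) {
      switch(e$type,
             fixed = e$aa,
             alternation = e$set[1L],
             wildcard = sample(alpha, 1L),
             gap = if (e$min == 0L) "" else
               paste(sample(alpha, e$min, replace = TRUE), collapse = ""))
    }, ""), collapse = "")
    w <- nchar(instance)
    start <- if (identical(position, "random"))
      sample.int(L - w + 1L, 1L) else as.integer(position)
  })
  if (start < 1L || start + nchar(instance) - 1L > L)
    stop("motif does not fit at position ", start)
  end <- start + nchar(instance) - 1L
  out <- paste0(substr(sequence, 1L, start - 1L), instance,
                substr(sequence, end + 1L, L))
  list(sequence = out, span = c(start = start, end = end))
}

#' Simulate genome incompleteness by random gene dropout
#'
#' Retains exactly `round(N * completeness)` proteins, sampled without
#' replacement, preserving the original relative gene order (so operon
#' adjacency among survivors is meaningful downstream).
#'
#' @param prot A `Proteome`.
#' @param completeness Fraction in (0, 1].
#' @param rng_seed Integer seed.
#' @return A list with `proteome` (the reduced `Proteome`, flagged
#'   `"draft"` when genes were dropped) and `dropped_ids` (character).
#' @export
apply_dropout <- function(prot, completeness, rng_seed) {
  stopifnot(inherits(prot, "Proteome"), completeness > 0, completeness <= 1)
  N <- nrow(prot$proteins)
  keep_n <- round(N * completeness)
  if (keep_n == N)
    return(list(proteome = prot, dropped_ids = character()))
  keep <- with_seed(rng_seed, sort(sample.int(N, keep_n)))
  dropped <- prot$proteins$protein_id[-keep]
  out <- proteome(prot$genome_id,
                  prot$proteins$protein_id[keep],
                  prot$proteins$sequence[keep],
                  locus = prot$proteins$locus[keep],
                  taxon_group = prot$taxon_group,
                  completeness = "draft")
  list(proteome = out, dropped_ids = dropped)
}

#' Define a query family
#'
#' A family bundles what the classifier needs: one or more seed sequences,
#' an optional stricter acceptance policy, required diagnostic motifs, and
#' optional operon membership used for synteny support.
#'
#' @param family_name Unique family name (e.g. `"SufB"`).
#' @param seed_sequences Character vector of >= 1 protein strings.
#' @param policy_override Optional [acceptance_policy()] replacing the
#'   default thresholds for this family.
#' @param required_motifs Character vector of pattern ids that accepted
#'   homologs must carry (may be empty).
#' @param operon Optional operon name (e.g. `"ahb"`, `"cyd"`, `"suf"`).
#' @return A `QueryFamily` object.
#' @export
query_family <- function(family_name, seed_sequences, policy_override = NULL,
                         required_motifs = character(), operon = NA_character_) {
  stopifnot(length(seed_sequences) >= 1L, all(nzchar(seed_sequences)))
  structure(list(family_name = family_name,
                 seed_sequences = toupper(seed_sequences),
                 policy_override = policy_override,
                 required_motifs = required_motifs,
                 operon = operon),
            class = "QueryFamily")
}

#' Built-in synthetic family definitions
#'
#' A self-contained set of `QueryFamily` objects covering the surveyed
#' systems: Fe(II) import (FeoA/FeoB), the Suf [Fe-S] scaffold
#' (SufB/SufC/SufS), tetrapyrrole and heme biosynthesis (HemB/C/D,
#' AhbA-D), siroheme biosynthesis and use (SirA, SirC, Dsr, Fsr), and
#' heme b users (VhoC, HdrE, KatG, CydA, CydB). The seed sequences are
#' synthetic: deterministic pseudo-random proteins (cysteine-free
#' background) with the family's diagnostic motif planted where one is
#' required — stand-ins that exercise the pipeline without bundling any
#' database sequence. SirB-type chelatases are deliberately unsupported:
#' they cannot be demarcated from paralogs on primary sequence alone.
#'
#' @param seed_length Length of each synthetic seed protein.
#' @return Named list of `QueryFamily` objects.
#' @export
default_families <- function(seed_length = 180L) {
  defs <- list(
    FeoA = list(),
    FeoB = list(),
    SufB = list(operon = "suf"),
    SufC = list(operon = "suf"),
    SufS = list(),
    HemB = list(),
    HemC = list(),
    HemD = list(),
    AhbA = list(operon = "ahb"),
    AhbB = list(operon = "ahb"),
    AhbC = list(operon = "ahb"),
    AhbD = list(operon = "ahb"),
    SirA = list(),
    SirC = list(),
    Dsr  = list(required_motifs = c("siroheme_CX4")),
    Fsr  = list(required_motifs = c("siroheme_CX4")),
    VhoC = list(required_motifs = c("heme_b_GXHRXCXGX")),
    HdrE = list(required_motifs = c("heme_b_GXHRXCXGX")),
    KatG = list(),
    CydA = list(operon = "cyd"),
    CydB = list(operon = "cyd")
  )
  lib <- default_motif_library()
  fams <- lapply(seq_along(defs), function(i) {
    name <- names(defs)[i]
    d <- defs[[i]]
    # family-specific deterministic seed: stable across sessions
    seq <- with_seed(7000L + i, random_protein(seed_length, "cysteine_free"))
    req <- if (is.null(d$required_motifs)) character() else d$required_motifs
    for (pid in req) {
      seq <- plant_motif(seq, lib[[pid]], position = 20L + 30L * match(pid, req),
                         rng_seed = 7100L + i, alphabet_policy = "cysteine_free")$sequence
    }
    query_family(name, seq, required_motifs = req,
                 operon = if (is.null(d$operon)) NA_character_ else d$operon)
  })
  stats::setNames(fams, names(defs))
}

#' Describe a synthetic taxon group
#'
#' @param group_name Taxon label.
#' @param carriage Named numeric vector: probability (0..1) that a genome
#'   of this group carries each family.
#' @param planted_fes_fraction Target fraction of proteins carrying an
#'   [Fe-S] motif (0..1).
#' @param target_identity Named numeric vector or single value: percent
#'   identity of planted homologs relative to the family seed.
#' @return A `GroupProfile` object.
#' @export
group_profile <- function(group_name, carriage, planted_fes_fraction = 0,
                          target_identity = 60) {
  stopifnot(all(carriage >= 0), all(carriage <= 1),
            planted_fes_fraction >= 0, planted_fes_fraction <= 1,
            all(target_identity > 0), all(target_identity <= 100))
  structure(list(group_name = group_name, carriage = carriage,
                 planted_fes_fraction = planted_fes_fraction,
                 target_identity = target_identity),
            class = "GroupProfile")
}

#' Assemble a cohort configuration
#'
#' @param groups List of [group_profile()] objects.
#' @param families Named list of [query_family()] objects (families
#'   referenced by group carriage maps must be present).
#' @param n_genomes_per_group Genomes simulated per group.
#' @param background_proteins_per_genome Background (non-planted) proteins
#'   per genome.
#' @param background_length_range Length-2 residue range for background
#'   proteins; the minimum must accommodate the longest planted motif.
#' @param background_alphabet_policy `"full20"` or `"cysteine_free"`.
#' @param completeness Fraction of genes retained per genome (1 = no
#'   dropout).
#' @param rng_seed Master integer seed.
#' @return A `CohortConfig` object.
#' @export
cohort_config <- function(groups, families = default_families(),
                          n_genomes_per_group = 10L,
                          background_proteins_per_genome = 20L,
                          background_length_range = c(120L, 240L),
                          background_alphabet_policy = "cysteine_free",
                          completeness = 1.0, rng_seed = 1L) {
  stopifnot(length(groups) >= 1L, completeness > 0, completeness <= 1)
  fam_names <- names(families)
  for (g in groups) {
    unknown <- setdiff(names(g$carriage), fam_names)
    if (length(unknown))
      stop("group '", g$group_name, "' references undefined families: ",
           paste(unknown, collapse = ", "))
  }
  fes_max <- max(vapply(default_fes_library(), `[[`, 0L, "min_len"))
  stopifnot(background_length_range[1] >= fes_max)
  structure(list(groups = groups, families = families,
                 n_genomes_per_group = as.integer(n_genomes_per_group),
                 background_proteins_per_genome = as.integer(background_proteins_per_genome),
                 background_length_range = as.integer(background_length_range),
                 background_alphabet_policy = match.arg(background_alphabet_policy,
                                                        c("full20", "cysteine_free")),
                 completeness = completeness,
                 rng_seed = as.integer(rng_seed)),
            class = "CohortConfig")
}

#' Generate a synthetic proteome cohort with planted truth
#'
#' For each genome: background proteins are drawn i.i.d.; for every family
#' a Bernoulli draw against the group's carriage probability decides
#' planting; planted homologs are [mutate_to_identity()] copies of the
#' family seed; families sharing an operon are planted as adjacent loci
#' (exercising the synteny rule); [Fe-S] motifs are planted into
#' `round(N * planted_fes_fraction)` proteins; finally [apply_dropout()]
#' simulates incompleteness. Everything planted, planted motif spans, and
#' dropped protein ids are recorded in the truth manifest, which is
#' sufficient to recompute every expected downstream call.
#'
#' @param config A [cohort_config()].
#' @return A list with `proteomes` (named list of `Proteome`) and `truth`
#'   (class `SyntheticTruth`): per genome `group`, `planted_families`,
#'   `planted_motifs` (data.frame protein_id/pattern_id/start/end),
#'   `dropped_ids`, and the `rng_seed` used.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  fes_lib <- default_fes_library()
  motif_lib <- default_motif_library()
  proteomes <- list()
  truth <- list(rng_seed = config$rng_seed, genomes = list())
  # per-genome sub-seeds drawn from the master stream, so no arithmetic
  # relation ties a genome's stream to any other seeded stream
  n_total <- length(config$groups) * config$n_genomes_per_group
  gseeds <- with_seed(config$rng_seed, sample.int(2^31 - 1L, n_total))
  genome_counter <- 0L
  for (gi in seq_along(config$groups)) {
    grp <- config$groups[[gi]]
    for (k in seq_len(config$n_genomes_per_group)) {
      genome_counter <- genome_counter + 1L
      gseed <- gseeds[genome_counter]
      gid <- sprintf("G%03d_%s", genome_counter, grp$group_name)
      gen <- with_seed(gseed, {
        nbg <- config$background_proteins_per_genome
        lens <- sample(seq(config$background_length_range[1],
                           config$background_length_range[2]), nbg, replace = TRUE)
        seqs <- vapply(lens, random_protein, "",
                       alphabet_policy = config$background_alphabet_policy)
        ids <- sprintf("%s_p%03d", gid, seq_len(nbg))
        # decide family carriage
        fam_names <- names(config$families)
        probs <- vapply(fam_names, function(f)
          if (f %in% names(grp$carriage)) grp$carriage[[f]] else 0, 0)
        carried <- fam_names[stats::runif(length(fam_names)) < probs]
        # plant homologs; operon co-members planted adjacently
        planted <- character()
        plant_seq <- character()
        for (f in carried) {
          fam <- config$families[[f]]
          tid <- if (length(grp$target_identity) == 1L && is.null(names(grp$target_identity)))
            grp$target_identity else
              if (f %in% names(grp$target_identity)) grp$target_identity[[f]] else 60
          sub_alpha <- switch(config$background_alphabet_policy,
                              full20 = AA_STANDARD,
                              cysteine_free = setdiff(AA_STANDARD, c("C", "G", "H")))
          hom <- mutate_to_identity(fam$seed_sequences[[1L]], tid,
                                    rng_seed = sample.int(2^30, 1L),
                                    alphabet = sub_alpha)
          # diagnostic motifs are functionally conserved: restore the seed's
          # required-motif residues in the mutated homolog
          for (pid in fam$required_motifs) {
            hit <- scan_protein(fam$seed_sequences[[1L]], motif_lib[[pid]])
            if (nrow(hit)) {
              substr(hom, hit$start[1L], hit$end[1L]) <-
                substr(fam$seed_sequences[[1L]], hit$start[1L], hit$end[1L])
            }
          }
          planted <- c(planted, f)
          plant_seq <- c(plant_seq, hom)
        }
        # order planted proteins so operon members are adjacent
        operons <- vapply(planted, function(f) {
          op <- config$families[[f]]$operon
          if (is.na(op)) paste0("solo_", f) else op
        }, "")
        ord <- order(operons, planted)
        planted <- planted[ord]; plant_seq <- plant_seq[ord]
        all_ids <- c(ids, sprintf("%s_%s", gid, planted))
        all_seqs <- c(seqs, plant_seq)
        # plant [Fe-S] motifs into background proteins
        n_fes <- round(length(all_ids) * grp$planted_fes_fraction)
        motif_rows <- list()
        if (n_fes > 0L) {
          hosts <- sample(seq_len(nbg), n_fes)  # background hosts only
          for (h in hosts) {
            pat <- fes_lib[[sample.int(length(fes_lib), 1L)]]
            pl <- plant_motif(all_seqs[h], pat, position = "random",
                              rng_seed = sample.int(2^30, 1L),
                              alphabet_policy = config$background_alphabet_policy)
            all_seqs[h] <- pl$sequence
            motif_rows[[length(motif_rows) + 1L]] <-
              data.frame(protein_id = all_ids[h], pattern_id = pat$pattern_id,
                         start = pl$span["start"], end = pl$span["end"],
                         stringsAsFactors = FALSE)
          }
        }
        list(ids = all_ids, seqs = all_seqs, planted = planted,
             motifs = if (length(motif_rows)) do.call(rbind, motif_rows) else
               data.frame(protein_id = character(), pattern_id = character(),
                          start = integer(), end = integer(), stringsAsFactors = FALSE),
             drop_seed = sample.int(2^30, 1L))
      })
      prot <- proteome(gid, gen$ids, gen$seqs, taxon_group = grp$group_name,
                       completeness = if (config$completeness < 1) "draft" else "complete")
      dr <- apply_dropout(prot, config$completeness, gen$drop_seed)
      proteomes[[gid]] <- dr$proteome
      truth$genomes[[gid]] <- list(
        group = grp$group_name,
        planted_families = setdiff(gen$planted,
                                   sub("^.*_", "", dr$dropped_ids)),
        planted_families_pre_dropout = gen$planted,
        planted_motifs = gen$motifs[!(gen$motifs$protein_id %in% dr$dropped_ids), ,
                                    drop = FALSE],
        dropped_ids = dr$dropped_ids,
        rng_seed = gseed)
    }
  }
  class(truth) <- "SyntheticTruth"
  list(proteomes = proteomes, truth = truth)
}

#' Serialize a truth manifest to JSON
#' @param truth A `SyntheticTruth`.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
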