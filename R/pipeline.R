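# End-to-end pipeline: simulate (optional) -> scan -> search -> classify
# -> call -> summarize -> ordinate, with per-stage TSV/JSON artifacts and
# a provenance log so every output is regenerable from config + seed.

#' Survey a cohort of proteomes
#'
#' Runs the full analysis on an in-memory cohort: motif scanning and
#' [Fe-S] fractions, the pairwise homolog search and tiered
#' classification with synteny support, pathway feature calling, the
#' presence/absence matrix, per-group summaries, and the Jaccard/PCO
#' ordination.
#'
#' @param proteomes Named list of `Proteome` objects.
#' @param families Named list of [query_family()] objects.
#' @param rules A [pathway_rules()] object.
#' @param policy Default [acceptance_policy()].
#' @param library Motif library (named list of `MotifPattern`).
#' @param fes_library [Fe-S] motif library for proteome fractions.
#' @param synteny_k,synteny_w Operon-support parameters for
#'   [apply_synteny()].
#' @param taxon_map Optional named character vector genome -> group;
#'   defaults to each proteome's `taxon_group`.
#' @return A list: `calls` (all classified hits), `presence` (genome x
#'   family logical matrix), `matrix` (`PresenceAbsenceMatrix`),
#'   `vectors` (list of `FeatureVector`), `fractions` (named numeric),
#'   `motif_counts` (genome x pattern matrix of motif-bearing protein
#'   counts), `summaries` (per-group `TaxonSummary`), `dissimilarity`,
#'   `ordination`.
#' @export
survey_cohort <- function(proteomes, families = default_families(),
                          rules = pathway_rules(),
                          policy = acceptance_policy(),
                          library = default_motif_library(),
                          fes_library = default_fes_library(),
                          synteny_k = 2L, synteny_w = 5L,
                          taxon_map = NULL) {
  stopifnot(length(proteomes) >= 1L)
  if (is.null(names(proteomes)) || any(!nzchar(names(proteomes))))
    names(proteomes) <- vapply(proteomes, `[[`, "", "genome_id")
  if (is.null(taxon_map))
    taxon_map <- vapply(proteomes, `[[`, "", "taxon_group")
  pattern_ids <- vapply(library, `[[`, "", "pattern_id")

  all_calls <- list()
  vectors <- list()
  fractions <- numeric()
  motif_counts <- matrix(0L, nrow = length(proteomes), ncol = length(library),
                         dimnames = list(names(proteomes), pattern_ids))
  for (gid in names(proteomes)) {
    prot <- proteomes[[gid]]
    sc <- scan_proteome(prot, library)
    motif_counts[gid, names(sc$protein_counts)] <- sc$protein_counts
    fractions[[gid]] <- fes_fraction(prot, fes_library)
    hits <- do.call(rbind, lapply(families, pairwise_search, prot = prot))
    calls <- classify_hits(hits, families, prot = prot, policy = policy,
                           library = library)
    calls <- apply_synteny(calls, families, k = synteny_k, w = synteny_w)
    all_calls[[gid]] <- calls
    pres <- family_presence(calls, families)
    vectors[[gid]] <- call_features(pres, rules, genome_id = gid)
  }
  presence <- do.call(rbind, lapply(vectors, function(v)
    v$features[names(families)] == 1L))
  rownames(presence) <- names(proteomes)
  mat <- build_matrix(vectors, rules = rules)
  completeness <- vapply(proteomes, `[[`, "", "completeness")
  summaries <- summarize_groups(mat, fractions, taxon_map, completeness)
  D <- jaccard_dissimilarity(mat)
  ord <- if (nrow(mat) >= 3L) pco(D) else NULL
  list(calls = do.call(rbind, all_calls), presence = presence, matrix = mat,
       vectors = vectors, fractions = fractions, motif_counts = motif_counts,
       summaries = summaries, dissimilarity = D, ordination = ord,
       taxon_map = taxon_map)
}

#' Run the pipeline and write its artifact bundle
#'
#' Simulates a cohort from `config` (or loads FASTA proteomes from
#' `proteome_dir`), runs [survey_cohort()], and writes every stage's
#' artifact under `out_dir`: the cohort FASTA and truth manifest (when
#' simulated), the motif scan table, classified calls, family presence,
#' the presence/absence matrix, group summaries, ordination coordinates
#' and axis variances, and a provenance JSON (package version, seed,
#' parameters, input hashes). Rerunning with the same inputs and seed
#' reproduces the bundle byte for byte.
#'
#' @param config A [cohort_config()] for simulation, or `NULL` when
#'   reading proteomes from disk.
#' @param proteome_dir Directory of FASTA files (used when `config` is
#'   `NULL`).
#' @param taxon_map_path TSV (genome_id, taxon_group) required with
#'   `proteome_dir`.
#' @param out_dir Output directory (created if missing).
#' @param ... Passed to [survey_cohort()].
#' @return The [survey_cohort()] result, invisibly, with
#'   `$artifact_paths` attached.
#' @export
run_pipeline <- function(config = NULL, proteome_dir = NULL,
                         taxon_map_path = NULL, out_dir, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- NULL
  if (!is.null(config)) {
    cohort <- generate_cohort(config)
    proteomes <- cohort$proteomes
    truth <- cohort$truth
    write_fasta(proteomes, file.path(out_dir, "cohort.faa"))
    write_truth(truth, file.path(out_dir, "truth.json"))
  } else {
    if (is.null(proteome_dir)) stop("either config or proteome_dir is required")
    if (is.null(taxon_map_path)) stop("taxon map required before any compute")
    tm <- utils::read.delim(taxon_map_path, stringsAsFactors = FALSE)
    files <- list.files(proteome_dir, pattern = "\\.(fa|faa|fasta)$",
                        full.names = TRUE)
    if (length(files) == 0L) stop("no FASTA files in ", proteome_dir)
    proteomes <- do.call(c, lapply(files, read_fasta))
    tmap <- stats::setNames(tm[[2L]], tm[[1L]])
    for (gid in names(proteomes)) proteomes[[gid]]$taxon_group <- tmap[[gid]]
  }
  res <- survey_cohort(proteomes, ...)
  paths <- list(
    calls = file.path(out_dir, "calls.tsv"),
    presence = file.path(out_dir, "family_presence.tsv"),
    matrix = file.path(out_dir, "presence_absence_matrix.tsv"),
    summary = file.path(out_dir, "group_summary.tsv"),
    coords = file.path(out_dir, "pco_coordinates.tsv"),
    axes = file.path(out_dir, "pco_axes.tsv"),
    provenance = file.path(out_dir, "provenance.json"))
  utils::write.table(res$calls, paths$calls, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(genome_id = rownames(res$presence),
               ifelse(res$presence, 1L, 0L), check.names = FALSE),
    paths$presence, sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix(res$matrix, paths$matrix)
  write_summary_table(res$summaries, paths$summary)
  if (!is.null(res$ordination))
    write_ordination(res$ordination, paths$coords, paths$axes)
  prov <- list(
    package = "fesurvey",
    version = as.character(utils::packageVersion("fesurvey")),
    seed = if (!is.null(config)) config$rng_seed else NA,
    n_genomes = length(proteomes),
    parameters = list(...),
    input_md5 = if (is.null(config))
      vapply(list.files(proteome_dir, full.names = TRUE), function(f)
        as.character(tools::md5sum(f)), "") else NULL)
  jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  res$truth <- truth
  res$artifact_paths <- paths
  invisible(res)
}

#' Expected presence/absence matrix from a truth manifest
#'
#' Recomputes, from the planted ground truth alone, the family and
#' pathway feature matrix the pipeline should recover on a noise-free
#' cohort.
#'
#' @param truth A `SyntheticTruth` from [generate_cohort()].
#' @param families Named list of `QueryFamily` (column universe).
#' @param rules A [pathway_rules()].
#' @return A `PresenceAbsenceMatrix` with the same column layout
#'   [build_matrix()] produces.
#' @export
truth_matrix <- function(truth, families = default_families(),
                         rules = pathway_rules()) {
  vectors <- lapply(names(truth$genomes), function(gid) {
    planted <- truth$genomes[[gid]]$planted_families
    pres <- stats::setNames(names(families) %in% planted, names(families))
    call_features(pres, rules, genome_id = gid)
  })
  build_matrix(vectors, rules = rules)
}
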