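#' @keywords internal
"_PACKAGE"

AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_AMBIGUOUS <- c("B", "Z", "J", "U", "O", "X")
AA_ALLOWED <- c(AA_STANDARD, AA_AMBIGUOUS)

#' Construct a proteome
#'
#' A `Proteome` is the per-genome unit of the survey: an ordered list of
#' predicted protein sequences with stable identifiers and strictly
#' increasing locus indices (gene order is retained because operon synteny
#' is used downstream as annotation evidence).
#'
#' @param genome_id Genome identifier (single string).
#' @param protein_ids Character vector of unique protein identifiers.
#' @param sequences Character vector of amino-acid sequences (uppercased;
#'   the 20 standard residues plus ambiguity codes B, Z, J, U, O, X).
#' @param locus Integer vector of locus indices; defaults to input order.
#' @param taxon_group Optional taxon-group label (e.g. an order name).
#' @param completeness `"complete"` or `"draft"`.
#' @return An object of class `Proteome`: a list with elements `genome_id`,
#'   `taxon_group`, `completeness`, and `proteins` (a data.frame with
#'   columns `protein_id`, `locus`, `sequence`).
#' @export
proteome <- function(genome_id, protein_ids, sequences, locus = seq_along(protein_ids),
                     taxon_group = NA_character_, completeness = "complete") {
  stopifnot(is.character(genome_id), length(genome_id) == 1L, nzchar(genome_id))
  if (length(protein_ids) != length(sequences))
    stop("protein_ids and sequences must have equal length")
  if (anyDuplicated(protein_ids))
    stop("duplicate protein ids in genome '", genome_id, "': ",
         paste(unique(protein_ids[duplicated(protein_ids)]), collapse = ", "))
  sequences <- toupper(sequences)
  if (any(!nzchar(sequences))) stop("empty sequence records in genome '", genome_id, "'")
  bad <- grepl(sprintf("[^%s]", paste(AA_ALLOWED, collapse = "")), sequences)
  if (any(bad))
    stop("illegal characters in sequences of genome '", genome_id, "': ",
         paste(protein_ids[bad], collapse = ", "))
  locus <- as.integer(locus)
  if (any(diff(locus) <= 0L) && length(locus) > 1L)
    stop("locus indices must be strictly increasing")
  completeness <- match.arg(completeness, c("complete", "draft"))
  structure(list(
    genome_id = genome_id,
    taxon_group = taxon_group,
    completeness = completeness,
    proteins = data.frame(protein_id = as.character(protein_ids),
                          locus = locus,
                          sequence = sequences,
                          stringsAsFactors = FALSE)
  ), class = "Proteome")
}

#' @export
print.Proteome <- function(x, ...) {
  cat(sprintf("Proteome '%s' (%s%s): %d proteins\n", x$genome_id,
              x$completeness,
              if (is.na(x$taxon_group)) "" else paste0(", ", x$taxon_group),
              nrow(x$proteins)))
  invisible(x)
}

#' @export
length.Proteome <- function(x) nrow(x$proteins)

#' Read proteomes from a multi-FASTA file
#'
#' Headers follow the dialect `>genomeID|proteinID|locusIndex`. Plain
#' headers (no `|`) are accepted when `genome_id` is supplied; locus
#' indices then default to file order. `*` stop characters are stripped
#' with a warning; sequences are uppercased.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @param genome_id Genome id to use when headers are plain identifiers.
#' @param taxon_group,completeness Passed to [proteome()].
#' @return A named list of `Proteome` objects (one per genome id found).
#' @export
read_fasta <- function(path, genome_id = NULL, taxon_group = NA_character_,
                       completeness = "complete") {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("no FASTA records in ", path)
  seqs <- as.character(aa)
  headers <- sub("\\s.*$", "", names(aa))
  parts <- strsplit(headers, "|", fixed = TRUE)
  npart <- lengths(parts)
  if (all(npart >= 2L)) {
    gid <- vapply(parts, `[`, "", 1L)
    pid <- vapply(parts, `[`, "", 2L)
    loc <- ifelse(npart >= 3L, vapply(parts, `[`, "", 3L), NA_character_)
  } else {
    if (is.null(genome_id))
      stop("plain FASTA headers require an explicit genome_id")
    gid <- rep(genome_id, length(headers))
    pid <- headers
    loc <- rep(NA_character_, length(headers))
  }
  if (any(grepl("*", seqs, fixed = TRUE))) {
    warning("stripping '*' stop characters from ", sum(grepl("[*]", seqs)), " record(s)")
    seqs <- gsub("*", "", seqs, fixed = TRUE)
  }
  out <- lapply(split(seq_along(gid), factor(gid, levels = unique(gid))), function(idx) {
    l <- suppressWarnings(as.integer(loc[idx]))
    if (anyNA(l)) l <- seq_along(idx)
    o <- order(l)
    proteome(gid[idx][1L], pid[idx][o], seqs[idx][o], locus = l[o],
             taxon_group = taxon_group, completeness = completeness)
  })
  out
}

#' Write proteomes to a multi-FASTA file
#'
#' Inverse of [read_fasta()]: headers are `>genomeID|proteinID|locus`,
#' sequences wrapped at 60 columns. Output is byte-stable for a given
#' input, so cohorts serialize reproducibly.
#'
#' @param proteomes A `Proteome` or list of `Proteome` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteomes, path) {
  if (inherits(proteomes, "Proteome")) proteomes <- list(proteomes)
  con <- file(path, "wb")  # binary mode: identical bytes on every platform
  on.exit(close(con))
  for (p in proteomes) {
    df <- p$proteins
    for (i in seq_len(nrow(df))) {
      writeLines(sprintf(">%s|%s|%d", p$genome_id, df$protein_id[i], df$locus[i]), con)
      s <- df$sequence[i]
      starts <- seq(1L, nchar(s), by = 60L)
      writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
    }
  }
  invisible(path)
}
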