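# Cofactor-binding motif grammar:
#   capital letter          fixed residue        (C, H, K, ...)
#   X                       wildcard             (one arbitrary residue)
#   (A/B/...)               alternation          (one residue from the set)
#   X{m}, X{m,n}, Xm        bounded gap of m (or m..n) arbitrary residues
#   Xn                      open-length gap -> bounded by a configurable
#                           default, (1, 50) unless overridden
# Ambiguity codes in sequences (B Z J U O X) satisfy wildcards and gaps but
# never a fixed residue or an alternation: an ambiguous residue must not
# create a fixed-anchor hit.

DEFAULT_OPEN_GAP <- c(1L, 50L)

#' Parse a motif specification string
#'
#' Compiles a motif written in the field's conventional shorthand (e.g.
#' `"CXXCH"` for the canonical heme c binding motif, `"GX(H/R)XCXGX"` for
#' the heme b motif, `"CX{4,5}CXnCX{3}C"` for the siroheme / [Fe-S]
#' cysteine cluster) into a `MotifPattern`: an element list plus length
#' bounds and a regular-expression translation used by the scanner.
#'
#' @param spec Motif string. Grammar: capital letters are fixed residues;
#'   `X` a single-residue wildcard; `(A/B)` an alternation; `X{m}`,
#'   `X{m,n}` or `X<digits>` a bounded gap; the literal token `Xn` an
#'   open-length gap bounded by `open_gap`.
#' @param pattern_id Identifier for the pattern; defaults to `spec`.
#' @param open_gap Length-2 integer bound substituted for the open `Xn`
#'   gap token. The default (1, 50) comfortably spans known sulfite
#'   reductase cysteine-cluster spacings.
#' @return A `MotifPattern` object with fields `pattern_id`, `spec`,
#'   `elements`, `min_len`, `max_len`.
#' @examples
#' p <- parse_motif("CXXCH")
#' p$min_len  # 5
#' @export
parse_motif <- function(spec, pattern_id = spec, open_gap = DEFAULT_OPEN_GAP) {
  stopifnot(is.character(spec), length(spec) == 1L, nzchar(spec))
  open_gap <- as.integer(open_gap)
  stopifnot(length(open_gap) == 2L, open_gap[1] >= 0L, open_gap[1] <= open_gap[2])
  chars <- strsplit(spec, "")[[1]]
  elements <- list()
  i <- 1L
  n <- length(chars)
  perr <- function(msg, pos) stop(sprintf("motif parse error at position %d in '%s': %s",
                                          pos, spec, msg), call. = FALSE)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "X") {
      nxt <- if (i < n) chars[i + 1L] else ""
      if (nxt == "{") {
        j <- i + 2L
        k <- j
        while (k <= n && chars[k] != "}") k <- k + 1L
        if (k > n) perr("unterminated gap '{'", i + 1L)
        body <- paste(chars[j:(k - 1L)], collapse = "")
        if (!grepl("^[0-9]+(,[0-9]+)?$", body)) perr(sprintf("bad gap '{%s}'", body), j)
        bounds <- as.integer(strsplit(body, ",")[[1]])
        if (length(bounds) == 1L) bounds <- c(bounds, bounds)
        if (bounds[1] > bounds[2]) perr(sprintf("gap min %d > max %d", bounds[1], bounds[2]), j)
        elements[[length(elements) + 1L]] <- list(type = "gap", min = bounds[1], max = bounds[2])
        i <- k + 1L
      } else if (nxt == "n") {
        elements[[length(elements) + 1L]] <- list(type = "gap",
                                                  min = open_gap[1], max = open_gap[2])
        i <- i + 2L
      } else if (grepl("^[0-9]$", nxt)) {
        j <- i + 1L
        k <- j
        while (k <= n && grepl("^[0-9]$", chars[k])) k <- k + 1L
        m <- as.integer(paste(chars[j:(k - 1L)], collapse = ""))
        elements[[length(elements) + 1L]] <- list(type = "gap", min = m, max = m)
        i <- k
      } else {
        elements[[length(elements) + 1L]] <- list(type = "wildcard")
        i <- i + 1L
      }
    } else if (ch == "(") {
      k <- i + 1L
      while (k <= n && chars[k] != ")") k <- k + 1L
      if (k > n) perr("unterminated alternation '('", i)
      body <- paste(chars[(i + 1L):(k - 1L)], collapse = "")
      if (!grepl("^[A-Z](/[A-Z])*$", body)) perr(sprintf("bad alternation '(%s)'", body), i)
      set <- strsplit(body, "/", fixed = TRUE)[[1]]
      elements[[length(elements) + 1L]] <- list(type = "alternation", set = set)
      i <- k + 1L
    } else if (grepl("^[A-WYZ]$", ch)) {  # any capital but X (X is the wildcard token)
      elements[[length(elements) + 1L]] <- list(type = "fixed", aa = ch)
      i <- i + 1L
    } else {
      perr(sprintf("unexpected character '%s'", ch), i)
    }
  }
  if (length(elements) == 0L) perr("empty pattern", 1L)
  min_len <- sum(vapply(elements, function(e) if (e$type == "gap") e$min else 1L, 0L))
  max_len <- sum(vapply(elements, function(e) if (e$type == "gap") e$max else 1L, 0L))
  structure(list(pattern_id = pattern_id, spec = spec, elements = elements,
                 min_len = min_len, max_len = max_len,
                 regex = motif_regex(elements)),
            class = "MotifPattern")
}

# Regex translation. Fixed residues and alternations are literal classes over
# the standard alphabet only; wildcards and gaps admit ambiguity codes too.
# Gaps use lazy quantifiers so each start position reports its shortest-gap
# expansion.
motif_regex <- function(elements) {
  any_res <- sprintf("[%s]", paste(AA_ALLOWED, collapse = ""))
  parts <- vapply(elements, function(e) {
    switch(e$type,
           fixed = e$aa,
           wildcard = any_res,
           alternation = sprintf("[%s]", paste(e$set, collapse = "")),
           gap = if (e$min == e$max) sprintf("%s{%d}", any_res, e$min)
                 else sprintf("%s{%d,%d}?", any_res, e$min, e$max))
  }, "")
  paste(parts, collapse = "")
}

#' Render a compiled motif back to its specification string
#'
#' Round-trip companion of [parse_motif()]: the rendered string reparses
#' to an equivalent pattern.
#'
#' @param pattern A `MotifPattern`.
#' @return A motif specification string.
#' @export
render_motif <- function(pattern) {
  stopifnot(inherits(pattern, "MotifPattern"))
  paste(vapply(pattern$elements, function(e) {
    switch(e$type,
           fixed = e$aa,
           wildcard = "X",
           alternation = sprintf("(%s)", paste(e$set, collapse = "/")),
           gap = if (e$min == e$max) sprintf("X{%d}", e$min)
                 else sprintf("X{%d,%d}", e$min, e$max))
  }, ""), collapse = "")
}

#' @export
print.MotifPattern <- function(x, ...) {
  cat(sprintf("MotifPattern '%s': %s (length %d..%d)\n",
              x$pattern_id, x$spec, x$min_len, x$max_len))
  invisible(x)
}

#' Scan one protein sequence for a motif
#'
#' Reports every match start position. Overlapping matches at distinct
#' starts are all reported; for patterns with variable-length gaps a
#' single match per start is returned, instantiated with the shortest-gap
#' expansion (leftmost gap minimized first). Motif occurrence is counted
#' per protein downstream, so match multiplicity within a start is not
#' enumerated.
#'
#' @param sequence Uppercase amino-acid sequence (ambiguity codes allowed;
#'   they satisfy wildcard and gap positions only).
#' @param pattern A `MotifPattern` from [parse_motif()].
#' @param protein_id Identifier attached to the result rows.
#' @return A data.frame with columns `protein_id`, `pattern_id`, `start`,
#'   `end` (1-based inclusive residue coordinates), zero rows if no match.
#' @examples
#' scan_protein("MACPPCHG", parse_motif("CXXCH"))  # span (3, 7)
#' @export
scan_protein <- function(sequence, pattern, protein_id = NA_character_) {
  stopifnot(inherits(pattern, "MotifPattern"))
  empty <- data.frame(protein_id = character(), pattern_id = character(),
                      start = integer(), end = integer(), stringsAsFactors = FALSE)
  if (is.na(sequence) || nchar(sequence) < pattern$min_len) return(empty)
  # A lookahead wrapper makes gregexpr report every (possibly overlapping)
  # start; the capture group carries the lazily-expanded match length.
  m <- gregexpr(sprintf("(?=(%s))", pattern$regex), sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m)
  lens <- attr(m, "capture.length")[, 1L]
  data.frame(protein_id = protein_id, pattern_id = pattern$pattern_id,
             start = starts, end = starts + as.integer(lens) - 1L,
             stringsAsFactors = FALSE)
}

#' Scan a whole proteome against a motif library
#'
#' @param prot A `Proteome`.
#' @param library A list of `MotifPattern` objects (non-empty).
#' @return A list with `matches` (data.frame: `genome_id`, `protein_id`,
#'   `pattern_id`, `start`, `end`) and `protein_counts` (named integer:
#'   per pattern, the number of distinct proteins with at least one match
#'   — a protein with three CXXCH matches contributes one).
#' @export
scan_proteome <- function(prot, library) {
  stopifnot(inherits(prot, "Proteome"))
  if (length(library) == 0L) stop("motif library must be non-empty")
  if (inherits(library, "MotifPattern")) library <- list(library)
  if (anyDuplicated(prot$proteins$protein_id)) stop("duplicate protein ids")
  res <- list()
  for (pat in library) {
    for (i in seq_len(nrow(prot$proteins))) {
      hit <- scan_protein(prot$proteins$sequence[i], pat, prot$proteins$protein_id[i])
      if (nrow(hit)) res[[length(res) + 1L]] <- hit
    }
  }
  matches <- if (length(res)) do.call(rbind, res) else
    data.frame(protein_id = character(), pattern_id = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  matches <- cbind(genome_id = rep(prot$genome_id, nrow(matches)), matches,
                   stringsAsFactors = FALSE)
  ids <- vapply(library, `[[`, "", "pattern_id")
  counts <- vapply(ids, function(pid)
    length(unique(matches$protein_id[matches$pattern_id == pid])), 0L)
  names(counts) <- ids
  list(matches = matches, protein_counts = counts)
}

#' Per-genome [Fe-S]-motif proteome fraction
#'
#' The fraction of protein-coding genes whose product carries at least one
#' [Fe-S]-cluster binding motif: motif-bearing proteins divided by the
#' total protein count of the genome. Motif detection is a sequence-level
#' approximation of domain-model screening, so absolute fractions on real
#' proteomes are indicative rather than comparable across methods.
#'
#' @param prot A non-empty `Proteome`.
#' @param fes_library List of `MotifPattern`s describing [Fe-S] binding
#'   motifs; defaults to the [4Fe-4S] ferredoxin pattern `CX{2}CX{2}CX{3}C`
#'   and the broader cysteine cluster `CX{4,5}CXnCX{3}C`.
#' @return A fraction in \[0, 1\].
#' @export
fes_fraction <- function(prot, fes_library = default_fes_library()) {
  stopifnot(inherits(prot, "Proteome"))
  if (nrow(prot$proteins) == 0L) stop("empty proteome")
  sc <- scan_proteome(prot, fes_library)
  length(unique(sc$matches$protein_id)) / nrow(prot$proteins)
}

#' Default [Fe-S] cluster motif library
#' @return List of `MotifPattern`s.
#' @export
default_fes_library <- function() {
  list(parse_motif("CX{2}CX{2}CX{3}C", pattern_id = "FeS_ferredoxin"),
       parse_motif("CX{4,5}CXnCX{3}C", pattern_id = "FeS_cys_cluster"))
}

#' Default cofactor motif library
#'
#' Heme c (CXXCH and the minor CPV, CX15CH, CXXCK motifs), heme b
#' (GX(H/R)XCXGX), siroheme (CX4-5CXnCX3C, split into its two spacings),
#' and the [Fe-S] patterns of [default_fes_library()]. The single-cysteine
#' CXXXAH variant seen in some heme-sensor proteins is available via
#' `include_cxxxah = TRUE` but disabled by default.
#'
#' @param include_cxxxah Include the optional CXXXAH pattern.
#' @param open_gap Bound applied to open-length `Xn` gaps.
#' @return Named list of `MotifPattern`s keyed by pattern id.
#' @export
default_motif_library <- function(include_cxxxah = FALSE, open_gap = DEFAULT_OPEN_GAP) {
  specs <- c(heme_c_CXXCH = "CXXCH",
             heme_c_CPV = "CPV",
             heme_c_CX15CH = "CX{15}CH",
             heme_c_CXXCK = "CXXCK",
             heme_b_GXHRXCXGX = "GX(H/R)XCXGX",
             siroheme_CX4 = "CX{4}CXnCX{3}C",
             siroheme_CX5 = "CX{5}CXnCX{3}C",
             FeS_ferredoxin = "CX{2}CX{2}CX{3}C",
             FeS_cys_cluster = "CX{4,5}CXnCX{3}C")
  if (include_cxxxah) specs <- c(specs, heme_c_single_CXXXAH = "CXXXAH")
  lapply(stats::setNames(names(specs), names(specs)),
         function(id) parse_motif(specs[[id]], pattern_id = id, open_gap = open_gap))
}

#' Annotate minor heme c motif hits with companion evidence
#'
#' CX15CH and CXXCK hits gain a `companion_cxxch` flag when the same
#' protein also carries a canonical CXXCH motif; CPV hits gain a
#' `ccmb_associated` note (CPV is diagnostic of the heme exporter subunit
#' CcmB rather than a general heme c attachment site).
#'
#' @param matches Match data.frame from [scan_proteome()].
#' @return `matches` with `companion_cxxch` (logical) and `note`
#'   (character) columns added.
#' @export
annotate_heme_c_matches <- function(matches) {
  cxxch_prot <- unique(matches$protein_id[matches$pattern_id == "heme_c_CXXCH"])
  minor <- matches$pattern_id %in% c("heme_c_CX15CH", "heme_c_CXXCK")
  matches$companion_cxxch <- minor & matches$protein_id %in% cxxch_prot
  matches$note <- ifelse(matches$pattern_id == "heme_c_CPV", "CcmB-associated", "")
  matches
}

#' Check a sequence for a family's required motifs
#'
#' Used as desk-scale domain evidence: families can require that accepted
#' homologs carry a diagnostic motif (e.g. sulfite reductases must carry
#' the siroheme cysteine cluster). Vacuously true for families that
#' declare no required motifs.
#'
#' @param sequence Protein sequence.
#' @param family A `QueryFamily` (see [query_family()]).
#' @param library Named list of `MotifPattern`s resolving the family's
#'   `required_motifs` pattern ids.
#' @return `TRUE` iff every required pattern matches at least once.
#' @export
verify_required_motif <- function(sequence, family, library = default_motif_library()) {
  req <- family$required_motifs
  if (length(req) == 0L) return(TRUE)
  for (pid in req) {
    pat <- library[[pid]]
    if (is.null(pat)) stop("required motif '", pid, "' not in library")
    if (nrow(scan_protein(sequence, pat)) == 0L) return(FALSE)
  }
  TRUE
}

#' Read / write a motif library as TSV
#'
#' Columns: `pattern_id`, `spec`, `cofactor_class`.
#' @param path TSV file path.
#' @param open_gap Bound applied to open-length gaps on read.
#' @return `read_motif_library`: named list of `MotifPattern`s.
#' @export
read_motif_library <- function(path, open_gap = DEFAULT_OPEN_GAP) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pattern_id", "spec") %in% names(df)))
  pats <- lapply(seq_len(nrow(df)), function(i)
    parse_motif(df$spec[i], pattern_id = df$pattern_id[i], open_gap = open_gap))
  stats::setNames(pats, df$pattern_id)
}

#' @rdname read_motif_library
#' @param library Named list of `MotifPattern`s.
#' @param cofactor_class Optional character vector parallel to `library`.
#' @export
write_motif_library <- function(library, path, cofactor_class = NA_character_) {
  df <- data.frame(pattern_id = vapply(library, `[[`, "", "pattern_id"),
                   spec = vapply(library, `[[`, "", "spec"),
                   cofactor_class = cofactor_class,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
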