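# Pathway-level presence/absence calling.
#
# Family presence bits are combined into pathway features with explicit
# counting rules: the [Fe-S] scaffold requires both SufB and SufC; the
# shared tetrapyrrole trunk (HemBCD) is scored positive on any one of
# HemB/HemC/HemD, tolerating incomplete draft genomes; the alternative
# heme pathway requires all of AhbABCD, with a companion Ahb_partial
# any-of feature that preserves draft-genome signal. Fe(II) import is a
# categorical feature over FeoA/FeoB co-occurrence.

#' Default pathway rule set
#'
#' @param feo_as_columns If `TRUE` (default) the Feo category is expanded
#'   into three binary matrix columns (`FeoAB`, `FeoA_only`, `FeoB_only`);
#'   otherwise kept as one categorical field only.
#' @param overrides Named list of manual feature overrides, each a
#'   character vector of genome ids forced positive for that feature
#'   (used e.g. for known homologs sitting outside search thresholds);
#'   applied by [build_matrix()] and logged.
#' @return A `PathwayRuleSet` object.
#' @export
pathway_rules <- function(feo_as_columns = TRUE, overrides = list()) {
  rules <- list(
    SufBC = list(op = "all", of = c("SufB", "SufC")),
    HemBCD = list(op = "any", of = c("HemB", "HemC", "HemD")),
    AhbABCD = list(op = "all", of = c("AhbA", "AhbB", "AhbC", "AhbD")),
    Ahb_partial = list(op = "any", of = c("AhbA", "AhbB", "AhbC", "AhbD"))
  )
  structure(list(rules = rules, feo_as_columns = feo_as_columns,
                 overrides = overrides),
            class = "PathwayRuleSet")
}

#' Call pathway features for one genome
#'
#' @param presence Named logical vector of family presence (families not
#'   named default to `FALSE`).
#' @param rules A [pathway_rules()] object.
#' @param genome_id Genome identifier carried into the result.
#' @return A `FeatureVector`: list with `genome_id`, `features` (named
#'   0/1 integer vector: the family bits plus the pathway bits),
#'   `feo_state` (one of `"FeoAB"`, `"FeoA_only"`, `"FeoB_only"`,
#'   `"none"`), and `flags` (`heme_auxotroph_candidate`,
#'   `siroheme_orphan`).
#' @export
call_features <- function(presence, rules = pathway_rules(), genome_id = NA_character_) {
  stopifnot(inherits(rules, "PathwayRuleSet"))
  get_bit <- function(f) isTRUE(unname(presence[f])[1L])  # absent family -> FALSE
  feats <- as.integer(vapply(names(presence), function(f) get_bit(f), TRUE))
  names(feats) <- names(presence)
  for (fname in names(rules$rules)) {
    r <- rules$rules[[fname]]
    bits <- vapply(r$of, get_bit, TRUE)
    feats[[fname]] <- as.integer(switch(r$op, all = all(bits), any = any(bits),
                                        stop("unknown rule op '", r$op, "'")))
  }
  feo_a <- get_bit("FeoA"); feo_b <- get_bit("FeoB")
  feo_state <- if (feo_a && feo_b) "FeoAB" else if (feo_a) "FeoA_only"
    else if (feo_b) "FeoB_only" else "none"
  if (rules$feo_as_columns) {
    feats[["FeoAB"]] <- as.integer(feo_a && feo_b)
    feats[["FeoA_only"]] <- as.integer(feo_a && !feo_b)
    feats[["FeoB_only"]] <- as.integer(!feo_a && feo_b)
  }
  fv <- structure(list(genome_id = genome_id, features = feats,
                       feo_state = feo_state,
                       flags = c(heme_auxotroph_candidate = FALSE,
                                 siroheme_orphan = FALSE)),
                  class = "FeatureVector")
  fv$flags[["heme_auxotroph_candidate"]] <- flag_heme_auxotrophy(fv)
  fv$flags[["siroheme_orphan"]] <- flag_siroheme_orphan(fv)
  fv
}

#' Flag candidate heme auxotrophs
#'
#' A genome that encodes heme-using proteins but lacks a complete
#' alternative heme biosynthesis pathway (AhbABCD) plausibly relies on
#' environmentally derived heme.
#'
#' @param vector A `FeatureVector`.
#' @param heme_user_families Families whose presence marks heme usage.
#' @return `TRUE` iff at least one heme-user family is present and
#'   AhbABCD is absent.
#' @export
flag_heme_auxotrophy <- function(vector,
                                 heme_user_families = c("VhoC", "HdrE", "KatG",
                                                        "CydA", "CydB")) {
  f <- vector$features
  users <- heme_user_families[heme_user_families %in% names(f)]
  any(f[users] == 1L) && identical(unname(f[["AhbABCD"]]), 0L)
}

#' Flag siroheme orphans
#'
#' Genomes carrying the siroheme biosynthesis enzymes SirA and SirC but
#' no known siroheme-binding sulfite reductase (neither Dsr nor Fsr)
#' point to unknown siroheme destinations.
#'
#' @param vector A `FeatureVector`.
#' @return `TRUE` iff SirA and SirC present and both Dsr and Fsr absent.
#' @export
flag_siroheme_orphan <- function(vector) {
  f <- vector$features
  bit <- function(x) if (x %in% names(f)) f[[x]] == 1L else FALSE
  bit("SirA") && bit("SirC") && !bit("Dsr") && !bit("Fsr")
}

#' Assemble the genomes-by-features presence/absence matrix
#'
#' @param vectors List of `FeatureVector`s with unique genome ids.
#' @param feature_order Optional character vector fixing column order;
#'   defaults to the union of feature names in first-seen order.
#' @param rules The rule set (supplies manual overrides, applied here
#'   with a message naming each override).
#' @return An integer 0/1 matrix, genomes as rows (input order), features
#'   as columns, of class `PresenceAbsenceMatrix`.
#' @export
build_matrix <- function(vectors, feature_order = NULL, rules = NULL) {
  ids <- vapply(vectors, `[[`, "", "genome_id")
  if (anyDuplicated(ids))
    stop("duplicate genome ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is.null(feature_order)) {
    feature_order <- character()
    for (v in vectors) feature_order <- union(feature_order, names(v$features))
  }
  m <- matrix(0L, nrow = length(vectors), ncol = length(feature_order),
              dimnames = list(ids, feature_order))
  for (i in seq_along(vectors)) {
    f <- vectors[[i]]$features
    common <- intersect(names(f), feature_order)
    m[i, common] <- as.integer(f[common])
  }
  if (!is.null(rules) && length(rules$overrides)) {
    for (feat in names(rules$overrides)) {
      g <- intersect(rules$overrides[[feat]], ids)
      if (length(g) && feat %in% feature_order) {
        message("manual override: ", feat, " forced positive for ",
                paste(g, collapse = ", "))
        m[g, feat] <- 1L
      }
    }
  }
  class(m) <- c("PresenceAbsenceMatrix", class(m))
  m
}

#' Write / read a presence/absence matrix as TSV
#' @param m A `PresenceAbsenceMatrix` (genomes x features).
#' @param path TSV path (genomes as rows; first column `genome_id`).
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(genome_id = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "integer"
  rownames(m) <- df$genome_id
  class(m) <- c("PresenceAbsenceMatrix", class(m))
  m
}
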