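# Independent oracles, deliberately written with none of the package's
# scanning machinery (no regex translation): direct enumeration of start
# positions and gap assignments.

# All concrete gap assignments of a pattern, ordered lexicographically with
# the leftmost gap most significant (the order in which a backtracking
# matcher with minimal-first gap expansion explores them).
oracle_assignments <- function(pattern) {
  gaps <- Filter(function(e) e$type == "gap", pattern$elements)
  if (length(gaps) == 0L) return(matrix(integer(), nrow = 1L, ncol = 0L))
  grid <- expand.grid(lapply(gaps, function(g) g$min:g$max))
  grid <- grid[do.call(order, as.list(grid)), , drop = FALSE]
  as.matrix(grid)
}

# Does the pattern, with the given gap assignment, match chars at start?
oracle_match_at <- function(chars, elements, start, assignment) {
  pos <- start
  gi <- 0L
  for (e in elements) {
    if (e$type == "gap") {
      gi <- gi + 1L
      pos <- pos + assignment[gi]
      next
    }
    if (pos > length(chars)) return(FALSE)
    ch <- chars[pos]
    ok <- switch(e$type,
                 fixed = identical(ch, e$aa),
                 wildcard = TRUE,
                 alternation = ch %in% e$set)
    if (!ok) return(FALSE)
    pos <- pos + 1L
  }
  pos - 1L <= length(chars)
}

# Full oracle scan: every matching start, span from the first (leftmost-gap
# minimal) matching assignment.
oracle_scan <- function(sequence, pattern) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  asg <- oracle_assignments(pattern)
  fixed_len <- sum(vapply(pattern$elements,
                          function(e) if (e$type == "gap") 0L else 1L, 0L))
  out <- list()
  for (start in seq_len(max(n - pattern$min_len + 1L, 0L))) {
    for (r in seq_len(nrow(asg))) {
      a <- asg[r, ]
      len <- fixed_len + sum(a)
      if (start + len - 1L > n) next
      if (oracle_match_at(chars, pattern$elements, start, a)) {
        out[[length(out) + 1L]] <- c(start = start, end = start + len - 1L)
        break
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(), end = integer()))
  as.data.frame(do.call(rbind, out))
}

# Column-wise percent identity between equal-length sequences.
oracle_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  100 * sum(ca == cb) / length(ca)
}

# Brute-force pairwise Jaccard over a binary matrix, via explicit sets.
oracle_jaccard <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    A <- which(m[i, ] == 1L); B <- which(m[j, ] == 1L)
    u <- length(union(A, B))
    d[i, j] <- if (u == 0) 0 else 1 - length(intersect(A, B)) / u
  }
  d
}

# Random test sequence over an alphabet enriched for motif anchors so the
# scanner sees genuine hits, not just absences.
random_test_seq <- function(len, alphabet = c("C", "H", "A", "G")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Small synthetic hit record for classifier tests.
make_hit <- function(e_value = 1e-10, identity = 50, coverage = 80,
                     family = "SufB", subject = "p1", locus = 1L) {
  data.frame(family_name = family, genome_id = "G1",
             subject_protein_id = subject, e_value = e_value,
             bit_score = 100, percent_identity = identity,
             percent_query_coverage = coverage, query_length = 100L,
             locus = locus, stringsAsFactors = FALSE)
}

# Vectorized variant of oracle_scan for larger corpora: enumerates concrete
# gap assignments and checks anchored positions across all starts at once.
# Independently derived from oracle_scan; both implement the same
# enumeration semantics.
oracle_scan_fast <- function(sequence, pattern) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (n < pattern$min_len)
    return(data.frame(start = integer(), end = integer()))
  asg <- oracle_assignments(pattern)
  # per-assignment anchored offsets
  ends <- rep(NA_integer_, n)
  for (r in seq_len(nrow(asg))) {
    a <- asg[r, ]
    offs <- integer(); checks <- list(); gi <- 0L; off <- 0L
    for (e in pattern$elements) {
      if (e$type == "gap") { gi <- gi + 1L; off <- off + a[gi]; next }
      offs <- c(offs, off); checks <- c(checks, list(e)); off <- off + 1L
    }
    len <- off
    if (len > n) next
    starts <- seq_len(n - len + 1L)
    ok <- rep(TRUE, length(starts))
    for (j in seq_along(offs)) {
      e <- checks[[j]]
      ch <- chars[starts + offs[j]]
      ok <- ok & switch(e$type,
                        fixed = ch == e$aa,
                        wildcard = TRUE,
                        alternation = ch %in% e$set)
      if (!any(ok)) break
    }
    hit <- starts[ok]
    new <- hit[is.na(ends[hit])]
    ends[new] <- new + len - 1L
  }
  st <- which(!is.na(ends))
  data.frame(start = st, end = ends[st])
}
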