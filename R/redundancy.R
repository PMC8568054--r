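# Deterministic redundancy collapse of candidate proteins: exact
# duplicates first, then single-linkage clusters of near-duplicates
# found by global-alignment identity.

#' Global-alignment percent identity between two protein sequences
#'
#' Needleman-Wunsch with match +1, mismatch 0 and linear gap penalty -1
#' (end gaps penalized); identity is the number of identical aligned
#' pairs divided by the alignment length (gap columns included). Among
#' co-optimal alignments, the one with the most identical pairs (then
#' the most aligned columns) defines the value, so the result is
#' well-defined and reproducible.
#'
#' @param a,b Non-empty sequence strings.
#' @param detail If `TRUE`, return the full alignment statistics list
#'   (`identity`, `score`, `matches`, `aligned_pairs`,
#'   `alignment_length`, `coverage_a`, `coverage_b`), where coverage is
#'   the fraction of a sequence's residues sitting in non-gap columns.
#' @return Identity fraction in `[0, 1]`, or the statistics list.
#' @export
pairwise_identity <- function(a, b, detail = FALSE) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1, length(b) == 1)
  if (nchar(a) == 0 || nchar(b) == 0)
    stop("sequences must be non-empty")
  st <- .align_stats(toupper(a), toupper(b))
  if (detail) st else st$identity
}

.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Collapse redundant protein records
#'
#' Two-phase deterministic replacement for manual deduplication of a
#' candidate set. Phase 1 removes exact sequence duplicates, keeping the
#' lexicographically smallest id. Phase 2 single-links pairs whose
#' global-alignment identity is at least `identity_threshold` and whose
#' mutual coverage (aligned non-gap columns over each sequence length)
#' is at least `min_coverage`; each cluster collapses to its longest
#' member (ties: smallest id). The operation is idempotent and
#' order-independent.
#'
#' Pairs whose length ratio `min/max` falls below
#' `max(identity_threshold, min_coverage)` cannot satisfy both cutoffs
#' (identity <= min/max and coverage of the longer <= min/max), so they
#' are skipped without alignment; this is exact, not heuristic.
#'
#' @param records Protein records data frame (`id`, `sequence`).
#' @param identity_threshold Identity cutoff in `[0, 1]`; default 0.99
#'   removes near-identical assembly artifacts only.
#' @param min_coverage Mutual coverage cutoff in `[0, 1]`; default 0.9.
#' @return List with `records` (kept rows, input order) and `report`, a
#'   data frame over all input ids with columns `id`, `kept`, `reason`
#'   (`exact-duplicate` or `near-duplicate` for removed ids) and
#'   `collapsed_into`; thresholds are attached as attributes.
#' @export
collapse_redundant <- function(records, identity_threshold = 0.99,
                               min_coverage = 0.9) {
  stopifnot(is.data.frame(records), !anyDuplicated(records$id))
  ids <- records$id
  seqs <- records$sequence
  reason <- rep(NA_character_, length(ids))
  into <- rep(NA_character_, length(ids))

  # phase 1: exact duplicates
  grp <- split(seq_along(ids), seqs)
  for (g in grp) {
    if (length(g) < 2) next
    keep <- g[order(ids[g])][1]
    for (i in setdiff(g, keep)) {
      reason[i] <- "exact-duplicate"
      into[i] <- ids[keep]
    }
  }
  alive <- which(is.na(reason))

  # phase 2: near-duplicates among survivors (single linkage)
  if (length(alive) > 1 && identity_threshold <= 1) {
    lens <- nchar(seqs[alive])
    cut <- max(identity_threshold, min_coverage)
    parent <- seq_along(alive)
    ord <- order(lens)
    for (ii in seq_along(ord)) {
      for (jj in seq_len(ii - 1L)) {
        i <- ord[ii]; j <- ord[jj]   # lens[j] <= lens[i]
        if (lens[j] < cut * lens[i]) next
        st <- .align_stats(seqs[alive[i]], seqs[alive[j]])
        if (st$identity >= identity_threshold &&
            min(st$coverage_a, st$coverage_b) >= min_coverage) {
          ri <- .uf_find(parent, i); rj <- .uf_find(parent, j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    roots <- vapply(seq_along(alive), function(i) .uf_find(parent, i),
                    integer(1))
    for (cl in split(seq_along(alive), roots)) {
      if (length(cl) < 2) next
      keep <- cl[order(-lens[cl], ids[alive[cl]])][1]
      for (i in setdiff(cl, keep)) {
        reason[alive[i]] <- "near-duplicate"
        into[alive[i]] <- ids[alive[keep]]
      }
    }
  }

  # re-point exact-duplicate targets whose representative was removed,
  # so no removed id maps to another removed id
  removed <- !is.na(reason)
  for (i in which(removed)) {
    t <- match(into[i], ids)
    while (removed[t]) {
      into[i] <- into[t]
      t <- match(into[i], ids)
    }
  }

  report <- data.frame(id = ids, kept = !removed, reason = reason,
                       collapsed_into = into, stringsAsFactors = FALSE)
  attr(report, "identity_threshold") <- identity_threshold
  attr(report, "min_coverage") <- min_coverage
  list(records = records[!removed, , drop = FALSE], report = report)
}

#' Write a deduplication report to TSV
#'
#' @param report Report data frame from [collapse_redundant()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dedup_report <- function(report, path) {
  out <- as.data.frame(report)
  out$reason[is.na(out$reason)] <- ""
  out$collapsed_into[is.na(out$collapsed_into)] <- ""
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
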