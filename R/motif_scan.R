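# RING octet scanner: locates the eight zinc-coordinating metal-ligand
# residues (M1..M8) with bounded spacers directly in protein sequences.

#' Octet grammar for RING metal-ligand scanning
#'
#' A grammar fixes the residues allowed at each of the eight
#' metal-ligand positions and the permitted number of residues strictly
#' between consecutive ligands (spacers s1..s7). The default follows the
#' canonical RING consensus
#' C-X2-C-X(9-39)-C-X(1-3)-(C/H)-X(2-3)-(C/H)-X2-C-X(4-48)-C-X(1-6)-C:
#' positions 1, 2, 3, 6, 7 and 8 are Cys-conserved while positions 4 and
#' 5 admit Cys or His; the last spacer is deliberately wide so that
#' HCa/HCb spacing is decided by the classifier, not the scanner.
#' `X` never matches a ligand position: an unknown residue cannot be
#' confirmed as Cys/His.
#'
#' @param residues List of 8 character vectors over `c("C","H")`, the
#'   residues allowed at M1..M8.
#' @param spacer_min,spacer_max Integer vectors of length 7; bounds
#'   (inclusive) for spacers s1..s7.
#' @return An `octet_grammar` object.
#' @export
octet_grammar <- function(residues = NULL,
                          spacer_min = c(2L, 9L, 1L, 2L, 2L, 4L, 1L),
                          spacer_max = c(2L, 39L, 3L, 3L, 2L, 48L, 6L)) {
  if (is.null(residues))
    residues <- list("C", "C", "C", c("C", "H"), c("C", "H"), "C", "C", "C")
  residues <- lapply(residues, as.character)
  spacer_min <- as.integer(spacer_min)
  spacer_max <- as.integer(spacer_max)
  if (length(residues) != 8 || any(lengths(residues) == 0))
    stop("grammar needs a non-empty residue set for each of M1..M8")
  if (!all(unlist(residues) %in% c("C", "H")))
    stop("metal-ligand residues must be C or H")
  if (length(spacer_min) != 7 || length(spacer_max) != 7)
    stop("grammar needs 7 spacer intervals")
  if (any(spacer_min < 0) || any(spacer_min > spacer_max))
    stop("each spacer interval needs 0 <= min <= max")
  structure(list(residues = residues, spacer_min = spacer_min,
                 spacer_max = spacer_max),
            class = "octet_grammar")
}

.empty_positions <- function() matrix(integer(), nrow = 0, ncol = 8)

# Exhaustive enumeration of all ligand-position octets compatible with
# the grammar, grown level by level over precomputed candidate positions.
.enumerate_octets <- function(chars, grammar) {
  allowed <- lapply(grammar$residues, function(set) which(chars %in% set))
  if (length(allowed[[1]]) == 0) return(.empty_positions())
  paths <- matrix(allowed[[1]], ncol = 1)
  for (lev in 2:8) {
    if (nrow(paths) == 0) return(.empty_positions())
    cand <- allowed[[lev]]
    if (length(cand) == 0) return(.empty_positions())
    lo <- paths[, lev - 1] + grammar$spacer_min[lev - 1] + 1L
    hi <- paths[, lev - 1] + grammar$spacer_max[lev - 1] + 1L
    nxt <- lapply(seq_len(nrow(paths)),
                  function(i) cand[cand >= lo[i] & cand <= hi[i]])
    reps <- lengths(nxt)
    paths <- cbind(paths[rep.int(seq_len(nrow(paths)), reps), , drop = FALSE],
                   unlist(nxt, use.names = FALSE))
  }
  paths
}

# Redundancy resolution on raw position octets:
#   1. among matches sharing M1, keep the smallest total spacer sum
#      (ties: lexicographically smallest position tuple);
#   2. among overlapping spans keep the leftmost-starting (then smallest
#      spacer sum, then lexicographic tuple), greedily left to right.
.resolve_octets <- function(pos) {
  if (nrow(pos) <= 1) return(pos)
  spsum <- pos[, 8] - pos[, 1] - 7L
  ord <- do.call(order, c(list(pos[, 1], spsum),
                          lapply(seq_len(8), function(k) pos[, k])))
  pos <- pos[ord, , drop = FALSE]
  pos <- pos[!duplicated(pos[, 1]), , drop = FALSE]
  keep <- logical(nrow(pos))
  max_end <- -1L
  for (i in seq_len(nrow(pos))) {
    if (pos[i, 1] > max_end) {
      keep[i] <- TRUE
      max_end <- max(max_end, pos[i, 8])
    }
  }
  pos[keep, , drop = FALSE]
}

.match_frame <- function(id, chars, pos, offset = 0L) {
  if (nrow(pos) == 0) {
    out <- data.frame(protein_id = character(),
                      m1 = integer(), m2 = integer(), m3 = integer(),
                      m4 = integer(), m5 = integer(), m6 = integer(),
                      m7 = integer(), m8 = integer(),
                      residues = character(),
                      s1 = integer(), s2 = integer(), s3 = integer(),
                      s4 = integer(), s5 = integer(), s6 = integer(),
                      s7 = integer(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  res <- apply(pos, 1, function(p) paste(chars[p], collapse = ""))
  sp <- pos[, -1, drop = FALSE] - pos[, -8, drop = FALSE] - 1L
  abs_pos <- pos + offset
  out <- data.frame(protein_id = rep(id, nrow(pos)), abs_pos,
                    residues = res, sp,
                    start = abs_pos[, 1], end = abs_pos[, 8],
                    stringsAsFactors = FALSE)
  names(out) <- c("protein_id", paste0("m", 1:8), "residues",
                  paste0("s", 1:7), "start", "end")
  rownames(out) <- NULL
  out
}

#' Scan one protein for RING metal-ligand octets
#'
#' Enumerates every ligand-position octet compatible with the grammar
#' (identical, as a set, to naive backtracking over all C/H index
#' combinations), then resolves redundancy: one match per M1 (smallest
#' total spacer sum) and one match per overlapping span (leftmost
#' start). Disjoint domains in the same protein are all reported.
#'
#' @param record A one-row data frame (or named list) with `id` and
#'   `sequence`, or a plain sequence string.
#' @param grammar An [octet_grammar()].
#' @param resolve If `FALSE`, return all raw matches without redundancy
#'   resolution (used by property tests and diagnostics).
#' @param offset Integer added to all reported coordinates (used when
#'   scanning a sub-sequence cut out of a longer protein).
#' @return Data frame of matches ordered by `m1`: ligand positions
#'   `m1..m8` (1-based, inclusive), `residues` (8 letters), spacers
#'   `s1..s7`, and the `start`/`end` span.
#' @export
scan_octets <- function(record, grammar = octet_grammar(), resolve = TRUE,
                        offset = 0L) {
  if (is.character(record) && length(record) == 1) {
    id <- NA_character_
    seqs <- record
  } else {
    id <- record$id
    seqs <- record$sequence
  }
  stopifnot(length(seqs) == 1, nchar(seqs) >= 1)
  chars <- strsplit(toupper(seqs), "")[[1]]
  pos <- .enumerate_octets(chars, grammar)
  if (resolve) pos <- .resolve_octets(pos)
  pos <- pos[order(pos[, 1]), , drop = FALSE]
  .match_frame(id, chars, pos, offset = as.integer(offset))
}

#' Scan a whole proteome for RING octets
#'
#' @param records Data frame of protein records (see [read_fasta()]);
#'   ids must be unique.
#' @param grammar An [octet_grammar()].
#' @param hits Optional data frame of domain hits (see
#'   [read_hmmer_domtbl()]); when given, scanning is restricted to hit
#'   envelopes extended by `flank`, mirroring an upstream HMMER stage.
#' @param flank Residues added on both sides of each hit envelope.
#' @return Data frame of matches for all proteins with at least one
#'   match, ordered by protein id then `m1`; coordinates always refer to
#'   the full-length sequence.
#' @export
scan_proteome <- function(records, grammar = octet_grammar(), hits = NULL,
                          flank = 25L) {
  stopifnot(is.data.frame(records))
  if (anyDuplicated(records$id))
    stop("duplicate protein ids in records")
  if (!is.null(hits)) {
    windows <- filter_by_hits(records, hits, flank)
    raw <- lapply(seq_len(nrow(windows)), function(i)
      scan_octets(windows[i, ], grammar, resolve = FALSE,
                  offset = windows$offset[i]))
    raw <- do.call(rbind, c(list(.match_frame(character(), character(),
                                              .empty_positions())), raw))
    # resolve per protein across windows (windows are disjoint but
    # resolution rules are defined on the full coordinate space)
    out <- lapply(split(raw, raw$protein_id), function(mf) {
      pos <- .resolve_octets(as.matrix(mf[, paste0("m", 1:8)]))
      rec <- records[records$id == mf$protein_id[1], ]
      .match_frame(rec$id, strsplit(rec$sequence, "")[[1]], pos)
    })
  } else {
    out <- lapply(seq_len(nrow(records)), function(i)
      scan_octets(records[i, ], grammar))
  }
  out <- do.call(rbind, c(list(.match_frame(character(), character(),
                                            .empty_positions())), out))
  out <- out[order(out$protein_id, out$m1), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict protein records to domain-hit envelopes
#'
#' Cuts each protein down to the union of its hit envelopes extended by
#' `flank` residues on each side (overlapping windows are merged), so a
#' scanner run on the result reports matches in original full-sequence
#' coordinates via the `offset` column.
#'
#' @param records Protein records data frame.
#' @param hits Domain hits data frame (`protein_id`, `env_start`,
#'   `env_end`).
#' @param flank Non-negative integer flank.
#' @return Data frame with columns `id`, `sequence` (the window) and
#'   `offset` (0-based shift back to full coordinates). Hits referencing
#'   unknown proteins are skipped with a warning; with no usable hits an
#'   empty frame is returned and a message logged.
#' @export
filter_by_hits <- function(records, hits, flank = 25L) {
  stopifnot(is.data.frame(records), is.data.frame(hits))
  flank <- as.integer(flank)
  stopifnot(flank >= 0)
  unknown <- setdiff(unique(hits$protein_id), records$id)
  if (length(unknown) > 0) {
    warning("skipping hit(s) for unknown protein(s): ",
            paste(unknown, collapse = ", "))
    hits <- hits[!hits$protein_id %in% unknown, , drop = FALSE]
  }
  if (nrow(hits) == 0) {
    message("no usable domain hits supplied; nothing to scan")
    return(data.frame(id = character(), sequence = character(),
                      offset = integer(), stringsAsFactors = FALSE))
  }
  out <- lapply(split(hits, hits$protein_id), function(h) {
    len <- nchar(records$sequence[records$id == h$protein_id[1]])
    ir <- IRanges::IRanges(start = pmax(1L, h$env_start - flank),
                           end = pmin(len, h$env_end + flank))
    ir <- IRanges::reduce(ir)
    data.frame(id = h$protein_id[1],
               sequence = substring(records$sequence[records$id == h$protein_id[1]],
                                    IRanges::start(ir), IRanges::end(ir)),
               offset = IRanges::start(ir) - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write scanner/classifier matches to TSV
#'
#' @param matches Match data frame (optionally carrying a `subtype`
#'   column from [classify_matches()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matches <- function(matches, path) {
  cols <- c("protein_id", paste0("m", 1:8), "residues", paste0("s", 1:7))
  out <- as.data.frame(matches)[, cols, drop = FALSE]
  out$subtype <- if ("subtype" %in% names(matches)) matches$subtype else ""
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
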