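# Readers and writers for the external formats the pipeline touches:
# protein FASTA, HMMER3 per-domain tables (domtblout), expression TSV and
# qPCR Ct TSV. All tabular files are tab-separated UTF-8 with a mandatory
# header and '.' as decimal point.

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
           "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read a protein FASTA file
#'
#' Parses a (possibly line-wrapped) FASTA file into a data frame of
#' protein records. Sequences are upper-cased; a single trailing `*`
#' (translated stop codon, common in archive proteomes) is stripped.
#' `X` is accepted as an unknown residue; any other non-standard letter
#' is an error. Internal `*` characters are rejected.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id`, `description`, `sequence`,
#'   one row per record, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) {
    return(data.frame(id = character(), description = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  set <- Biostrings::readAAStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  names(seqs) <- NULL

  if (any(ids == "")) stop("FASTA record with empty identifier")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0)
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))

  # trailing stop allowed, stripped; '*' anywhere else is an error
  seqs <- sub("\\*$", "", seqs)
  if (any(grepl("\\*", seqs, fixed = FALSE)))
    stop("internal '*' in sequence(s): ",
         paste(ids[grepl("\\*", seqs)], collapse = ", "))
  if (any(nchar(seqs) == 0))
    stop("empty sequence for id(s): ",
         paste(ids[nchar(seqs) == 0], collapse = ", "))

  allowed <- c(.AA20, "X")
  bad <- lapply(strsplit(seqs, ""), function(ch) unique(setdiff(ch, allowed)))
  if (any(lengths(bad) > 0)) {
    off <- which(lengths(bad) > 0)
    stop("invalid residue character(s) ",
         paste(unique(unlist(bad[off])), collapse = ", "),
         " in sequence(s): ", paste(ids[off], collapse = ", "))
  }
  data.frame(id = ids, description = desc, sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' @param records Data frame with columns `id`, `sequence` and optionally
#'   `description`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  hdr <- ifelse(is.na(desc) | desc == "", records$id,
                paste(records$id, desc))
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read HMMER3 per-domain tabular output (domtblout)
#'
#' One domain hit per non-comment line; envelope coordinates are taken
#' from the `env from`/`env to` columns (20 and 21), the per-domain
#' independent E-value from column 13 and the domain bit score from
#' column 14.
#'
#' @param path Path to a domtblout file.
#' @return Data frame with columns `protein_id`, `model_name`,
#'   `env_start`, `env_end`, `independent_evalue`, `score`.
#' @export
read_hmmer_domtbl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  empty <- data.frame(protein_id = character(), model_name = character(),
                      env_start = integer(), env_end = integer(),
                      independent_evalue = numeric(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (!any(keep)) return(empty)
  lineno <- which(keep)
  rows <- lapply(seq_along(lineno), function(k) {
    f <- strsplit(trimws(lines[lineno[k]]), "[ \t]+")[[1]]
    if (length(f) < 22)
      stop("malformed domtblout line ", lineno[k], ": expected >= 22 fields, got ",
           length(f))
    num <- suppressWarnings(as.numeric(f[c(13, 14, 20, 21)]))
    if (anyNA(num))
      stop("malformed domtblout line ", lineno[k], ": non-numeric field")
    if (num[3] < 1 || num[3] > num[4])
      stop("malformed domtblout line ", lineno[k],
           ": envelope coordinates ", num[3], "..", num[4])
    if (num[1] < 0)
      stop("malformed domtblout line ", lineno[k], ": negative E-value")
    data.frame(protein_id = f[1], model_name = f[4],
               env_start = as.integer(num[3]), env_end = as.integer(num[4]),
               independent_evalue = num[1], score = num[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a gene x stress x timepoint expression table
#'
#' Expects a tab-separated file with header columns `gene`, `stress`,
#' `timepoint`, `control`, `treatment`. Every (gene, stress, timepoint)
#' cell must carry both a control and a treatment value, both
#' non-negative.
#'
#' @param path Path to the TSV file.
#' @return A validated `expression_matrix` data frame.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   colClasses = "character", check.names = FALSE,
                   fileEncoding = "UTF-8")
  need <- c("gene", "stress", "timepoint", "control", "treatment")
  if (!all(need %in% names(df)))
    stop("expression table must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  df$control <- suppressWarnings(as.numeric(df$control))
  df$treatment <- suppressWarnings(as.numeric(df$treatment))
  as_expression_matrix(df)
}

#' Validate an expression table
#'
#' @param df Data frame with columns `gene`, `stress`, `timepoint`,
#'   `control`, `treatment`.
#' @return The validated data frame with class `expression_matrix`.
#' @export
as_expression_matrix <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("gene", "stress", "timepoint", "control", "treatment")
  if (!all(need %in% names(df)))
    stop("expression table must have columns: ", paste(need, collapse = ", "))
  if (anyNA(df$control) || anyNA(df$treatment)) {
    miss <- df[is.na(df$control) | is.na(df$treatment),
               c("gene", "stress", "timepoint")]
    stop("missing/non-numeric expression value(s) at: ",
         paste(utils::head(paste(miss$gene, miss$stress, miss$timepoint,
                                 sep = "/"), 10), collapse = ", "))
  }
  if (any(df$control < 0) || any(df$treatment < 0))
    stop("negative expression values are not allowed")
  key <- paste(df$gene, df$stress, df$timepoint, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), c("gene", "stress", "timepoint")]
    stop("duplicate (gene, stress, timepoint) row(s): ",
         paste(utils::head(paste(d$gene, d$stress, d$timepoint, sep = "/"), 10),
               collapse = ", "))
  }
  class(df) <- c("expression_matrix", "data.frame")
  df
}

#' Write an expression table to TSV
#'
#' @param mat An `expression_matrix` (or compatible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(mat, path) {
  write.table(as.data.frame(mat)[, c("gene", "stress", "timepoint",
                                     "control", "treatment")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' Tab-separated with header `sample`, `gene`, `replicate`, `ct`.
#' The housekeeping gene (reference used to form delta-Ct) must be
#' present in every sample, and the calibrator sample must exist.
#'
#' @param path Path to the TSV file.
#' @param housekeeping Housekeeping gene label (default `"GAPDH"`,
#'   glyceraldehyde-3-phosphate dehydrogenase).
#' @param calibrator Calibrator (untreated control) sample label.
#' @return A `ct_table` data frame with `housekeeping` and `calibrator`
#'   attributes.
#' @export
read_ct_table <- function(path, housekeeping = "GAPDH", calibrator = "control") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   colClasses = "character", check.names = FALSE,
                   fileEncoding = "UTF-8")
  need <- c("sample", "gene", "replicate", "ct")
  if (!all(need %in% names(df)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  df$ct <- suppressWarnings(as.numeric(df$ct))
  as_ct_table(df, housekeeping = housekeeping, calibrator = calibrator)
}

#' Validate a Ct table
#'
#' @param df Data frame with columns `sample`, `gene`, `replicate`, `ct`.
#' @param housekeeping Housekeeping gene label.
#' @param calibrator Calibrator sample label.
#' @return The validated `ct_table`.
#' @export
as_ct_table <- function(df, housekeeping = "GAPDH", calibrator = "control") {
  stopifnot(is.data.frame(df))
  need <- c("sample", "gene", "replicate", "ct")
  if (!all(need %in% names(df)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  if (anyNA(df$ct) || any(!is.finite(df$ct)))
    stop("all Ct values must be finite numbers")
  key <- paste(df$sample, df$gene, df$replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (sample, gene, replicate) row(s) in Ct table")
  samples <- unique(df$sample)
  has_hk <- vapply(samples, function(s)
    any(df$sample == s & df$gene == housekeeping), logical(1))
  if (!all(has_hk))
    stop("housekeeping gene '", housekeeping, "' missing for sample(s): ",
         paste(samples[!has_hk], collapse = ", "))
  if (!calibrator %in% samples)
    stop("calibrator sample '", calibrator, "' not present in Ct table")
  structure(df, class = c("ct_table", "data.frame"),
            housekeeping = housekeeping, calibrator = calibrator)
}

#' Write a Ct table to TSV
#'
#' @param ct A `ct_table` (or compatible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct, path) {
  write.table(as.data.frame(ct)[, c("sample", "gene", "replicate", "ct")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
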