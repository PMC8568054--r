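# End-to-end orchestration: scan -> classify -> dedup -> stress calls ->
# Venn -> report, as one deterministic run with machine-readable outputs.

#' Pipeline run configuration
#'
#' @param fasta Path to the proteome FASTA file.
#' @param expression Optional path to an expression TSV (see
#'   [read_expression_table()]); when given, the stress screen and Venn
#'   decomposition run.
#' @param hits Optional path to an HMMER3 domtblout file; when given,
#'   scanning is restricted to hit envelopes plus `flank`.
#' @param out_dir Optional output directory; created if needed. When
#'   set, the run writes `matches.tsv`, `family_summary.json`,
#'   `dedup_report.tsv`, `stress_calls.tsv`, `venn.json`, `report.json`
#'   and `config.yaml`.
#' @param grammar An [octet_grammar()].
#' @param signatures A [signature_table()].
#' @param flank Flank width for hit-restricted scanning.
#' @param identity_threshold,min_coverage Dedup cutoffs (see
#'   [collapse_redundant()]).
#' @param threshold_log2,pseudocount Stress-call parameters (see
#'   [call_responsive_all()]).
#' @param gene_mode `"H2"` restricts the stress screen to genes whose
#'   protein carries a RING-H2 domain (the survey's default); `"all"`
#'   screens every gene in the expression table.
#' @param stresses Expected stress names; an expression table containing
#'   any other stress aborts the run.
#' @return A `run_config` object.
#' @export
run_config <- function(fasta, expression = NULL, hits = NULL, out_dir = NULL,
                       grammar = octet_grammar(),
                       signatures = signature_table(),
                       flank = 25L,
                       identity_threshold = 0.99, min_coverage = 0.9,
                       threshold_log2 = 1, pseudocount = 0.1,
                       gene_mode = c("H2", "all"),
                       stresses = c("cold", "salt", "drought", "MeJA")) {
  gene_mode <- match.arg(gene_mode)
  for (p in c(fasta, expression, hits))
    if (!is.null(p) && !file.exists(p)) stop("file not found: ", p)
  structure(list(fasta = fasta, expression = expression, hits = hits,
                 out_dir = out_dir, grammar = grammar,
                 signatures = signatures, flank = as.integer(flank),
                 identity_threshold = identity_threshold,
                 min_coverage = min_coverage,
                 threshold_log2 = threshold_log2,
                 pseudocount = pseudocount, gene_mode = gene_mode,
                 stresses = stresses),
            class = "run_config")
}

.config_as_list <- function(config) {
  list(fasta = config$fasta, expression = config$expression,
       hits = config$hits, out_dir = config$out_dir,
       grammar = list(residues = config$grammar$residues,
                      spacer_min = config$grammar$spacer_min,
                      spacer_max = config$grammar$spacer_max),
       signatures = config$signatures$rows,
       flank = config$flank,
       identity_threshold = config$identity_threshold,
       min_coverage = config$min_coverage,
       threshold_log2 = config$threshold_log2,
       pseudocount = config$pseudocount,
       gene_mode = config$gene_mode,
       stresses = config$stresses)
}

#' Write a run configuration to YAML
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(.config_as_list(config), path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path Path to a YAML file written by [write_run_config()] (or
#'   hand-edited in the same layout).
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  grammar <- if (is.null(x$grammar)) octet_grammar() else
    octet_grammar(residues = x$grammar$residues,
                  spacer_min = unlist(x$grammar$spacer_min),
                  spacer_max = unlist(x$grammar$spacer_max))
  sigs <- if (is.null(x$signatures)) signature_table() else
    signature_table(rows = lapply(x$signatures, function(r) {
      if (!is.null(r$spacers))
        r$spacers <- lapply(r$spacers, function(con)
          lapply(con, as.integer))
      r$m4 <- unlist(r$m4); r$m5 <- unlist(r$m5)
      r
    }))
  run_config(fasta = x$fasta, expression = x$expression, hits = x$hits,
             out_dir = x$out_dir, grammar = grammar, signatures = sigs,
             flank = if (is.null(x$flank)) 25L else x$flank,
             identity_threshold = x$identity_threshold %||% 0.99,
             min_coverage = x$min_coverage %||% 0.9,
             threshold_log2 = x$threshold_log2 %||% 1,
             pseudocount = x$pseudocount %||% 0.1,
             gene_mode = x$gene_mode %||% "H2",
             stresses = unlist(x$stresses) %||%
               c("cold", "salt", "drought", "MeJA"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage_msg <- function(stage, ...) message("[", stage, "] ", ...)

#' Run the full survey pipeline
#'
#' Stages: read FASTA (optionally restricted to domain-hit envelopes),
#' scan for RING octets, classify subtypes, collapse redundant
#' candidates, then (if an expression table is configured) call
#' stress-responsive genes and decompose the responsive sets into Venn
#' cells. Stage counts are validated for conservation before the report
#' is returned; identical config and inputs give byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return A `run_report` list: `version`, `config_hash`, `counts`
#'   (per-stage), `family` (a `family_summary`), `dedup` report, `calls`
#'   and `venn` (when expression was analyzed), plus the paths written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  .stage_msg("read", "loading proteome from ", config$fasta)
  records <- read_fasta(config$fasta)
  hits <- if (!is.null(config$hits)) read_hmmer_domtbl(config$hits) else NULL

  .stage_msg("scan", nrow(records), " proteins")
  matches <- scan_proteome(records, config$grammar, hits = hits,
                           flank = config$flank)
  .stage_msg("scan", nrow(matches), " octet matches in ",
             length(unique(matches$protein_id)), " proteins")

  .stage_msg("classify", "applying signature table")
  matches <- classify_matches(matches, config$signatures)

  candidates <- records[records$id %in% matches$protein_id, , drop = FALSE]
  .stage_msg("dedup", nrow(candidates), " candidate proteins")
  dd <- collapse_redundant(candidates, config$identity_threshold,
                           config$min_coverage)
  kept_ids <- dd$records$id
  matches_kept <- matches[matches$protein_id %in% kept_ids, , drop = FALSE]
  family <- summarize_family(matches_kept, config$signatures)
  .stage_msg("dedup", length(kept_ids), " kept, ",
             nrow(candidates) - length(kept_ids), " removed")

  calls <- NULL
  venn <- NULL
  if (!is.null(config$expression)) {
    .stage_msg("stress", "loading expression from ", config$expression)
    mat <- read_expression_table(config$expression)
    unknown <- setdiff(unique(mat$stress), config$stresses)
    if (length(unknown) > 0)
      stop("[stress] unknown stress name(s) in expression table: ",
           paste(unknown, collapse = ", "))
    genes <- unique(mat$gene)
    if (config$gene_mode == "H2") {
      h2 <- unique(matches_kept$protein_id[matches_kept$subtype == "RING-H2"])
      genes <- intersect(genes, h2)
      .stage_msg("stress", length(genes), " RING-H2 genes in the screen")
    }
    if (length(genes) > 0) {
      calls <- call_responsive_all(mat, config$threshold_log2,
                                   config$pseudocount, genes = genes,
                                   stresses = config$stresses)
      venn <- venn_decompose(calls, config$stresses)
      .stage_msg("venn", "union of responsive sets: ", venn$union_size)
    } else {
      .stage_msg("stress", "no genes to screen; skipping")
    }
  }

  counts <- list(
    proteins_in = nrow(records),
    octet_matches = nrow(matches),
    candidates = nrow(candidates),
    duplicates_removed = nrow(candidates) - length(kept_ids),
    proteins_kept = length(kept_ids),
    domain_counts = as.list(family$domain_counts),
    protein_counts = as.list(family$protein_counts),
    per_stress_responsive = if (!is.null(venn)) as.list(venn$per_stress),
    venn_cells = if (!is.null(venn)) as.list(venn$cells),
    genes_screened = if (!is.null(calls)) length(unique(calls$gene))
  )
  # conservation checks
  stopifnot(counts$candidates == counts$proteins_kept +
              counts$duplicates_removed,
            sum(family$domain_counts) == nrow(matches_kept))
  if (!is.null(venn))
    stopifnot(sum(venn$cells) == venn$union_size,
              all(vapply(venn$stresses, function(s)
                sum(venn$cells[grepl(paste0("(^|&)", s, "(&|$)"),
                                     names(venn$cells))]) ==
                  venn$per_stress[[s]], logical(1))))

  cfg_yaml <- yaml::as.yaml(.config_as_list(config))
  # hash excludes the output location: identical analysis settings give
  # the same hash wherever results are written
  tf <- tempfile(fileext = ".yaml")
  writeLines(yaml::as.yaml(.config_as_list(config)[
    setdiff(names(.config_as_list(config)), "out_dir")]), tf)
  config_hash <- unname(tools::md5sum(tf))
  unlink(tf)

  report <- structure(list(
    version = as.character(utils::packageVersion("ringscreen")),
    config_hash = config_hash,
    counts = counts, family = family, dedup = dd$report,
    calls = calls, venn = venn, kept_ids = kept_ids,
    out_dir = out_dir), class = "run_report")

  if (!is.null(out_dir)) {
    write_matches(matches_kept, file.path(out_dir, "matches.tsv"))
    jsonlite::write_json(
      list(domain_counts = as.list(family$domain_counts),
           protein_counts = as.list(family$protein_counts),
           n_domains = family$n_domains,
           n_classified = family$n_classified,
           n_proteins = family$n_proteins,
           percent = as.list(round(family$percent, 4))),
      file.path(out_dir, "family_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_dedup_report(dd$report, file.path(out_dir, "dedup_report.tsv"))
    if (!is.null(calls))
      write_stress_calls(calls, file.path(out_dir, "stress_calls.tsv"))
    if (!is.null(venn))
      write_venn_json(venn, file.path(out_dir, "venn.json"))
    writeLines(cfg_yaml, file.path(out_dir, "config.yaml"))
    jsonlite::write_json(
      list(version = report$version, config_hash = config_hash,
           counts = counts),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
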