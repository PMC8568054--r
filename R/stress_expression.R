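# Stress-response selection: log2 treatment/control ratios, a
# twofold-at-any-timepoint responsiveness rule, and the full Venn
# decomposition of responsive gene sets across conditions.

#' log2 treatment/control ratio with pseudocount
#'
#' `log2((treatment + pseudocount) / (control + pseudocount))`.
#' Vectorized; antisymmetric in its two value arguments.
#'
#' @param treatment,control Non-negative expression values.
#' @param pseudocount Non-negative stabilizer; must be positive whenever
#'   a value is zero.
#' @return Numeric log2 ratio(s).
#' @export
log2_ratio <- function(treatment, control, pseudocount = 0.1) {
  stopifnot(all(treatment >= 0), all(control >= 0), all(pseudocount >= 0))
  if (any(pseudocount == 0 & (treatment == 0 | control == 0)))
    stop("zero expression value requires a positive pseudocount")
  log2((treatment + pseudocount) / (control + pseudocount))
}

#' Per-timepoint log2 ratios for a whole expression table
#'
#' @param matrix An `expression_matrix`.
#' @param pseudocount See [log2_ratio()].
#' @return Long data frame `gene`, `stress`, `timepoint`, `control`,
#'   `treatment`, `log2_ratio`.
#' @export
log2_ratio_table <- function(matrix, pseudocount = 0.1) {
  df <- as.data.frame(matrix)
  df$log2_ratio <- log2_ratio(df$treatment, df$control, pseudocount)
  df
}

#' Responsiveness call for one gene under one stress
#'
#' A gene is responsive to a stress if any timepoint shows at least a
#' twofold change, i.e. `|log2 ratio| >= threshold_log2` (inclusive:
#' "twice as much" is read as reaching twofold). Direction is `up` if
#' all qualifying timepoints are positive, `down` if all negative,
#' `mixed` otherwise, `none` when not responsive.
#'
#' @param matrix An `expression_matrix`.
#' @param gene,stress Identifiers present in the matrix.
#' @param threshold_log2 Call threshold on `|log2 ratio|`; default 1.
#' @param pseudocount See [log2_ratio()].
#' @return A `stress_call` list: `gene`, `stress`, `timepoints`,
#'   `log2_ratios`, `responsive`, `direction`, `max_abs_log2`.
#' @export
call_responsive <- function(matrix, gene, stress, threshold_log2 = 1,
                            pseudocount = 0.1) {
  df <- as.data.frame(matrix)
  rows <- df$gene == gene & df$stress == stress
  if (!any(rows))
    stop("no expression cells for gene '", gene, "' under stress '",
         stress, "'")
  sub <- df[rows, , drop = FALSE]
  r <- log2_ratio(sub$treatment, sub$control, pseudocount)
  qual <- abs(r) >= threshold_log2
  responsive <- any(qual)
  direction <- if (!responsive) "none"
    else if (all(r[qual] > 0)) "up"
    else if (all(r[qual] < 0)) "down"
    else "mixed"
  structure(list(gene = gene, stress = stress,
                 timepoints = sub$timepoint, log2_ratios = r,
                 responsive = responsive, direction = direction,
                 max_abs_log2 = max(abs(r))),
            class = "stress_call")
}

#' Responsiveness calls for all genes and stresses
#'
#' @param matrix An `expression_matrix`.
#' @param threshold_log2,pseudocount See [call_responsive()].
#' @param genes,stresses Optional subsets; defaults to everything in the
#'   matrix. Every requested (gene, stress) combination must have at
#'   least one timepoint cell.
#' @return Data frame with one row per gene x stress: `gene`, `stress`,
#'   `responsive`, `direction`, `max_abs_log2`, `n_timepoints`.
#' @export
call_responsive_all <- function(matrix, threshold_log2 = 1, pseudocount = 0.1,
                                genes = NULL, stresses = NULL) {
  df <- as.data.frame(matrix)
  if (is.null(genes)) genes <- unique(df$gene)
  if (is.null(stresses)) stresses <- unique(df$stress)
  df <- df[df$gene %in% genes & df$stress %in% stresses, , drop = FALSE]
  have <- unique(paste(df$gene, df$stress, sep = "\r"))
  want <- as.vector(outer(genes, stresses, paste, sep = "\r"))
  if (!all(want %in% have)) {
    miss <- want[!want %in% have]
    stop("missing expression cells for: ",
         paste(utils::head(sub("\r", "/", miss), 10), collapse = ", "))
  }
  df$log2_ratio <- log2_ratio(df$treatment, df$control, pseudocount)
  key <- factor(paste(df$gene, df$stress, sep = "\r"), levels = want)
  out <- do.call(rbind, lapply(split(df, key), function(sub) {
    r <- sub$log2_ratio
    qual <- abs(r) >= threshold_log2
    responsive <- any(qual)
    data.frame(gene = sub$gene[1], stress = sub$stress[1],
               responsive = responsive,
               direction = if (!responsive) "none"
                 else if (all(r[qual] > 0)) "up"
                 else if (all(r[qual] < 0)) "down" else "mixed",
               max_abs_log2 = max(abs(r)),
               n_timepoints = nrow(sub),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(match(out$gene, genes), match(out$stress, stresses)), ]
}

.subset_keys <- function(stresses) {
  k <- length(stresses)
  keys <- character(0)
  for (size in seq_len(k)) {
    cmb <- utils::combn(stresses, size)
    keys <- c(keys, apply(cmb, 2, paste, collapse = "&"))
  }
  keys
}

#' Venn decomposition of responsive gene sets
#'
#' Splits the union of responsive genes into exact-membership cells: the
#' cell `"cold&salt"` holds the genes responsive to cold and salt and to
#' nothing else. Cells are disjoint and sum to the union size; each
#' per-stress total is the sum of the cells containing that stress.
#' Generalizes to up to 6 conditions (2^k - 1 cells).
#'
#' @param calls Data frame from [call_responsive_all()] (needs `gene`,
#'   `stress`, `responsive`), covering the identical gene set for every
#'   stress.
#' @param stresses Optional stress ordering; defaults to order of
#'   appearance.
#' @return A `venn_summary` list: `stresses`, `per_stress` (named
#'   responsive counts), `cells` (named counts for all 2^k - 1 exact
#'   cells), `exclusive` (single-stress cells), `all_intersection`,
#'   `union_size`, `n_genes` and `gene_lists` (sorted, per non-empty
#'   cell).
#' @export
venn_decompose <- function(calls, stresses = NULL) {
  stopifnot(all(c("gene", "stress", "responsive") %in% names(calls)))
  if (is.null(stresses)) stresses <- unique(calls$stress)
  k <- length(stresses)
  if (k < 1 || k > 6) stop("between 1 and 6 stresses supported")
  if (!setequal(unique(calls$stress), stresses))
    stop("calls cover stresses ", paste(unique(calls$stress), collapse = ", "),
         " but ", paste(stresses, collapse = ", "), " requested")
  genes <- unique(calls$gene)
  tab <- table(calls$gene, calls$stress)
  if (any(tab != 1)) {
    bad <- rownames(tab)[apply(tab != 1, 1, any)]
    stop("gene(s) without exactly one call per stress: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  mem <- matrix(FALSE, length(genes), k, dimnames = list(genes, stresses))
  mem[cbind(match(calls$gene, genes), match(calls$stress, stresses))] <-
    calls$responsive
  key <- apply(mem, 1, function(m) paste(stresses[m], collapse = "&"))
  keys <- .subset_keys(stresses)
  cells <- stats::setNames(integer(length(keys)), keys)
  tb <- table(key[key != ""])
  cells[names(tb)] <- as.integer(tb)
  gene_lists <- lapply(split(genes[key != ""], key[key != ""]), sort)
  structure(list(
    stresses = stresses,
    per_stress = stats::setNames(colSums(mem)[stresses], stresses),
    cells = cells,
    exclusive = cells[stresses],
    all_intersection = unname(cells[paste(stresses, collapse = "&")]),
    union_size = sum(key != ""),
    n_genes = length(genes),
    gene_lists = gene_lists
  ), class = "venn_summary")
}

#' Select genes from a Venn summary
#'
#' @param summary A [venn_decompose()] result.
#' @param mode One of `"all"` (responsive to every stress),
#'   `"exclusive"` (responsive to `stress` only), `"union"` (responsive
#'   to anything), or `"cell"` (exact membership given by `stress`, a
#'   vector of stresses).
#' @param stress Stress name(s) for modes `"exclusive"` and `"cell"`.
#' @return Sorted character vector of gene ids.
#' @export
select_candidates <- function(summary, mode = c("all", "exclusive", "union",
                                                "cell"),
                              stress = NULL) {
  stopifnot(inherits(summary, "venn_summary"))
  mode <- match.arg(mode)
  pick <- function(key) {
    g <- summary$gene_lists[[key]]
    if (is.null(g)) character(0) else g
  }
  switch(mode,
    all = pick(paste(summary$stresses, collapse = "&")),
    union = {
      g <- unlist(summary$gene_lists, use.names = FALSE)
      if (is.null(g)) character(0) else sort(unique(g))
    },
    exclusive = {
      if (is.null(stress) || length(stress) != 1 ||
          !stress %in% summary$stresses)
        stop("mode 'exclusive' needs one known stress name")
      pick(stress)
    },
    cell = {
      if (is.null(stress) || !all(stress %in% summary$stresses))
        stop("mode 'cell' needs a vector of known stress names")
      pick(paste(summary$stresses[summary$stresses %in% stress],
                 collapse = "&"))
    })
}

#' Write responsiveness calls to TSV
#' @param calls Data frame from [call_responsive_all()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stress_calls <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Serialize a Venn summary to JSON
#' @param summary A `venn_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_venn_json <- function(summary, path) {
  x <- list(stresses = summary$stresses,
            per_stress = as.list(summary$per_stress),
            cells = as.list(summary$cells),
            exclusive = as.list(summary$exclusive),
            all_intersection = summary$all_intersection,
            union_size = summary$union_size,
            n_genes = summary$n_genes,
            gene_lists = summary$gene_lists)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
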