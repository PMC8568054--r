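# Relative quantification of qPCR data by the classic 2^-ddCt method
# (amplification efficiency fixed at 2, no efficiency correction).

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, delta-Ct = Ct(target) - Ct(housekeeping), pairing
#' target and housekeeping wells by (sample, replicate). Per sample the
#' mean delta-Ct is formed, delta-delta-Ct is taken against the
#' calibrator sample, and fold change = `2^(-ddCt)`. The calibrator's
#' fold is 1 by construction, and adding a constant to all Ct values of
#' a sample (target and housekeeping alike) leaves folds unchanged.
#'
#' Replicate aggregation: with `"nested"`, replicate labels of the form
#' `"<biological>.<technical>"` (e.g. `"b1.t2"`) are averaged within
#' each biological replicate first, then across biological replicates;
#' `"pooled"` takes one mean over all replicates. `"auto"` (default)
#' uses nested aggregation when every label contains a dot. For balanced
#' designs the two agree. Replicate dispersion is always reported as the
#' standard deviation of per-replicate delta-Ct values.
#'
#' @param ct A `ct_table` (see [read_ct_table()]).
#' @param target_gene Gene to quantify.
#' @param housekeeping,calibrator Override the table's designated
#'   housekeeping gene / calibrator sample.
#' @param aggregation `"auto"`, `"nested"` or `"pooled"`.
#' @return Data frame with one row per sample: `sample`, `gene`,
#'   `n_replicates`, `mean_dct`, `sd_dct`, `ddct`, `fold`.
#' @export
delta_delta_ct <- function(ct, target_gene,
                           housekeeping = attr(ct, "housekeeping"),
                           calibrator = attr(ct, "calibrator"),
                           aggregation = c("auto", "nested", "pooled")) {
  aggregation <- match.arg(aggregation)
  stopifnot(is.data.frame(ct))
  if (is.null(housekeeping) || is.null(calibrator))
    stop("housekeeping gene and calibrator sample must be designated")
  df <- as.data.frame(ct)
  if (!target_gene %in% df$gene)
    stop("target gene '", target_gene, "' not in Ct table")
  if (!calibrator %in% df$sample)
    stop("calibrator sample '", calibrator, "' not in Ct table")
  tg <- df[df$gene == target_gene, c("sample", "replicate", "ct")]
  hk <- df[df$gene == housekeeping, c("sample", "replicate", "ct")]
  m <- merge(tg, hk, by = c("sample", "replicate"),
             suffixes = c("_target", "_hk"))
  samples <- unique(df$sample)
  n_rep <- vapply(samples, function(s) sum(m$sample == s), integer(1))
  if (any(n_rep < 1))
    stop("no paired target/housekeeping replicate for sample(s): ",
         paste(samples[n_rep < 1], collapse = ", "))
  m$dct <- m$ct_target - m$ct_hk

  if (aggregation == "auto")
    aggregation <- if (all(grepl(".", m$replicate, fixed = TRUE)))
      "nested" else "pooled"
  mean_dct <- vapply(samples, function(s) {
    d <- m[m$sample == s, ]
    if (aggregation == "nested") {
      bio <- sub("\\..*$", "", d$replicate)
      mean(tapply(d$dct, bio, mean))
    } else mean(d$dct)
  }, numeric(1))
  sd_dct <- vapply(samples, function(s) {
    d <- m$dct[m$sample == s]
    if (length(d) > 1) stats::sd(d) else NA_real_
  }, numeric(1))

  if (!calibrator %in% samples)
    stop("calibrator sample '", calibrator, "' has no '", target_gene,
         "' measurements")
  ddct <- mean_dct - mean_dct[match(calibrator, samples)]
  data.frame(sample = samples, gene = target_gene,
             n_replicates = n_rep,
             mean_dct = unname(mean_dct), sd_dct = unname(sd_dct),
             ddct = unname(ddct), fold = unname(2^(-ddct)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Strongest response across a timecourse
#'
#' For results where samples are timepoints of one treatment, reports
#' each gene's maximum fold change and the timepoint achieving it (ties
#' go to the earliest timepoint in `sample_order`, default input order).
#'
#' @param results Data frame with columns `gene`, `sample`, `fold`
#'   (e.g. rows of [delta_delta_ct()] output, calibrator excluded or
#'   not).
#' @param sample_order Optional ordering of the timepoint labels.
#' @return Data frame `gene`, `max_fold`, `timepoint`.
#' @export
summarize_timecourse <- function(results, sample_order = NULL) {
  stopifnot(all(c("gene", "sample", "fold") %in% names(results)),
            nrow(results) >= 1)
  if (is.null(sample_order)) sample_order <- unique(results$sample)
  out <- lapply(split(results, results$gene), function(d) {
    d <- d[order(match(d$sample, sample_order)), ]
    i <- which.max(d$fold)   # first maximum = earliest timepoint on ties
    data.frame(gene = d$gene[1], max_fold = d$fold[i],
               timepoint = d$sample[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
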