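# a match row with chosen M4/M5 residues and s7, grammar-conformant elsewhere
make_match <- function(m4 = "H", m5 = "H", s7 = 2L) {
  sp <- c(2L, 9L, 1L, 2L, 2L, 4L, s7)
  pos <- cumsum(c(1L, sp + 1L))
  df <- data.frame(protein_id = "p", t(pos),
                   residues = paste0("CCC", m4, m5, "CCC"),
                   t(sp), start = pos[1], end = pos[8],
                   stringsAsFactors = FALSE)
  names(df) <- c("protein_id", paste0("m", 1:8), "residues",
                 paste0("s", 1:7), "start", "end")
  df
}

test_that("default table reproduces the six subtype signatures", {
  expect_equal(classify_match(make_match("H", "H")), "RING-H2")
  expect_equal(classify_match(make_match("H", "C", s7 = 2L)), "RING-HCa")
  expect_equal(classify_match(make_match("H", "C", s7 = 4L)), "RING-HCb")
  expect_equal(classify_match(make_match("C", "C")), "RING-C2")
  expect_equal(classify_match(make_match("C", "H")), "RING-v")
  expect_equal(classify_match(make_match("H", "C", s7 = 3L)), "RING-G")
})

test_that("default signature rows are exhaustive and pairwise disjoint over (M4, M5, s7)", {
  tab <- signature_table()
  for (m4 in c("C", "H")) for (m5 in c("C", "H")) for (s7 in 1:6) {
    hits <- vapply(tab$rows, function(r) {
      ok <- m4 %in% r$m4 && m5 %in% r$m5
      if (ok && !is.null(r$spacers[["7"]])) {
        con <- r$spacers[["7"]]
        if (!is.null(con$values)) ok <- s7 %in% con$values
        if (ok && !is.null(con$exclude)) ok <- !(s7 %in% con$exclude)
      }
      ok
    }, logical(1))
    expect_equal(sum(hits), 1,
                 info = sprintf("M4=%s M5=%s s7=%d", m4, m5, s7))
    expect_equal(classify_match(make_match(m4, m5, s7 = as.integer(s7))),
                 subtype_names(tab)[which(hits)])
  }
})

test_that("every match gets exactly one label; custom tables can leave matches unclassified", {
  h2_only <- suppressWarnings(
    signature_table(rows = list(list(subtype = "RING-H2", m4 = "H", m5 = "H"))))
  expect_equal(classify_match(make_match("C", "C"), h2_only), "unclassified")
  expect_equal(classify_match(make_match("H", "H"), h2_only), "RING-H2")
})

test_that("overlapping user-edited rows trigger a warning; first match wins", {
  expect_warning(
    tab <- signature_table(rows = list(
      list(subtype = "wide", m4 = c("C", "H"), m5 = c("C", "H")),
      list(subtype = "h2", m4 = "H", m5 = "H"))),
    "overlapping")
  expect_equal(classify_match(make_match("H", "H"), tab), "wide")
})

test_that("family summary counts planted subtypes exactly, at both levels", {
  counts <- c("RING-H2" = 6, "RING-HCa" = 4, "RING-HCb" = 2,
              "RING-C2" = 2, "RING-v" = 1, "RING-G" = 1)
  pr <- generate_proteome(proteome_spec(counts = counts, n_decoys = 15,
                                        seed = 31))
  m <- classify_matches(scan_proteome(pr$records))
  fam <- summarize_family(m)
  expect_equal(fam$domain_counts[names(counts)], counts)
  expect_equal(fam$protein_counts[names(counts)],
               stats::setNames(as.integer(counts), names(counts)))
  expect_equal(fam$n_proteins, sum(counts))
  # zero confusion against the planted labels
  merged <- merge(m, pr$truth, by = "protein_id",
                  suffixes = c("_called", "_planted"))
  expect_equal(merged$subtype_called, merged$subtype_planted)
})

test_that("an empty match set yields an all-zero summary", {
  m <- classify_matches(scan_proteome(
    data.frame(id = "d", description = "", sequence = strrep("A", 50))))
  fam <- summarize_family(m)
  expect_true(all(fam$domain_counts == 0))
  expect_equal(fam$n_proteins, 0)
})

test_that("percentages follow domain shares (214 of 335 is 64% rounded)", {
  m <- do.call(rbind, c(
    lapply(1:214, function(i) make_match("H", "H")),
    lapply(1:121, function(i) make_match("C", "C"))))
  m$protein_id <- sprintf("p%03d", seq_len(nrow(m)))
  m$subtype <- vapply(seq_len(nrow(m)),
                      function(i) classify_match(m[i, ]), character(1))
  fam <- summarize_family(m)
  expect_equal(fam$n_classified, 335)
  expect_equal(round(fam$percent[["RING-H2"]]), 64)
  expect_equal(sum(fam$percent), 100)
})
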