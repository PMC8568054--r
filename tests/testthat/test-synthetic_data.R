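test_that("generators are byte-deterministic under a fixed seed", {
  a <- generate_proteome(proteome_spec(seed = 4))
  b <- generate_proteome(proteome_spec(seed = 4))
  expect_identical(a, b)
  expect_false(identical(
    a$records$sequence,
    generate_proteome(proteome_spec(seed = 5))$records$sequence))

  ea <- generate_expression(venn_spec(seed = 4))
  eb <- generate_expression(venn_spec(seed = 4))
  expect_identical(ea, eb)

  ca <- generate_ct(ct_spec(seed = 4))
  cb <- generate_ct(ct_spec(seed = 4))
  expect_identical(ca, cb)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(100)
  x <- runif(1)
  set.seed(100)
  invisible(generate_proteome(proteome_spec(seed = 9)))
  expect_identical(runif(1), x)
})

test_that("a single planted motif is re-found by the scanner at truth positions", {
  pr <- generate_proteome(proteome_spec(counts = c("RING-H2" = 1),
                                        n_decoys = 0, seed = 1))
  expect_equal(nrow(pr$records), 1)
  m <- scan_octets(pr$records[1, ])
  expect_equal(nrow(m), 1)
  expect_equal(unlist(m[paste0("m", 1:8)], use.names = FALSE),
               unlist(pr$truth[paste0("m", 1:8)], use.names = FALSE))
})

test_that("realistic background still yields scanner-clean planted truth", {
  pr <- generate_proteome(proteome_spec(
    counts = c("RING-H2" = 3, "RING-HCa" = 2), n_decoys = 12,
    background = "realistic", seed = 19))
  m <- classify_matches(scan_proteome(pr$records))
  expect_setequal(unique(m$protein_id), pr$truth$protein_id)
  merged <- merge(m, pr$truth, by = "protein_id",
                  suffixes = c("_called", "_planted"))
  expect_equal(merged$subtype_called, merged$subtype_planted)
})

test_that("near-miss decoys violate exactly one constraint and never match", {
  pr <- generate_proteome(proteome_spec(counts = c("RING-H2" = 2),
                                        n_decoys = 30,
                                        near_miss_fraction = 0.5, seed = 28))
  near <- pr$records[pr$records$description == "decoy near-miss", ]
  expect_equal(nrow(near), 15)
  for (i in seq_len(nrow(near)))
    expect_equal(nrow(scan_octets(near[i, ])), 0)
})

test_that("expression generator enforces its noise margin and zero-noise exactness", {
  expect_error(venn_spec(noise_sd = 0.2), "4 \\* noise_sd")
  expect_error(venn_spec(genes = c("a", "b"), cells = c(cold = 3)),
               "only 2 genes")
  expect_error(venn_spec(cells = c("salt&cold" = 1)), "unknown cell")

  sp <- venn_spec(genes = sprintf("g%d", 1:8),
                  cells = c(cold = 2, "cold&salt&drought&MeJA" = 2),
                  noise_sd = 0, seed = 2)
  ex <- generate_expression(sp)
  r <- log2_ratio_table(ex$expression, pseudocount = 0)
  # non-member effects stay inside the planted bound exactly
  nm <- merge(r, ex$truth[, c("gene", "cell")], by = "gene")
  outside <- nm[nm$cell == "", ]
  expect_true(all(abs(outside$log2_ratio) <= sp$nonmember_max_log2 + 1e-12))
  # each member (gene, stress) pair has a qualifying timepoint
  m4 <- nm[nm$cell == "cold&salt&drought&MeJA", ]
  agg <- tapply(abs(m4$log2_ratio), paste(m4$gene, m4$stress), max)
  expect_true(all(agg >= sp$member_min_log2 - 1e-12))
})

test_that("zero-noise Ct generation gives delta-delta-Ct of 0 for fold 1, exact folds otherwise", {
  gc <- generate_ct(ct_spec(folds = c(control = 1, same = 1), noise_sd = 0))
  res <- delta_delta_ct(gc$ct, "target")
  expect_equal(res$ddct, c(0, 0))
  gc4 <- generate_ct(ct_spec(folds = c(control = 1, q = 4), noise_sd = 0))
  expect_equal(delta_delta_ct(gc4$ct, "target")$fold, c(1, 4))
})

test_that("fold 3.28 recovery error follows the propagated noise envelope", {
  # per-replicate delta-Ct noise sd 0.05; mean over 3 x 3 wells and the
  # calibrator contrast give sd(ddCt) = 0.05 * sqrt(2/9), and the fold's
  # relative error is ~ ln(2) * ddCt error
  sd_ddct <- 0.05 * sqrt(2 / 9)
  err <- vapply(1:100, function(s) {
    gc <- generate_ct(ct_spec(folds = c(control = 1, salt12h = 3.28),
                              noise_sd = 0.05, seed = s))
    f <- delta_delta_ct(gc$ct, "target")$fold[2]
    abs(f - 3.28) / 3.28
  }, numeric(1))
  expect_lt(max(err), 4 * sd_ddct * log(2))    # 4 sigma envelope
  expect_gte(mean(err < 3 * sd_ddct * log(2)), 0.95)
})

test_that("ct_spec validates its inputs", {
  expect_error(ct_spec(folds = c(control = 1, bad = -2)), "positive")
  expect_error(ct_spec(folds = c(control = 2, x = 3)), "fold must be 1")
  expect_error(ct_spec(folds = c(a = 1, b = 2)), "include the calibrator")
})

test_that("the study-scale preset carries the documented design", {
  specs <- paper_preset(seed = 1)
  expect_equal(sum(specs$proteome$counts), 335)
  expect_equal(specs$proteome$counts[["RING-H2"]], 214)
  expect_equal(specs$proteome$n_decoys, 500L)
  expect_equal(length(specs$expression$genes), 214)
  expect_equal(sum(specs$expression$cells), 175)
  expect_equal(specs$qpcr$folds[["NaCl-12h"]], 3.28)
  # cell sizes reproduce the reported per-stress marginals
  cells <- specs$expression$cells
  per_stress <- vapply(specs$expression$stresses, function(s)
    sum(cells[grepl(paste0("(^|&)", s, "(&|$)"), names(cells))]),
    numeric(1))
  expect_equal(unname(per_stress), c(128, 134, 121, 82))
})
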