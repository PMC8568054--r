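make_expr <- function(ratios, gene = "g1", stress = "cold", control = 8,
                      pseudocount = 0) {
  # build a table whose log2 ratios at pseudocount 0 are exactly `ratios`
  as_expression_matrix(data.frame(
    gene = gene, stress = stress, timepoint = paste0("t", seq_along(ratios)),
    control = control, treatment = control * 2^ratios))
}

test_that("log2_ratio definition, identity and antisymmetry", {
  expect_equal(log2_ratio(4, 2, 0), 1.0)
  expect_equal(log2_ratio(7.3, 7.3, 0.5), 0)
  expect_equal(log2_ratio(0, 0, 0.1), 0)
  expect_error(log2_ratio(0, 4, 0), "pseudocount")
  set.seed(3)
  a <- runif(50, 0, 100); b <- runif(50, 0, 100); p <- runif(50, 0.01, 1)
  expect_equal(log2_ratio(a, b, p), -log2_ratio(b, a, p))
})

test_that("responsiveness is any-timepoint twofold, with inclusive boundary", {
  cl <- call_responsive(make_expr(c(0.2, 1.3, 0.5)), "g1", "cold",
                        pseudocount = 0)
  expect_true(cl$responsive)
  expect_equal(cl$direction, "up")
  expect_equal(cl$max_abs_log2, 1.3)

  cl0 <- call_responsive(make_expr(c(0, 0, 0)), "g1", "cold", pseudocount = 0)
  expect_false(cl0$responsive)
  expect_equal(cl0$direction, "none")

  # exactly twofold counts as responsive
  clb <- call_responsive(make_expr(1.0), "g1", "cold", pseudocount = 0)
  expect_true(clb$responsive)

  cld <- call_responsive(make_expr(c(-1.4, 0.1)), "g1", "cold",
                         pseudocount = 0)
  expect_equal(cld$direction, "down")
  clm <- call_responsive(make_expr(c(-1.4, 2.0)), "g1", "cold",
                         pseudocount = 0)
  expect_equal(clm$direction, "mixed")

  expect_error(call_responsive(make_expr(1), "g1", "salt"), "no expression")
})

test_that("raising the threshold never adds a responsive gene", {
  set.seed(6)
  ex <- generate_expression(venn_spec(seed = 6))$expression
  lo <- call_responsive_all(ex, threshold_log2 = 1)
  hi <- call_responsive_all(ex, threshold_log2 = 1.8)
  expect_true(all(lo$responsive[hi$responsive]))
})

test_that("Venn cells equal brute-force enumeration on random membership", {
  set.seed(12)
  stresses <- c("cold", "salt", "drought", "MeJA")
  for (i in 1:20) {
    n <- sample(1:64, 1)
    mem <- matrix(runif(n * 4) < runif(1, 0.1, 0.9), n, 4,
                  dimnames = list(sprintf("g%02d", 1:n), stresses))
    v <- venn_decompose(calls_from_membership(mem, stresses), stresses)
    expect_equal(v$cells, oracle_venn_cells(mem, stresses))
    expect_equal(sum(v$cells), v$union_size)
    expect_equal(unname(v$per_stress), unname(colSums(mem)))
    for (s in stresses)
      expect_equal(sum(v$cells[grepl(paste0("(^|&)", s, "(&|$)"),
                                     names(v$cells))]),
                   v$per_stress[[s]])
  }
})

test_that("a single all-stress gene fills only the four-way cell", {
  stresses <- c("cold", "salt", "drought", "MeJA")
  mem <- matrix(TRUE, 1, 4, dimnames = list("g1", stresses))
  v <- venn_decompose(calls_from_membership(mem, stresses), stresses)
  expect_equal(v$all_intersection, 1)
  expect_true(all(v$exclusive == 0))
  expect_equal(v$union_size, 1)
})

test_that("venn_decompose demands a complete gene x stress grid", {
  calls <- data.frame(gene = c("a", "a", "b"),
                      stress = c("cold", "salt", "cold"),
                      responsive = TRUE)
  expect_error(venn_decompose(calls, c("cold", "salt")), "exactly one call")
})

test_that("planted memberships are recovered exactly and selections match", {
  cells <- c(cold = 3, salt = 4, "cold&salt" = 2, "cold&drought&MeJA" = 2,
             "cold&salt&drought&MeJA" = 5)
  sp <- venn_spec(genes = sprintf("G%03d", 1:30), cells = cells, seed = 14)
  ex <- generate_expression(sp)
  calls <- call_responsive_all(ex$expression, threshold_log2 = 1)
  v <- venn_decompose(calls, sp$stresses)
  expect_equal(v$cells[names(cells)], cells)
  expect_equal(v$union_size, sum(cells))

  truth_all4 <- sort(ex$truth$gene[ex$truth$cell ==
                                     "cold&salt&drought&MeJA"])
  expect_equal(select_candidates(v, "all"), truth_all4)
  expect_equal(select_candidates(v, "exclusive", "drought"), character(0))
  expect_equal(select_candidates(v, "exclusive", "cold"),
               sort(ex$truth$gene[ex$truth$cell == "cold"]))
  expect_equal(select_candidates(v, "cell", c("cold", "salt")),
               sort(ex$truth$gene[ex$truth$cell == "cold&salt"]))
  expect_setequal(select_candidates(v, "union"),
                  ex$truth$gene[ex$truth$cell != ""])
  expect_error(select_candidates(v, "nope"), "arg")
})

test_that("select_candidates on an empty summary returns empty lists", {
  stresses <- c("cold", "salt", "drought", "MeJA")
  mem <- matrix(FALSE, 2, 4, dimnames = list(c("a", "b"), stresses))
  v <- venn_decompose(calls_from_membership(mem, stresses), stresses)
  expect_equal(length(select_candidates(v, "union")), 0)
  expect_equal(length(select_candidates(v, "all")), 0)
})
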