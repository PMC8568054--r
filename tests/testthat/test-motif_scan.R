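# Frozen expectation verified against the brute-force enumerator.
test_that("scanner locates a constructed octet at the exact ligand positions", {
  s <- "MAACAACAAAAAAAAACAHAAHAACAAAACAACKK"
  m <- scan_octets(s)
  expect_equal(nrow(m), 1)
  expect_equal(unlist(m[paste0("m", 1:8)], use.names = FALSE),
               c(4L, 7L, 17L, 19L, 22L, 25L, 30L, 33L))
  expect_equal(m$residues, "CCCHHCCC")
  expect_equal(unlist(m[paste0("s", 1:7)], use.names = FALSE),
               c(2L, 9L, 1L, 2L, 2L, 4L, 2L))
  expect_equal(octet_set(as.matrix(m[paste0("m", 1:8)])),
               octet_set(oracle_scan(s)))
})

test_that("sequences without a compatible octet yield no match", {
  expect_equal(nrow(scan_octets(strrep("A", 60))), 0)
  expect_equal(nrow(scan_octets("CC")), 0)
  expect_equal(nrow(scan_octets("MKXV")), 0)  # X never matches a ligand
})

test_that("raw matches equal brute-force enumeration on random sequences", {
  set.seed(421)
  for (i in 1:120) {
    s <- random_protein(sample(20:120, 1))
    got <- scan_octets(s, resolve = FALSE)
    expect_identical(octet_set(as.matrix(got[paste0("m", 1:8)])),
                     octet_set(oracle_scan(s)),
                     info = paste("seq", i))
  }
})

test_that("every reported ligand index points at an allowed residue", {
  set.seed(77)
  g <- octet_grammar()
  for (i in 1:40) {
    s <- random_protein(sample(60:150, 1))
    m <- scan_octets(s, g)
    if (nrow(m) == 0) next
    chars <- strsplit(s, "")[[1]]
    for (r in seq_len(nrow(m)))
      for (k in 1:8)
        expect_true(chars[m[[paste0("m", k)]][r]] %in% g$residues[[k]])
  }
})

test_that("widening a spacer interval never removes a raw match", {
  set.seed(55)
  base <- octet_grammar()
  for (i in 1:25) {
    s <- random_protein(sample(60:150, 1))
    raw <- octet_set(as.matrix(scan_octets(s, base,
                                           resolve = FALSE)[paste0("m", 1:8)]))
    k <- sample(7, 1)
    smin <- base$spacer_min; smax <- base$spacer_max
    smin[k] <- max(0L, smin[k] - 2L); smax[k] <- smax[k] + 3L
    wide <- octet_grammar(spacer_min = smin, spacer_max = smax)
    raw_w <- octet_set(as.matrix(scan_octets(s, wide,
                                             resolve = FALSE)[paste0("m", 1:8)]))
    expect_true(all(raw %in% raw_w))
  }
})

test_that("redundancy resolution keeps one call per region, disjoint domains both", {
  # two disjoint planted octets in one protein:
  # C-x2-C-x9-C-x1-C-x2-C-x2-C-x4-C-x2-C
  motif <- paste0("C", "AA", "C", strrep("A", 9), "C", "A", "C", "AA",
                  "C", "AA", "C", strrep("A", 4), "C", "AA", "C")
  one <- scan_octets(motif)
  expect_equal(nrow(one), 1)
  two <- scan_octets(paste0("MMM", motif, strrep("A", 10), motif, "MM"))
  expect_equal(nrow(two), 2)
  expect_true(two$start[2] > two$end[1])

  # same M1 with a longer alternative M8: smallest spacer sum wins
  m <- scan_octets(paste0(motif, "AAC"))
  expect_equal(nrow(m), 1)
  expect_equal(m$s7, 2L)
})

test_that("scan_proteome recovers planted motifs and rejects decoys", {
  pr <- generate_proteome(proteome_spec(
    counts = c("RING-H2" = 3, "RING-C2" = 2), n_decoys = 20, seed = 9))
  m <- scan_proteome(pr$records)
  expect_setequal(unique(m$protein_id), pr$truth$protein_id)
  got <- m[match(pr$truth$protein_id, m$protein_id), paste0("m", 1:8)]
  expect_equal(unname(as.matrix(got)),
               unname(as.matrix(pr$truth[paste0("m", 1:8)])))
  expect_equal(nrow(scan_proteome(pr$records[0, ])), 0)
})

test_that("hit-restricted scanning reports full-sequence coordinates", {
  pr <- generate_proteome(proteome_spec(counts = c("RING-H2" = 2),
                                        n_decoys = 0, seed = 13))
  full <- scan_proteome(pr$records)
  hits <- data.frame(protein_id = pr$truth$protein_id,
                     model_name = "RING",
                     env_start = pr$truth$m1, env_end = pr$truth$m8,
                     independent_evalue = 1e-9, score = 40)
  restricted <- scan_proteome(pr$records, hits = hits, flank = 10)
  expect_equal(restricted, full)

  # hit disjoint from the motif -> nothing found
  far <- data.frame(protein_id = pr$truth$protein_id[1], model_name = "RING",
                    env_start = 1, env_end = 5,
                    independent_evalue = 1, score = 1)
  expect_equal(nrow(scan_proteome(pr$records, hits = far, flank = 2)), 0)

  # no hits at all -> empty result, logged
  none <- far[0, ]
  expect_message(out <- scan_proteome(pr$records, hits = none), "no usable")
  expect_equal(nrow(out), 0)

  # unknown protein -> warning, hit skipped
  bad <- far; bad$protein_id <- "nosuch"
  expect_warning(expect_equal(nrow(suppressMessages(
    scan_proteome(pr$records, hits = bad))), 0), "unknown")
})

test_that("scanning is deterministic", {
  pr <- generate_proteome(proteome_spec(seed = 21))
  a <- scan_proteome(pr$records)
  b <- scan_proteome(pr$records)
  expect_identical(a, b)
})
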