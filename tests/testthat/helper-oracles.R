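# Independent oracles used by the tests. Each reimplements the checked
# quantity by a different, simpler route than the package code.

# Brute-force octet enumerator: plain recursion trying every C/H index
# combination against the grammar (residue set + spacer interval checks
# only). Returns the raw match set as a position matrix.
oracle_scan <- function(seq, grammar = octet_grammar()) {
  chars <- strsplit(toupper(seq), "")[[1]]
  ch <- which(chars %in% c("C", "H"))
  res <- list()
  rec <- function(path) {
    lev <- length(path) + 1L
    if (lev == 9L) {
      res[[length(res) + 1L]] <<- path
      return(invisible(NULL))
    }
    for (p in ch) {
      if (lev > 1L) {
        if (p <= path[lev - 1L]) next
        sp <- p - path[lev - 1L] - 1L
        if (sp < grammar$spacer_min[lev - 1L] ||
            sp > grammar$spacer_max[lev - 1L]) next
      }
      if (!(chars[p] %in% grammar$residues[[lev]])) next
      rec(c(path, p))
    }
  }
  rec(integer(0))
  if (length(res) == 0) matrix(integer(), 0, 8) else do.call(rbind, res)
}

# canonical string form of a raw match set, for set comparison
octet_set <- function(pos) sort(apply(pos, 1, paste, collapse = ","))

# Quadratic DP identity oracle in plain R: global alignment, match +1 /
# mismatch 0 / gap -1, lexicographic tie-break (score, matches, aligned
# pairs); identity = matches / alignment length.
oracle_identity <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0L, n + 1, m + 1); M <- S; P <- S
  S[1, ] <- -(0:m); S[, 1] <- -(0:n)
  better <- function(x, y) {
    if (x[1] != y[1]) return(x[1] > y[1])
    if (x[2] != y[2]) return(x[2] > y[2])
    x[3] > y[3]
  }
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    eq <- as.integer(A[i - 1] == B[j - 1])
    best <- c(S[i - 1, j - 1] + eq, M[i - 1, j - 1] + eq, P[i - 1, j - 1] + 1L)
    up <- c(S[i - 1, j] - 1L, M[i - 1, j], P[i - 1, j])
    if (better(up, best)) best <- up
    le <- c(S[i, j - 1] - 1L, M[i, j - 1], P[i, j - 1])
    if (better(le, best)) best <- le
    S[i, j] <- best[1]; M[i, j] <- best[2]; P[i, j] <- best[3]
  }
  M[n + 1, m + 1] / (n + m - P[n + 1, m + 1])
}

# Brute-force Venn cells: for every non-empty stress subset, count genes
# whose responsive set equals exactly that subset.
oracle_venn_cells <- function(mem, stresses) {
  keys <- character(0)
  counts <- integer(0)
  for (size in seq_along(stresses)) {
    cmb <- utils::combn(stresses, size, simplify = FALSE)
    for (sub in cmb) {
      inset <- colnames(mem) %in% sub
      hit <- apply(mem, 1, function(r) all(r[inset]) && !any(r[!inset]))
      keys <- c(keys, paste(sub, collapse = "&"))
      counts <- c(counts, sum(hit))
    }
  }
  stats::setNames(counts, keys)
}

random_protein <- function(n, alphabet = c("A", "C", "H", "G")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# membership matrix -> calls data frame, as call_responsive_all would
# emit it
calls_from_membership <- function(mem, stresses) {
  genes <- rownames(mem)
  data.frame(gene = rep(genes, times = length(stresses)),
             stress = rep(stresses, each = length(genes)),
             responsive = as.vector(mem),
             stringsAsFactors = FALSE)
}

# 23-field HMMER3 domtblout line in user-guide column order
domtbl_line <- function(target = "P1", query = "RING-HMM", tlen = 350,
                        qlen = 64, ievalue = 1.1e-10, score = 44.2,
                        env_from = 10, env_to = 62) {
  paste(target, "-", tlen, query, "-", qlen, "1.2e-10", "45.1", "0.1",
        "1", "2", "3.4e-12", format(ievalue), format(score), "0.0",
        "2", "60", "8", "58", env_from, env_to, "0.95",
        "synthetic test hit")
}
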