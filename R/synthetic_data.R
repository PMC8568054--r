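# Planted-truth synthetic data: a proteome with RING octets of known
# subtype among decoys, an expression matrix with known responsive-set
# memberships, and replicate Ct tables with known fold changes. Each
# generator's truth is exactly recoverable by the corresponding pipeline
# stage under the documented margins.

.BG18 <- setdiff(.AA20, c("C", "H"))

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  expr
}

#' Specification for a planted-truth synthetic proteome
#'
#' @param counts Named integer vector of planted motif counts per
#'   subtype (names from [subtype_names()]).
#' @param n_decoys Number of decoy proteins.
#' @param near_miss_fraction Fraction of decoys that are near-misses: a
#'   real motif violating exactly one grammar constraint (one ligand
#'   mutated or one spacer pushed out of range); the rest are shuffled
#'   background.
#' @param background `"clean"` draws flank/decoy/spacer residues
#'   uniformly from the 18 non-Cys/His letters, so accidental octets are
#'   impossible by construction; `"realistic"` uses all 20 letters in
#'   flanks and decoys with scanner-verified rejection sampling.
#' @param flank_range Length range (inclusive) for each flank.
#' @param seed Optional RNG seed; a fixed seed gives byte-identical
#'   output.
#' @return A `proteome_spec` object.
#' @export
proteome_spec <- function(counts = c("RING-H2" = 2, "RING-HCa" = 2,
                                     "RING-HCb" = 1, "RING-C2" = 1,
                                     "RING-v" = 1, "RING-G" = 1),
                          n_decoys = 10, near_miss_fraction = 0.2,
                          background = c("clean", "realistic"),
                          flank_range = c(30, 80), seed = NULL) {
  background <- match.arg(background)
  known <- subtype_names()
  if (is.null(names(counts)) || !all(names(counts) %in% known))
    stop("counts must be named by subtypes: ", paste(known, collapse = ", "))
  stopifnot(all(counts >= 0), n_decoys >= 0,
            near_miss_fraction >= 0, near_miss_fraction <= 1,
            length(flank_range) == 2, flank_range[1] >= 0,
            flank_range[1] <= flank_range[2])
  structure(list(counts = counts, n_decoys = as.integer(n_decoys),
                 near_miss_fraction = near_miss_fraction,
                 background = background,
                 flank_range = as.integer(flank_range), seed = seed),
            class = "proteome_spec")
}

.bg_sample <- function(n, mode) {
  pool <- if (mode == "realistic") .AA20 else .BG18
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# sample grammar-conformant spacer lengths for one motif; s7 is pinned
# by the subtype so classification truth is unambiguous
.sample_spacers <- function(subtype, grammar) {
  s <- integer(7)
  for (i in 1:7) {
    s[i] <- if (grammar$spacer_min[i] == grammar$spacer_max[i])
      grammar$spacer_min[i]
    else sample(grammar$spacer_min[i]:grammar$spacer_max[i], 1)
  }
  s[7] <- switch(subtype,
                 "RING-HCa" = 2L,
                 "RING-HCb" = 4L,
                 "RING-G" = sample(setdiff(grammar$spacer_min[7]:
                                             grammar$spacer_max[7],
                                           c(2L, 4L)), 1),
                 s[7])
  s
}

.subtype_residues <- function(subtype) {
  m45 <- switch(subtype,
                "RING-H2" = c("H", "H"),
                "RING-HCa" = c("H", "C"),
                "RING-HCb" = c("H", "C"),
                "RING-G" = c("H", "C"),
                "RING-C2" = c("C", "C"),
                "RING-v" = c("C", "H"),
                stop("no residue signature for subtype ", subtype))
  c("C", "C", "C", m45, "C", "C", "C")
}

# assemble motif string (M1..M8 span) and relative ligand positions;
# spacers are always C/H-free so the planted octet is the only one
.build_motif <- function(residues, spacers) {
  parts <- character(0)
  rel <- integer(8)
  pos <- 0L
  for (i in 1:8) {
    pos <- pos + 1L
    rel[i] <- pos
    parts <- c(parts, residues[i])
    if (i < 8) {
      parts <- c(parts, .bg_sample(spacers[i], "clean"))
      pos <- pos + spacers[i]
    }
  }
  list(seq = paste(parts, collapse = ""), rel = rel)
}

#' Generate a planted-truth proteome
#'
#' Planted proteins carry exactly one motif satisfying the grammar and
#' signature table; decoys carry none. Every record is verified with the
#' scanner itself at generation time (with `"realistic"` background,
#' flanks are resampled until the scan is clean).
#'
#' @param spec A [proteome_spec()].
#' @param grammar The [octet_grammar()] the truth must satisfy.
#' @param table The [signature_table()] defining subtype truth.
#' @return List with `records` (protein data frame: planted then decoys)
#'   and `truth` (`protein_id`, `subtype`, `m1..m8`).
#' @export
generate_proteome <- function(spec, grammar = octet_grammar(),
                              table = signature_table()) {
  stopifnot(inherits(spec, "proteome_spec"))
  .with_seed(spec$seed, {
    counts <- spec$counts[spec$counts > 0]
    subtypes <- rep(names(counts), counts)
    n_plant <- length(subtypes)
    recs <- vector("list", n_plant)
    truth <- vector("list", n_plant)
    for (i in seq_len(n_plant)) {
      id <- sprintf("SYNP%04d", i)
      res <- .subtype_residues(subtypes[i])
      spac <- .sample_spacers(subtypes[i], grammar)
      motif <- .build_motif(res, spac)
      for (attempt in 1:100) {
        lf <- sample(spec$flank_range[1]:spec$flank_range[2], 1)
        rf <- sample(spec$flank_range[1]:spec$flank_range[2], 1)
        seqs <- paste0(.bg_sample(lf, spec$background), motif$seq,
                       .bg_sample(rf, spec$background))
        found <- scan_octets(seqs, grammar)
        ok <- nrow(found) == 1 &&
          all(unlist(found[paste0("m", 1:8)]) == lf + motif$rel) &&
          classify_match(found, table) == subtypes[i]
        if (ok) break
        if (attempt == 100)
          stop("could not place a clean ", subtypes[i],
               " motif after 100 attempts")
      }
      recs[[i]] <- data.frame(id = id,
                              description = paste("planted", subtypes[i]),
                              sequence = seqs, stringsAsFactors = FALSE)
      tr <- data.frame(protein_id = id, subtype = subtypes[i],
                       t(lf + motif$rel), stringsAsFactors = FALSE)
      names(tr) <- c("protein_id", "subtype", paste0("m", 1:8))
      truth[[i]] <- tr
    }

    n_near <- round(spec$n_decoys * spec$near_miss_fraction)
    decoys <- vector("list", spec$n_decoys)
    for (j in seq_len(spec$n_decoys)) {
      id <- sprintf("DECOY%04d", j)
      near <- j <= n_near
      for (attempt in 1:100) {
        if (near) {
          st <- sample(names(counts), 1)
          res <- .subtype_residues(st)
          spac <- .sample_spacers(st, grammar)
          kind <- sample(c("mutate_ligand", "spacer_out"), 1)
          if (kind == "mutate_ligand") {
            res[sample(8, 1)] <- sample(.BG18, 1)
          } else {
            i7 <- sample(7, 1)
            lowroom <- grammar$spacer_min[i7] > 0
            down <- lowroom && runif(1) < 0.5
            spac[i7] <- if (down) grammar$spacer_min[i7] - 1L
                        else grammar$spacer_max[i7] + 1L
          }
          motif <- .build_motif(res, spac)
          lf <- sample(spec$flank_range[1]:spec$flank_range[2], 1)
          rf <- sample(spec$flank_range[1]:spec$flank_range[2], 1)
          seqs <- paste0(.bg_sample(lf, spec$background), motif$seq,
                         .bg_sample(rf, spec$background))
          desc <- "decoy near-miss"
        } else {
          seqs <- .bg_sample(sample(100:300, 1), spec$background)
          desc <- "decoy shuffled"
        }
        if (nrow(scan_octets(seqs, grammar)) == 0) break
        if (attempt == 100)
          stop("could not build a scanner-clean decoy after 100 attempts")
      }
      decoys[[j]] <- data.frame(id = id, description = desc,
                                sequence = seqs, stringsAsFactors = FALSE)
    }

    list(records = do.call(rbind, c(recs, decoys)),
         truth = do.call(rbind, truth))
  })
}

#' Specification for a planted Venn expression matrix
#'
#' @param genes Gene identifiers (total gene count = length).
#' @param stresses Stress names, in canonical order.
#' @param cells Named integer vector of exact-membership cell sizes;
#'   names are `&`-joined stress subsets in canonical order (e.g.
#'   `"cold&salt"`). Genes not covered by any cell are planted as
#'   non-responsive everywhere.
#' @param timepoints Named list of timepoint labels per stress; the
#'   default mirrors a four-treatment design (a four-step cold
#'   acclimation/de-acclimation series and 3-point salt, drought and
#'   MeJA series).
#' @param member_min_log2 Lower bound on a planted member's |log2|
#'   effect (default 1.5).
#' @param nonmember_max_log2 Upper bound on a non-member's |log2| effect
#'   (default 0.3).
#' @param threshold_log2 Call threshold the margins must straddle.
#' @param noise_sd SD of log2-scale noise, truncated at 3.9 sd so the
#'   planted calls can never be crossed; both margins must be at least
#'   `4 * noise_sd`.
#' @param control_range Range for per-(gene, stress) control levels
#'   (abstract non-negative expression units).
#' @param seed Optional RNG seed.
#' @return A `venn_spec` object.
#' @export
venn_spec <- function(genes = sprintf("G%03d", 1:20),
                      stresses = c("cold", "salt", "drought", "MeJA"),
                      cells = c(cold = 2, salt = 2,
                                "cold&salt&drought&MeJA" = 3),
                      timepoints = NULL,
                      member_min_log2 = 1.5, nonmember_max_log2 = 0.3,
                      threshold_log2 = 1, noise_sd = 0.1,
                      control_range = c(5, 50), seed = NULL) {
  if (is.null(timepoints)) {
    timepoints <- list(
      cold = c("CA1-6h", "CA1-7d", "CA2-7d", "DA-7d"),
      salt = c("24h", "48h", "72h"),
      drought = c("24h", "48h", "72h"),
      MeJA = c("12h", "24h", "48h"))[stresses]
    names(timepoints) <- stresses
    timepoints[vapply(timepoints, is.null, logical(1))] <-
      list(c("t1", "t2", "t3"))
  }
  keys <- .subset_keys(stresses)
  if (length(cells) > 0 && !all(names(cells) %in% keys))
    stop("unknown cell name(s): ",
         paste(setdiff(names(cells), keys), collapse = ", "),
         " (stresses must appear in canonical order)")
  if (sum(cells) > length(genes))
    stop("cell sizes sum to ", sum(cells), " but only ", length(genes),
         " genes available")
  if (member_min_log2 - threshold_log2 < 4 * noise_sd ||
      threshold_log2 - nonmember_max_log2 < 4 * noise_sd)
    stop("margins must be at least 4 * noise_sd on both sides of the ",
         "call threshold")
  stopifnot(anyDuplicated(genes) == 0, nonmember_max_log2 >= 0,
            control_range[1] > 0, control_range[1] <= control_range[2])
  structure(list(genes = genes, stresses = stresses, cells = cells,
                 timepoints = timepoints,
                 member_min_log2 = member_min_log2,
                 nonmember_max_log2 = nonmember_max_log2,
                 threshold_log2 = threshold_log2, noise_sd = noise_sd,
                 control_range = control_range, seed = seed),
            class = "venn_spec")
}

#' Generate a planted-truth expression matrix
#'
#' Member (gene, stress) pairs get one timepoint with a planted |log2|
#' effect of at least `member_min_log2` (random sign); every other
#' planted effect stays within `nonmember_max_log2`. Truncated noise
#' plus the enforced margins guarantee [call_responsive_all()] at
#' `threshold_log2` recovers the planted memberships exactly.
#'
#' @param spec A [venn_spec()].
#' @return List with `expression` (an `expression_matrix`) and `truth`
#'   (data frame: `gene`, one logical column per stress, and `cell`, the
#'   exact-membership key or `""`).
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "venn_spec"))
  .with_seed(spec$seed, {
    genes <- spec$genes
    stresses <- spec$stresses
    mem <- matrix(FALSE, length(genes), length(stresses),
                  dimnames = list(genes, stresses))
    gi <- 0L
    for (key in names(spec$cells)) {
      n <- spec$cells[[key]]
      if (n == 0) next
      in_cell <- strsplit(key, "&", fixed = TRUE)[[1]]
      mem[gi + seq_len(n), in_cell] <- TRUE
      gi <- gi + n
    }
    rows <- list()
    for (s in stresses) {
      tps <- spec$timepoints[[s]]
      for (g in seq_along(genes)) {
        ctrl <- runif(1, spec$control_range[1], spec$control_range[2])
        eff <- runif(length(tps), -spec$nonmember_max_log2,
                     spec$nonmember_max_log2)
        if (mem[g, s]) {
          hit <- sample(length(tps), 1)
          eff[hit] <- sample(c(-1, 1), 1) *
            runif(1, spec$member_min_log2, spec$member_min_log2 + 1.5)
        }
        noise <- pmax(pmin(rnorm(length(tps), 0, spec$noise_sd),
                           3.9 * spec$noise_sd), -3.9 * spec$noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = genes[g], stress = s, timepoint = tps,
          control = ctrl, treatment = ctrl * 2^(eff + noise),
          stringsAsFactors = FALSE)
      }
    }
    truth <- data.frame(gene = genes, mem,
                        cell = apply(mem, 1, function(m)
                          paste(stresses[m], collapse = "&")),
                        stringsAsFactors = FALSE, row.names = NULL)
    list(expression = as_expression_matrix(do.call(rbind, rows)),
         truth = truth)
  })
}

#' Specification for synthetic qPCR Ct tables
#'
#' @param folds Named positive vector of planted fold changes per
#'   sample; must include the calibrator with fold 1.
#' @param calibrator Calibrator sample label.
#' @param target_gene,housekeeping Gene labels.
#' @param n_bio,n_tech Biological and technical replicate counts
#'   (default 3 x 3).
#' @param hk_ct Housekeeping baseline Ct (cycles).
#' @param dct_calibrator Calibrator delta-Ct (cycles between target and
#'   housekeeping in the untreated sample).
#' @param noise_sd Per-well Gaussian Ct noise (cycles).
#' @param seed Optional RNG seed.
#' @return A `ct_spec` object.
#' @export
ct_spec <- function(folds = c(control = 1, treated = 4),
                    calibrator = "control", target_gene = "target",
                    housekeeping = "GAPDH", n_bio = 3, n_tech = 3,
                    hk_ct = 20, dct_calibrator = 3, noise_sd = 0.05,
                    seed = NULL) {
  if (is.null(names(folds)) || !calibrator %in% names(folds))
    stop("folds must be named per sample and include the calibrator")
  if (any(folds <= 0)) stop("planted folds must be positive")
  if (folds[[calibrator]] != 1)
    stop("the calibrator's planted fold must be 1")
  stopifnot(n_bio >= 1, n_tech >= 1, noise_sd >= 0)
  structure(list(folds = folds, calibrator = calibrator,
                 target_gene = target_gene, housekeeping = housekeeping,
                 n_bio = as.integer(n_bio), n_tech = as.integer(n_tech),
                 hk_ct = hk_ct, dct_calibrator = dct_calibrator,
                 noise_sd = noise_sd, seed = seed),
            class = "ct_spec")
}

#' Generate a synthetic Ct table with planted fold changes
#'
#' Per well, `Ct(housekeeping) = hk_ct + noise` and
#' `Ct(target) = hk_ct + dct_calibrator - log2(fold) + noise`, so
#' [delta_delta_ct()] recovers the planted folds up to noise
#' propagation.
#'
#' @param spec A [ct_spec()].
#' @return List with `ct` (a `ct_table`; replicate labels `"b<i>.t<j>"`)
#'   and `truth` (data frame `sample`, `fold`).
#' @export
generate_ct <- function(spec) {
  stopifnot(inherits(spec, "ct_spec"))
  .with_seed(spec$seed, {
    rows <- list()
    for (s in names(spec$folds)) {
      for (b in seq_len(spec$n_bio)) for (t in seq_len(spec$n_tech)) {
        rep_lab <- sprintf("b%d.t%d", b, t)
        # target Ct is built on the same well's housekeeping Ct, so the
        # housekeeping fluctuation cancels in the per-replicate delta-Ct
        ct_hk <- spec$hk_ct + rnorm(1, 0, spec$noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s,
          gene = c(spec$housekeeping, spec$target_gene),
          replicate = rep_lab,
          ct = c(ct_hk,
                 ct_hk + spec$dct_calibrator -
                   log2(spec$folds[[s]]) + rnorm(1, 0, spec$noise_sd)),
          stringsAsFactors = FALSE)
      }
    }
    ct <- as_ct_table(do.call(rbind, rows),
                      housekeeping = spec$housekeeping,
                      calibrator = spec$calibrator)
    list(ct = ct,
         truth = data.frame(sample = names(spec$folds),
                            fold = unname(spec$folds),
                            stringsAsFactors = FALSE))
  })
}

#' Study-scale preset specifications
#'
#' Loads the packaged preset (`inst/extdata/preset_paper.yaml`): a
#' 335-protein family (214 RING-H2, 104 HCa, 3 HCb, 7 C2, 6 v, 1 G)
#' plus 500 decoys; a 214-gene four-stress expression design whose
#' exact-membership Venn cells give per-stress totals 128/134/121/82,
#' an all-four intersection of 53 and single-stress exclusives
#' 26 (salt) / 5 (cold) / 0 / 0; and a qPCR design with a planted
#' salt-12h fold of 3.28 over 3 x 3 replicates. See the preset file for
#' which numbers are anchored and which are free choices.
#'
#' @param seed Base seed; the three generators use `seed`, `seed + 1`
#'   and `seed + 2`.
#' @param h2_genes Optional gene ids for the expression design
#'   (typically the planted RING-H2 protein ids from the proteome
#'   truth); defaults to generic ids.
#' @param noise_sd_ct Ct noise for the qPCR spec (cycles).
#' @return List with elements `proteome`, `expression`, `qpcr`.
#' @export
paper_preset <- function(seed = 42, h2_genes = NULL, noise_sd_ct = 0.05) {
  path <- system.file("extdata", "preset_paper.yaml", package = "ringscreen")
  cfg <- yaml::read_yaml(path)
  counts <- unlist(cfg$proteome$counts)
  if (is.null(h2_genes))
    h2_genes <- sprintf("H2G%03d", seq_len(cfg$expression$n_genes))
  stopifnot(length(h2_genes) == cfg$expression$n_genes)
  list(
    proteome = proteome_spec(
      counts = counts,
      n_decoys = cfg$proteome$n_decoys,
      near_miss_fraction = cfg$proteome$near_miss_fraction,
      background = cfg$proteome$background,
      flank_range = unlist(cfg$proteome$flank_range),
      seed = seed),
    expression = venn_spec(
      genes = h2_genes,
      stresses = unlist(cfg$expression$stresses),
      cells = unlist(cfg$expression$cells),
      noise_sd = cfg$expression$noise_sd,
      seed = seed + 1),
    qpcr = ct_spec(
      folds = unlist(cfg$qpcr$folds),
      calibrator = cfg$qpcr$calibrator,
      target_gene = cfg$qpcr$target_gene,
      housekeeping = cfg$qpcr$housekeeping,
      n_bio = cfg$qpcr$n_bio, n_tech = cfg$qpcr$n_tech,
      noise_sd = noise_sd_ct,
      seed = seed + 2))
}
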