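# RING subtype classification from the residues at metal-ligand
# positions 4 and 5 plus spacer constraints (notably s7, the run between
# ligands 7 and 8, which separates HCa from HCb).

#' Signature table of RING subtypes
#'
#' An ordered rule list; the first row whose M4/M5 residues and spacer
#' constraints all hold wins. The default ships the six field labels:
#' \describe{
#'   \item{RING-H2}{M4 = H, M5 = H (two His, hence "H2")}
#'   \item{RING-HCa}{M4 = H, M5 = C, s7 = 2}
#'   \item{RING-HCb}{M4 = H, M5 = C, s7 = 4}
#'   \item{RING-C2}{M4 = C, M5 = C}
#'   \item{RING-v}{M4 = C, M5 = H}
#'   \item{RING-G}{M4 = H, M5 = C, s7 not 2 or 4 — a provisional
#'     catch-all for the remaining HC spacing; no published residue
#'     definition exists for this subtype, so the row is meant to be
#'     replaced via configuration when one does.}
#' }
#'
#' Each row is a list with `subtype`, `m4`, `m5` (character vectors of
#' allowed residues) and optional `spacers`, a named list keyed by
#' spacer index whose entries have `values` (allowed lengths) and/or
#' `exclude` (forbidden lengths).
#'
#' @param rows Optional list of rule rows replacing the default table.
#' @return A `signature_table` object. Overlapping rows (two rows
#'   satisfiable by the same M4/M5/spacer combination) trigger a
#'   warning; first-match-wins keeps the result deterministic anyway.
#' @export
signature_table <- function(rows = NULL) {
  if (is.null(rows)) {
    rows <- list(
      list(subtype = "RING-H2",  m4 = "H", m5 = "H"),
      list(subtype = "RING-HCa", m4 = "H", m5 = "C",
           spacers = list(`7` = list(values = 2L))),
      list(subtype = "RING-HCb", m4 = "H", m5 = "C",
           spacers = list(`7` = list(values = 4L))),
      list(subtype = "RING-C2",  m4 = "C", m5 = "C"),
      list(subtype = "RING-v",   m4 = "C", m5 = "H"),
      list(subtype = "RING-G",   m4 = "H", m5 = "C",
           spacers = list(`7` = list(exclude = c(2L, 4L))))
    )
  }
  nm <- vapply(rows, function(r) r$subtype, character(1))
  if (anyDuplicated(nm)) stop("subtype names must be unique")
  for (r in rows) {
    if (!all(c(r$m4, r$m5) %in% c("C", "H")))
      stop("row '", r$subtype, "': M4/M5 residues must be C or H")
    if (!is.null(r$spacers) && !all(names(r$spacers) %in% as.character(1:7)))
      stop("row '", r$subtype, "': spacer constraints must be keyed 1..7")
  }
  tab <- structure(list(rows = rows), class = "signature_table")
  ov <- .signature_overlaps(tab)
  if (nrow(ov) > 0)
    warning("overlapping signature rows (first match wins): ",
            paste(paste(ov$row_a, ov$row_b, sep = " ~ "), collapse = "; "))
  tab
}

# enumerate (m4, m5, s1..s7 over 0..60) satisfiability to find row pairs
# that can both match; only spacers actually constrained are enumerated.
.signature_overlaps <- function(table) {
  rows <- table$rows
  hit <- function(r, m4, m5, s) {
    if (!(m4 %in% r$m4) || !(m5 %in% r$m5)) return(FALSE)
    if (is.null(r$spacers)) return(TRUE)
    for (k in names(r$spacers)) {
      con <- r$spacers[[k]]
      v <- s[as.integer(k)]
      if (!is.null(con$values) && !(v %in% con$values)) return(FALSE)
      if (!is.null(con$exclude) && (v %in% con$exclude)) return(FALSE)
    }
    TRUE
  }
  idx <- unique(unlist(lapply(rows, function(r) as.integer(names(r$spacers)))))
  out <- data.frame(row_a = character(), row_b = character(),
                    stringsAsFactors = FALSE)
  grid <- expand.grid(m4 = c("C", "H"), m5 = c("C", "H"),
                      stringsAsFactors = FALSE)
  svals <- if (length(idx) == 0) list(integer(7)) else {
    vs <- expand.grid(rep(list(0:60), length(idx)))
    lapply(seq_len(nrow(vs)), function(i) {
      s <- integer(7); s[idx] <- as.integer(vs[i, ]); s
    })
  }
  for (a in seq_along(rows)) for (b in seq_along(rows)) {
    if (b <= a) next
    clash <- any(vapply(seq_len(nrow(grid)), function(g) {
      any(vapply(svals, function(s)
        hit(rows[[a]], grid$m4[g], grid$m5[g], s) &&
        hit(rows[[b]], grid$m4[g], grid$m5[g], s), logical(1)))
    }, logical(1)))
    if (clash)
      out <- rbind(out, data.frame(row_a = rows[[a]]$subtype,
                                   row_b = rows[[b]]$subtype,
                                   stringsAsFactors = FALSE))
  }
  out
}

#' Names of the subtypes in a signature table
#' @param table A [signature_table()].
#' @return Character vector of subtype names, in rule order.
#' @export
subtype_names <- function(table = signature_table()) {
  vapply(table$rows, function(r) r$subtype, character(1))
}

#' Classify a single RING match
#'
#' @param match One match row from [scan_octets()] (needs `residues` and
#'   `s1..s7`).
#' @param table A [signature_table()].
#' @return The first matching subtype name, or `"unclassified"`.
#' @export
classify_match <- function(match, table = signature_table()) {
  m4 <- substr(match$residues, 4, 4)
  m5 <- substr(match$residues, 5, 5)
  s <- as.integer(unlist(match[paste0("s", 1:7)]))
  for (r in table$rows) {
    if (!(m4 %in% r$m4) || !(m5 %in% r$m5)) next
    ok <- TRUE
    for (k in names(r$spacers)) {
      con <- r$spacers[[k]]
      v <- s[as.integer(k)]
      if (!is.null(con$values) && !(v %in% con$values)) { ok <- FALSE; break }
      if (!is.null(con$exclude) && (v %in% con$exclude)) { ok <- FALSE; break }
    }
    if (ok) return(r$subtype)
  }
  "unclassified"
}

#' Classify all matches of a proteome scan
#'
#' @param matches Match data frame from [scan_proteome()].
#' @param table A [signature_table()].
#' @return `matches` with a `subtype` column appended.
#' @export
classify_matches <- function(matches, table = signature_table()) {
  matches$subtype <- if (nrow(matches) == 0) character(0) else
    vapply(seq_len(nrow(matches)),
           function(i) classify_match(matches[i, ], table), character(1))
  matches
}

#' Family composition summary
#'
#' Because a protein may carry several RING domains, counts are reported
#' at both levels: `domain_counts` counts matches, `protein_counts`
#' counts distinct proteins carrying at least one domain of the subtype.
#' Percentages are per-subtype shares of classified domains.
#'
#' @param matches Classified match data frame (from
#'   [classify_matches()]).
#' @param table The [signature_table()] used (fixes subtype order).
#' @return A `family_summary` list with `domain_counts`,
#'   `protein_counts`, `n_domains`, `n_proteins`, `n_classified` and
#'   `percent` (named numeric, classified subtypes only).
#' @export
summarize_family <- function(matches, table = signature_table()) {
  nm <- subtype_names(table)
  lv <- c(nm, "unclassified")
  st <- factor(matches$subtype, levels = lv)
  domain_counts <- as.integer(table(st))
  names(domain_counts) <- lv
  protein_counts <- vapply(lv, function(s)
    length(unique(matches$protein_id[matches$subtype == s])), integer(1))
  classified <- matches$subtype != "unclassified"
  n_classified <- sum(classified)
  pct <- if (n_classified > 0) 100 * domain_counts[nm] / n_classified else
    stats::setNames(rep(NA_real_, length(nm)), nm)
  structure(list(
    domain_counts = domain_counts,
    protein_counts = protein_counts,
    n_domains = nrow(matches),
    n_classified = n_classified,
    n_proteins = length(unique(matches$protein_id[classified])),
    percent = pct
  ), class = "family_summary")
}

#' @export
print.family_summary <- function(x, ...) {
  cat("RING family summary:", x$n_proteins, "proteins,",
      x$n_classified, "classified domains of", x$n_domains, "\n")
  df <- data.frame(subtype = names(x$domain_counts),
                   domains = as.integer(x$domain_counts),
                   proteins = as.integer(x$protein_counts),
                   percent = round(c(x$percent, NA_real_)[
                     seq_along(x$domain_counts)], 1))
  print(df, row.names = FALSE)
  invisible(x)
}
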