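# Exhaustive exact localisation of library peptides within proteins.
#
# The default engine is a multi-pattern Aho-Corasick automaton (compiled
# code, one pass over each protein regardless of library size); the naive
# per-peptide sliding-window scan is retained both as a user-selectable
# engine and as the independent oracle in the test suite. Both engines
# report every occurrence, overlapping ones included; coordinates are
# 1-based and inclusive.

#' Find every exact occurrence of every library peptide
#'
#' Scans each protein for each library peptide sequence and emits one hit
#' per occurrence. Overlapping occurrences are counted (a length-k peptide
#' occurs n - k + 1 times in a homopolymer of length n); pass
#' `overlap = FALSE` for leftmost non-overlapping counting. Library records
#' sharing the same sequence each receive the full set of occurrences.
#'
#' @param lib A [biopeptide_library()].
#' @param proteome Data frame from [load_proteome()] (columns `protein_id`,
#'   `sequence`).
#' @param engine `"automaton"` (Aho-Corasick, default) or `"naive"`
#'   (per-peptide sliding window; identical results, quadratic time).
#' @param overlap Count overlapping occurrences (default `TRUE`).
#' @return Data frame of hits with columns `protein_id`, `peptide_id`,
#'   `start`, `end`, `peptide_sequence`, ordered by protein input order,
#'   then `start`, then `peptide_id`.
#' @export
find_matches <- function(lib, proteome, engine = c("automaton", "naive"),
                         overlap = TRUE) {
  engine <- match.arg(engine)
  empty <- data.frame(protein_id = character(), peptide_id = character(),
                      start = integer(), end = integer(),
                      peptide_sequence = character(),
                      stringsAsFactors = FALSE)
  if (nrow(lib) == 0L) {
    warning("find_matches: empty library, no hits possible")
    return(empty)
  }
  if (nrow(proteome) == 0L) return(empty)

  # peptides containing 'X' or any character outside A-Z can never produce
  # an exact match; both engines skip them up front
  pat <- unique(lib$sequence)
  pat <- pat[grepl("^[A-WYZ]+$", pat)]
  raw <- if (length(pat) == 0L) {
    list(text = integer(0), pattern = integer(0), start = integer(0))
  } else if (engine == "automaton") {
    .ac_search(proteome$sequence, pat)
  } else {
    .naive_search(proteome$sequence, pat)
  }
  if (length(raw$text) == 0L) return(empty)

  hits <- data.table::data.table(
    text = raw$text, pattern = raw$pattern, start = raw$start)
  # expand unique sequences back to (possibly duplicated) library records
  rec <- data.table::data.table(
    pattern = match(lib$sequence, pat),
    peptide_id = lib$peptide_id,
    peptide_sequence = lib$sequence,
    k = nchar(lib$sequence))
  hits <- merge(hits, rec, by = "pattern", allow.cartesian = TRUE)
  hits[, end := start + k - 1L]

  data.table::setorder(hits, text, start, peptide_id)
  if (!overlap) {
    hits <- hits[, .SD[.keep_leftmost(start, end)],
                 by = c("text", "peptide_id")]
    data.table::setorder(hits, text, start, peptide_id)
  }
  out <- data.frame(protein_id = proteome$protein_id[hits$text],
                    peptide_id = hits$peptide_id,
                    start = hits$start, end = hits$end,
                    peptide_sequence = hits$peptide_sequence,
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

# greedy leftmost non-overlapping selection within one (protein, peptide)
# group; starts are sorted ascending
.keep_leftmost <- function(start, end) {
  keep <- logical(length(start))
  last_end <- 0L
  for (i in seq_along(start)) {
    if (start[i] > last_end) {
      keep[i] <- TRUE
      last_end <- end[i]
    }
  }
  keep
}

# Sliding-window reference engine: vectorised substring comparison per
# peptide per protein. Same output contract as .ac_search. 'X' in the text
# is masked so it can never take part in a match.
.naive_search <- function(texts, patterns) {
  t_idx <- integer(0); p_idx <- integer(0); s_pos <- integer(0)
  for (t in seq_along(texts)) {
    txt <- chartr("X", "*", texts[t])
    n <- nchar(txt)
    for (p in seq_along(patterns)) {
      k <- nchar(patterns[p])
      if (k > n) next
      starts <- seq_len(n - k + 1L)
      hit <- starts[substring(txt, starts, starts + k - 1L) == patterns[p]]
      if (length(hit)) {
        t_idx <- c(t_idx, rep.int(t, length(hit)))
        p_idx <- c(p_idx, rep.int(p, length(hit)))
        s_pos <- c(s_pos, hit)
      }
    }
  }
  list(text = t_idx, pattern = p_idx, start = s_pos)
}

#' Group hits into per-protein, per-peptide match records
#'
#' Aggregates the hit stream into exactly one record per (protein, peptide)
#' pair with at least one hit, carrying the hit count and the sorted
#' occurrence coordinates — the per-protein match record of the output
#' report.
#'
#' @param hits Data frame from [find_matches()].
#' @param lib The [biopeptide_library()] the hits were produced from (source
#'   of `peptide_name`).
#' @return Data frame with columns `protein_id`, `peptide_id`,
#'   `peptide_name`, `n_hits`, `peptide_sequence`, and a list column
#'   `locations` of two-column matrices (start, end) sorted by start.
#' @export
count_hits <- function(hits, lib) {
  if (nrow(hits) == 0L) {
    out <- data.frame(protein_id = character(), peptide_id = character(),
                      peptide_name = character(), n_hits = integer(),
                      peptide_sequence = character(),
                      stringsAsFactors = FALSE)
    out$locations <- list()
    return(out)
  }
  unknown <- setdiff(unique(hits$peptide_id), lib$peptide_id)
  if (length(unknown))
    stop_validation("count_hits: peptide_id absent from library: %s",
                    paste(unknown, collapse = ", "))
  dt <- data.table::as.data.table(hits)
  dt[, .ord := .I]
  agg <- dt[order(.ord), {
    o <- order(start)
    list(n_hits = .N,
         peptide_sequence = peptide_sequence[1L],
         locations = list(cbind(start = start[o], end = end[o])),
         .first = min(.ord))
  }, by = c("protein_id", "peptide_id")]
  data.table::setorder(agg, .first)
  out <- data.frame(protein_id = agg$protein_id,
                    peptide_id = agg$peptide_id,
                    peptide_name = lib$name[match(agg$peptide_id,
                                                  lib$peptide_id)],
                    n_hits = agg$n_hits,
                    peptide_sequence = agg$peptide_sequence,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$locations <- agg$locations
  out
}

#' Write the six-field match report
#'
#' TSV with columns `protein_id`, `peptide_id`, `peptide_name`, `n_hits`,
#' `peptide_sequence`, `locations` (semicolon-joined `start-end` pairs).
#'
#' @param counts Data frame from [count_hits()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_match_report <- function(counts, path) {
  loc <- vapply(counts$locations, function(m) {
    paste(sprintf("%d-%d", m[, "start"], m[, "end"]), collapse = ";")
  }, character(1))
  out <- data.frame(protein_id = counts$protein_id,
                    peptide_id = counts$peptide_id,
                    peptide_name = counts$peptide_name,
                    n_hits = counts$n_hits,
                    peptide_sequence = counts$peptide_sequence,
                    locations = loc, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a match report written by [write_match_report()]
#'
#' @param path TSV path.
#' @return Data frame in [count_hits()] layout (with `locations` list
#'   column).
#' @export
read_match_report <- function(path) {
  if (!file.exists(path)) stop_io("match report not found: %s", path)
  raw <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  raw$n_hits <- as.integer(raw$n_hits)
  raw$locations <- lapply(strsplit(raw$locations, ";", fixed = TRUE),
                          function(p) {
    se <- do.call(rbind, strsplit(p, "-", fixed = TRUE))
    cbind(start = as.integer(se[, 1]), end = as.integer(se[, 2]))
  })
  if (nrow(raw) == 0L) raw$locations <- list()
  raw
}
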