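# In-silico gastrointestinal proteolysis and match releasability.
#
# EXTENSION: exact-match localisation says where a bioactive peptide sits in
# a protein, but not whether digestion could ever liberate it. This module
# simulates cleavage with P1/P1'-style protease rules and classifies each
# match as exact_release (a digest fragment IS the peptide), contained
# (the peptide survives inside a larger fragment) or split (a cleavage site
# cuts through it).

#' Define a protease cleavage rule
#'
#' P1/P1' convention: the enzyme cleaves the backbone after any residue in
#' `cleave_after` unless the next residue is in `not_before`.
#'
#' @param name Protease name.
#' @param cleave_after Residues cleaved after (P1); character vector or a
#'   single string of one-letter codes.
#' @param not_before Residues that block cleavage when immediately following
#'   (P1'); may be empty.
#' @return A `cleavage_rule` object.
#' @export
cleavage_rule <- function(name, cleave_after, not_before = character()) {
  split1 <- function(x) {
    x <- toupper(unlist(strsplit(as.character(x), "", fixed = TRUE)))
    unique(x[nzchar(x)])
  }
  p1 <- split1(cleave_after)
  if (length(p1) == 0L)
    stop_validation("cleavage_rule '%s': cleave_after must be non-empty", name)
  structure(list(protease_name = as.character(name),
                 p1_residues = p1,
                 blocked_p1prime = split1(not_before)),
            class = "cleavage_rule")
}

#' @export
print.cleavage_rule <- function(x, ...) {
  cat(sprintf("cleavage rule '%s': after [%s]%s\n", x$protease_name,
              paste(x$p1_residues, collapse = ""),
              if (length(x$blocked_p1prime))
                sprintf(", not before [%s]",
                        paste(x$blocked_p1prime, collapse = "")) else ""))
  invisible(x)
}

#' Built-in gastrointestinal protease rules
#'
#' Simplified P1/P1' specificities for the main gastrointestinal
#' endopeptidases: trypsin (after K/R, not before P), chymotrypsin in its
#' high-specificity form (after F/Y/W, not before P), pepsin at low pH
#' (after F/L) and pancreatic elastase (after the small aliphatic residues
#' A/V/S/G/L/I, not before P). Carboxypeptidases are exopeptidases and have
#' no site rule. Pepsin and elastase specificities are context-dependent in
#' reality; the single-residue rules here are the usual in-silico
#' approximation.
#'
#' @param names Which rules to return (default all four).
#' @return Named list of [cleavage_rule()] objects.
#' @export
builtin_cleavage_rules <- function(names = c("trypsin", "chymotrypsin",
                                             "pepsin", "elastase")) {
  all <- list(
    trypsin      = cleavage_rule("trypsin", "KR", "P"),
    chymotrypsin = cleavage_rule("chymotrypsin", "FYW", "P"),
    pepsin       = cleavage_rule("pepsin", "FL"),
    elastase     = cleavage_rule("elastase", "AVSGLI", "P")
  )
  unknown <- setdiff(names, names(all))
  if (length(unknown))
    stop_validation("unknown built-in protease: %s",
                    paste(unknown, collapse = ", "))
  all[names]
}

#' Load protease rules from a YAML config
#'
#' One block per protease: `name: {cleave_after: "KR", not_before: "P"}`.
#'
#' @param path YAML file path.
#' @return Named list of [cleavage_rule()] objects.
#' @export
load_cleavage_rules <- function(path) {
  if (!file.exists(path)) stop_io("rule file not found: %s", path)
  spec <- yaml::read_yaml(path)
  if (length(spec) == 0L) return(list())
  rules <- lapply(names(spec), function(nm) {
    blk <- spec[[nm]]
    cleavage_rule(nm, blk$cleave_after %||% "",
                  blk$not_before %||% character())
  })
  names(rules) <- names(spec)
  rules
}

# positions i such that the backbone is cut between residues i and i+1
cleavage_sites <- function(sequence, rules) {
  n <- nchar(sequence)
  if (n < 2L || length(rules) == 0L) return(integer(0))
  res <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  sites <- integer(0)
  for (r in rules) {
    cand <- which(res[-n] %in% r$p1_residues)
    if (length(r$blocked_p1prime))
      cand <- cand[!(res[cand + 1L] %in% r$blocked_p1prime)]
    sites <- c(sites, cand)
  }
  sort(unique(sites))
}

#' Digest one protein with a set of protease rules
#'
#' Cleavage sites are the union over all rules of positions after a P1
#' residue not followed by a blocked P1' residue. The zero-missed-cleavage
#' fragments partition the protein (contiguous, non-overlapping,
#' concatenating to the full sequence). With `missed_cleavages = m`, merged
#' runs of up to `m + 1` adjacent fragments are additionally emitted,
#' flagged with `is_partition = FALSE` so the partition remains
#' recoverable.
#'
#' @param sequence Protein amino-acid sequence (a single string).
#' @param rules List of [cleavage_rule()] objects. An empty list yields a
#'   single fragment spanning the protein (with a warning).
#' @param missed_cleavages Non-negative integer (default 0).
#' @param protein_id Identifier copied into the output.
#' @return Data frame with columns `protein_id`, `start`, `end`, `sequence`,
#'   `n_missed`, `is_partition`.
#' @export
digest <- function(sequence, rules, missed_cleavages = 0L,
                   protein_id = "protein") {
  stopifnot(length(sequence) == 1L, missed_cleavages >= 0L)
  if (length(rules) == 0L)
    warning("digest: empty rule list, returning the undigested protein")
  if (inherits(rules, "cleavage_rule")) rules <- list(rules)
  n <- nchar(sequence)
  if (n == 0L)
    return(data.frame(protein_id = character(), start = integer(),
                      end = integer(), sequence = character(),
                      n_missed = integer(), is_partition = logical(),
                      stringsAsFactors = FALSE))
  sites <- cleavage_sites(sequence, rules)
  starts <- c(1L, sites + 1L)
  ends <- c(sites, n)
  frag <- function(s, e, miss) data.frame(
    protein_id = protein_id, start = s, end = e,
    sequence = substring(sequence, s, e),
    n_missed = miss, is_partition = miss == 0L,
    stringsAsFactors = FALSE)
  out <- frag(starts, ends, 0L)
  m <- min(as.integer(missed_cleavages), length(starts) - 1L)
  if (m > 0L) {
    merged <- lapply(seq_len(m), function(k) {
      i <- seq_len(length(starts) - k)
      frag(starts[i], ends[i + k], k)
    })
    out <- rbind(out, do.call(rbind, merged))
  }
  out[order(out$start, out$end), , drop = FALSE]
}

#' Digest every protein in a proteome
#'
#' @param proteome Data frame from [load_proteome()].
#' @param rules List of [cleavage_rule()] objects.
#' @param missed_cleavages Passed to [digest()].
#' @return Data frame of fragments for all proteins (see [digest()]).
#' @export
digest_proteome <- function(proteome, rules, missed_cleavages = 0L) {
  if (length(rules) == 0L)
    warning("digest_proteome: empty rule list, proteins left undigested")
  frags <- lapply(seq_len(nrow(proteome)), function(i) {
    suppressWarnings(digest(proteome$sequence[i], rules, missed_cleavages,
                            protein_id = proteome$protein_id[i]))
  })
  out <- do.call(rbind, frags)
  if (is.null(out))
    out <- data.frame(protein_id = character(), start = integer(),
                      end = integer(), sequence = character(),
                      n_missed = integer(), is_partition = logical(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify whether digestion can release each matched peptide
#'
#' For each hit, against the zero-missed-cleavage digest partition of its
#' protein: `exact_release` if the hit's coordinates equal a fragment's,
#' `contained` if the hit lies strictly inside one fragment, `split` if at
#' least one cleavage boundary falls within the hit. The three statuses are
#' mutually exclusive and exhaustive.
#'
#' @param hits Data frame from [find_matches()].
#' @param fragments Data frame from [digest_proteome()] over the same
#'   proteome (only `is_partition` rows are used).
#' @param rules_used Character vector of protease names, recorded in the
#'   output.
#' @return `hits` with added columns `status` and `protease_set`.
#' @export
classify_releasability <- function(hits, fragments,
                                   rules_used = character()) {
  pset <- paste(rules_used, collapse = "+")
  if (nrow(hits) == 0L) {
    hits$status <- character(0)
    hits$protease_set <- character(0)
    return(hits)
  }
  fragments <- fragments[fragments$is_partition, , drop = FALSE]
  missing <- setdiff(unique(hits$protein_id), unique(fragments$protein_id))
  if (length(missing))
    stop_validation("classify_releasability: no fragments for protein(s): %s",
                    paste(missing, collapse = ", "))
  frag_by_prot <- split(fragments[c("start", "end")], fragments$protein_id)
  idx_by_prot <- split(seq_len(nrow(hits)), hits$protein_id)
  status <- character(nrow(hits))
  for (pid in names(idx_by_prot)) {
    fr <- frag_by_prot[[pid]]
    o <- order(fr$start)
    fs <- fr$start[o]; fe <- fr$end[o]
    idx <- idx_by_prot[[pid]]
    # fragment whose span contains the hit's start position
    j <- findInterval(hits$start[idx], fs)
    status[idx] <- ifelse(
      hits$end[idx] > fe[j], "split",
      ifelse(hits$start[idx] == fs[j] & hits$end[idx] == fe[j],
             "exact_release", "contained"))
  }
  hits$status <- status
  hits$protease_set <- pset
  hits
}

#' Write the releasability report
#'
#' TSV of hits with their status and the protease set used.
#'
#' @param calls Data frame from [classify_releasability()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_releasability_report <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
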