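# Reading and validating the three inputs: the curated biopeptide library
# (delimited text), the proteome (amino-acid FASTA) and the differential
# expression table.

.ID_ALIASES <- list(
  peptide_id = c("biopeptide_id", "peptide_id", "id"),
  name       = c("biopeptid_name", "biopeptide_name", "name"),
  sequence   = c("peptide_sequence", "sequence", "seq"),
  mass       = c("chemical_mass", "mass"),
  activity   = c("biological_activity_category", "activity_category",
                 "activity", "activities")
)

# normalise a header: lower-case, drop parenthesised qualifiers such as
# "(biological role)", squeeze separators to single underscores
.norm_header <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("\\(.*?\\)", "", x)
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

.map_columns <- function(headers, aliases, required, what) {
  norm <- .norm_header(headers)
  out <- vapply(names(aliases), function(canon) {
    hit <- which(norm %in% aliases[[canon]])
    if (length(hit) == 0L) NA_integer_ else hit[1L]
  }, integer(1))
  missing <- intersect(required, names(out)[is.na(out)])
  if (length(missing))
    stop_validation("%s: missing mandatory column(s): %s (have: %s)",
                    what, paste(missing, collapse = ", "),
                    paste(headers, collapse = ", "))
  out
}

.read_delim_auto <- function(path, sep = NULL) {
  if (!file.exists(path)) stop_io("file not found: %s", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, colClasses = "character",
             fileEncoding = "UTF-8", blank.lines.skip = TRUE)
}

#' Construct a biopeptide library
#'
#' Builds the validated library object from its five fields. Users normally
#' call [load_library()]; the synthetic generator and tests use this
#' constructor directly.
#'
#' @param peptide_id Character vector of unique identifiers.
#' @param name Free-text biological role per peptide.
#' @param sequence Amino-acid sequences (upper-cased on construction).
#' @param mass Stated chemical masses in daltons (`NA` where absent).
#' @param activities List of character vectors: the activity categories of
#'   each peptide (a single character vector is recycled element-wise).
#' @param provenance Free-text source tag.
#' @param out_of_range Logical: flags records whose length falls outside the
#'   2-60 residue biopeptide definition (see [load_library()]).
#' @return A `biopeptide_library`: a data frame with columns `peptide_id`,
#'   `name`, `sequence`, `mass`, `activities` (list column), `out_of_range`,
#'   and a `provenance` attribute.
#' @export
biopeptide_library <- function(peptide_id = character(), name = character(),
                               sequence = character(), mass = numeric(),
                               activities = list(), provenance = "",
                               out_of_range = logical()) {
  n <- length(peptide_id)
  if (!is.list(activities)) activities <- as.list(activities)
  if (length(out_of_range) == 0L && n > 0L) out_of_range <- rep(FALSE, n)
  if (length(mass) == 0L && n > 0L) mass <- rep(NA_real_, n)
  sequence <- toupper(as.character(sequence))
  dup <- duplicated(peptide_id)
  if (any(dup))
    stop_validation("duplicate peptide_id: %s",
                    paste(unique(peptide_id[dup]), collapse = ", "))
  lib <- data.frame(peptide_id = as.character(peptide_id),
                    name = as.character(name),
                    sequence = sequence,
                    mass = as.numeric(mass),
                    out_of_range = as.logical(out_of_range),
                    stringsAsFactors = FALSE)
  lib$activities <- activities
  attr(lib, "provenance") <- provenance
  class(lib) <- c("biopeptide_library", "data.frame")
  lib
}

#' @export
print.biopeptide_library <- function(x, ...) {
  cat(sprintf("biopeptide library: %d record(s), %d activity categories%s\n",
              nrow(x), length(unique(unlist(x$activities))),
              if (nzchar(attr(x, "provenance") %||% ""))
                paste0(" [", attr(x, "provenance"), "]") else ""))
  if (nrow(x)) print(utils::head(as.data.frame(x)[, c("peptide_id", "name",
                                                      "sequence", "mass")], 10))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a curated biopeptide library
#'
#' Reads a delimited-text library export (such as a BIOPEP-UWM download) with
#' the five fields: peptide id, name/biological role, sequence, chemical
#' mass, and activity category. Header names are matched case-insensitively
#' against common aliases (including the `biopeptid_name` spelling found in
#' some exports); extra columns are ignored.
#'
#' Record validity: sequences must use only the 20 standard residues
#' (ambiguity codes B/J/Z/X/U/O are invalid), and biopeptides are defined as
#' 2-60 residues long. Out-of-range records load only with
#' `allow_out_of_range = TRUE` and are tagged in the `out_of_range` column.
#'
#' @param path Path to a TSV or CSV file (delimiter auto-detected from the
#'   extension; override with `sep`). A header row is mandatory.
#' @param strict If `TRUE` (default) any invalid row aborts the load with an
#'   error naming the row and problem; if `FALSE` invalid rows are skipped
#'   and their count reported via `message()`.
#' @param sep Field delimiter; `NULL` auto-detects (`","` for `.csv`, tab
#'   otherwise).
#' @param column_map Optional named character vector mapping canonical field
#'   names (`peptide_id`, `name`, `sequence`, `mass`, `activity`) to the
#'   file's actual header names.
#' @param activity_delim Delimiter splitting multi-activity cells (default
#'   `";"`).
#' @param allow_out_of_range Load (and tag) records shorter than 2 or longer
#'   than 60 residues instead of rejecting them.
#' @return A [biopeptide_library()].
#' @export
load_library <- function(path, strict = TRUE, sep = NULL, column_map = NULL,
                         activity_delim = ";", allow_out_of_range = FALSE) {
  raw <- .read_delim_auto(path, sep)
  headers <- names(raw)
  aliases <- .ID_ALIASES
  if (!is.null(column_map)) {
    for (canon in names(column_map))
      aliases[[canon]] <- unique(c(.norm_header(column_map[[canon]]),
                                   aliases[[canon]]))
  }
  idx <- .map_columns(headers, aliases,
                      required = c("peptide_id", "name", "sequence"),
                      what = "library")
  if (nrow(raw) == 0L)
    return(biopeptide_library(provenance = path))

  get_col <- function(canon, default = NA_character_) {
    if (is.na(idx[[canon]])) rep(default, nrow(raw)) else raw[[idx[[canon]]]]
  }
  ids  <- trimws(get_col("peptide_id"))
  nms  <- trimws(get_col("name"))
  seqs <- toupper(trimws(get_col("sequence")))
  mass_raw <- trimws(get_col("mass"))
  mass <- suppressWarnings(as.numeric(mass_raw))
  mass[!nzchar(mass_raw) | is.na(mass_raw)] <- NA_real_
  act_raw <- trimws(get_col("activity", default = ""))
  acts <- lapply(strsplit(act_raw, activity_delim, fixed = TRUE),
                 function(a) { a <- trimws(a); a[nzchar(a)] })
  acts[lengths(acts) == 0L] <- list("unclassified")

  valid_res <- standard_residues()
  bad_char <- vapply(strsplit(seqs, "", fixed = TRUE), function(res) {
    bad <- setdiff(res, valid_res)
    if (length(bad)) bad[1L] else NA_character_
  }, character(1))
  bad_char[!nzchar(seqs)] <- "<empty>"
  len <- nchar(seqs)
  oor <- len < 2L | len > 60L

  drop <- logical(nrow(raw))
  for (i in seq_len(nrow(raw))) {
    if (!is.na(bad_char[i])) {
      if (strict)
        stop_validation("library row %d (%s): invalid residue '%s' in sequence",
                        i, ids[i], bad_char[i])
      drop[i] <- TRUE
    } else if (oor[i] && !allow_out_of_range) {
      if (strict)
        stop_validation(paste0("library row %d (%s): sequence length %d outside ",
                               "the 2-60 biopeptide range ",
                               "(use allow_out_of_range to keep it)"),
                        i, ids[i], len[i])
      drop[i] <- TRUE
    }
  }
  if (any(drop))
    message(sprintf("load_library: skipped %d invalid row(s)", sum(drop)))
  keep <- !drop
  dup <- duplicated(ids[keep])
  if (any(dup))
    stop_validation("library: duplicate peptide_id: %s",
                    paste(unique(ids[keep][dup]), collapse = ", "))
  biopeptide_library(peptide_id = ids[keep], name = nms[keep],
                     sequence = seqs[keep], mass = mass[keep],
                     activities = acts[keep], provenance = path,
                     out_of_range = oor[keep])
}

#' Write a biopeptide library back to delimited text
#'
#' Inverse of [load_library()]: writing and re-loading yields field-identical
#' records.
#'
#' @param lib A [biopeptide_library()].
#' @param path Output path (`.csv` writes comma-separated, else tab).
#' @param activity_delim Delimiter used to join multi-activity sets.
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path, activity_delim = ";") {
  out <- data.frame(
    biopeptide_ID = lib$peptide_id,
    biopeptid_name = lib$name,
    peptide_sequence = lib$sequence,
    chemical_mass = ifelse(is.na(lib$mass), "",
                           format(lib$mass, digits = 15, trim = TRUE,
                                  scientific = FALSE)),
    biological_activity_category = vapply(lib$activities, paste,
                                          character(1),
                                          collapse = activity_delim),
    stringsAsFactors = FALSE, check.names = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Load a proteome from amino-acid FASTA
#'
#' One record per header. The protein id is the header token up to the first
#' whitespace; the remainder is kept as the description. Sequences are
#' upper-cased and a single trailing stop symbol `*` is stripped; internal
#' `*` are retained verbatim (exact matches can never cross them).
#'
#' @param path Path to a FASTA file.
#' @return Data frame with columns `protein_id`, `description`, `sequence`.
#' @export
load_proteome <- function(path) {
  if (!file.exists(path)) stop_io("proteome file not found: %s", path)
  if (file.size(path) == 0L) {
    warning("load_proteome: empty FASTA file")
    return(data.frame(protein_id = character(), description = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  aa <- Biostrings::readBStringSet(path)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  dup <- duplicated(ids)
  if (any(dup))
    stop_validation("proteome: duplicate protein_id: %s",
                    paste(unique(ids[dup]), collapse = ", "))
  seqs <- toupper(as.character(aa))
  seqs <- sub("\\*$", "", seqs)
  all_res <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1L]]
  if (length(all_res) &&
      mean(all_res %in% c("A", "C", "G", "T", "N")) >= 0.95)
    warning("load_proteome: sequences look nucleotide (>=95% ACGTN); ",
            "an amino-acid FASTA is expected")
  data.frame(protein_id = ids, description = desc, sequence = seqs,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Load a differential-expression table
#'
#' Expects columns `gene_id` and `log2fc` (extra columns ignored). Rows with
#' non-numeric or non-finite log2 fold-changes are rejected with their row
#' numbers reported.
#'
#' @param path Path to a TSV (or CSV) file.
#' @param sep Field delimiter; `NULL` auto-detects by extension.
#' @param contrast Label attached to the records (e.g. the tissue contrast).
#' @return Data frame with columns `gene_id`, `log2fc`, `contrast`.
#' @export
load_expression <- function(path, sep = NULL, contrast = "") {
  raw <- .read_delim_auto(path, sep)
  idx <- .map_columns(names(raw),
                      list(gene_id = c("gene_id", "gene", "id"),
                           log2fc = c("log2fc", "log2_fold_change", "log2foldchange", "lfc")),
                      required = c("gene_id", "log2fc"), what = "expression")
  if (nrow(raw) == 0L)
    return(data.frame(gene_id = character(), log2fc = numeric(),
                      contrast = character(), stringsAsFactors = FALSE))
  lfc <- suppressWarnings(as.numeric(raw[[idx[["log2fc"]]]]))
  bad <- !is.finite(lfc)
  if (any(bad))
    message(sprintf("load_expression: rejected %d row(s) with non-numeric log2fc: rows %s",
                    sum(bad), paste(which(bad), collapse = ", ")))
  data.frame(gene_id = trimws(raw[[idx[["gene_id"]]]][!bad]),
             log2fc = lfc[!bad],
             contrast = contrast, stringsAsFactors = FALSE, row.names = NULL)
}

#' Check the library's stated masses against computed masses
#'
#' Quality control on the library's chemical-mass column. Each record's mass
#' is recomputed from its sequence with both the average and monoisotopic
#' residue tables (library exports rarely say which convention they use);
#' records whose stated mass differs from the `mode` computation by more
#' than `tolerance` are reported. Never raises on a discrepancy.
#'
#' @param lib A [biopeptide_library()].
#' @param mode Which computed mass the discrepancy test uses: `"average"`
#'   (default) or `"monoisotopic"`. Both computed values appear in the
#'   report either way.
#' @param tolerance Daltons (> 0); default 0.5.
#' @return List with `discrepancies` (peptide_id, stated_mass,
#'   computed_average, computed_monoisotopic, delta) and `missing_mass`
#'   (records lacking a stated mass).
#' @export
validate_library_masses <- function(lib, mode = c("average", "monoisotopic"),
                                    tolerance = 0.5) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(tolerance), tolerance > 0)
  empty <- data.frame(peptide_id = character(), stated_mass = numeric(),
                      computed_average = numeric(),
                      computed_monoisotopic = numeric(), delta = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(lib) == 0L)
    return(list(discrepancies = empty,
                missing_mass = character()))
  avg <- compute_peptide_mass(lib$sequence, "average")
  mono <- compute_peptide_mass(lib$sequence, "monoisotopic")
  computed <- if (mode == "average") avg else mono
  missing <- is.na(lib$mass)
  delta <- lib$mass - computed
  flag <- !missing & abs(delta) > tolerance
  list(
    discrepancies = data.frame(
      peptide_id = lib$peptide_id[flag], stated_mass = lib$mass[flag],
      computed_average = avg[flag], computed_monoisotopic = mono[flag],
      delta = delta[flag], stringsAsFactors = FALSE, row.names = NULL),
    missing_mass = lib$peptide_id[missing]
  )
}
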