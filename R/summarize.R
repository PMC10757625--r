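# Activity-level aggregation and differential-expression cross-reference.
#
# "Instances" is deliberately reported two ways — total occurrences
# (n_instances) and distinct protein-peptide pairs (n_pairs) — because
# headline counts in the literature rarely say which convention they use.

#' Summarise matches by biological-activity category
#'
#' One summary row per activity category with at least one hit. A
#' multi-activity peptide contributes its full counts to each of its
#' categories, so column sums across activities can exceed the overall
#' totals.
#'
#' @param counts Data frame from [count_hits()].
#' @param lib The [biopeptide_library()].
#' @param include_empty Also emit zero rows for library activities without
#'   any hit.
#' @return Data frame with columns `activity`, `n_peptide_types`
#'   (distinct matched peptide ids), `n_instances` (total occurrences),
#'   `n_pairs` (distinct protein-peptide pairs), `n_proteins` (distinct
#'   proteins hit), sorted alphabetically by activity.
#' @export
summarize_by_activity <- function(counts, lib, include_empty = FALSE) {
  empty <- data.frame(activity = character(), n_peptide_types = integer(),
                      n_instances = integer(), n_pairs = integer(),
                      n_proteins = integer(), stringsAsFactors = FALSE)
  act_of <- function(ids) lib$activities[match(ids, lib$peptide_id)]
  if (nrow(counts) == 0L) {
    out <- empty
  } else {
    acts <- act_of(counts$peptide_id)
    dt <- data.table::data.table(
      protein_id = rep(counts$protein_id, lengths(acts)),
      peptide_id = rep(counts$peptide_id, lengths(acts)),
      n_hits = rep(counts$n_hits, lengths(acts)),
      activity = unlist(acts))
    agg <- dt[, list(n_peptide_types = length(unique(peptide_id)),
                     n_instances = sum(n_hits),
                     n_pairs = .N,
                     n_proteins = length(unique(protein_id))),
              by = "activity"]
    out <- as.data.frame(agg)
  }
  if (include_empty) {
    missing <- setdiff(unique(unlist(lib$activities)), out$activity)
    if (length(missing))
      out <- rbind(out, data.frame(activity = missing, n_peptide_types = 0L,
                                   n_instances = 0L, n_pairs = 0L,
                                   n_proteins = 0L, stringsAsFactors = FALSE))
  }
  out <- out[order(out$activity), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-reference matched proteins with differential expression
#'
#' Counts the upregulated genes (log2 fold-change greater than or equal to
#' `threshold`; the cutoff is inclusive) whose protein products carry at
#' least one matched biopeptide, and collects the union of activity
#' categories those biopeptides represent.
#'
#' @param counts Data frame from [count_hits()].
#' @param expr Data frame from [load_expression()].
#' @param lib The [biopeptide_library()] (source of activity labels).
#' @param threshold log2 fold-change cutoff, inclusive (default 1.0).
#' @param id_map Optional two-column data frame (`gene_id`, `protein_id`)
#'   mapping genes to protein products; defaults to identity (the gene id
#'   names its product). Mapped proteins absent from the match table are
#'   allowed; mapped proteins absent from the scan are reported with a
#'   warning only when the map itself is explicit.
#' @return List with `summary` (one-row data frame: `contrast`, `threshold`,
#'   `n_genes`, `n_activities`, `activities` semicolon-joined) and `detail`
#'   (per-gene table: `gene_id`, `log2fc`, `n_hits`, `activities`).
#' @export
cross_reference_expression <- function(counts, expr, lib, threshold = 1.0,
                                       id_map = NULL) {
  stopifnot(is.finite(threshold))
  contrast <- if (nrow(expr) && nzchar(expr$contrast[1L])) expr$contrast[1L] else ""
  if (is.null(id_map)) {
    id_map <- data.frame(gene_id = expr$gene_id, protein_id = expr$gene_id,
                         stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("gene_id", "protein_id") %in% names(id_map)))
    unknown <- setdiff(id_map$protein_id, counts$protein_id)
    if (length(unknown))
      warning(sprintf(
        "cross_reference_expression: %d mapped protein(s) have no match record",
        length(unknown)))
  }
  up <- expr[expr$log2fc >= threshold, , drop = FALSE]
  det <- merge(up[c("gene_id", "log2fc")], id_map, by = "gene_id")
  act_of <- function(ids) lib$activities[match(ids, lib$peptide_id)]
  rows <- lapply(unique(det$gene_id), function(g) {
    prots <- det$protein_id[det$gene_id == g]
    sub <- counts[counts$protein_id %in% prots, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    data.frame(gene_id = g,
               log2fc = det$log2fc[match(g, det$gene_id)],
               n_hits = sum(sub$n_hits),
               activities = paste(sort(unique(unlist(act_of(sub$peptide_id)))),
                                  collapse = ";"),
               stringsAsFactors = FALSE)
  })
  detail <- do.call(rbind, rows)
  if (is.null(detail))
    detail <- data.frame(gene_id = character(), log2fc = numeric(),
                         n_hits = integer(), activities = character(),
                         stringsAsFactors = FALSE)
  detail <- detail[order(detail$gene_id), , drop = FALSE]
  rownames(detail) <- NULL
  all_acts <- sort(unique(unlist(strsplit(detail$activities, ";", fixed = TRUE))))
  list(summary = data.frame(contrast = contrast, threshold = threshold,
                            n_genes = nrow(detail),
                            n_activities = length(all_acts),
                            activities = paste(all_acts, collapse = ";"),
                            stringsAsFactors = FALSE),
       detail = detail)
}

#' Write activity and carrier reports
#'
#' Writes `activity_summary` and `carriers` tables as TSV and/or JSON
#' twins with deterministic column order and row sort, so repeated runs are
#' byte-identical.
#'
#' @param activity_summary Data frame from [summarize_by_activity()].
#' @param carriers Detail data frame from [cross_reference_expression()]
#'   (or `NULL` to skip).
#' @param dir Output directory (created if absent).
#' @param formats Subset of `c("tsv", "json")`.
#' @return Character vector of files written, invisibly.
#' @export
write_reports <- function(activity_summary, carriers = NULL, dir = ".",
                          formats = c("tsv", "json")) {
  formats <- match.arg(formats, several.ok = TRUE)
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop_io("cannot create output directory: %s", dir)
  written <- character(0)
  emit <- function(df, stem) {
    if ("tsv" %in% formats) {
      f <- file.path(dir, paste0(stem, ".tsv"))
      write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE,
                  fileEncoding = "UTF-8")
      written <<- c(written, f)
    }
    if ("json" %in% formats) {
      f <- file.path(dir, paste0(stem, ".json"))
      jsonlite::write_json(df, f, dataframe = "rows", digits = NA,
                           pretty = TRUE)
      written <<- c(written, f)
    }
  }
  emit(activity_summary, "activity_summary")
  if (!is.null(carriers)) emit(carriers, "carriers")
  invisible(written)
}
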