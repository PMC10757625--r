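# Seeded synthetic data: proteomes with planted peptide occurrences and a
# ground-truth table, peptide libraries with computed masses, and
# expression tables with a known upregulated set. Everything the pipeline
# consumes can be generated offline and deterministically.

# Swiss-Prot average amino-acid composition (fractions), the default
# background model: i.i.d. per residue, no positional or Markov structure.
.SWISSPROT_FREQS <- c(
  A = 0.0825, R = 0.0553, N = 0.0406, D = 0.0545, C = 0.0138,
  Q = 0.0393, E = 0.0675, G = 0.0707, H = 0.0227, I = 0.0596,
  L = 0.0966, K = 0.0584, M = 0.0242, F = 0.0386, P = 0.0470,
  S = 0.0656, T = 0.0534, W = 0.0109, Y = 0.0292, V = 0.0687
)

#' Default background residue frequencies
#'
#' Swiss-Prot average amino-acid composition, renormalised to sum exactly
#' to one.
#' @return Named numeric 20-vector.
#' @export
default_residue_frequencies <- function() {
  .SWISSPROT_FREQS / sum(.SWISSPROT_FREQS)
}

# run expr with a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

.check_freqs <- function(residue_freqs) {
  if (is.null(residue_freqs)) return(default_residue_frequencies())
  if (length(residue_freqs) != 20L ||
      !setequal(names(residue_freqs), standard_residues()))
    stop_validation("residue_freqs must be a named 20-vector over the standard residues")
  if (abs(sum(residue_freqs) - 1) > 1e-9)
    stop_validation("residue_freqs must sum to 1 (got %.12f)", sum(residue_freqs))
  residue_freqs
}

#' Generate a synthetic proteome with planted peptide occurrences
#'
#' Background residues are drawn i.i.d. from `residue_freqs`; planted
#' peptides overwrite the background at their positions (protein lengths
#' stay exact). The returned truth table records exactly the planted
#' occurrences; the background may additionally contain coincidental
#' copies, so an exact-match scan recovers a superset of the truth table.
#'
#' @param n_proteins Number of proteins.
#' @param length_mean,length_sd Normal distribution of protein lengths
#'   (rounded; floored at 10 residues or the longest planted peptide).
#' @param residue_freqs Named 20-vector summing to 1; `NULL` uses
#'   [default_residue_frequencies()].
#' @param plants Data frame with column `sequence` and optional columns
#'   `protein` (1-based protein index) and `start` (1-based position);
#'   `NA`/absent values are drawn uniformly among feasible placements. A
#'   stated placement that does not fit inside its protein is an error.
#'   Optional `peptide_id` column names the truth-table rows.
#' @param seed Integer seed; the same spec and seed give byte-identical
#'   output.
#' @return List with `proteome` (data frame as from [load_proteome()];
#'   protein ids `g1..gN` so the identity gene-protein map applies) and
#'   `truth` (data frame `protein_id`, `peptide_id`, `start`, `end`,
#'   `peptide_sequence`).
#' @export
generate_proteome <- function(n_proteins, length_mean = 400,
                              length_sd = 100, residue_freqs = NULL,
                              plants = NULL, seed = 1L) {
  stopifnot(n_proteins >= 0L)
  residue_freqs <- .check_freqs(residue_freqs)
  res <- names(residue_freqs)
  truth0 <- data.frame(protein_id = character(), peptide_id = character(),
                       start = integer(), end = integer(),
                       peptide_sequence = character(),
                       stringsAsFactors = FALSE)
  if (n_proteins == 0L)
    return(list(proteome = data.frame(protein_id = character(),
                                      description = character(),
                                      sequence = character(),
                                      stringsAsFactors = FALSE),
                truth = truth0))
  if (!is.null(plants) && nrow(plants)) {
    plants$sequence <- toupper(plants$sequence)
    bad <- !vapply(strsplit(plants$sequence, "", fixed = TRUE),
                   function(x) all(x %in% standard_residues()), logical(1))
    if (any(bad))
      stop_validation("plants: non-standard residue in planted sequence %d",
                      which(bad)[1L])
  }
  min_len <- max(10L, if (!is.null(plants) && nrow(plants))
    max(nchar(plants$sequence)) else 0L)
  .with_seed(seed, {
    lens <- pmax(min_len, as.integer(round(rnorm(n_proteins, length_mean,
                                                 length_sd))))
    chars <- sample(res, sum(lens), replace = TRUE, prob = residue_freqs)
    seqs <- vapply(split(chars, rep.int(seq_len(n_proteins), lens)),
                   paste, character(1), collapse = "")
    names(seqs) <- NULL
    truth <- truth0
    if (!is.null(plants) && nrow(plants)) {
      np <- nrow(plants)
      prot <- if ("protein" %in% names(plants)) as.integer(plants$protein)
              else rep(NA_integer_, np)
      pos <- if ("start" %in% names(plants)) as.integer(plants$start)
             else rep(NA_integer_, np)
      pid <- if ("peptide_id" %in% names(plants)) plants$peptide_id
             else sprintf("planted_%d", seq_len(np))
      k <- nchar(plants$sequence)
      occupied <- vector("list", n_proteins)  # intervals already planted
      overlaps <- function(p, s, e) {
        occ <- occupied[[p]]
        !is.null(occ) && any(s <= occ[, 2L] & e >= occ[, 1L])
      }
      for (i in seq_len(np)) {
        random_placement <- is.na(prot[i]) || is.na(pos[i])
        for (try in seq_len(200L)) {
          if (is.na(prot[i]) || (random_placement && try > 1L)) {
            fits <- which(lens >= k[i])
            if (length(fits) == 0L)
              stop_validation("plants row %d: no protein long enough", i)
            prot[i] <- fits[sample.int(length(fits), 1L)]
          }
          if (prot[i] < 1L || prot[i] > n_proteins)
            stop_validation("plants row %d: protein index %d out of range",
                            i, prot[i])
          if (is.na(pos[i]) || (random_placement && try > 1L))
            pos[i] <- sample.int(lens[prot[i]] - k[i] + 1L, 1L)
          if (pos[i] < 1L || pos[i] + k[i] - 1L > lens[prot[i]])
            stop_validation("plants row %d: peptide does not fit protein %d at position %d",
                            i, prot[i], pos[i])
          # random placements avoid already-planted regions so earlier
          # plants are never overwritten; explicit positions are honoured
          if (!random_placement || !overlaps(prot[i], pos[i],
                                             pos[i] + k[i] - 1L)) break
          if (try == 200L)
            stop_validation("plants row %d: no non-overlapping placement found", i)
        }
        occupied[[prot[i]]] <- rbind(occupied[[prot[i]]],
                                     c(pos[i], pos[i] + k[i] - 1L))
        s <- seqs[prot[i]]
        substr(s, pos[i], pos[i] + k[i] - 1L) <- plants$sequence[i]
        seqs[prot[i]] <- s
      }
      truth <- data.frame(protein_id = paste0("g", prot),
                          peptide_id = pid, start = pos,
                          end = pos + k - 1L,
                          peptide_sequence = plants$sequence,
                          stringsAsFactors = FALSE)
    }
    proteome <- data.frame(protein_id = paste0("g", seq_len(n_proteins)),
                           description = "synthetic protein",
                           sequence = seqs, stringsAsFactors = FALSE)
    # generator self-check: every truth row must slice-match the proteome
    if (nrow(truth)) {
      sl <- substring(proteome$sequence[match(truth$protein_id,
                                              proteome$protein_id)],
                      truth$start, truth$end)
      stopifnot(identical(sl, truth$peptide_sequence))
    }
    list(proteome = proteome, truth = truth)
  })
}

# 18 activity-category labels in the style of curated biopeptide databases
.DEFAULT_ACTIVITIES <- c(
  "ACE inhibitor", "DPP-4 inhibitor", "antioxidative", "antibacterial",
  "anticancer", "antithrombotic", "antiamnestic", "immunomodulating",
  "antiviral", "antiaging", "renin inhibitor", "opioid",
  "hypocholesterolemic", "stimulating", "binding", "anorectic",
  "regulating", "neuropeptide")

#' Generate a synthetic biopeptide library
#'
#' Random sequences with lengths uniform in `length_range`, activity labels
#' assigned round-robin, and chemical masses computed from the average
#' residue table (so [validate_library_masses()] reports no discrepancy).
#'
#' @param n Number of records.
#' @param length_range Integer pair within the 2-60 biopeptide definition.
#' @param activities Character vector of category labels (default: 18
#'   labels in the style of curated databases).
#' @param residue_freqs As in [generate_proteome()].
#' @param seed Integer seed.
#' @return A [biopeptide_library()].
#' @export
generate_library <- function(n, length_range = c(2L, 60L),
                             activities = .DEFAULT_ACTIVITIES,
                             residue_freqs = NULL, seed = 1L) {
  stopifnot(n >= 0L)
  length_range <- as.integer(length_range)
  if (length(length_range) != 2L || length_range[1L] < 1L ||
      length_range[1L] > length_range[2L])
    stop_validation("invalid length_range [%s]",
                    paste(length_range, collapse = ", "))
  residue_freqs <- .check_freqs(residue_freqs)
  if (n == 0L)
    return(biopeptide_library(provenance = "synthetic"))
  .with_seed(seed, {
    lens <- sample(seq(length_range[1L], length_range[2L]), n, replace = TRUE)
    seqs <- vapply(lens, function(k) {
      paste(sample(names(residue_freqs), k, replace = TRUE,
                   prob = residue_freqs), collapse = "")
    }, character(1))
    act <- activities[(seq_len(n) - 1L) %% length(activities) + 1L]
    biopeptide_library(
      peptide_id = sprintf("BP%05d", seq_len(n)),
      name = paste("synthetic", act, "peptide"),
      sequence = seqs,
      mass = compute_peptide_mass(seqs, "average"),
      activities = as.list(act),
      provenance = sprintf("synthetic (seed %d)", as.integer(seed)),
      out_of_range = lens < 2L | lens > 60L)
  })
}

#' Generate a synthetic differential-expression table
#'
#' A chosen fraction of genes is set to `+effect` log2 fold-change; the
#' remainder are drawn uniformly on [-2.5, 0.95], strictly below the usual
#' upregulation cutoff of 1.0.
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param fraction_up Proportion in [0, 1] of genes upregulated.
#' @param effect log2 fold-change assigned to upregulated genes
#'   (default 2.0).
#' @param contrast Label for the contrast column.
#' @param seed Integer seed.
#' @return List with `expression` (data frame `gene_id`, `log2fc`,
#'   `contrast`) and `upregulated` (character vector: the truth list).
#' @export
generate_expression <- function(gene_ids, fraction_up = 0.25, effect = 2.0,
                                contrast = "seed_vs_rest", seed = 1L) {
  stopifnot(fraction_up >= 0, fraction_up <= 1)
  n <- length(gene_ids)
  .with_seed(seed, {
    n_up <- round(fraction_up * n)
    up <- sort(sample.int(n, n_up))
    lfc <- runif(n, -2.5, 0.95)
    lfc[up] <- effect
    list(expression = data.frame(gene_id = gene_ids, log2fc = lfc,
                                 contrast = contrast,
                                 stringsAsFactors = FALSE),
         upregulated = gene_ids[up])
  })
}

#' Write a proteome to FASTA
#'
#' @param proteome Data frame with `protein_id`, `description`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteome, path) {
  hdr <- ifelse(nzchar(proteome$description),
                paste(proteome$protein_id, proteome$description),
                proteome$protein_id)
  writeLines(paste0(">", hdr, "\n", proteome$sequence), path)
  invisible(path)
}

#' Write / read a planted-occurrence truth table
#'
#' @param truth Data frame from [generate_proteome()].
#' @param path TSV path.
#' @return `path` (write) or the truth data frame (read).
#' @export
write_truth_table <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  if (!file.exists(path)) stop_io("truth table not found: %s", path)
  read.delim(path, stringsAsFactors = FALSE)
}
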