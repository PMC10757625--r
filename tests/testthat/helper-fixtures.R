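# Shared fixture builders and the independent match oracle.

# quick in-code library constructor: lib_of(P1 = "AA", P2 = "AB")
lib_of <- function(...) {
  seqs <- c(...)
  if (length(seqs) == 0L) return(biopeptide_library(provenance = "test"))
  biopeptide_library(peptide_id = names(seqs),
                     name = paste("peptide", names(seqs)),
                     sequence = unname(seqs),
                     mass = rep(NA_real_, length(seqs)),
                     activities = as.list(rep("test", length(seqs))),
                     provenance = "test")
}

proteome_of <- function(...) {
  seqs <- c(...)
  data.frame(protein_id = if (is.null(names(seqs))) character() else names(seqs),
             description = character(length(seqs)),
             sequence = unname(seqs), stringsAsFactors = FALSE)
}

# Independent oracle: per-pattern overlapping exact matching via Biostrings.
# Returns hits in the same layout as find_matches(), unsorted.
biostrings_oracle <- function(lib, proteome) {
  rows <- list()
  for (t in seq_len(nrow(proteome))) {
    subject <- Biostrings::BString(proteome$sequence[t])
    for (p in seq_len(nrow(lib))) {
      m <- Biostrings::matchPattern(lib$sequence[p], subject)
      if (length(m) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = proteome$protein_id[t],
        peptide_id = lib$peptide_id[p],
        start = BiocGenerics::start(m), end = BiocGenerics::end(m),
        peptide_sequence = lib$sequence[p], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein_id = character(), peptide_id = character(),
                      start = integer(), end = integer(),
                      peptide_sequence = character(), stringsAsFactors = FALSE)
  out
}

# canonical sort so hit tables can be compared as multisets
sort_hits <- function(h) {
  h <- h[order(h$protein_id, h$peptide_id, h$start), , drop = FALSE]
  rownames(h) <- NULL
  h
}

random_instance <- function(seed, max_proteins = 50L, max_len = 200L,
                            max_peptides = 30L) {
  set.seed(seed)
  # small alphabet so matches are frequent enough to exercise the automaton
  alpha <- c("A", "C", "D", "G", "K", "R")
  np <- sample.int(max_proteins, 1L)
  prot <- vapply(seq_len(np), function(i)
    paste(sample(alpha, sample.int(max_len, 1L), replace = TRUE),
          collapse = ""), character(1))
  nk <- sample.int(max_peptides, 1L)
  peps <- vapply(seq_len(nk), function(i)
    paste(sample(alpha, sample(2:6, 1L), replace = TRUE), collapse = ""),
    character(1))
  lib <- biopeptide_library(peptide_id = sprintf("P%03d", seq_len(nk)),
                            name = "random", sequence = peps,
                            activities = as.list(rep("x", nk)),
                            mass = rep(NA_real_, nk))
  list(lib = lib,
       proteome = data.frame(protein_id = sprintf("t%03d", seq_len(np)),
                             description = "", sequence = prot,
                             stringsAsFactors = FALSE))
}

write_tsv_fixture <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
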