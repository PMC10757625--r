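test_that("trypsin and chymotrypsin reproduce hand-derived digests", {
  tryp <- builtin_cleavage_rules("trypsin")
  # K2 is blocked by P3; K5 cleaves
  fr <- digest("AKPGKG", tryp, protein_id = "p")
  expect_equal(fr$sequence, c("AKPGK", "G"))
  expect_equal(fr$start, c(1L, 6L))
  expect_equal(fr$end, c(5L, 6L))

  chym <- builtin_cleavage_rules("chymotrypsin")
  fr2 <- digest("GFGPYG", chym)
  expect_equal(fr2$sequence, c("GF", "GPY", "G"))
  # F cleaves, Y followed by G cleaves; W/F before P would be blocked
  expect_equal(digest("AFPA", chym)$sequence, "AFPA")
})

test_that("pepsin and elastase site rules behave as specified", {
  pep <- builtin_cleavage_rules("pepsin")
  expect_equal(digest("GLGFG", pep)$sequence, c("GL", "GF", "G"))
  ela <- builtin_cleavage_rules("elastase")
  expect_equal(digest("KAKVK", ela)$sequence, c("KA", "KV", "K"))
  expect_equal(digest("KAPK", ela)$sequence, "KAPK")  # P1' proline blocks
})

test_that("empty rule set leaves the protein as one fragment", {
  expect_warning(fr <- digest("GGGG", list(), protein_id = "p"), "empty rule")
  expect_equal(fr$sequence, "GGGG")
  expect_equal(c(fr$start, fr$end), c(1L, 4L))
})

test_that("zero-missed-cleavage fragments partition every protein", {
  rules <- builtin_cleavage_rules()
  set.seed(7)
  for (i in 1:100) {
    seqn <- paste(sample(standard_residues(), sample(5:120, 1), TRUE),
                  collapse = "")
    for (r in rules) {
      fr <- digest(seqn, list(r))
      expect_equal(paste(fr$sequence, collapse = ""), seqn)
      expect_equal(fr$start, c(1L, head(fr$end, -1) + 1L))
      expect_true(all(fr$end >= fr$start))
    }
    # the union digest partitions too
    fr_all <- digest(seqn, rules)
    expect_equal(paste(fr_all$sequence, collapse = ""), seqn)
  }
})

test_that("adding a rule never removes cleavage sites", {
  rules <- builtin_cleavage_rules()
  set.seed(8)
  for (i in 1:30) {
    seqn <- paste(sample(standard_residues(), 80, TRUE), collapse = "")
    s1 <- biopepscan:::cleavage_sites(seqn, rules["trypsin"])
    s2 <- biopepscan:::cleavage_sites(seqn, rules[c("trypsin", "pepsin")])
    expect_true(all(s1 %in% s2))
  }
})

test_that("missed cleavages add flagged merged fragments, partition intact", {
  tryp <- builtin_cleavage_rules("trypsin")
  fr <- digest("AKGKGK", tryp, missed_cleavages = 1L)
  part <- fr[fr$is_partition, ]
  expect_equal(part$sequence, c("AK", "GK", "GK"))
  merged <- fr[!fr$is_partition, ]
  expect_equal(sort(merged$sequence), sort(c("AKGK", "GKGK")))
  expect_true(all(merged$n_missed == 1L))
  # merging more than available sites is capped, not an error
  fr2 <- digest("AK", tryp, missed_cleavages = 5L)
  expect_equal(nrow(fr2), 1L)
})

test_that("releasability trichotomy on the worked trypsin example", {
  tryp <- builtin_cleavage_rules("trypsin")
  prot <- proteome_of(p = "AKPGKG")
  frags <- digest_proteome(prot, tryp)
  hit <- function(s, e) data.frame(
    protein_id = "p", peptide_id = "x", start = s, end = e,
    peptide_sequence = substring("AKPGKG", s, e), stringsAsFactors = FALSE)
  expect_equal(classify_releasability(hit(1, 5), frags, "trypsin")$status,
               "exact_release")
  expect_equal(classify_releasability(hit(4, 6), frags, "trypsin")$status,
               "split")
  expect_equal(classify_releasability(hit(2, 4), frags, "trypsin")$status,
               "contained")
})

test_that("under the empty rule set every hit is contained or exact", {
  prot <- proteome_of(p = "GGAAGG")
  frags <- suppressWarnings(digest_proteome(prot, list()))
  lib <- lib_of(P1 = "AA", P2 = "GGAAGG")
  calls <- classify_releasability(find_matches(lib, prot), frags, character())
  expect_equal(calls$status[calls$peptide_id == "P1"], "contained")
  expect_equal(calls$status[calls$peptide_id == "P2"], "exact_release")
})

test_that("every hit gets exactly one status over random instances", {
  rules <- builtin_cleavage_rules()
  set.seed(9)
  for (i in 1:20) {
    inst <- random_instance(i + 500, max_proteins = 10L, max_len = 100L)
    hits <- find_matches(inst$lib, inst$proteome)
    if (nrow(hits) == 0L) next
    frags <- digest_proteome(inst$proteome, rules)
    calls <- classify_releasability(hits, frags, names(rules))
    expect_equal(nrow(calls), nrow(hits))
    expect_true(all(calls$status %in% c("exact_release", "contained", "split")))
    # spot-check split against the boundary definition
    sites <- lapply(inst$proteome$sequence, biopepscan:::cleavage_sites,
                    rules = rules)
    names(sites) <- inst$proteome$protein_id
    crosses <- mapply(function(pid, s, e) {
      any(sites[[pid]] >= s & sites[[pid]] < e)
    }, calls$protein_id, calls$start, calls$end)
    expect_equal(unname(calls$status == "split"), unname(crosses))
  }
})

test_that("hits on proteins missing from the digest are a consistency error", {
  frags <- digest_proteome(proteome_of(p = "AKGK"),
                           builtin_cleavage_rules("trypsin"))
  hit <- data.frame(protein_id = "q", peptide_id = "x", start = 1L, end = 2L,
                    peptide_sequence = "AK", stringsAsFactors = FALSE)
  expect_error(classify_releasability(hit, frags, "trypsin"), "q",
               class = "biopepscan_validation_error")
})

test_that("rules load from YAML config and invalid rules are rejected", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("trypsin:", "  cleave_after: KR", "  not_before: P",
               "cnbr:", "  cleave_after: M"), f)
  rules <- load_cleavage_rules(f)
  expect_equal(names(rules), c("trypsin", "cnbr"))
  expect_equal(rules$trypsin$p1_residues, c("K", "R"))
  expect_equal(rules$cnbr$blocked_p1prime, character(0))
  expect_equal(digest("GMG", rules["cnbr"])$sequence, c("GM", "G"))
  expect_error(cleavage_rule("bad", ""), "non-empty",
               class = "biopepscan_validation_error")
})
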