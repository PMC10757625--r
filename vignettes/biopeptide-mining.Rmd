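---
title: "Mining bioactive peptides in proteomes: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining bioactive peptides in proteomes: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biopepscan)
```

## What the pipeline computes

`biopepscan` annotates a proteome with known bioactive peptides
(biopeptides): 2–60-residue fragments of dietary proteins with documented
physiological roles such as ACE inhibition (antihypertensive) or DPP-4
inhibition (antidiabetic). The pipeline has four stages:

1. **Localisation.** Every exact occurrence of every library peptide in
   every protein, overlapping occurrences included, 1-based inclusive
   coordinates.
2. **Aggregation.** Per activity category: distinct matched peptide types,
   total occurrences, distinct protein–peptide pairs, distinct carrier
   proteins.
3. **Expression cross-reference.** Upregulated genes (inclusive log2
   fold-change cutoff) whose protein products carry at least one matched
   biopeptide, with the union of carried activities.
4. **Releasability (extension).** Whether a chosen set of gastrointestinal
   proteases could liberate each matched peptide intact.

Stages 1–3 reconstruct a published in-silico annotation workflow;
stage 4 closes the gap that workflow explicitly left open (its script did
not look for protease digestion sites near a match).

## Matching model and its assumptions

Matching is exact string equality over the amino-acid alphabet. No
scoring, no substitutions, no motifs: a biopeptide is either literally
present in a protein or it is not. This makes "best match" trivially
well-defined — all exact matches — and admits a clean reference
implementation. Two deliberate semantic choices:

* **Overlaps count.** A length-$k$ peptide occurs $n-k+1$ times in a
  homopolymer of length $n$. This is the only convention under which the
  count equals what a naive re-scan finds; leftmost non-overlapping
  counting is available (`overlap = FALSE`) for sensitivity analysis.
* **`X` and `*` never match.** An unknown residue cannot be claimed equal
  to anything; a stop symbol inside a sequence separates translation
  products, so matches never cross it. All other A–Z letters compare by
  plain equality; ambiguity codes (B, J, Z, U, O) are policed at library
  load (rejected in strict mode, skipped in lenient mode) rather than in
  the matcher.

The default engine is an Aho–Corasick automaton over the full pattern set,
built once and streamed over each protein — time is linear in proteome
size plus output size, independent of library size, which is what makes
~4,000 patterns × ~48,000 proteins routine. The naive sliding-window
engine gives identical output and serves as the in-package reference; the
test suite additionally cross-checks both against `Biostrings` pattern
matching on random instances.

Records sharing a sequence are *type-indexed*: two library entries with
identical sequences each receive the full occurrence list, because curated
databases list the same sequence under different identities and roles.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| length bounds | 2–60 aa | definition of a biopeptide; out-of-range library records load only with `allow_out_of_range = TRUE` and are tagged |
| `threshold` | 1.0 | inclusive log2 fold-change cutoff for "upregulated"; ≥, not > |
| `overlap` | `TRUE` | count overlapping occurrences |
| `engine` | `"automaton"` | `"naive"` is the reference implementation |
| `missed_cleavages` | 0 | extra merged digest fragments, flagged separately |
| mass `mode` | `"average"` | `"monoisotopic"` also available; `validate_library_masses()` reports both computed values because exports rarely state their convention |
| mass `tolerance` | 0.5 Da | audit tolerance; the synthetic generator is exact to < 0.01 Da |

"Instances" is reported both as total occurrences (`n_instances`) and as
distinct protein–peptide pairs (`n_pairs`); headline numbers in the
literature rarely say which convention they use, so both columns always
appear rather than choosing silently.

## Digestion model

Cleavage rules follow the P1/P1′ convention: cleave after any residue in
the P1 set unless the next residue is blocked. Built-ins: trypsin (after
K/R, not before P), chymotrypsin high-specificity (after F/Y/W, not before
P), pepsin at low pH (after F/L) and pancreatic elastase (after
A/V/S/G/L/I, not before P). The pepsin and elastase rules are simplified:
their true specificity depends on wider sequence context than a single P1/P1′
pair can express, and published rule sets differ. Users can supply their
own YAML rules. Carboxypeptidases are exopeptidases — no site rule — and
are out of scope, as are cleavage-probability models, pH kinetics and
bioavailability.

Releasability is this package's own operational definition, not a
published one: against the zero-missed-cleavage fragment partition of a
protein, a hit is `exact_release` if its coordinates equal a fragment's,
`contained` if it lies strictly inside one fragment, `split` if a cleavage
boundary falls inside it. The three statuses are mutually exclusive and
exhaustive (the test suite checks the trichotomy against an independent
boundary-crossing computation). Note the asymmetry of interpretation:
`split` is decisive (these proteases destroy the peptide), while
`contained` means "not liberated by endopeptidase action alone" —
exopeptidase trimming, which this model omits, could still release it.

## Synthetic data: what it emulates and what it does not

Generators are seeded and byte-reproducible; every stage of the pipeline
can therefore be tested against known ground truth without any downloads.

* **Proteome.** Residues drawn i.i.d. from Swiss-Prot average amino-acid
  composition (a realistic single-residue background; uniform frequencies
  would overweight rare residues like W and C). Protein lengths are
  normal with configurable mean/sd (default 400 ± 100, the scale of a
  typical plant proteome's mean product), floored at the longest planted
  peptide. Planted peptides *overwrite* the background at their positions,
  keeping lengths exact; the truth table records exactly the planted
  occurrences and the generator self-checks slice equality before
  returning. Because the background is random, a scan recovers a
  *superset* of the truth table — coincidental background occurrences are
  expected, and the test suite verifies their rate against the
  $L\prod_i f(r_i)$ i.i.d. expectation across 200 seeded replicates.
* **Library.** Lengths uniform on the 2–60 range, activities assigned
  round-robin over 18 category labels styled after curated databases,
  masses computed exactly from the embedded average table.
* **Expression.** A chosen fraction of genes is set to exactly the effect
  size (default +2.0 log2FC); the rest are drawn uniformly on
  [−2.5, 0.95], strictly below the 1.0 cutoff, so the upregulated truth
  set is unambiguous at the default threshold.

What the synthetic model deliberately lacks: homology and repeat
structure, Markov/compositional correlation along sequences, biased codon
or domain composition, realistic activity multi-labelling, and any
relation between expression and sequence. Passing tests on synthetic data
therefore demonstrate *algorithmic correctness* (recall = 1 on planted
occurrences, precision = 1 by slice equality, exact aggregation laws) —
they do not validate biological conclusions drawn from any particular
curated library, whose coverage and curation quality dominate real-world
results.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive everywhere user-visible.
* Masses: residue-sum plus one water; average and monoisotopic tables are
  embedded constants (IUPAC-derived), so results never depend on network
  resources. Additivity ($m(s_1 s_2) = m(s_1) + m(s_2) - m_{H_2O}$) is a
  tested invariant.
* Empty inputs degrade explicitly: empty library → warning and empty hit
  stream; empty rule set → one fragment spanning the protein (warning),
  under which every hit is `contained` (or `exact_release` if the peptide
  is the whole protein); header-only tables → empty collections.
* Determinism: reports sort activities alphabetically and proteins in
  input order; identical inputs give byte-identical outputs; all
  generators take explicit seeds and restore the caller's RNG state.
* Sort order of the hit stream is protein input order, then start
  position, then peptide id — fully specified so engines can be compared
  `identical()`-style.

## Problem sizes used in the checks

The shipped verification uses: 100 random matcher instances (≤ 50 proteins
× ≤ 200 residues, ≤ 30 peptides) for engine-vs-oracle equivalence; a
1,000-protein × ~400-residue proteome with 50 planted peptides for
recovery; an 8,000-protein synthetic study for the end-to-end quantities
in `scripts/acceptance.R`; and one full-scale smoke test at 48,090
proteins × ~400 residues against 4,341 peptides — the scale of a recently
annotated plant proteome against a full BIOPEP-UWM export — which
completes in minutes on a single CPU.

## Known limitations

* Exact matching only: a single conservative substitution hides a
  peptide. This is inherent to the annotation model, not an oversight —
  fuzzy matching would require an activity-preserving similarity measure
  that does not exist for short peptides.
* The releasability trichotomy ignores exopeptidases and digestion
  kinetics; `contained` calls are upper bounds on survivability, not
  release predictions.
* The gene↔protein identity mapping assumes one product per gene id;
  supply an explicit two-column map for proteomes with isoform-level ids.
* Library curation is manual by design: no BIOPEP-UWM client is included,
  and no enrichment statistics are computed over activity categories.
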