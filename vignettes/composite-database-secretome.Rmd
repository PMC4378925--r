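---
title: "Sorting serum contaminants from cell secretomes with composite search databases"
author: "contamsort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sorting serum contaminants from cell secretomes with composite search databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contamsort)
```

## The analytical problem

Secretome samples collected from cultured human cells carry residual
fetal bovine serum (FBS) protein — on the order of 5–10% of total
protein — despite serum-free collection and repeated washing. A shotgun
LC-MS/MS search of such a sample faces a database dilemma. A human-only
database cannot match contaminant spectra at all, or worse, matches them
to spurious human sequences. A full human+bovine database recovers the
contaminants but enlarges the search space so much that implausible
bovine proteins (never observed in FBS, and too dilute to be detectable
from a trace contaminant) are "identified". The composite-database
strategy threads the needle: append to the human proteome only the
bovine proteins actually observed when FBS itself is deeply profiled,
plus the usual utility sequences (proteases, mass standards). This keeps
the search space honest while giving every plausible contaminant
spectrum a correct target.

`contamsort` implements this strategy end to end: database construction,
cross-species peptide specificity, PSM filtering and protein inference,
cross-database comparison, SILAC auditing, and a synthetic-data
generator that provides ground truth for validating all of it.

## Database construction

A `sequence_db` holds FASTA records tagged with a species
(`human`/`bovine`/`utility`) and a source label, with per-component
provenance. `merge_databases()` concatenates in argument order, so entry
counts are exactly additive; at the scale of the original databases an
88,304-entry human set plus a 24,235-entry bovine set gives 112,539
entries, and appending the 199 profiled FBS sequences to the human set
gives 88,503. Accessions must be unique within a database; cross-part
collisions are suffix-disambiguated with the source label by default
(UniProt accessions do not collide across species, but user-supplied
databases may), with a strict `collision = "error"` mode available.
Ambiguity codes B/J/X/Z/U are tolerated with a warning and terminal `*`
stop characters are stripped, matching what real UniProt releases
contain. FASTA is written with `accession description` headers wrapped
at 60 columns.

The packaged 20-entry utility set is synthetic: the categories
(trypsin, chymotrypsin, Arg-C, Lys-C, Asp-N fragments; yeast enolase
standards) are standard, but no authoritative accession list exists for
them, so placeholder sequences carry the `utility` species tag. Only
their count and tag matter downstream: utility matches are censused in
their own bin, never as human or bovine.

## In-silico digestion and the peptide index

`digest()` produces fully tryptic peptides: cleavage C-terminal to K or
R, suppressed when the next residue is proline (the classic rule;
configurable, as some search engines cleave KP/RP), with 0–2 internal
missed cleavages by default. Length bounds default to 6–50 residues, the
practically observable range for an ion-trap instrument; the bounds are
parameters because they are instrument conventions, not facts about
trypsin. Semi-tryptic and non-specific peptides are deliberately out of
scope — the search settings this package post-processes used full
enzyme specificity.

`build_peptide_index()` digests whole proteomes and maps each peptide to
all its (protein, species) parents. `classify_peptide()` then reads off
species specificity: a peptide is `shared` (orthologous) when both a
human and a bovine protein yield it. Isoleucine/leucine folding
(`equate_il`) is off by default — indexing works on exact sequences —
but is exposed because CID fragmentation cannot distinguish I from L, so
any species-specificity conclusion should be checked under both
settings. Modified residues are ignored for indexing: specificity is a
property of the bare sequence.

The digestion routine is verified against an independent brute-force
oracle that enumerates all substrings of random proteins and keeps those
with valid tryptic termini and admissible internal site counts; the two
agree exactly over hundreds of random proteins at 0–2 missed cleavages.

## PSM filtering, protein inference, q-values

`filter_psms()` retains a PSM iff q ≤ 0.01, XCorr meets its
charge-state threshold (+1: 1.5, +2: 2, +3: 2.25, +4: 2.5, +5: 2.75,
+6: 3, +7: 3.2, above +7: 3.4), and it is the top-ranked match. The
comparisons are exact (no epsilon slack). Protein-level criteria apply
after grouping: at least one unique peptide, and a protein score of at
least 10. When the input table carries no vendor protein score, the sum
of retained PSM XCorr per group is used as a documented proxy — the
vendor metric is not public, so equivalence is not claimed.

`group_proteins()` implements greedy maximum-parsimony inference:
proteins with identical explained-peptide sets merge; groups are chosen
by descending gain in unexplained peptides, ties broken by total peptide
count and then lexicographically smallest accession, and each peptide is
assigned to exactly one group. Greedy set cover is not guaranteed
minimal in general, but on small instances (≤6 proteins, ≤8 peptides)
it matches an exhaustive minimum-cover search in the test suite, and its
determinism is what matters for reproducible censuses.

`estimate_q_values()` is plumbing for synthetic end-to-end runs, not a
replacement for a production rescoring engine: FDR at threshold t is
#decoys ≥ t over #targets ≥ t, tied scores share the FDR computed at
the last PSM of the tie, and q is the running minimum from the bottom of
the score ranking, making it monotone non-increasing in score.

## Species census and cross-search comparison

`census_psms()` partitions PSMs into six classes. Orthologous peptides
take precedence: whatever protein the search engine reported, a
shared-sequence peptide cannot identify a species. Bovine-unique PSMs
are split by contaminant-list membership into major FBS (top-abundance
profiled contaminants), minor FBS (the rest of the profiled list) and
other bovine (never observed in FBS profiling — under a composite
database this class should be empty, and its appearance under a full
bovine database is the false-positive signature). The class counts
always sum to the PSM total.

`compare_searches()` joins two searches of the same spectra on
(spectrum file, scan) — charge is excluded from the key so re-searches
join — and takes the best (lowest-PEP) PSM when one spectrum carries
several charges. The comparison statistic is
Δ(−logPEP) = −log₁₀PEP_B − (−log₁₀PEP_A). Conventions the figure-style
regions need but that no standard fixes: logarithms are base 10; PEP is
floored at 1e-10 before the log to avoid infinities; |Δ| < 0.7 is grey,
Δ ≥ +0.7 red, Δ ≤ −0.7 green (the boundary value itself is assigned to
the colored region so the five regions partition the joined spectra);
spectra present only in B are blue, and spectra present only in A are
reported as `a_only_unmatched` rather than silently dropped. Swapping
the arguments maps red↔green and blue↔a_only_unmatched and fixes grey,
which the test suite asserts on simulated spectra.

## SILAC auditing

In a SILAC culture, newly synthesized (cellular) proteins incorporate
heavy arginine (+10.01 Da) and lysine (+8.01 Da); serum proteins in the
medium remain light. Metabolic Arg→Pro conversion additionally produces
+6.01 Da prolines at a low rate. `annotate_labels()` flags each R/K/P
residue of a peptide by whether a matching label modification sits at
its position (a label annotated on the wrong residue type is treated as
a corrupt table and rejected). `residue_census()` aggregates labeled and
unlabeled counts per species class, so a correct census shows
human-class R/K at the incorporation efficiency and bovine-class
residues at zero — the orthogonal evidence that the composite-database
assignment is sound.

`classify_protein_labels()` classifies each protein group three ways:
labeled (all supporting peptides carry a label), non-labeled (none do),
partially labeled (a mix). Because the underlying experiment does not
define whether "peptides" means distinct sequences or distinct
observations, both tallies are emitted: the primary status counts
distinct (sequence, charge, label-state) observations, and
`status_sequence` applies an any-PSM-labeled rule per sequence.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated; its defaults are fixed, not tuning knobs:

* contaminant PSM fraction 0.07 — the midpoint of the 5–10% residual-FBS
  share expected in secretome preparations;
* 30 major FBS proteins receiving 93% of contaminant PSMs, matching the
  top-30 dominance observed when FBS is profiled deeply;
* SILAC label efficiency 0.97 per R/K residue (incorporation above 95%
  after several passages) and an Arg→Pro conversion rate of 0.03;
* orthology fraction 0.25 of bovine proteins cloned from human templates
  — a value chosen once as a realistic degree of cross-species sharing;
  each clone preserves one tryptic peptide (and its cleavage context)
  exactly while the rest of the sequence is mutated, giving exact
  control over shared peptides;
* residue sampling frequencies with K+R ≈ 11% so tryptic peptide lengths
  are realistic;
* a two-population score model: correct matches draw XCorr from
  N(3.2, 0.4), incorrect ones from N(1.6, 0.35), with
  PEP = 1/(1 + exp(3·(XCorr − 2.2))) and a 0.05-SD per-database jitter.
  This is a test harness, not a claim about SEQUEST score distributions.

Under each database a spectrum yields a PSM only if its true peptide
exists there; bovine-unique contaminant spectra therefore vanish under a
human-only database (the blue-region mechanism) or, with probability
`incorrect_psm_rate`, are forced onto a wrong low-scoring human peptide
(the red-region mechanism). q-values are filled by target-decoy counting
over generated decoys. All randomness flows through seeds derived
deterministically from the configured seed, stage by stage, and the
session RNG state is left untouched; identical seed and configuration
give identical output.

What the generator does **not** emulate: spectra, m/z and mass errors,
retention time, chromatographic and fractionation effects, homology
that is partial rather than exact-peptide-preserving, shared peptides
within a species, and vendor-specific score metrics. Passing tests on
synthetic data therefore demonstrate the correctness of the
classification and counting machinery under controlled conditions, not
the performance of any search engine on real spectra.

## Problem sizes and verification

The test suite and the acceptance script exercise: database arithmetic
at the published scale (88,304 + 24,235 and 88,304 + 199 placeholder
entries); digestion against the brute-force oracle on 200 random
proteins of up to 60 residues at 0–2 missed cleavages; census and
region invariants on 1,000-spectrum simulations across 20 seeds; one
end-to-end scenario of 5,000 spectra at contaminant fraction 0.07
(recovery within the binomial 99% CI, empty high-confidence green
region, every bovine-unique contaminant in blue or red); SILAC recovery
at efficiency 0.97 (human R/K fractions within 3 binomial SEs, bovine
fractions exactly zero, bovine groups non-labeled); and false-discovery
control of the target-decoy estimator at q ≤ 0.01. These sizes were
chosen to give the binomial checks adequate power at desk scale.

## Known limitations

* Greedy parsimony can, in principle, produce more groups than a
  minimal cover on adversarial instances; it is used because it is the
  field's convention and is deterministic under the documented
  tie-breaks.
* When a human-origin spectrum on a shared peptide is assigned by
  parsimony to a bovine contaminant group, that group inherits a labeled
  peptide and is classified partially labeled rather than non-labeled.
  This occurs occasionally across random seeds; it is a faithful
  consequence of observation-level classification in the presence of
  orthologous peptides, and is the group-level analogue of why
  orthologous PSMs get their own census class.
* The target-decoy q-value estimator is deliberately simple (no
  rescoring, no feature learning); it exists so synthetic runs have
  calibrated q-values, and its false-discovery control is verified only
  under the generator's score model.
* `read_psm_table()` consumes delimited exports only; mzIdentML/mzML
  parsing is out of scope.
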