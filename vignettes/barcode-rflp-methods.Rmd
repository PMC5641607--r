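---
title: "Methods: in-silico PCR-RFLP diagnostics on the COI barcode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-silico PCR-RFLP diagnostics on the COI barcode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeRFLP)
```

## The problem

Five cockroach species dominate human-associated pest problems: the
American (*Periplaneta americana*), Oriental (*Blatta orientalis*),
Turkestan (*Shelfordella lateralis*), German (*Blattella germanica*) and
Brown-banded (*Supella longipalpa*) cockroaches. Morphological keys fail
exactly when identification matters most — decayed specimens, body
fragments in food, immature stages. A PCR-RFLP assay on the mitochondrial
COI barcode solves this cheaply: amplify a 710 bp fragment with the
universal barcode primers, digest with a single restriction enzyme (AluI,
recognition `AGCT`), and read the species off the band pattern on an
agarose gel.

`barcodeRFLP` implements that assay — and the analysis used to design and
defend it — as composable, in-silico operations: virtual PCR, pairwise
similarity at the DNA and amino-acid level, neighbor-joining phylogeny,
restriction digestion, and a gel-visibility model under which enzyme
libraries can be screened for single-enzyme diagnostics.

## Models and procedures

### Virtual PCR

Primer annealing uses asymmetric IUPAC matching: a primer base matches a
template base when the template base's concrete set is contained in the
primer base's ambiguity set; a template `N` never matches (an unread base
is not evidence of annealing). The 3'-terminal primer base must match
exactly whatever the mismatch budget, reflecting the polymerase's
requirement for a paired 3' end; the default budget is 0 mismatches so
results are deterministic. The amplicon spans both primer footprints
(forward-primer 5' end through reverse-primer 5' end) and is normalized to
the forward-primer strand so cut positions are comparable across
templates. A template producing no product is skipped with a warning; more
than one consistent primer pairing is reported as ambiguous rather than
silently resolved.

The bundled primer pair is the universal COI barcode pair LCO1490
(forward, 25 nt) / HCO2198 (reverse, 27 nt as configured here). Note that
this HCO2198 string carries one extra leading `T` relative to the
canonical 26 nt sequence; it is kept verbatim as configured in the assay
rather than "corrected", since the extra 5' base does not change the
annealing site or product length downstream of the footprint.

### Distances and translation

Pairwise comparisons use Needleman–Wunsch global alignment with a linear
gap penalty and a fixed traceback tie-break (diagonal, then gap in the
second sequence, then gap in the first), so every alignment is
bit-reproducible. DNA percent identity is `100 × identical / comparable`
columns, where comparable columns have no gap in either row — this mirrors
the usual practice of scoring identity over the mutual ungapped window.
Amino-acid identity translates the degapped window under the invertebrate
mitochondrial genetic code (NCBI table 5: `ATA`=Met, `TGA`=Trp,
`AGA/AGG`=Ser), with ambiguous codons rendered as `X` (compared
literally) and stops as `*`. The reading frame is not annotated on raw
amplicons, so it is chosen once per panel as the frame minimizing internal
stop codons, ties to the lowest frame.

Scoring defaults are match +1, mismatch −1, gap −5. The gap penalty is
deliberately stiff relative to the mismatch cost: with a cheap gap (−2), a
pair of compensating internal gaps costs 4 but can convert three or more
mismatches into matches in divergent A-T-rich sequences, biasing percent
identity upward by over a point at ~20% divergence. At −5 the optimal
alignment of substitution-only data stays gapless, and measured identity
equals the underlying p-distance. Both parameters are exposed for users
who want other schemes.

Raw (uncorrected) similarity is used throughout, matching how such
barcode tables are conventionally reported; substitution-model corrections
(Jukes–Cantor, K2P) are intentionally out of scope. The molecular-clock
helper divides percent divergence by a rate, default 2% per million years
(the conventional insect mtDNA clock). Note 22.26 / 2 = 11.13 MY, which
the source literature rounds to "about 10 MY"; the package reports the
unrounded quotient. Published similarity tables for this panel describe
the amino-acid comparison as 210 residues while 648/3 = 216; the package
simply reports whatever length the trimmed window yields rather than
forcing either figure. Intra-species polymorphism is reported as both the
mean and the maximum pairwise divergence, because a single quoted figure
(for example 2.62% within American cockroaches) does not disambiguate the
two conventions.

### Neighbor joining

`neighbor_joining()` is the Saitou–Nei agglomeration on a divergence
matrix (`100 − similarity`): join the pair minimizing
`Q(i,j) = (r−2)·d(i,j) − R(i) − R(j)`, assign pendant lengths by the
three-point formulas, reduce the matrix, repeat. Ties in `Q` are broken by
the lowest (row, column) index pair and negative branch lengths are
clamped to zero with a warning, so trees are reproducible bit-for-bit. On
additive matrices the algorithm provably recovers the generating tree and
its lengths, and the test suite checks this against an exhaustive
least-squares topology search. Rooting places the root at the midpoint of
the outgroup's pendant edge, which preserves all leaf-to-leaf path
lengths. Monophyly is an exact clade test: a taxon set is monophyletic iff
some clade's leaf set equals it.

The five-species divergence matrix places the three Blattidae species
(American, Oriental, Turkestan) in one clade when the tree is rooted on
the Brown-banded cockroach — the structural claim the package tests. The
full published 16-taxon phylogeny with GenBank comparators is *not*
reproduced as a golden artifact: the comparator sequences are external and
the original alignment settings are unstated, so only structural
properties (clades, outgroup placement, family monophyly on synthetic
family-structured panels) are asserted.

### Restriction digestion

Cut positions are reported as *prefix lengths* — the number of bases 5' of
the cut on the forward strand — so "cuts at 251 and 455" on a 710 bp
product directly yields fragments 251, 204, 255 by successive differences.
Internally coordinates are 0-based half-open; all user-facing reports are
1-based. Both strands are scanned; IUPAC codes in the recognition site
expand, template ambiguity codes never match (no phantom sites from
uncertain bases); overlapping occurrences are all reported and only
identical cut coordinates are deduplicated. Blunt palindromic cutters like
AluI (`AG^CT`) therefore yield one coordinate per site, while staggered
palindromes (e.g. HinfI `G^ANTC`) correctly yield two, one per strand.
Digestion is linear only — amplicons are linear PCR products. The
conservation invariant (fragments sum to the amplicon length) is
property-tested and re-verified on every digest.

The five species' published AluI maps are bundled: Turkestan (251, 455 →
251/204/255), American (167, 251, 392, 612 → 167/84/141/220/98), Oriental
(251, 275 → 251/24/435), German and Brown-banded (seven cuts each, eight
bands summing to 710). Band lists are kept in map order, including
duplicate sizes, consistent with all five profiles.

### The gel model and the diagnostic screen

What a gel reader can resolve is modelled with two parameters:

* `min_visible` (default 100 nt): bands below this size are dropped —
  sub-100 bp bands are not reliably visible on routine agarose gels run
  against a 100 bp ladder. Whether faint sub-100 bp bands should count as
  absent or merely weak is genuinely open; the threshold is therefore a
  parameter, and every test that depends on it fixes it explicitly.
* `comigration_tol` (default 0.04): bands `a ≥ b` co-migrate when
  `a − b ≤ tol · a`. Co-migrating runs are merged greedily down the
  descending size list, each merged band being the rounded mean, re-checked
  against the next band. Greedy order matters only for pathological
  ladders of overlapping near-equal sizes; it is documented and fixed.
  At tolerance 0 the signature is exactly the sorted fragment list
  (duplicates preserved), which gives a clean oracle equivalence for
  testing.

At the 4% default the Turkestan 251/255 pair merges (difference 4 ≤
10.2), while the Brown-banded 132/138 pair remains just resolvable
(6 > 5.52); a tolerance of about 4.5% would merge both. The default keeps
the conventional 4% figure rather than tuning it to force both merges —
at 4% the five species remain fully distinguishable either way.

Two signatures are distinguishable unless they have the same number of
visible bands and every positional pair co-migrates — i.e. the comparison
is done on what the eye reads off the lanes, not on exact fragment
multisets. `screen_enzymes()` applies this across an enzyme library and
ranks enzymes by species pairs distinguished, then by total band count
(simpler gels first), flagging enzymes that separate every pair as fully
diagnostic. On the default panel AluI distinguishes all 10 species pairs
while the bundled negative control EcoRI (no sites in the panel, by
construction) distinguishes none.

## The synthetic panel generator

Reproducing the study's claims offline requires sequences with its exact
statistical structure. `simulate_panel()` builds them by construction
rather than by stochastic search:

1. **Ancestor.** One 710 nt amplicon: the two primer footprints at the
   ends, an interior drawn as a shuffled fixed-count base multiset tuned
   so the whole amplicon hits the target A-T content (65.7% by default) —
   composition is exact, not binomial. Every site window that any species
   will use is pre-seeded with a near-site placeholder (`AGCA`), and all
   accidental recognition sites of the panel enzyme and the control
   enzymes are destroyed by minimal edits.
2. **Divergence.** The target pairwise divergence matrix (defaults: the
   published five-species values, e.g. 22.26% American/Brown-banded,
   11.57% American/Oriental) is converted to difference counts, the known
   planting differences are subtracted, and the remainder is decomposed
   over the 15 bipartitions of the species set by non-negative least
   squares with greedy integer refinement. Each bipartition gets its own
   disjoint set of alignment columns; species on one side of the split
   carry the substituted base. Because every column is used exactly once,
   realized p-distances equal the targets up to integer rounding (about
   0.15 points on 710 bp). Substitutions use the composition-stationary
   swap A↔T / C↔G, never fall inside primer footprints or padded site
   windows, and are re-drawn if they would create a recognition site.
3. **Maps.** Each species' cut map is then planted exactly (one base per
   window changes, already budgeted in step 2) and verified:
   `find_sites()` must return exactly the planted map, and the control
   enzymes must have zero sites.
4. **Variants and templates.** Optional intra-species variants diverge
   from their representative by a configurable percentage (default 2.62%
   for the American label, 0 elsewhere), and every record is wrapped in
   random template flanks so the in-silico PCR stage has real work to do.

All randomness flows from one master seed through per-species streams
derived by stable label hashing, so identical configurations are
byte-identical and adding a species never perturbs the others.

What the generator deliberately does **not** emulate: indels (the
published comparisons are over a gapless shared window), codon-aware or
selection-structured substitution (real COI divergence is mostly
synonymous; here substitutions are placed uniformly, so synthetic
amino-acid identities are far lower than the published ones — a separate
synonymous-only mutator exists to test the "silent substitutions leave the
protein untouched" property), sequencing error, heteroplasmy, and
intra-species map variation. Passing tests on synthetic panels therefore
validate the *operations* — digestion arithmetic, gel logic, tree
algorithms, identity computation — not the biological claim that real
specimens will show these exact profiles; that claim rests on the
deposited sequences, which require network access to re-analyze and are
out of scope here.

## Numerical and design choices

* Percent values in matrices are rounded half-up to 2 decimals; all
  internal arithmetic is unrounded.
* The enzyme screen's ranking tie-break (fewer total bands first, then
  name) is arbitrary but fixed, keeping reports stable across runs.
* `plant_sites()` requires cut spacing of at least the recognition length
  and refuses sites overlapping protected intervals, naming the conflict.
* Degenerate inputs fail loudly with named errors (no amplification,
  ambiguous amplification, undefined identity on zero comparable columns,
  non-ascending cuts, unknown taxa, unbalanced Newick parentheses with
  the offending position).
* The pipeline orchestrator (`run_pipeline()`) is pure composition of the
  exported module functions; the package exposes its stages as ordinary R
  functions rather than a shell entry point, since the natural interface
  for an analysis package is the R session and the functions map
  one-to-one onto pipeline stages (simulate, amplify, distance, tree,
  digest, screen, report).

## Problem sizes used in the test suite

The suite runs entirely on generated data: 710 bp amplicons, five-species
panels, enzyme libraries of ten common cutters, 20-seed round-trip loops
for the plant/digest property, and exhaustive topology searches up to
five taxa (15 topologies). These sizes keep every oracle exact (brute
force enumeration for alignment scores at length ≤ 6, naive substring
scans for digestion, full least-squares topology search) while exercising
the same code paths as full-scale use.

## A worked pass

```{r worked, eval = FALSE}
panel <- simulate_panel(panel_config(seed = 42))
primers <- folmer_primers()
amp <- extract_amplicon(panel$templates$Turkestan_1_template,
                        primers$forward, primers$reverse)
digest(amp, alui())$fragment_lengths      # 251 204 255
visible_bands(digest(amp, alui()))$bands  # 253 204 (251/255 co-migrate)

amps <- lapply(panel$panel, function(r) r[[1]]$residues)
screen_enzymes(amps, default_enzyme_library())[1:3, 1:4]

divg <- divergence_matrix(similarity_matrix(amps))
tree <- root_with_outgroup(neighbor_joining(divg), "Brown-banded")
is_monophyletic(tree, c("American", "Oriental", "Turkestan"))  # TRUE
divergence_time(max(divg))  # ~11.1 MY under the 2%/MY clock
```

## Known limitations

* Thermodynamics are out of scope: no melting temperature, annealing
  kinetics, or multiplex interactions — primer matching is purely
  combinatorial.
* Methylation sensitivity, star activity, partial digestion and combined
  double digests are not modelled; enzymes are applied independently.
* Band intensity is not modelled; the gel model is binary
  visible/invisible with positional comparison.
* GenBank retrieval is intentionally absent; reproducing the published
  numbers from the deposited accessions is documented but not automated.
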