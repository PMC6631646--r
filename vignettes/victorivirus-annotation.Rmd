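---
title: "Annotating bicistronic victorivirus genomes and inferring their translation strategy"
author: "vicscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating bicistronic victorivirus genomes and inferring their translation strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vicscan)
```

## The biological problem

Victoriviruses (family *Totiviridae*) carry a nonsegmented dsRNA genome whose
plus strand is a bicistronic mRNA: a 5' ORF encoding the capsid protein (CP)
and a 3' ORF encoding the RNA-dependent RNA polymerase (RdRp). How the
downstream ORF gets translated differs across the family and is diagnosed
from sequence signals and protein evidence:

* **Stop/restart (termination–reinitiation).** A ribosome terminating the CP
  ORF reinitiates on a nearby start. In the well-characterized cases this is
  facilitated by a tetranucleotide `AUGA` or pentanucleotide `UAAUG` in which
  stop and start codons overlap, acting together with an H-type pseudoknot
  immediately upstream. Two separate proteins result.
* **−1 programmed ribosomal frameshift (−1 PRF).** At a slippery heptamer of
  consensus `X XXY YYZ` (first three bases identical, middle three identical),
  aided by a downstream structure, the ribosome slips one nucleotide backward
  and continues in the new frame, producing a single CP–RdRp fusion protein.
* **Bridge-extended initiation.** Translation of the RdRp frame may begin at
  a noncanonical start upstream of the annotated RdRp AUG, inside the
  inter-ORF "bridge".

`vicscan` packages the desk-scale part of such a genome characterization:
ORF annotation, recoding-signal scanning, heuristic RNA-structure calls,
product modelling with molecular masses, and adjudication between the
strategies from peptide-mass-fingerprint (PMF) evidence. Every stage is
exercised against a synthetic genome generator whose outputs carry exact
ground truth, so the pipeline is fully testable offline.

## Coordinate contract

All interfaces use 1-based, inclusive intervals on the plus strand — the same
convention as printed genome map positions. Conversion to half-open
coordinates happens only inside implementation internals. The frame label of
a position $p$ is $((p-1) \bmod 3) + 1$; an ORF interval includes its stop
codon, so a 2298-nt ORF encodes $2298/3 - 1 = 765$ residues. Only the plus
strand is annotated by default (the victorivirus mRNA *is* the plus strand);
six-frame peptide mapping is available through `build_frame_index(reverse =
TRUE)`.

## The layout model

`find_orfs()` reports maximal AUG-to-stop ORFs: within each run between
consecutive in-frame stops, the ORF starts at the 5'-most AUG. Noncanonical
start codons can be supplied (`start_codons`) because bridge-extended
initiation is one of the hypotheses the tool must express, but they are never
the default. `classify_layout()` picks ORF1 as the 5'-most of the two longest
non-nested ORFs and ORF2 as the longest ORF starting after it, with
deterministic tie-breaks (earlier start, then longer). Everything else —
UTRs, the inter-ORF bridge (or an overlap record when the ORFs overlap), and
the codon-phase offset of ORF2 relative to ORF1 (reported in $\{0, +1, -1\}$
with $+1 \equiv -2$) — follows by arithmetic.

A point worth stating: a junction can be *named* a −1 frameshift site while
the annotated start codons sit at a $+1$ codon-phase offset, because phase
offset between annotated AUGs and the mechanistic shift at the slippery site
are different quantities. The layout reports the arithmetic offset and leaves
mechanistic naming to the adjudicator.

## Recoding signals

* `scan_slippery()` scores every 7-mer in a window by its Hamming distance to
  the consensus class `X XXY YYZ`. No base-class restriction (such as the
  classical Z ≠ G) is imposed by default, since the consensus itself states
  none; `x_bases`/`y_bases`/`z_bases` reinstate stricter patterns. The default
  tolerance of one mismatch is what lets a "slippery-like" site such as
  `CCAAAAU` (one deviation in the first triplet) be reported.
* `scan_facilitators()` finds `AUGA`/`UAAUG` occurrences near the ORF1 stop
  and flags whether the embedded stop triplet lies in ORF1's codon phase.
  The default window, 40 nt upstream to 10 nt downstream of the stop, brackets
  the ~38-nt span shown to suffice for stop/restart in the prototype
  victorivirus. A facilitator is *reported*, not *required*, to overlap the
  reinitiation AUG — absence of facilitators is itself a finding.
* `scan_utr_motifs()` looks for the conserved victorivirus 5'-UTR
  octanucleotide `AGGGUUCC` and its 15-nt extension `AGGGUUCCGUUGAUC`,
  reporting each hit's distance to the ORF1 start codon.
* `find_agp_rich()` slides a window (default 20 aa, threshold 0.6) over a
  protein and merges qualifying windows into maximal Ala/Gly/Pro-rich
  regions — the hallmark of victorivirus CP C-termini.

## RNA structure heuristics

The structure module is deliberately **not** a thermodynamic folder. Stems
are perfect helices under $\{AU, UA, GC, CG, GU, UG\}$ scored 3/2/1
(GC/AU/GU) with no loop penalty by default — a toy stability score chosen
because it is deterministic and checkable against brute-force enumeration.
Maximal helices are those extendable neither outward nor inward; a shifted
sub-register helix whose arms both lie inside a longer helix's arms is
dominated and dropped. `find_stem_loops()` reports hairpins 5'-to-3' (so
tandem hairpins appear in genome order); `find_pseudoknots()` reports stem
pairs in H-type crossing topology (stem 2's 5' arm inside stem 1's loop, its
3' arm beyond stem 1), with a greedy non-overlapping selection by score
flagged as the primary call. Bulges and internal loops are not modelled, and
no free energies are produced; published pseudoknot coordinates from
thermodynamic tools are treated as qualitative reference only. Presence,
position and topology — not energetics — are the intended outputs.

## Product models and masses

`model_products()` always emits the two separate products. Given a slippery
hit it adds a fusion model. The −1 join convention is: the resumption point is
$J = \text{heptamer end} + \text{shift}$ (so $J = \text{end} - 1$ for the
canonical shift of −1); the 0-frame segment is recorded as
$[\text{ORF1 start}, J]$ and reading continues at $J$ in the frame of $J$ —
one nucleotide is decoded twice, as in the physical slippage event. The exact
junction codon of a −1 fusion is ambiguous in general; this convention is
documented and applied uniformly. A fusion whose shifted reading meets an
immediate stop is flagged `terminated_in_bridge`, never silently dropped.
A bridge-extended RdRp model can be anchored at any upstream in-phase start;
`find_bridge_extension_start()` supplies the 5'-most stop-free choice.

Masses are sums of **average** residue masses plus one water (18.02 Da),
because the downstream comparison is to SDS-PAGE band estimates; monoisotopic
masses are available for MS-oriented work. The default band-mass tolerance in
adjudication is ±15%, reflecting the imprecision of gel-based size calls.

## PMF evidence and adjudication

Digestion follows the trypsin rule (cleave after K/R, not before P), with
missed cleavages emitting all concatenations of up to $m+1$ adjacent
fragments. Peptides are matched as exact substrings of stop-agnostic frame
translations in which stops are a sentinel `*` that can never match — a
deliberate choice that prevents biologically impossible placements. Matches
crossing a region boundary are labelled `spanning` rather than fractionally
split, keeping region counts integral.

`adjudicate()` applies ordered rules: (1) peptides from both ORF regions at a
band mass fitting both separate products, with no single-chain model at that
mass spanning both ORFs, imply two co-migrating separate products; (2) a band
at the fusion mass implies the fusion; (3) ORF2-frame bridge peptides plus a
fitting bridge-extended model imply extended initiation; otherwise the verdict
is inconclusive, and the rationale says which rules fired.

## What the synthetic generator emulates — and what it does not

`generate_genome("paper_layout")` emits a 5120-nt genome with a 266-nt 5'UTR,
a 2298-nt CP ORF at [267, 2564], a 322-nt bridge, a 2157-nt RdRp ORF at
[2887, 5043] and a 77-nt 3'UTR; the 15-nt conserved motif at [204, 218], the
slippery-like heptamer `CCAAAAU` at [2555, 2561] immediately upstream of the
`UAG` stop, no stop/restart facilitator, and bridge codons for the tryptic
peptide `TASDLDLYLK` at [2593, 2622] in the RdRp frame (reverse-translated
with seed-determined synonymous codons, since only the peptide is known).
The bridge is built from non-stop, non-AUG codons in ORF2's phase, so the
RdRp-frame reading runs from the junction through the bridge into ORF2 — the
arrangement implied by finding junction-encoded peptides in the RdRp band.
Generation is self-certifying: each candidate is re-annotated and re-scanned,
and random segments are resampled from the seeded RNG until the truth layout
is recovered exactly, the junction window contains exactly the intended
facilitators, and planted motifs and anchors are unique. Background
composition is uniform (GC 0.5, configurable); composition is irrelevant to
the coordinate arithmetic under test.

What it does **not** emulate: real codon usage, UTR secondary structure,
coverage artefacts of sequencing, mass-spectral noise (contamination is
modelled only as random decoy peptides), or the real virus's sequence — so
passing tests demonstrate correctness of the arithmetic, scanning and
decision logic, not recovery of any real genome's masses. Product masses of
the real virus (e.g. an ~80-kDa CP or an ~171-kDa fusion) are reproduced only
if the user supplies the corresponding FASTA; on synthetic genomes the masses
are whatever the sampled codons give.

`simulate_pmf()` draws identifiable peptides (≥ 6 aa) from the digest of each
scenario's true product(s): `separate` mimics two co-migrating proteins in
one band reported at the CP mass; `fusion` digests the frameshift product at
its mass; `bridge_extended` digests an extended RdRp band alone — the CP band
is not the one under digestion, which is what makes the scenario
distinguishable from `separate` under the rule order above.

## Numerical and design choices

* Ties in ORF selection: earlier start wins, then longer — deterministic.
* `min_aa` defaults to 100 for genome-scale annotation; tests lower it.
* Slippery-site selection for the fusion model: the hit whose heptamer end is
  nearest the last pre-stop nucleotide, then fewest mismatches — the junction
  arrangement under study places the functional heptamer against the stop.
* The structure score threshold (`structure_min_score = 12`) corresponds to
  two stems of four average pairs; it gates only the pipeline report, not the
  enumeration functions.
* Degenerate inputs: proteins shorter than the composition window warn and
  return an empty result; a genome with fewer than two qualifying ORFs yields
  a partial report with an explicit error field; an empty peptide match set
  adjudicates to `inconclusive` with a warning.
* Problem sizes used by the test suite: 1,000 random sequences (≤ 600 nt) for
  the ORF oracle, 100 planted pseudoknot fixtures, 200 simulated PMF datasets
  per scenario, chosen to make the property suites statistically meaningful
  while completing in minutes on one CPU.

## Worked example

```{r example, eval = FALSE}
g <- generate_genome("paper_layout", seed = 42)
layout <- classify_layout(g$record)
layout

sim <- simulate_pmf(g$record, g$truth, "separate", n_peptides = 30, seed = 7)
report <- run_pipeline(g$record, peptides = sim$peptides,
                       band_mass_da = sim$band_mass_da)
report$verdict
```

## Known limitations

* Perfect helices only; no bulges, internal loops or coaxial stacking, and
  no free-energy model — structure calls are screening heuristics.
* Exact peptide string matching only; no mass-tolerance spectral matching,
  PTMs or FDR control.
* No IRES prediction and no alignment-based conservation scoring across
  victoriviruses; the UTR motif scan is exact-match.
* The adjudicator reasons over one band at a time; multi-band gels are run
  as separate calls.
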