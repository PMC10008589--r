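---
title: "Designing and quantifying ADAR-activatable RNA sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and quantifying ADAR-activatable RNA sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dartvadar)
```

## The sensing model

An ADAR-activatable sensor couples the detection of an RNA (the *trigger*)
to translation of a payload. The sensor region of the circuit transcript is
the reverse complement of a window of the trigger, except for one designed
substitution that creates a central, in-frame UAG stop codon. When sensor
and trigger hybridize, the UAG's adenosine sits in an A:C mismatch opposite
the central C of a `CCA` triplet on the trigger — the substrate
configuration ADAR deaminates efficiently, with the additional benefit that
the sensor A's 5' neighbor is a U, ADAR's preferred nearest neighbor.
Deamination produces inosine, decoded as G, so the amber codon becomes UGG
(tryptophan) and ribosomes read through into the payload. Requiring the
`CCA` motif on the target is therefore the entire substrate model used here;
no further nearest-neighbor or thermodynamic scoring is applied (a no-op
plugin point is left in the ranker for structure-aware scores).

In the autocatalytic *closed-loop* layout the payload region also encodes a
compact editor — MCP fused to the hyperactive ADAR2 deaminase domain
(E488Q) with a nuclear export signal — recruited to the edit site via MS2
stem-loops flanking the sensor UAG. Edited sensors thus produce the enzyme
that edits further sensors. The package assembles this layout alongside its
controls: the open-loop pair (sensor without enzyme + enzyme in trans), the
basic no-enzyme sensor, and the stop-less backbone in which the UAG is
pre-converted to UGG (the maximum-expression reference).

## Coordinate and alphabet conventions

Sequences are stored as DNA (U normalized to T on input) because assembled
constructs are plasmid-level DNA objects; RNA rendering is available on
output. Internally all intervals are 0-based half-open; every user-facing
position is 1-based and, when a CDS is annotated, anchored at the start
codon (the A of AUG is +1, the base before it is −1; there is no 0). Site
names like `CCA60` use the anchored position of the **first C** of the
motif. The numbering base within the motif is a genuine convention choice —
field usage is not uniform — so `scan_cca(number_from =)` can switch to the
central C or the A; the default is the first C, and the chosen convention is
recorded in the output table alongside the raw 0-based offset, which is
unambiguous.

## Site classification and ranking

Translating ribosomes unwind sensor:trigger duplexes, so ribosome-free
contexts make better targets. Sites are classified by the annotated region
containing the motif start and ranked:

1. `cds_secreted` — CDS of a signal-peptide-bearing product (ribosomes stall
   early on ER-targeted messages);
2. `three_prime_utr`;
3. `five_prime_utr`;
4. `cds_translated`;
5. `noncoding` (unannotated).

Secreted-CDS above 3'UTR reflects the observed ordering of activation
levels; the policy vector is an argument, so either preference can be
swapped without code changes. Ties break by ascending transcript position,
making the ranking a total order independent of input order.
Nuclear-localized transcripts are refused outright (empty ranking plus an
advisory) rather than down-weighted: sensors against nuclear RNAs fail
because the editing machinery used here acts in the cytoplasm, and a soft
penalty would invite designs that cannot work.

## Sensor design rules

* **Window length** `L` must satisfy `L ≡ 3 (mod 6)` so `(L−3)/2` is a
  multiple of 3 and the central triplet lands on a codon boundary of the
  insert's frame 0. Defaults: 75 nt (UAG at insert codon 13), short preset
  51 nt. Longer windows pair more stably but encode longer foreign peptides.
* **Single designed mismatch.** The sensor is the exact reverse complement
  of the window except G→A opposite the central C. Reverting every designed
  substitution must reproduce `revcomp(window)` exactly; this is enforced by
  a property test and by `validate_design()`.
* **Residual stops reject the site.** If frame 0 of the sensor contains any
  stop beyond the designed UAG(s), the design is *rejected* (with the
  reason), not recoded: recoding would break complementarity to the target,
  which is the one thing a sensor cannot sacrifice. Callers then move to the
  next-ranked site. The UAG stays exactly central; ±1-codon shifts to dodge
  residual stops were considered and not implemented, because off-center
  placement changes the mismatch's flanking duplex symmetrically claimed by
  the design and would need its own validation — rejection keeps the rule
  auditable.
* **allstop mode** converts every additional window `CCA` whose opposing
  sensor triplet falls on a frame-0 codon boundary from TGG to UAG
  (multiple editable stops); out-of-frame `CCA`s are left as perfect TGG
  pairs and reported, since converting them would place the stop out of
  frame.
* **SNV discrimination.** For a variant whose ALT allele creates a `CCA`
  with the variant base as its central C (wild-type context C-T-A), the
  centered sensor is fully complementary to the wild type — the A:U pair
  protects the adenosine from ADAR — while pairing with the mutant forms
  exactly one A:C mismatch at the editable position. Both properties are
  verified against both alleles before the design is returned. The
  imperfect hybridization is modelled as an A:C mismatch rather than an
  unpaired bulge; at single-base scale the two descriptions coincide for
  design purposes (same sequences), and the mismatch view matches the ADAR
  substrate preference that motivates the motif.
* Windows containing N are rejected (pairing cannot be guaranteed).

## Construct assembly

Coding components are all multiples of 3 and internally stop-free, so
junctions fall on codon boundaries; the assembler still validates the whole
ORF (frame, exactly one terminal stop, internal stop count equal to the
designed UAG count) because hairpin insertion can split sensor codons.

MS2 hairpin blocks are the 19-nt wild-type stem-loop padded with AAC-repeat
linker bases to a multiple of 3, inserted in configuration `C` (one block on
each side of the UAG), `L` or `R` (both blocks 5' or 3' of it). Spacers
count nucleotides between the UAG codon and the nearest block edge; the
default (9, 9) places blocks on codon boundaries of the default design and
is an explicit, arbitrary default — the optimal spacing is an empirical
question the configuration knobs exist to explore. If a block would create
an in-frame stop it is auto-shifted by prepending up to three neutral bases
(the bundled hairpin needs one such shim); assembly fails loudly if no
stop-free padding exists within three shifts. The hairpin blocks are
translated in-frame as part of the sensor peptide — they are not skipped —
and their positions are recorded in the layout.

The size budget counts every component, promoter and terminator included,
against a 5000-nt packaging capacity (the practical AAV limit). With the
bundled fixtures the closed loop totals 4142 nt (82.8% of capacity) and the
full-length ADAR1 p150 CDS alone takes 73.6% — the size argument for using
the minimal deaminase domain.

Bundled fixture sequences: P2A (66 nt) and the MS2 stem-loop (19 nt) are the
published sequences; all other parts are seed-deterministic synthetic CDSs
generated at the real components' lengths and labelled `synthetic=true`.
They have correct structure (start codon, no internal stops, length) but not
the real sequences, so GenBank outputs built from them are structural
templates, not clonable plasmids; `load_components()` accepts a user FASTA
of real parts.

## Editing quantification

The editing fraction at a reference-A position is `G/(A+G)` over piled-up
read bases. The denominator is deliberately not total depth: sequencing
errors to C or T then cannot deflate the estimate. Fractions are reported
only where `A+G ≥ min_depth` (default 100). Base qualities are ignored by
default. SAM alignments go through Rsamtools; raw amplicon FASTQ reads are
placed by an ungapped minimum-mismatch scan over all offsets (amplicons are
fixed constructs; indel-containing reads belong in the SAM path), with a
mismatch ceiling (default 20% of read length) discarding unmappable reads.

Fold change is the ratio of geometric means of reporter intensity with and
without trigger, with a percentile bootstrap 95% CI under an explicit seed
(the CI method is a package choice; an analytic log-scale interval would be
equally defensible). Cells are binned by transfection-marker intensity at
half-log10 intervals anchored at 1. Closed- vs open-loop comparisons report
`log10(FC_CL/FC_OL)` and `log10(OFF_CL/OFF_OL)`.

## What the simulator emulates — and what it does not

`make_trigger()` plants `CCA` motifs at exact anchored positions on a
random background (5'UTR/CDS/3'UTR, clean ORF) and additionally scrubs, in
the 75-nt design window around each planted site, target triplets whose
reverse complement would be a residual in-frame sensor stop. Planted sites
are therefore designable by construction, which is what the workflow tests
need; *real* transcripts offer no such guarantee, and on random sequence a
meaningful fraction of `CCA` sites is rejected for residual stops — that is
the expected behavior, handled by ranking and iteration, not a defect.

`simulate_reads()` applies independent per-position A→G conversion at
planted probabilities with optional uniform substitution error (default 0 so
recovery oracles are exact binomial draws). `simulate_cells()` draws
log-normal intensities per population — the natural model when the readout
is a geometric mean — with planted fold change
`exp(mean_log_on − mean_log_off)`. Defaults follow the measurement
conventions of the field's sensor experiments: 2000 cells per arm (the
minimum used for fold-change estimates), read depth 5000, and editing
regimes of 0.30 and 0.03 corresponding to editing with and without enzyme
supplementation. None of this emulates realistic Illumina error profiles,
alignment ambiguity, cytometry spillover, or the kinetics of the feedback
loop; passing recovery tests shows the estimators are correct on their
stated model, not that the biology will reproduce the simulated numbers.

## Problem sizes and numerical choices

The test suite runs 1000 random 500-mers against a brute-force scanner
oracle, 100 seeded read-simulation runs at depth 5000 on a 120-nt amplicon
(recovery within 3 binomial SE expected in ≥99/100), and 40 seeded
cytometry simulations at 2000 cells/arm with 500 bootstrap replicates
(planted 9-fold change covered by the CI in ≥90%); these sizes make the
statistical checks sharp while keeping a full run in the low minutes on one
CPU. Determinism: every generator takes a seed and regenerates byte-identical
output; designs and assemblies are pure functions of their inputs.

## Known limitations

* No secondary-structure or accessibility scoring of target sites.
* No transcriptome-wide off-target complementarity search.
* Genome-space (spliced) coordinates are out of scope; all annotation is in
  transcript space.
* Ambiguity codes beyond N are not supported.
* Sensor peptides are reported but not scored for immunogenicity; the
  foreign peptide encoded by a sensor is target-dependent and is a real
  design consideration the package surfaces only as the translated sequence.
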