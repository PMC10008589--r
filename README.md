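# dartvadar

Design and quantification toolkit for ADAR-activatable RNA sensors —
single-transcript circuits in which hybridization with a trigger RNA licenses
A-to-I editing of a premature amber codon, switching on translation of a
downstream payload.

## The problem and the core transform

Adenosine deaminases acting on RNA (ADARs) efficiently deaminate adenosines
sitting in A:C mismatches within double-stranded RNA. An RNA sensor exploits
this: the sensor region is the reverse complement of a window of the target
transcript centered on a `CCA` triplet, with a single designed substitution —
the base opposite the central C is changed G→A, creating a central in-frame
`UAG` stop codon whose A is mismatched A:C against the target (and flanked 5'
by U, the neighbor ADAR prefers). Only when sensor and trigger hybridize is
that adenosine presented for editing:

```
target  5'-… N N N  C C A  N N N …-3'
sensor  3'-… N N N  G A U  N N N …-5'   (sensor reads 5'-…UAG…-3': amber stop)
                      ^ A:C mismatch, edited A→I; UAG → UIG ≡ UGG (Trp)
```

Editing converts the amber codon to tryptophan, so ribosomes read through
into the payload. In the autocatalytic (closed-loop) layout the payload
includes a compact editing enzyme — the MS2 coat protein fused to the
hyperactive ADAR2 deaminase domain (MCP-ADAR2DD(E488Q)-NES) — recruited back
to the edit site by MS2 stem-loops flanking the sensor UAG, forming a
positive feedback loop with low background and a genetic footprint small
enough for AAV delivery (< 5 kb including promoter and terminator).

The package covers the full dry-lab workflow:

| module | what it does |
| --- | --- |
| sequence core | FASTA/GFF3/TSV I/O, reverse complement, translation, start-codon-anchored coordinates (`codon_index(658) == 220`) |
| site finder | enumerate `CCA` sites, classify context (secreted CDS / 3'UTR / 5'UTR / translated CDS), rank ribosome-free contexts first, refuse nuclear targets |
| sensor designer | centered 75-nt (or 51-nt) windows with the central UAG; `allstop` multi-UAG variant; single-nucleotide-variant discrimination sensors; validation reports |
| construct assembler | closed-loop / open-loop / basic / stop-less topologies, MS2 hairpin placement (L/R/C with spacers), frame and junction checks, 5-kb size budget, GenBank output |
| editing quantification | per-position A/C/G/T pileups from SAM or FASTQ amplicon reads, editing fraction G/(A+G), logo matrices, half-log transfection binning, geometric-mean fold change with bootstrap CI, closed-vs-open-loop ratios |
| simulator | seed-deterministic triggers with planted designable CCA sites, amplicon reads with planted editing rates, log-normal cytometry tables |

Bundled component sequences: the 66-nt P2A and the 19-nt wild-type MS2
stem-loop are the published sequences; the remaining parts (promoter, TagBFP,
mNeonGreen, MCP, ADAR2 deaminase domain, NES, terminator, ADAR1 p150 CDS) are
synthetic stand-ins generated at the real components' lengths and flagged
`synthetic=true` in `inst/extdata/components_synthetic.fa`. Override them
with your own FASTA via `load_components(path)`.

## Worked example

```r
library(dartvadar)

spec    <- sim_spec(seed = 7, planted_cca = c(60, 150))
trigger <- make_trigger(spec)                  # 500-nt annotated trigger
sites   <- rank_sites(scan_cca(trigger), trigger)
as.data.frame(sites)
#>   transcript_id motif_start anchored_pos   name        context rank_score
#> 1 trigger_seed7         119           60  CCA60 cds_translated          1
#> 2 trigger_seed7         209          150 CCA150 cds_translated          2

design <- design_sensor(trigger, sites[1, ])   # default 75-nt window
design
#> <dv_sensor_design> trigger_seed7 site CCA60, 75 nt, mode single_stop, accepted
#>  sensor:  GGACGCCCTGCTGCGTCAGATAACGAGTCTATGTCATAGTTTGCACATCTAAGAGATTCAGATCGTAGGAAACGA
#>  peptide: GRPAASDNESMS*FAHLRDSDRRKR

layout <- assemble(design, "closed_loop")
layout
#> <dv_layout> closed_loop: 4142 nt, 10 components, 1 internal TAG
unlist(size_budget(layout))
#>             total_nt fraction_of_capacity        within_budget
#>            4142.0000               0.8284               1.0000
```

The site is named `CCA60` because the first C of the motif sits at position
60 counting the A of the start codon as +1. The sensor peptide carries
exactly one stop (`*`, the designed amber at codon 13 of the insert);
`simulate_edit(design)` flips it to Trp and restores the perfect reverse
complement of the target window. The assembled closed loop holds four coding
components insulated by P2A peptides, two MS2 hairpins flanking the UAG, and
fits the 5-kb packaging budget at 82.8%.

A shell interface wraps the same functions
(`exec/dartvadar scan|design|assemble|quantify|fc|simulate`); each run writes
a `.config.json` sidecar recording the effective parameters.

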