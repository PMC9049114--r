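---
title: "Methods: junction markers, collinearity anchoring and coloured k-mer painting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction markers, collinearity anchoring and coloured k-mer painting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triticolor)
```

# Scope

`triticolor` implements the bespoke computational stages used to compare
chromosome-scale assemblies of a polyploid crop panel: design of ISBP
(insertion site-based polymorphism) junction markers from
transposable-element annotations, collinearity-guided anchoring of
scaffolds into pseudomolecules, haplotype-block painting of a cultivar
panel with a coloured canonical k-mer index, introgression detection from
minority haplotype profiles corroborated by donor-read coverage, and
assembly QC statistics. A synthetic panel generator with machine-readable
truth tables makes every stage testable without any external download.

# ISBP junction markers

In a genome that is ~85 % transposable elements, genes are a poor source
of unique anchors: homoeologous copies are ~97 % identical and gene
density is low. The junctions between a TE body and its insertion site
are the opposite case — the body is multi-copy but the exact
body/flank boundary exists once. `design_isbp()` emits a 150-bp tag per
junction (75 bp on each side of the element start and end), dropping tags
that would overlap a chromosome end or contain `N`. `filter_unique()`
retains tags with exactly one passing placement in their source genome.

Mapping (`map_markers()`) is a seed-and-extend search: exact
`seed_len`-mer seeds (default 21) at every query offset locate candidate
loci on both strands; each candidate is verified by a banded global
alignment of the full query (band half-width 15). Identity is computed
over alignment columns; since the source never defines its identity
denominator for these short fixed-length queries, we use the common
convention `1 - edits/query_length`, which coincides with the
matches-over-columns definition for substitution-only differences.
Threshold presets mirror the pipeline stages: 80/90
(identity/coverage, anchoring), 90/90 (marker conservation), 95/95
(exon conservation) and a strict dot-plot preset (at most 2 mismatches at
full coverage). A best hit is flagged non-unique when a second passing
locus lies within `min_second_best_gap` (default 5) edits — the source
says only "uniquely mappable", so the tie window is declared, making
uniqueness deterministic.

A detection guarantee exists only when at least one exact seed survives:
a query diverged so heavily that every seed window is hit can be missed,
as with any seed-and-extend mapper. At the divergence this pipeline
operates on (0.7–3 % between cultivars) intact seeds are effectively
certain for 150-bp tags.

# Anchoring by marker-pair collinearity

Scaffolds are placed on chromosomes using reference-mapped ISBP markers
considered *in consecutive pairs* along each scaffold: a pair is valid
when its two hits are separated by less than 50 kb on both the scaffold
and the reference and the two source junctions share a reference
chromosome. Pairing is the noise filter — an isolated mis-mapped marker
cannot form a valid pair with either neighbour, so it contributes
nothing (the robustness test injects 10 % mis-mapped single hits and
verifies that no assignment changes).

A scaffold is assigned to the chromosome holding the most valid pairs,
provided that chromosome carries at least 50 % of them *and* strictly
beats every other chromosome; an exact 50/50 split is ambiguous and goes
to `chrUn`. Ordering uses the median reference midpoint of the assigned
pairs; orientation is the majority pair orientation, derived from marker
*order* rather than marker strand (individual hits can flip; order is
robust). Declared tie rules, none of which the source states: orientation
ties keep the assembly orientation (`+`, logged in the votes columns);
identical medians order the longer scaffold first, then lexicographic id.
Pseudomolecules are rebuilt with fixed 100-N joins, written as AGP v2.1
`U` gap rows (`scaffold`/`yes`/`map`) — the 100 N is a placeholder, not a
measured gap, which is why the unknown-size component type is retained.
`snap_break_to_gap()` retains the one algorithmic fragment of contact-map
curation that is in scope: a proposed break on a chimeric scaffold is
recalculated to the internal gap whose midpoint is nearest (equidistant
gaps resolve to the lower coordinate).

# Coloured k-mer haplotype painting

A coloured de Bruijn graph is queried in this analysis only for one
relation: which cultivars contain which k-mers. `build_colored_index()`
therefore stores a sorted table of canonical 31-mers (lexicographic min
of forward and reverse complement) with one presence bit per cultivar —
identical query semantics, no graph topology. Canonicality makes
painting invariant to each assembly's strand choices, so planted
inversions do not disturb profiles.

Painting extracts 1-kb markers every 20 kb (grid anchored at offset 0;
the source says only "evenly spaced") from each cultivar and asks, per
cultivar, what fraction of the marker's 970 valid 31-mers the index
contains for that colour. A cultivar is called *present* when the ratio
reaches `e = 0.95` (inclusive; the flag semantics of the original
tooling do not state inclusivity). The threshold arithmetic is what the
tests pin down: `ceiling(0.95 * 970) = 922`, so one substitution
(31 lost k-mers, 939 remain) keeps a marker present while two
substitutions at least 31 bp apart (62 lost, 908 remain) drop it. That
knife edge is what separates same-founder sequence (identical) from
different founders at 0.7 % divergence (~14 substitutions per kb).

Per chromosome, the 15 most abundant presence/absence profiles form the
palette (ties at the cut go to the smaller bit-vector value). Per-marker
20-kb blocks are merged into 1-Mb superblocks by modal profile (ties take
the leftmost member's profile; a trailing partial tile uses its available
members). Merging operates on raw profiles and classification happens
afterwards; whether the original study merged classes or profiles is not
stated. Display classes follow a declared precedence: popcount 1 is
*black* (cultivar-specific), popcount ≥ 10 is *grey*, then palette
membership gives a colour, everything else (including all-N windows) is
*white*. Grey/black take precedence over the palette because they are
described as separate categories from the coloured haplotypes.

Locus mode (`locus_haplotypes()`) first localizes a region of interest in
every panel genome by mapping 1-kb probes with the marker engine,
clustering the implied region origins (10-kb tolerance) and taking the
modal cluster and majority strand; cultivars where fewer than half the
probes localize consistently are reported "not localized". The localized
regions are then painted on the finer grid (1-kb markers every 5 kb,
`e = 0.97`).

# Introgression detection

Donor-read alignments are filtered to proper pairs with mapping quality
at least 10 and binned into fixed windows (1 Mb at genome scale); each
read contributes its overlap bases to every bin it intersects, so
total contributed bases are conserved exactly. Candidate introgressions
are maximal runs of at least `min_run = 5` consecutive blocks whose
profile is shared by at most `max_share = 5` cultivars; when donor
coverage is available a run is called only if its mean depth reaches
`cov_factor = 5` times the chromosome-median donor depth, otherwise runs
are emitted flagged as lacking coverage evidence (candidate status). The
run-length and coverage thresholds are this package's explicit tunables:
the original analysis delimited introgressions visually on the plotted
tracks, and a reusable implementation needs a stated rule. Background
donor coverage is expected to be non-zero (related subgenomes), which is
why the gate is relative to the chromosome median rather than zero.

# QC statistics

`assembly_stats()` implements the Nxx/NGxx family by the cumulative-walk
definition (NG statistics against an assumed genome size, 15 Gb for
hexaploid wheat; `NA` when the assembly never reaches the quantile), with
contigs obtained by splitting at `N` (`split_at_n()`).
`exon_conservation()` re-uses the marker search engine at 95/95 with
variable query length — one alignment engine validated once against the
brute-force oracle serves all conservation reports.
`find_telomere_arrays()` scans a 10-kb window at each chromosome end for
tandem arrays of `TTTAGGG` (both orientations at both ends; reverse
complement `CCCTAAA` expected at the 3' end), tolerating one mismatch per
copy because natural arrays are imperfect — the source states only the
motif. `kmer_qv()` re-implements the published k-mer survey formula
(`1 - (1 - E)^k = b/t`, `QV = -10 log10 E`) rather than deriving a new
estimator; the QC default is k = 21 (the original survey used 31-mers;
k is a parameter and the acceptance checks run at 21).

# The synthetic panel generator

`panel_config()` defaults *are* the study conditions at desk scale: 11
cultivars composed as mosaics of 6 founder haplotypes (exponential
segments, mean 200 kb) over 2-Mb chromosomes; founders diverge from a
common base at 0.7 % per base — the figure reported for exon-level
divergence between cultivars — and donor segments diverge at 3 %.
TE structure is emulated by a library of 20 motifs (500–5,000 bp)
replicated with 1 % internal divergence at 50 % genome density: bodies
multi-map, junctions stay unique, which is exactly the property ISBP
design needs. Scaffold inputs come from cutting a chromosome at random
breakpoints, shuffling, and flipping each piece with probability 0.5.
Donor-read tracks place reads at `depth/read_len` per base (Poisson)
inside and outside planted spans with configurable low-MAPQ and
improper-pair fractions.

Divergence is substitution-only so that marker and k-mer arithmetic has
closed-form expectations (indels enter only through explicit
configuration); truth tables tile chromosomes exactly and record every
planted feature. What the generator does **not** emulate: indel and
structural polymorphism between founders, sequencing error in the
assemblies, nested/fragmented TE copies, homoeologous subgenomes
(chromosomes are treated independently, as the chromosome-by-chromosome
analysis does), and real linkage disequilibrium between segments.
Passing tests therefore demonstrate algorithmic correctness under the
stated statistical structure, not performance on raw field data.

# Validation scenarios and problem sizes

The `scenario_*()` functions are the package's reproducible experiments
(the test suite and `scripts/acceptance.R` run them):

* `scenario_anchoring()` — 2-Mb chromosome, 40 scaffolds (each at least
  30 kb, guaranteeing ≥ 3 valid pairs), no rearrangement: assignment,
  order and orientation must all be exactly correct.
* `scenario_painting()` — 11 cultivars, 6 founders, 2 Mb, e = 0.95,
  k = 31, two planted cultivar-specific donor segments (6 and 7 bins):
  at least 95 % of 1-Mb superblocks must carry the planted sharing
  profile and at least 90 % of the planted bins must classify black.
  Superblock recovery is sensitive to genuine modal ties — a tile whose
  mosaic composition splits e.g. 7/7/7 across three profiles can flip
  winner on a single bin-level error; this is a property of the modal
  statistic, not of the index.
* `scenario_introgression()` — 4-Mb chromosome, uniform panel
  background, donor segments of 10/20/30 bins on a 20-kb grid plus
  isolated single-bin minority noise, donor reads at 100x background:
  recall 3/3, precision 1, boundaries within one bin at the default
  thresholds. The 20-kb bin grid (matching the block grid) stands in for
  the 1-Mb genome-scale windows; the grid length is a config field and
  the planted segments keep the same bin counts as the full-scale
  analysis.
* `scenario_qc()` — planted 6 % marker-locus deletions (94 % conserved),
  3.8 % exon-locus deletions (96.2 % conserved; exons are sampled
  outside repeat bodies so a deleted locus cannot be rescued by a
  paralogous copy), a 0.7 %-divergent target for the perfect-match
  fraction (expected `(1 - 0.007)^150 ≈ 0.349`), and QV 30 from a
  1e-3-per-base mutated 500-kb assembly.

These sizes run in well under a minute each on one CPU; they were chosen
so the coloured index stays in the tens of millions of k-mers and the
whole validation completes in minutes.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally and in BED; AGP and GFF3
  converters are the only places ±1 arithmetic occurs.
* Ambiguity codes other than `N` are rejected on read, keeping the k-mer
  space 2-bit codable.
* `split_at_n()` splits at N-runs of at least `min_gap_len` (default 1,
  where every `N` is a breakpoint and output intervals are exactly the
  maximal N-free runs).
* Presence comparison uses `>=` e; empty profiles (all-N windows)
  classify white; zero valid pairs give `chrUn`, not an error.
* The coloured index lives in memory behind an external pointer and is
  rebuilt rather than serialized; at these problem sizes a rebuild is
  seconds.
* A coverage gate with an all-zero median accepts only runs with
  strictly positive donor depth, so zero-coverage minority runs never
  pass on a technicality.

# Known limitations

Seed-and-extend detection requires one intact seed (above); the banded
alignment assumes collinear queries within ±15 bp of diagonal drift, so
large internal indels in a 150-bp tag would be missed; painting profiles
are per-chromosome and do not model homoeologous cross-talk;
introgression calls inherit the bin grid's resolution (boundaries are
bin-aligned); and the generator's substitution-only divergence means
indel robustness is asserted by design review, not by planted truth.
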