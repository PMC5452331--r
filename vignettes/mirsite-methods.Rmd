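---
title: "mirsite: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirsite: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsite)
```

This vignette is the package's account of its science: the duplex
energy model, the conventions every stage relies on, the design of the
synthetic-data generator, and the limits of what the package (and its
passing tests) can claim about real data.

## The duplex model

A microRNA of length L binds an mRNA site of the same length
antiparallel: miRNA position $i$ pairs site position $L-i+1$. We score
a candidate duplex by counting hydrogen bonds per pair class — G:C = 3,
A:U = 2, G:U wobble = 1, A:C = 0 by default — and convert the total $B$
to a free energy $\Delta G = -e \cdot B$ with a fixed per-bond constant
$e$. The package's default $e = 121/57 \approx 2.1228$ kJ/mol is
calibrated so that the perfect duplex of the bundled 22-nt miR-619-5p
query (13 G:C and 9 A:U pairs, 57 bonds) scores $\Delta G = -121$
kJ/mol, the canonical energy of its complete complementary site.

The acceptance statistic is the ratio
$$\frac{\Delta G}{\Delta G_m}\,(\%) = 100\cdot\frac{B(\text{site})}{B(\text{perfect complement})},$$
where $\Delta G_m$ is the energy against the miRNA's exact reverse
complement. Because the ratio is a quotient of bond counts, it is
invariant under rescaling $e$: the complete-complementarity criterion
(ratio = 100 %) holds for any calibration, and equals 100 exactly when
the site is the reverse complement of the query, provided the wobble
weight is strictly below the A:U weight. This makes the headline
criterion robust to the one parameter that cannot be derived from
counting.

Assumptions worth stating plainly:

* **Contiguous 22-mers only.** No gaps or bulges are modelled; the
  analysis targets complete-complementarity sites, where gapped
  hybridization never arises.
* **Whole-duplex counting, not nearest-neighbour thermodynamics.** The
  model deliberately avoids Turner-rule stacking energies and
  RNAfold/RNAhybrid-style structure prediction; its purpose is the
  complementarity ratio, not absolute folding energies.
* **Noncanonical pairs are configurable.** Whether A:C pairs contribute
  is debatable in the literature; the default is 0 bonds, adjustable
  via `energy_scheme(ac = ...)` or a YAML override. At the 100 %
  threshold the choice is irrelevant.

## Scanning and localization conventions

* Coordinates are **1-based, inclusive, on the mRNA 5'→3'** everywhere;
  the BED export converts to 0-based half-open and says so in a header
  comment.
* The canonical internal alphabet is RNA; DNA-written input is
  converted on read, and any letter outside `{A,C,G,U,T}` collapses to
  `N`, which never pairs.
* At threshold 100 the scan is provably identical to an exact substring
  search for the reverse complement; the test suite checks this against
  a naive search oracle. Below 100 the scan reports every window whose
  ratio clears the threshold (with a $10^{-9}$ tolerance so that exact
  percentages are never lost to floating-point).
* A hit is assigned to the region (5'UTR/CDS/3'UTR) containing its
  **start** position, with an explicit `boundary_flag` when the end
  falls in a different region. Junction-spanning sites are rare and
  ambiguous by nature; a deterministic rule plus a flag beats a silent
  choice.
* Overlapping hits are all reported. At 100 % complementarity overlaps
  of a non-periodic 22-mer cannot occur anyway.

## Reading frames and oligopeptide context

Frames are indexed 0/1/2 relative to the site's first nucleotide: frame
$f$ places codon boundaries at site positions $f+1, f+4, \dots$. Edge
codons are completed with real transcript nucleotides, never padding —
the tryptophan at the start of the WLMPVIP product requires the
nucleotide immediately upstream of the site, so context-aware
translation is mandatory. The frame whose codon grid coincides with the
transcript's CDS grid is the `annotated_frame`, computed as
$(\text{cds\_start} - \text{site\_start}) \bmod 3$. Stop codons are
emitted as `*` and never truncate the translation: the biological claim
of interest is the *presence* of a stop in one frame (the perfect site
reads `...UAA...` in frame 0), which truncation would erase. Only the
standard genetic code is supported.

For the printed-style context (`peptide_context()`), the core spans
from the first codon containing at least two site nucleotides through
the last codon lying entirely inside the site, with 7 flanking residues
on each side by default (truncated, never padded, at CDS ends). The
published tables are not perfectly self-consistent at the site edges —
the same edge codon is bolded on the left but not on the right — so the
package fixes one convention and documents it; it reproduces every
printed 7-residue core (WLMPVIP, AHACNPS and their ortholog variants).

## Conservation analysis

Ortholog fragments are **anchor-aligned**: each member's best-scoring
window (leftmost on ties) is placed at site columns 1..22, flanks
hanging at columns ≤ 0 and ≥ 23. No gapped multiple alignment is
attempted — the fragments this analysis consumes are gap-free, and an
anchor plus fixed flank columns is exact for them. The anchor threshold
defaults to 80 %: far above what random 22-mers reach (roughly 50–60 %
of the maximal bond count in uniform sequence), and comfortably below
the 94–96 % of the 1–2-substitution variants seen in real ortholog
families, which must anchor.

`substitution_profile()` tallies per-column mismatches of each member
against a declared reference, split into in-site and flank columns;
mismatch is symmetric, so swapping the reference between two members
leaves each pairwise mismatch set unchanged. `frequency_matrix()` pools
per-column base counts over a gene group; the consensus is the
column-wise argmax with ties rendered as IUPAC ambiguity letters, and
`N` counts toward coverage but never toward the consensus. For grouped
(Table-7-style) output, genes are sorted lexicographically and split
into four near-equal groups by default; the group count is a
convention, chosen here explicitly because published groupings of this
kind rarely state their boundaries.

One published ambiguity deserves note: the position columns printed
alongside ortholog fragments sometimes disagree with the flank widths
shown (a "position 1" next to a 7-nt upstream flank). The package
therefore verifies site placement *within* fragments — where the bold
offset is unambiguous — and treats full-mRNA positions as annotation it
stores but does not assert.

## The synthetic-data generator

The generator exists so that every stage can be validated against a
manifest that is the complete ground truth.

* **Background** is i.i.d. uniform over `{A,C,G,U}`. Plants (perfect
  sites or variants with substitutions at chosen site positions) are
  written at exact positions, constrained to lie inside one region and
  not overlap.
* **Accidental-site scrubbing:** after planting, any background
  occurrence of the perfect site is re-randomized away (never touching
  a planted interval). This is a deliberate departure from pure i.i.d.
  sampling — an accidental perfect 22-mer has probability about
  $4^{-22}$ per window, but "the manifest is exactly the truth" is a
  property worth guaranteeing rather than expecting.
* **Cohort defaults are the study conditions.** Site regions are drawn
  with weights 214 : 3 : 4 (3'UTR : CDS : 5'UTR), the empirical region
  proportions of the complete-complementarity target set this analysis
  characterizes; transcripts default to a 150-nt 5'UTR, 999-nt CDS and
  1500-nt 3'UTR — a typical mRNA shape consistent with the kilobase-
  scale site positions in published target tables.
* **Families** start from a reference fragment (perfect site, 10-nt
  flanks) and mutate each member per-position i.i.d. at rate `s_site`
  in the site and `f_flank` in the flanks, a substitution always
  changing the base. The defaults `f_flank = 0.1`, `s_site = 0.01`
  emulate the published families' pattern of visibly variable flanks
  around a nearly invariant site. Recovery of both rates within three
  binomial standard errors is part of the acceptance suite.
* All generators take an integer seed and are byte-deterministic given
  it; cohort members receive seeds derived from the master seed.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: realistic base composition or codon usage,
dinucleotide structure (real 3'UTR sites of this kind live in Alu-
derived repeats), phylogenetically correlated substitutions (members
mutate independently of a star-shaped reference), indels, and splice
variation.

## Numerical and degenerate-input choices

* Window ties in anchor alignment break to the leftmost window.
* Threshold comparisons use a $10^{-9}$ absolute tolerance on the
  percentage scale.
* A transcript shorter than the query yields an empty hit table with a
  warning, not an error; an empty hit table summarizes to all-zero
  tallies.
* Fragments that cannot anchor (best ratio below threshold) are
  excluded from a family with a message; a family in which no member
  anchors is an error.
* A CDS "complete" flag controls whether the length-divisible-by-3
  invariant is enforced; pipeline input relaxes it so UTR-truncated
  records remain usable for scanning.

## Problem sizes in the test and acceptance suites

The property suites run at reduced sizes chosen to exercise every code
path while keeping the default test run fast: 1,000 random generator
configurations with transcripts of roughly 200–500 nt and up to three
plants, 200 random sequences for the scan-vs-naive-search equivalence,
and three 20-member simulated families for rate recovery. These sizes
give the binomial checks enough events to be meaningful (about 380
flank positions per family) without simulating genome-scale input; the
genome-wide tallies of the original target set (hundreds of genes,
thousands of mRNAs) require the underlying sequence databases and are
out of scope by design.

## Known limitations

* The bond-count energy is a complementarity score, not a
  thermodynamic prediction; do not compare its ΔG values with
  nearest-neighbour energies from folding software.
* Region assignment by start position undercounts junction overlap;
  use `boundary_flag` when that matters.
* Conservation is descriptive — no substitution model, no tree, no
  significance test is fitted or claimed.
* Single-query design: scanning many miRNAs is a loop over queries,
  with no cross-miRNA competition model.
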