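---
title: "Measuring conserved extended haplotype architecture: dominant sequences, fixity and normalized crossover frequency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring conserved extended haplotype architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cehtools)
```

## The problem

Conserved extended haplotypes (CEHs) are megabase-scale haplotypes of the
human MHC that segregate at high population frequency with essentially
identical sequence among unrelated carriers. Because the members of a CEH
group descend from a common ancestral chromosome, their present-day
diversity is dominated by historical recombination: a haplotype carries
the ancestral ("dominant") sequence from a telomeric anchor up to the
point where a crossover replaced its centromeric portion with sequence
from another haplotype. `cehtools` turns this picture into a measurable
pipeline for phased SNP/DIP marker data in the class II region:

1. reconstruct founder haplotypes from nuclear-pedigree genotypes by
   segregation analysis;
2. assign haplotypes to CEH groups by required core-marker alleles (the
   role played in practice by HLA and complotype typing);
3. compute each group's **dominant sequence** and **fixity curve**;
4. localize each member's **break point** to a marker interval and
   measure how far an external reference haplotype (an MHC Haplotype
   Project cell line, say) represents a group;
5. summarize erosion per genomic sub-region with the **normalized
   crossover frequency (NCF)** statistic.

A synthetic-cohort generator with a complete ground-truth ledger
(`simulate_cohort()`) is first-class: every stage of the pipeline is
validated against planted truth.

## The dominant sequence and its tolerance rule

For a group of $n$ haplotypes aligned to a marker map, the sweep runs
telomere to centromere from the anchor. At each marker the dominant
allele is the modal allele among *retained* members with non-missing
calls. A retained member *deviates* where its call differs from the
dominant allele. The crucial distinction is between:

* **isolated deviations** — the member matches the dominant allele at
  its nearest non-missing marker on each side. These are private
  mutations or microvariation on an otherwise identical chromosome; the
  member stays retained and the deviation is logged.
* **non-isolated deviations** — two or more consecutive deviating
  markers, the signature of a crossover onto another haplotype. The
  member leaves the retained set at the first such marker and is never
  re-admitted.

Missing calls never remove a member: unsequenced intervals are bridged
under the assumption of sequence identity, so a member whose first
non-missing marker after a gap deviates is treated as deviating there,
and its break-point interval widens across the gap.

Numerical choices worth stating:

* *Isolation window.* "Isolated" is operationalized as matching at the
  single nearest comparable marker on each side (`isolation_window = 1`,
  configurable). This is the minimal reading of "apparently unlinked and
  isolated"; a run of two deviations is always a crossover.
* *Edges.* A deviation at the first or last analyzed marker has only one
  flank; the existing flank decides. A lone terminal mismatch therefore
  counts as isolated — the conservative choice, since a single final
  marker cannot distinguish a private mutation from a crossover.
* *Ties.* If the modal allele ties among retained members the group has
  split into two equally represented continuations (co-dominant
  variants). The tie is recorded with the carrier sets, the dominant
  allele is undefined there, and no member is removed by a tie: both
  continuations are conserved.
* *Markers where every retained member is missing* carry an undefined
  dominant allele and are excluded from all comparisons.
* *Fixed point.* The dominant allele and the retained set define each
  other, so the sweep iterates modal-allele and retained-set updates to
  a fixed point (convergence is almost always immediate; the iteration
  cap is 20).
* *Re-admission.* A member that leaves the retained set never returns,
  even if it matches again centromerically (back-recombination is not
  modeled); this is a fidelity assumption, not an observation.

The **fixity curve** is `retained_count / group size` per position, with
the full group membership as denominator throughout, so curves are
non-increasing from 1 and comparable across groups of different size.

## Break points, representation extents, tags and private variants

`call_breakpoints()` brackets each member's loss of the dominant
sequence between the last non-missing matching marker and the first
non-isolated deviation; the interval width is their plain position
difference. A member deviating at the anchor itself receives the
configured anchor boundary as its last-match position, reflecting the
convention that all group members carry the dominant sequence at the
centromeric end of the core region.

`representation_extent()` applies the identical isolation tolerance to
an external reference haplotype scanned against a group's dominant
sequence: isolated reference mismatches are recorded as candidate
private mutations of the reference; representation ends at the first
non-isolated mismatch, or at a co-dominant split the reference matches
neither continuation of. A reference missing at more than half of the
analyzed markers is declared unresolvable rather than scored.

`find_tag_markers()` reports (marker, allele) pairs carried by every
retained group member with a call and by no haplotype outside the
retained set — note the retained set, not the full group: crossed-over
members sit on the non-carrier side, which is what makes a regional tag
informative. `find_private_variants()` reports isolated deviations whose
allele occurs exactly once in the whole cohort.

## Normalized crossover frequency

For sub-region $r$ with centromeric-most analyzed point $b_r$,

$$\mathrm{NCF}_r = \frac{\text{crossovers}_r}{\text{remaining}_r}
  \times \frac{10^6}{b_r - b_{r-1}}$$

where `remaining` is the count of members still carrying the dominant
sequence throughout the region immediately telomeric (the full group
size for the first sub-region, by the anchor assumption), and a
crossover belongs to sub-region $r$ when its first non-isolated
deviation lies centromeric of $b_{r-1}$ and at or telomeric of $b_r$ —
so a crossover deduced to have happened between two analyzed regions is
counted in the centromeric one. Distances are plain subtraction of
1-based GRCh37 positions with no +1 adjustment. Because sub-regions have
very different sizes, the bar *areas* (height × genomic width), not the
heights, are the comparable quantity in `plot_ncf_fixity()`: for every
sub-region, `ncf * distance / 1e6` equals `crossovers / remaining`
exactly.

```{r ncf-example}
ncf_value(3, 16, 21096)         # 3 of 16 remaining over 21,096 bases
round(ncf_value(3, 16, 21096), 1)
```

Display values are rounded to one decimal; report tables keep full
precision alongside. Two open conventions had to be decided: the marker
map records both sub-region marker membership and the centromeric-most
point, and NCF uses the points; and a crossover whose bracketing
interval spans several sub-region boundaries is assigned by its first
mismatch position, with the interval width reported so the localization
uncertainty stays visible.

## Pedigree phasing

`phase_family()` supports nuclear families (two founder parents plus
children) and lone subjects — the units from which unrelated founder
haplotypes are actually reported; a lone subject homozygous throughout
contributes a single haplotype. Per marker, a child's paternal and
maternal alleles are determined whenever the split of its genotype
between the parents is unique; markers violating Mendelian transmission
are flagged (with a silent-allele suspicion when a homozygous child
faces a parent apparently lacking the allele) and excised for that
family rather than aborting it.

Phase linkage across heterozygous markers is the one genuinely open
design area. Markers are first resolved independently; linkage is then
chosen to minimize the total number of source switches across all
children's gametes, computed exactly by a small dynamic program over the
children's source-state vectors rather than greedily — a greedy scan can
silently absorb a real crossover into relabeling whenever a stretch of
markers is informative for only one child. Surviving switches are the
intra-family crossovers reported by `detect_family_crossovers()`;
recombinant gametes are never added to the founder list. When several
labelings achieve the minimum the choice falls deterministically toward
the allele-sorted labeling and the affected markers are flagged as
linkage ties; a crossover bracketed inside such a window is localized
only up to the window.

Residual ambiguity (markers heterozygous in every informative subject)
is never guessed during segregation: `assign_ambiguous_phase()` resolves
it afterwards, giving the dominant allele to the haplotype that matches
the group's dominant sequence at the nearest unambiguous flanking
markers; with no dominant context, or when neither haplotype matches,
a deterministic fallback assigns the lexically lower allele to the
first haplotype of the pair. Every resolved call is flagged as inferred.

## What the synthetic cohort emulates — and what it does not

`simulate_cohort()` plants, per group, one ancestral haplotype and `n`
members that erode centromerically: conditional on still carrying the
ancestral sequence, a member crosses over within sub-region $r$ with
probability `p_r`, at a position uniform between the sub-region's
flanking analyzed points and centromeric of the core markers; the donor
is drawn uniformly from a background pool plus the other groups'
ancestors, echoing the observation that post-crossover sequence is often
that of other common haplotypes. At most one crossover is planted per
haplotype because the analysis tracks only the first loss of the
dominant sequence. Private mutations arrive at rate `mu` per haplotype
per marker as novel-allele substitutions on the ancestral segment, never
at a core marker and never adjacent to a crossover or another mutation,
so "isolated" stays well-defined in the truth ledger. Missingness is
drawn per (haplotype, amplicon), mirroring amplicon-level sequencing
failure. Pedigree emission consumes four founder haplotypes per family
and transmits them through a configurable number of children, with a
configurable per-child probability of an intra-family crossover.

Two generator choices deserve emphasis. First, donors are re-drawn until
they differ from the ancestor at the two markers immediately centromeric
of the crossover point: a crossover onto a donor locally identical to
the ancestor is invisible to *any* method, so the ledger restricts
itself to observable events. Second, default conditions are chosen to
resemble a resequenced class II cohort: 308 markers over ~0.6 Mb of
GRCh37 chromosome 6, 11 sub-regions, about 10% DIPs, a handful of
high-frequency groups in a cohort of order 10^2 haplotypes, `p_r` a few
percent per sub-region, `mu = 0.001`, and amplicons of ~4 markers.

What it does **not** emulate: coalescent genealogy, mutation ages,
recombination-hotspot fine structure, gene conversion, back-recombination
onto the ancestor, genotyping error, or crossovers between locally
identical haplotypes. Passing tests therefore demonstrate that the
implementation recovers planted structure under the model's own
assumptions, not that real cohorts satisfy those assumptions.

## Validation strategy and problem sizes

The test suite validates each stage against independent routes: a
brute-force enumeration oracle for trio phasing; hand-evaluated
consensus examples; the truth ledger for crossover counts, NCF tables,
breakpoint containment and private-mutation recovery; and a randomized
battery (50 configurations) for the monotonicity and area-identity
invariants. Cohort-scale checks use 200 haplotypes per group for
oracle-equivalence and containment runs, 500 for rate recovery (within
three binomial standard errors of the planted `p_r`), and pooled cohorts
of several hundred crossovers for the containment-coverage estimate at
5% amplicon missingness, which lands near 96% — the residue being
crossovers whose local evidence an unlucky missing amplicon hides, so
that the identity-in-gaps assumption places the interval beside the true
position.

## Worked example

```{r pipeline, fig.width = 7, fig.height = 5}
cfg <- sim_config(groups = c(G1 = 30L, G2 = 16L), p_r = 0.05, seed = 7)
sim <- simulate_cohort(cfg)
haps <- assign_groups(sim$observed_haps, sim$specs, sim$map)
g1 <- subset_haplotypes(haps, which(haps$info$group_id %in% "G1"))
dom <- compute_dominant_sequence(g1, sim$map)
dom
fx <- compute_fixity_curve(dom)
bp <- call_breakpoints(g1, dom, sim$map, anchor_bp = sim$truth$anchor_bp)
tab <- compute_ncf(bp, sim$map, n_haplotypes(g1),
                   anchor_bp = sim$truth$anchor_bp)
tab[, c("subregion_id", "distance_bp", "crossovers", "remaining",
        "ncf_display")]
plot_ncf_fixity(list(fx), list(tab))
```

## Known limitations

* Phasing handles nuclear families and singletons; multi-generation
  pedigrees must be split into nuclear units first.
* Which meiosis recombined is unidentifiable from two children when the
  switch windows overlap; three or more informative meioses pin it.
* Break points are reported as bracketing intervals, never fine-mapped;
  multi-reference triangulation of a break point is out of scope.
* Recombination *rates* (cM/Mb) are deliberately not computed: the
  number of meioses a population haplotype has experienced is unknown,
  which is precisely why NCF is defined as it is.
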