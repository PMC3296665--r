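---
title: "Simulating pyrosequencing strategies for prokaryotic genome assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating pyrosequencing strategies for prokaryotic genome assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyroseval)
```

# Scope

`pyroseval` studies a practical question of sequencing-project design:
how do single-end (SE) shotgun depth, paired-end (PE) depth, read length
and PE insert size determine the quality of a de novo prokaryotic genome
assembly?  The package closes the whole loop in simulation:

1. generate a synthetic circular genome with planted gene and repeat
   annotations (the ground truth),
2. simulate 454-style flow-cycle reads from it (SE shotgun and PE
   libraries),
3. assemble the reads with a small greedy overlap assembler and a PE
   scaffolder,
4. score the assembly against its reference with the standard indicator
   set, and
5. relate assembly quality to genome repeat content across a panel by
   ordinary least squares.

The quality indicators are the usual ones for draft prokaryotic
assemblies: genome coverage (GCE, %), substitution error rate (SBE, %),
indel error rate (IDR, %), single-base accuracy (SBA = 100 − SBE − IDR),
false gene loss and duplication rates (FLT, FDT, % of annotated genes),
contig count (CN), contig N50 against the genome length (NB) and
scaffold count (SN).

# Synthetic genomes

`make_genome()` draws an i.i.d. base sequence at a requested GC content;
prokaryotic chromosomes are treated as circular but stored linearly, and
read sampling handles the origin wrap.  Coordinates are 0-based,
half-open everywhere inside the package; GFF3 export converts to the
1-based inclusive convention.

`plant_repeats()` writes near-identical repeat families over the
background: each family has a random consensus and each copy is an
independently mutated version of it (substitution rate `divergence`,
default 0.005 in panels — the near-identical class, like insertion
sequences and recently duplicated operons, is precisely the class that
confuses assemblers).  Copies land on a random strand at random
non-overlapping positions, so inverted repeats occur.  `plant_genes()`
adds annotation-only gene intervals (the interval *is* the gene);
a gene placed inside a repeat unit exists once per copy and carries
`true_copy_number` equal to the family copy number.  No codon structure
is modelled: the assembly metrics studied here depend on repeat
structure, not coding statistics.

`make_panel()` builds a graded panel: genome sizes are drawn with 90% of
the mass below a `size_q90` point (mirroring the strongly right-skewed
size distribution of sequenced prokaryotes), per-genome GC is uniform in
0.35–0.65, one gene per 5 kb of mean length 900 bp, and the fraction of
the genome in long repeats (copies > 300 bp) is spread evenly across the
requested range so a regression on repeat content has signal.

One panel-design point deserves emphasis.  Long (> 300 bp) and short
(≤ 300 bp) repeat content are drawn **independently** (the short-class
fraction is uniform in 0–3% per genome).  If both classes scale with a
single per-genome intensity they are collinear across the panel, and no
read-length contrast can be identified: every repeat indicator is then a
proxy for the same latent variable.  Decoupling the classes is what lets
400 bp reads (which resolve short repeats) and 100 bp reads (which do
not) produce different correlation structure.

# The read simulator

The error model is parametric and homopolymer-aware, standing in for an
empirical flow-cycle profile:

* **Substitutions** follow a per-relative-position probability profile,
  by default a linear ramp from 0.1% at the 5′ end to 0.5% at the 3′ end
  (flow-cycle error accumulates along the read).  An arbitrary empirical
  profile vector can be supplied instead.
* **Indels** are dominated by homopolymer miscalls: an observed run of
  true length $L$ is drawn from $\mathrm{round}\,\mathcal N(L,\,
  \sigma_0 + \sigma_1 L)$, truncated at zero; over-calls insert copies of
  the run base, under-calls delete.  Defaults $\sigma_0 = 0.03$,
  $\sigma_1 = 0.01$ keep miscalls rare for short runs and increasingly
  likely for long ones.
* A small **background indel** rate ($10^{-4}$ per base) applies outside
  homopolymers.

With these defaults total per-base error stays well under 2%.  Read
lengths come from a truncated normal (mean = target, sd = 10% of it,
support 30 bases to 1.2 × target) or an empirical table.

Single-end reads are placed uniformly on the circle with uniform strand;
the number of reads is chosen so emitted bases / genome length is within
1% of the requested depth.  The paired-end procedure is a four-step
Monte-Carlo construction: draw a fragment length from
$\mathcal N(\mu_\text{insert}, \sigma_\text{insert})$ and place it
uniformly; take the two inward-facing 200 bp anchors at the fragment
ends; extend each anchor to 200 + 500 bases of error-free source
sequence, truncated at the fragment midpoint; inject errors and trim
each read to a length drawn from the read-length distribution.  This
reproduces ~400 bp PE reads whose outer truth coordinates are exactly
one fragment apart.  PE depth counts both mates' emitted bases.

Per-read truth (error-free source interval, strand, injected error
counts) is carried alongside the sequence, which is what makes the
simulator–evaluator consistency loop testable.

Reads are drawn in fixed-size chunks, so at equal seed a shallower
library is a prefix of a deeper one.  This common-random-numbers
coupling reduces Monte-Carlo variance when depth ladders are compared;
it changes no marginal distribution.

# The assembler

The assembler is a deliberately small greedy overlap-layout-consensus
implementation.  Reads are indexed by minimizers in both orientations;
seed buckets far above the (entry-weighted) median occupancy are masked,
which is both a speed device and the mechanism by which high-copy repeat
interiors become unextendable — as in real overlap assemblers, where
repeat-induced overlap ambiguity breaks contigs.  A contig grows by
repeatedly appending the highest-scoring verified suffix–prefix overlap
(score = overlap length × identity, deterministic tie-breaks; default
thresholds 40 bp and 0.97).  Overlap verification is a fast
Hamming-with-repair comparison with a banded-alignment fallback, and
candidates whose overlap needed an indel repair are never preferred as
extenders, because they would put a frameshift into the contig backbone.
Contained reads are placed into the growing layout as they are met; a
running per-column vote polishes the contig behind the growing end, and
the final consensus is a strict-majority per-column vote (ties keep the
current base).

Extension stops at a *branch*: when a substantial fraction (≥ 30%) of
the near-best rival overlaps imply a conflicting continuation — the
signature of leaving a repeat copy — the contig is broken.  The margin
within which rivals are compared (30 bp) is what lets a read anchored in
unique flanking sequence beat the repeat-interior rivals and carry the
contig across a repeat shorter than the read length.  Contigs whose
bases are almost fully (≥ 95%) covered by matches to longer contigs are
removed; coverage is assessed piecewise so reads spanning the circular
closure of a rotated contig are recognised as redundant.

The scaffolder anchors mates on contigs by unique k-mer voting and
bundles pairs into edges between contig ends.  An edge needs at least
`min_links` = 3 pairs agreeing in orientation with a plausible implied
gap; edges with ≥ 30% orientation disagreement are dropped.  Three
standard graph clean-ups follow: edges are accepted in ascending
implied-gap order (so a long-insert link that merely skips over a short
middle contig cannot steal the ends its true neighbours need); an edge
explained by a two-hop path through a middle contig is transitively
reduced; and a contig end courted by several partners of comparable
support marks a collapsed repeat, so such hub contigs are demoted to a
fallback tier — spanning links get first pick of the ends, and the
repeat contig only joins where nothing else can.  Gap estimates are the
median implied gap, clamped at 1 for the reported N runs but kept
unclamped for the graph arithmetic.

# The evaluator

Whole-genome alignment is anchor-and-extend: k-mers unique in the
reference (k = 21) anchor each contig on both strands, anchors are
chained co-linearly, inter-anchor gaps are filled by banded global
alignment with unit costs, and contig ends are extended by banded
semi-global alignment with the far reference end free (trailing columns
after the last run of four matches are trimmed, so unrelated tails do
not count as error).  Every block carries exact base-level counts
satisfying `n_match + n_mismatch + n_del == ref_end − ref_start`.

Design choices that matter downstream:

* Coverage unions overlapping blocks before summing, so GCE is bounded
  by 100 (a literal sum of block sizes can exceed the genome).
* The identity denominator includes gap columns, which is what makes
  SBE + IDR + SBA decompose to exactly 100.
* NB is computed against the genome length by default (an NG50-style
  statistic); classic assembly-sum N50 is available.
* CN counts contigs ≥ 100 bp and SN counts top-level units
  (multi-contig scaffolds plus unplaced contigs) ≥ 2 kb; both cutoffs
  are arguments because assembler reporting conventions differ.
* Gene mapping applies the strict rules: an alignment is a gene copy
  only if identity > 0.99 **and** aligned gene fraction > 0.5 within a
  single contig; loci overlapping > 50% on a contig collapse to one.
  FLT is the percentage of genes found zero times; FDT is the
  percentage of excess copies beyond the true copy number.  Both use
  the total gene count as denominator.

External MUMmer `show-coords` listings and PAF (with `cg:Z` CIGARs) can
be ingested as alignment blocks; show-coords rows cannot separate
mismatches from indels without the delta file, so counts there are
apportioned from block lengths and percent identity.

# Repeat statistics and regression

`find_repeats()` is a simplified de novo detector: canonical k-mer seeds
occurring at least `min_copies` times are extended left and right while
enough copies stay within 90% of the running consensus under a 20-column
sliding identity window (boundaries are trimmed back over the trailing
mismatch run).  It recovers planted families on both strands; the
planted annotations remain the primary ground truth for metric tests,
and the detector exists for genomes without truth.  `summarize_repeats()`
computes the indicator set — copy count, total repeat length, and the
strictly-greater-than 300 bp and 700 bp long-repeat classes — with
overlapping copies unioned so percentages stay bounded.

`regress()` is ordinary least squares through `lm()`, reporting slope,
intercept, $R^2$ and the two-sided slope p-value on $n-2$ degrees of
freedom, with `tidy()`/`glance()` methods; `regress_panel()` tabulates a
predictor × response grid.

# Study conditions and what the tests show

The panel used by the acceptance suite has 20 genomes of 100–250 kb with
long-repeat content graded 0–12% (at least one genome above 10%), fixed
seeds throughout.  These sizes are the package's desk-scale choice: they
retain every phenomenon of interest — repeat-induced fragmentation,
insert-size-dependent scaffolding, read-length effects — at a few
seconds of assembly per genome.  Strategies follow the
`<se> × SE + <pe> × PE` convention with PE depth fixed at 10×.

Reproduced qualitative findings (each is a test):

* contig count rises with the total length of long (> 700 bp) repeats
  (positive OLS slope, p < 0.05, on the 20-genome panel);
* 400 bp reads yield far fewer contigs than 100 bp reads on the same
  panel, and the correlation between total repeat length and contig
  count weakens as reads lengthen (assessed within paired-bootstrap
  noise, which is the right yardstick for an $R^2$ difference measured
  on 20 genomes);
* on genomes planted with 1.5/2.5/4 kb repeat families, an 8 kb PE
  library scaffolds every genome into no more scaffolds than a 3 kb
  library, strictly fewer on most — long inserts bridge what short
  inserts cannot;
* error-free 20 × SE + 10 × PE reads of a repeat-free 500 kb genome
  assemble back to GCE 100, SBA 100, FLT = FDT = 0 and a single
  scaffold.

## A known limitation: depth and N50

One expected trend does **not** reproduce under these conditions: mean
contig N50 as a function of SE depth (6→10→15→20×, PE fixed at 10×) is
flat with Monte-Carlo noise rather than nondecreasing, and the
corresponding acceptance check fails honestly.  The reason is
structural.  At ≥ 16× total coverage there are essentially no coverage
gaps left in 100–250 kb genomes, so in this assembler the remaining
contig breaks are repeat-boundary breaks, which are driven by repeat
geometry rather than by depth; the only depth-dependent rescue
(sampling a read long enough, and anchored far enough into unique
flank, to span a near-read-length repeat) is a weak effect.  Production
assemblers of the flow-cycle era extracted more from extra depth through
coverage-dependent consensus and error correction, which is outside this
package's scope.  Paired per-genome comparisons at coupled seeds show a
weak positive tendency (more genomes improve than degrade from 6× to
20×), consistent with a small true effect below the noise floor of a
20-genome mean.

# Numerical and reproducibility notes

* All randomness flows through R's RNG; every simulation function takes
  a `seed`, panel genomes derive per-genome seeds from a stable string
  hash of `(seed, genome_id)`, and `run_strategy()` does the same, so
  adding genomes never perturbs existing results.
* The assembler, scaffolder and evaluator are deterministic: every
  tie-break (equal overlap scores, equal votes, equal consensus counts)
  is resolved by a total order.
* Degenerate inputs fail loudly: empty read sets, zero-length
  references, genes longer than the reference, regression on fewer than
  three genomes or a constant predictor are all errors, and an assembly
  with no aligned bases refuses to report accuracy rather than emitting
  0/0.
* N50 on an assembly spanning less than half the denominator returns 0
  with a warning rather than a misleading length.

What passing these tests does *not* show: the synthetic genomes have
i.i.d. backgrounds with no gene structure, GC skew, plasmids or mobile
elements; the error model is parametric rather than fitted to a real
flow-cycle run; and absolute indicator values (contig counts, N50s,
error percentages) live at desk scale, not at the scale of a real
sequencing study with Mb genomes and a production assembler.  The
package's claims are about directions and mechanisms, which is also how
its acceptance checks are phrased.
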