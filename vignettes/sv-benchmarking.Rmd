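---
title: "Benchmarking somatic structural-variant callers with svbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking somatic structural-variant callers with svbench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svbench)
```

## The problem

Somatic structural variants (SVs) — deletions, duplications, inversions,
insertions and break-end junctions acquired by a tumor genome — are
called from short-read sequencing with far less reliability than point
mutations. Benchmarking a caller requires (i) a tumor genome whose SVs
are known exactly, (ii) a scoring rule that gives credit to calls whose
breakpoints are close to, but not exactly at, the true junctions, and
(iii) analyses that separate the signal of a method from the noise of
its parameterization. svbench implements all three stages as a tested
library plus a thin command-line front end, and generates its own
synthetic study data so the whole pipeline runs end to end on a laptop.

## The SV data model

An SV record carries 1-based inclusive breakpoints `pos` and `end`, a
type from `DEL, DUP, INS, INV, CNV, BND`, optional break-end mate
linkage, a FILTER status, and a train/test label. VCF v4.1 is the
exchange format: `END` is resolved from INFO, then from the REF length,
then falls back to `POS`; `SVTYPE=MSK` rows inside a truth VCF declare
the masked regions whose overlapping SVs (>= 50% of the SV region,
computed against the union of masks) form the held-out testing set.

Preprocessing mirrors what a challenge submission undergoes:
filter-failing rows are dropped, lone break-ends get their mate
synthesized from the ALT adjacency, IDs are reassigned to be
unambiguous, and same-chromosome mate pairs whose bracket geometry is a
canonical deletion (`t[p[` / `]p]t`), tandem duplication (`]p]t` /
`t[p[`) or inversion (both `t]p]`, or both `[p[t`) are rewritten as one
typed record. Only these canonical cases are converted: the mapping
from arbitrary break-end geometry to a typed event is not well defined
in general, and a conservative rule avoids silently mislabeling
unusual junctions. Unknown type strings (e.g. `ITX`) are excluded with
a warning rather than coerced, which keeps scoring type-blind while
still refusing invalid vocabulary.

## Scoring

Two similarity schemes are supported.

*Region overlap.* The Jaccard coefficient
$j = |A \cap B| / |A \cup B|$ over the bases of the two inclusive
regions; by default any positive overlap ($j > 0$) qualifies. Insertions
reduce to 1-bp regions under this scheme, which is exactly why the
closeness scheme exists.

*Breakpoint closeness.* For each of the start and end breakpoints, the
distance $\Delta$ between the called and known coordinate is converted
to a relative closeness $c' = 1 - \Delta/f$ when $\Delta \le f$, where
$f$ (default 100 bp) is the flank parameter. The overall similarity is
the geometric mean $c = \sqrt{c'_{start} \, c'_{end}}$. If exactly one
breakpoint is within $f$ the pair is *partially matching*: it can never
become a match and it is counted in none of TP/FP/FN.
Single-breakpoint events (both records with `pos == end`) use the start
breakpoint alone.

When several calls compete for the same known SVs, the final one-to-one
matching is the assignment maximizing total similarity, solved with the
Hungarian algorithm (`clue::solve_LSAP`). Ties between equally similar
candidates are broken by preferring pairs with the same SVTYPE, then
the same train/test subset, then genomic order; these preferences are
applied as perturbations of at most $3\times 10^{-12}$, several orders
of magnitude below any meaningful similarity difference, so the
matching is always similarity-optimal. A property test checks the
matching against brute-force enumeration on hundreds of random
instances.

Matched SVs are TPs on both sides; unmatched records with at least one
qualifying edge are partial; the rest are FPs (called side) or FNs
(known side). Break-end mates are annotated separately, an FP mate
whose partner is TP or partial is downgraded to partial, and each mate
pair then counts as a single SV. Precision, recall and F-score are the
usual ratios, with 0/0 defined as 0. When scoring a single leaderboard
scope, FP calls (which carry no truth label) are attributed to the test
scope iff >= 50% of their region overlaps the mask set — the same rule
that allocates truth SVs; without masks, FPs count in either scope.

```{r scoring-example}
truth <- sv_records(c("a", "b"), "chr1", c(1000, 8000), c(2000, 9000), "DEL")
calls <- sv_records(c("x", "y"), "chr1", c(1020, 8010), c(2080, 9010), "DEL")
score(match_calls(calls, truth, scheme = "closeness", f = 100))
```

## Ensembles

Aggregation asks whether the majority of the top $k$ submissions can
out-call the best individual one. Break-end records are excluded, and
pairwise *breakpoint-length distances* are computed between calls from
different submissions. The distance must combine breakpoint distance
and predicted-length disagreement; svbench uses

$$d = \max(|\Delta_{start}|, |\Delta_{end}|, |L_a - L_b|),$$

the maximum of the three discrepancies. This combination rule was a
genuinely open design point; the max form was chosen because $d < f$
then implies every individual discrepancy is within $f$, which keeps
the ensemble threshold semantics aligned with the closeness flank. The
function is isolated behind `breakpoint_length_distance()` so an
alternative combination can be swapped in.

Calls with $d < f$ are sufficiently similar. The *baseline* aggregator
takes connected components of the similarity graph and, for components
whose median intra-set distance exceeds $f$, iteratively removes the
member with the greatest median distance to the rest (ties remove the
later call in genomic order). The *conservative* aggregator
additionally requires >= 1 bp region overlap and grows sets from the
closest pairs; a candidate joins a set only if its submission is not
already represented and its median distance to the members is at most
$f$ (guilt by association); pairs whose two calls are both already
assigned are discarded. Sets covering <= k/2 distinct submissions are
removed — survivors cover a strict majority — and each surviving set
collapses to a consensus call at the median start and end (the lower
median for even counts, so consensus coordinates are always observed
integers).

## Error characterization

Scoring annotations are pushed down to breakpoints to ask *where*
callers fail. A breakpoint inheriting several annotations is resolved
by the priority TP > FN > FP. True negatives are sampled by rejection:
lengths drawn from a log-normal with the log-mean and log-sd of the
known SV lengths (natural-log parameterization), start positions
outside gap/repeat regions, and no overlap with known or called SVs; a
cap of 1000 attempts per requested region turns an over-constrained
genome into an informative error instead of an endless loop.

Four per-breakpoint variables are computed natively — bridging-read
count (reads whose aligned span contains position ± 1 bp; no
split-read requirement), distance to the nearest germline INDEL,
nucleotide entropy of the ± 50 bp reference window
($-\sum_x p_x \log_2 p_x$ over A/C/G/T, case-insensitive, windows
truncated at contig ends), and strand bias (fraction of
breakpoint-overlapping reads on the forward strand). Additional
precomputed covariate columns (coverage, mapping quality, and similar
externally defined variables) pass through untouched, since their
definitions live outside this package's scope.

Univariate analysis correlates each continuous variable with the
proportion of teams making an error at the breakpoint (Pearson);
count- and distance-like variables are log10-transformed first, with
zeros replaced by −1 rather than logged. Categorical variables are
tested by a binomial GLM of the error proportion on the category with a
likelihood-ratio P value — the GLM's variable-level test is the
natural analogue of "significance of the variable in a fitted binomial
model", and the exact statistic is configurable territory rather than
load-bearing. Multivariate analysis fits random forests (FN vs TP, FP
vs TN; 500 trees; $\sqrt{p}$ variables per split) and reports
permutation importance — the mean decrease in accuracy — plus a
directional effect per numeric variable: the sign of the median shift
in the erroneous class, suppressed when a two-sided Mann-Whitney test
gives P > 0.01. A class with fewer than two members, or one above the
configurable convergence guard (default 15,000), is refused with an
error.

## The spike-in simulator

The simulator provides the study conditions: a seeded random reference
(default GC 0.5), error-free paired reads at uniform coverage (default
read length 100 bp, fragment 500 ± 50 bp) whose true placements double
as alignments, and SV spike-ins at chosen variant allele fractions.
Because the reads are error-free, local assembly is replaced by slicing
the reference around the SV span, padded by one fragment length per
side; the slice must span at least twice the mean fragment length, the
analogue of requiring an assembled contig long enough to anchor both
junctions. Variant-supporting pairs are simulated over the rearranged
contig at final coverage

$$C_f = \mathrm{VAF} \cdot C_o \cdot (L_f / L_o),$$

where $C_o$ is the original coverage and $L_o$, $L_f$ the original and
rearranged contig lengths. For deletions (and inversions, whose depth
should be unchanged) a VAF-scaled fraction of the original pairs with a
read overlapping the affected span is removed; duplications and
insertions only add pairs. Contig-simulated reads are mapped back to
reference coordinates through the rearrangement's block map, with soft
clips at junctions (reverse-complemented placement inside inverted
spans; reads falling entirely within novel insertions are emitted as
unmapped records on their mate's position), so that breakpoint features
such as bridging reads and strand bias see realistic clipped signal.
Truth records carry exactly the planned reference coordinates, and the
pair-count ledger (input − removed + simulated = output) is checked in
tests.

Default spike VAFs follow the subclonal design of the study conditions:
0.5 for clonal events in a diploid genome plus 0.33 and 0.2 for two
subclones. Synthetic "submissions" are derived from truth by breakpoint
jitter (Gaussian, default sd 10 bp), dropout at a false-negative rate,
and spurious calls with truth-like log-normal lengths placed outside
truth regions.

What the generator deliberately does **not** emulate: sequencing
errors, base-quality structure, GC or mappability coverage bias,
repetitive sequence, alignment ambiguity, and real library artifacts.
Passing tests therefore demonstrate the correctness of the scoring,
aggregation and profiling machinery — not that any particular caller
would perform equivalently on real tumors.

## Leaderboard analyses

Submissions are ranked by F-score (ties: precision, then team id). The
within-team variance statistic — the within-team sum of squares of
F-scores as a percentage of the total — quantifies how much of the
leaderboard spread is parameter tuning rather than methodology.

The overfitting-artifact experiment shows that $F_{train} - F_{test} >
0$ can arise with no fitting anywhere: truth subsets of a given total
are sampled, split into train/test at fractions 80–95%, and each fixed
submission is scored on both sides. Each submission is matched once
against the full truth set, so a call is an FP only if it matches no
known SV at all; within a split, that global FP burden cannot be
attributed to either side and counts against both, weighing far more
heavily against the few test-set TPs than the many training-set ones.
This convention is what makes a perfect submission show exactly zero
gap while imperfect ones show a gap that grows with the training
fraction — the artifact. The summary is the median gap over replicates
per submission, then the median across submissions.

## Numerical choices and problem sizes

* Coordinates are 1-based inclusive throughout the public model;
  interval arithmetic is delegated to IRanges with conversion at the
  boundary (BED masks are converted on input).
* FILTER `.` passes, matching the common dialect of truth VCFs.
* Exact similarity ties are resolved deterministically by (chromosome,
  position) ordering; the tie-break perturbations are bounded by
  $3 \times 10^{-12}$ per edge.
* Medians of even-sized ensembles use the lower median.
* The test and acceptance workloads are sized for interactive runs: a
  3-Mb single-contig genome with 500 truth SVs for scoring studies,
  60-kb contigs at 30× for spike-in depth checks, 200 random instances
  for the matching oracle, and 20 replicates over the 16-point
  training-fraction grid for the resampling experiment.

## Limitations

* Break-end conversion covers canonical same-chromosome DEL/DUP/INV
  adjacencies only; translocations and complex rearrangements stay BND
  and are excluded from ensembles by construction.
* The overlap scheme treats insertions as 1-bp regions; use the
  closeness scheme for insertion-bearing truth sets.
* The simulator's coverage model is exact only in expectation at each
  locus; VAF is honored in expectation, not per fragment.
* No genotype (FORMAT) interpretation, no CNV copy-number
  quantification, and no learned meta-classifier aggregation.
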