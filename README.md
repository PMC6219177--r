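# svbench

Challenge-style benchmarking of somatic structural-variant (SV)
callers, end to end: simulate a tumor with known SVs at chosen variant
allele fractions, score call sets against the truth under
breakpoint-aware similarity schemes, aggregate many submissions into
majority-vote ensembles, and characterize where callers fail.

It is written for method developers and benchmark organizers who need
the machinery of an SV calling challenge — truth-set construction,
fair matching, leaderboard analytics — without the infrastructure of
one.

## What it computes

**Scoring.** A called SV matches a known SV under either *region
overlap* (Jaccard coefficient `j = |A∩B| / |A∪B|`, any positive
overlap by default) or *breakpoint closeness*: with flank parameter
`f` (default 100 bp), each breakpoint at distance `Δ ≤ f` scores
`c' = 1 − Δ/f`, and the pair's similarity is the geometric mean
`c = √(c'_start · c'_end)`. Pairs with exactly one breakpoint within
`f` are *partial* matches, counted in none of TP/FP/FN. Ambiguities
are resolved by a one-to-one matching that maximizes total similarity
(Hungarian algorithm), and `precision = nTP/(nTP+nFP)`,
`recall = nTP/(nTP+nFN)` and the F-score follow.

**Ensembles.** Calls from the top *k* submissions that lie within a
breakpoint-length distance
`d = max(|Δstart|, |Δend|, |ΔL|) < f` of one another are grouped
(connected components, or a stricter overlap-constrained variant),
sets covering ≤ k/2 submissions are voted out, and survivors collapse
to consensus calls at the median breakpoints.

**Error profiles.** Breakpoints are labeled TP/FN/FP (priority
TP > FN > FP) or sampled as true negatives; per-breakpoint variables
(bridging reads, germline-INDEL distance, sequence entropy, strand
bias) feed univariate association tests and random forests whose
permutation importance says which variables drive FN and FP errors.

**Simulator.** SVs are planted by rearranging a local contig and
re-simulating error-free read pairs over it at final coverage
`C_f = VAF · C_o · (L_f/L_o)`, removing a VAF-scaled share of original
reads where the SV demands it, so read depth tracks the planned allele
fraction and junction-spanning soft-clipped reads exist.

## Worked example

```r
library(svbench)

ref   <- generate_reference(200000, gc = 0.5, seed = 42)
reads <- simulate_reads(ref, coverage = 30, seed = 43)
plan  <- spike_plan(chrom = "chr1",
                    start  = c(40000, 90000, 140000),
                    end    = c(43000, 92000, 142000),
                    svtype = c("DEL", "DUP", "INV"),
                    vaf    = c(0.5, 0.33, 0.2))
tumor <- spike_all(reads, ref, plan, seed = 44)
tumor$truth[, c("chrom", "pos", "end", "svtype", "vaf")]
#>   chrom    pos    end svtype  vaf
#> 1  chr1  40000  43000    DEL 0.50
#> 2  chr1  90000  92000    DUP 0.33
#> 3  chr1 140000 142000    INV 0.20

read_depth(tumor$tumor, "chr1", 40000, 43000)
#> [1] 16.4   # half the reads over the VAF-0.5 deletion are gone

sub <- perturb_callset(tumor$truth, ref, jitter_sd = 10,
                       fn_rate = 0, fp_count = 1, seed = 45)
score(match_calls(sub, tumor$truth, scheme = "closeness", f = 100))
#>   scope n_tp n_fp n_fn n_partial precision recall   f_score
#> 1   all    3    1    0         0      0.75      1 0.8571429
```

All three planted SVs are recovered (recall 1); the one spurious call
costs precision (3 of 4 calls are true), giving F = 0.857.

A command-line front end for scoring, ensembling and leaderboard
analyses ships in `inst/cli/svbench`; see the header of that script
for usage, and `vignettes/sv-benchmarking.Rmd` for the methods.

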