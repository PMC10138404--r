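---
title: "Methods: WGBS differential methylation analysis in goosemethyl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: WGBS differential methylation analysis in goosemethyl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

goosemethyl implements the analysis stages of a two-group WGBS comparison
downstream of alignment: its inputs are per-cytosine call tables (one row
per covered cytosine: chromosome, 0-based position, strand, CG/CHG/CHH
context, read depth, methylated-read count), a genome FASTA, gene models
(GFF3 or BED12), an FPKM matrix and a sample sheet.  Read QC, bisulfite
alignment and duplicate removal are upstream responsibilities; so is the
exclusion of SNP-induced false methylcytosine calls, which requires
read-level bases that no longer exist at this entry point.

All internal coordinates are 0-based half-open; GFF3 is shifted on read.
Calls are strand-specific everywhere.  CpG dyad merging is an explicit,
local operation — it happens only in the pyrosequencing-style promoter
comparison, where the assay itself reads dyads — because a per-cytosine
table may or may not have had dyads merged upstream, and silently merging
twice would halve apparent depth asymmetries.

# Methylcytosine identification

## Error model

Vertebrate methylation is almost exclusively CG, so the pooled methylation
fraction at non-CG sites estimates the combined error rate (bisulfite
non-conversion plus miscalls):

$$ r = \frac{n_{mCHH} + n_{mCHG}}{n_{depth}} $$

with the numerator the methylated-read counts summed over covered CHG and
CHH sites and the denominator their total depth.  This is the only reading
of the estimator under which it is a rate in [0, 1] and matches the
observed 0.69–0.88% non-CG methylation in goose muscle WGBS; the
alternative reading (counting covered cytosines rather than methylated
reads) would make it a coverage ratio and is not used.

## Binomial test

A site with $k$ methylated of $n$ reads is called 5mC iff
$P(X \ge k \mid X \sim \mathrm{Bin}(n, r)) < \alpha$ with $\alpha = 0.01$
(99% confidence) and $n \ge 4$.  The test is one-sided upper-tail: only an
excess of methylated reads is evidence of methylation; there is no
meaningful two-sided alternative at an unmethylated site.  Sites with
depth < 4 are excluded from every downstream CG statistic, not merely from
calling.  The per-site $\alpha$ is applied as such, without a
multiple-testing step at this stage; the binomial threshold is itself the
"false mC discovery" control, and any further FDR notion in this
tradition is not specified precisely enough to implement — the ambiguity
is deliberate and documented rather than guessed at.

Base-call quality enters through the Q score
$Q = 10 \log_{10}(p/(1-p))$: when the input table carries a per-site `q`
column, sites with Q < 20 are removed first, which guarantees the retained
calls are correct with probability ≥ 100/101 ≈ 99.01%.  Absent a quality
column all sites pass, since the filter properly belongs to base calling.

Numerics: the tail probability is computed with `pbinom(k − 1, n, r,
lower.tail = FALSE)`; the test suite checks it against direct log-scale
enumeration of point masses to 1e−12 for all depths ≤ 30 over a grid of
rates.

# CpG island, shore and shelf annotation

An island must satisfy all of: length > 200 bp, GC fraction > 0.5, and
observed/expected CpG $= \frac{\#CpG \cdot L}{\#C \cdot \#G} > 0.6$.  `N`
bases are excluded from counts and from the effective length, and a window
containing `N` never seeds an island (its composition is undefined).

The thresholds do not determine an algorithm, so a Takai–Jones-style
sliding-window scheme is used: every passing 201-bp window (step 1) seeds;
overlapping or abutting seeds merge into runs; each run is revalidated as a
whole and, if the union fails (possible when a weak linker joins two
CpG-rich cores), deterministically shrunk by discarding the end seed with
the lower observed/expected ratio until it passes — a single seed window
passes by construction, so the loop terminates.  Every emitted island is
re-checked by a post-hoc validator; detection is invariant to chromosome
order.  Shores (±2 kb of islands) and shelves (the next ±2 kb) are derived
by interval arithmetic with precedence island > shore > shelf, so no base
is double-labelled and neighbouring islands' features never overlap.

# Regional levels, metagene profiles, clustering

A region's level is the weighted quotient $\sum m_i / \sum d_i$ over
qualifying sites (depth ≥ 4, matching context) — never the mean of
per-site fractions, which would overweight shallow sites.  A region with no
qualifying site is *missing*, never 0.

Metagene profiles use 20 upstream flank bins of 100 bp, 60
percent-of-length body bins and 20 downstream bins, oriented by strand.
The flank bin width follows the 100-bp convention of TSS/TTS profile
plots; 60 body bins keeps body and flank bins visually comparable on one
axis for typical toy gene lengths (the body binning itself is a free
choice; nothing downstream depends on it).  Bin levels pool reads over all
genes, and the plotted line is a centered 5-bin moving average whose window
shrinks symmetrically at the series ends rather than padding with
fabricated values.

Between-group comparisons of per-replicate region levels use a two-sided
Welch t-test — with n = 3 replicates per group an unequal-variance default
is the safe choice, and the tradition this follows marks significance stars
without naming its test.  Sample-level structure uses CG levels on a fixed
10-kb genome tiling; windows with fewer than 5 qualifying sites in any
sample are dropped entirely so that between-sample distances are computed
on a common support.  Clustering is Ward's minimum variance on Euclidean
distances (`hclust(method = "ward.D2")`, the squared-distance-correct
form), ordination is PCA of the centered window matrix; a constant matrix
has no ordination and is an error, not a silent result.

# DMR and DMG detection

DMRs are called on CpG sites shared by both groups after pooling replicates
within each group (the criteria are count-based, and the motivating design
compares pooled libraries of n = 3); windows are 5 consecutive such sites,
sliding one site at a time, discarded when any neighbour gap exceeds 1 kb.
Each window gets a two-sided Fisher exact p on the pooled 2×2 count table,
computed directly from the hypergeometric density (summing point masses ≤
the observed one, with the same 1 + 1e−7 relative tolerance as
`fisher.test`, which serves as the independent oracle in the tests).
Benjamini–Hochberg adjustment runs across all tested windows; passing
windows (|Δ| ≥ 0.25, q ≤ 0.05) merge when overlapping or within 1 kb with
the same direction, and merged regions are re-scored on their full CpG
content and must satisfy every threshold again.  Two published definitions
of this procedure coexist (a three-consecutive-CpG p/FDR < 0.01 rule and
the ≥5-CpG/|Δ|≥0.25/q≤0.05 rule); the stricter, fully quantified rule is
implemented, keeping the 1-kb gap constraint from the other.  "Q value" is
implemented as BH FDR of the window test.

Group-swap symmetry (deltas negate, intervals unchanged) is enforced by
construction and tested.  A gene is DMR-related for a region type
(upstream 2 kb, body, downstream 2 kb) on ≥1 bp overlap; its net direction
is the depth-weighted sign of overlapping deltas, and exact ties exclude
the gene from quadrant classification since the quadrant scheme admits no
mixed class.  DMGs compare pooled regional levels per gene:
$\log_2((\ell_A + c)/(\ell_B + c))$ with pseudocount $c = 0.01$ keeping a
zero level finite, Fisher p on the pooled counts, BH within region type,
reported at |log2 FC| ≥ 1 and FDR ≤ 0.001.

# Expression integration

Expression classes follow fixed FPKM cut-offs: high ≥ 100, middle [10,
100), low (0, 10), none = 0.  The printed class definitions overlap at
zero ("0 ≤ FPKM < 10" vs "FPKM = 0"); exactly-zero means *none* and any
positive value below 10 is *low*.  DE testing is a deliberately simple,
dependency-free surrogate for a count-based package test: log2 fold change
of group-mean FPKM with pseudocount 1, a two-sided Welch t on
log2(FPKM + 1) per gene, BH across genes, thresholds |log2 FC| ≥ 1 and
FDR ≤ 0.05.  It is not an edgeR reproduction and is documented as a
divergence; at the planted effect sizes (FC = 4, log-normal dispersion 0.1,
n = 3) its recall is ≥ 0.9 by construction and verified in the tests.

DEG × DMR-related intersections are labelled E±&M± from the joint
directions.  The promoter per-site comparison takes a TSS-relative
half-open offset interval (negative = upstream; the −723..−480 interval of
the motivating assay is the default in the pipeline), converts it
strand-awarely to genomic coordinates, pools the two strands of each CpG
dyad per replicate, requires coverage (pooled depth ≥ 4) in *every*
replicate of both groups, and reports per-site Welch p-values without
multiple-testing adjustment, matching the per-site-stars presentation of
pyrosequencing panels.  Whether such offsets count from the TSS or the
start codon is an assay-reporting ambiguity; TSS-relative is the
implemented convention and the interval is a configurable argument, never
a hard-wired constant.

# The synthetic dataset: what it emulates

`simulate_dataset()` is deterministic in (config, seed); the master seed is
expanded into per-sample substreams so samples are independent but the
whole dataset regenerates bit-identically.  Defaults define the study
conditions:

| parameter | default | why |
|---|---|---|
| genome | 2 × 500 kb | all analyses complete in minutes on one CPU |
| genes | 200, 1.2–2.4 kb, 1–4 exons | gene-dense toy keeps every region type populated |
| islands | ~1 / 50 kb, 300–600 bp | every truth island passes all three thresholds by construction |
| planted DMRs | 40, Δ = 0.5 over 8 CpGs | comfortably above the 0.25/5-CpG reporting floor; sub-threshold effects would conflate caller power with generator choices |
| depth | Poisson, mean 30 | simplest count model consistent with WGBS; no alternative is specified |
| conversion error | 0.008, symmetric | inside the observed 0.69–0.88% non-CG range; an unconverted unmethylated C reads as methylated, which is exactly what the non-CG proxy measures |
| breed/stage offsets | WZE 0/−0.03/−0.08, STE 0/−0.005/−0.02 | the WZE-like breed demethylates faster over E23→P1; STE-like stays higher at the two later stages |
| expression coupling | log2 FPKM = 10.5 − 9·(promoter methylation), lognormal dispersion 0.1 | spans all four FPKM classes with a strong negative promoter correlation; real effect-size distributions are unpublished, so these are conventions, not estimates |
| DE genes | 40 at FC 4 between breeds | recoverable at n = 3 without making the test trivial |

The methylation surface is built per CpG dyad: background 0.78,
hypomethylated islands (0.10), a Gaussian dip (depth 0.85, σ = 350 bp)
centered on every TSS, a variable proximal-promoter zone (1.2 kb upstream
of the TSS, per-gene level uniform on [0.2, 0.95]) that drives expression
through the negative coupling, and a TTS-proximal body zone (last 40% of
the body) whose level rises with expression class for the non-high classes
(none 0.52 < low 0.65 < middle = high 0.78) — producing the TSS-proximal
anti-correlation and the TTS-proximal positive correlation that real
muscle methylomes show, with the high class saturating.  60% of planted
DMRs sit on DE genes with the opposite-signed methylation change, 20%
same-signed, 20% on non-DE genes, so the joint quadrant analysis has a
discordant (E+&M−, E−&M+) majority by design.  DMR dyads are forced to a
0.5 base level before ±Δ/2 is applied to the two breeds, so the planted
difference survives clipping to [0, 1] exactly.

One plus-strand gene away from any truth island is the pyrosequencing
target: its TSS-relative [−723, −480) segment is rewritten to contain
exactly 13 CpG dyads separated by A/T filler (no accidental CpG can form at
the boundaries).

What the generator does *not* emulate — and hence what passing tests do not
show about real data: read-level artefacts (PCR duplicates, M-bias,
SNP-induced false calls), beta-binomial overdispersion between replicates
(counts are exactly binomial given the surface), chromatin-driven
correlation between neighbouring CpGs beyond the painted zones, repeat
content, and realistic intergenic sparsity.  The toy genome is deliberately
gene-dense (≈ 40% of bases lie in a gene or its 2-kb flanks), so its
*global* CG level (~55–57%) sits below the ~65% genome-wide level of real
muscle WGBS, where vast fully-methylated intergenic stretches dominate;
regional contrasts, not the global marginal, are the object of study.
Non-CG cytosines are down-sampled to 10% of positions (fixed per dataset,
shared across samples): they exist only to carry the error signal for the
false-positive-rate estimator, and at mean depth 30 the retained ~40,000
positions per sample estimate a 0.8% rate with a standard error below
0.01%.

# Problem sizes and determinism

The test suite and the acceptance script run everything at the default
scale above: ≈ 11,000 CpG dyads, ≈ 22,000 strand-specific CG sites shared
between groups (and as many Fisher windows per comparison), 18 methylomes
of ≈ 60,000 rows each.  A full pipeline run (simulate → call-mc → annotate
→ profile → windows/cluster → three stage-wise DMR/DEG/integration
comparisons → promoter table) takes well under a minute per run on one
CPU, and two runs with the same seed produce byte-identical output trees
(the manifest records config, seed, version and md5 checksums, and
contains no timestamps for precisely this reason).

# Known limitations

Replicate-aware DMR tests (beta-binomial, smoothing-based callers) are out
of scope — pooling replicates before the Fisher test discards
between-replicate variance, which is the main reason real analyses have
moved to dispersion-aware callers.  CHG/CHH analysis stops at levels (the
motivating biology is CG).  The DE surrogate ignores count uncertainty at
low FPKM.  The island detector's shrink rule can, in principle, discard a
passing seed window that abuts (rather than overlaps) the retained core of
a failing run; on CpG-rich islands over a depleted background this does not
occur, and the validator guarantees every *emitted* island passes the
thresholds regardless.
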