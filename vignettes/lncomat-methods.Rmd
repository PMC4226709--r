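---
title: "Methods: correlation-matrix integration of lncRNA and mRNA expression"
author: "lncomat maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlation-matrix integration of lncRNA and mRNA expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncomat)
```

# The problem

Uterine leiomyomas (fibroids) are benign smooth-muscle tumors profiled
against their matched normal tissue, the myometrium, in a paired design
with a tumor-size covariate: small tumors (<= 3 cm) and large tumors
(>= 10 cm). Both protein-coding mRNAs and long noncoding RNAs (lncRNAs)
are dysregulated in these tumors, with a characteristic asymmetry —
down-regulation dominates among mRNAs while up-regulation dominates among
lncRNAs — and the amount of dysregulation grows with tumor size. Because
most lncRNAs have no annotated function, the question of interest is
which mRNAs (and thereby which pathways) move together with which
lncRNAs. `lncomat` implements a correlation-matrix based integration of
the two RNA classes and every supporting stage around it, plus a
synthetic-data generator that emulates the design so that each stage can
be tested against planted ground truth.

# Differential expression

Expression enters as a log2 matrix (features x samples) with a sample
sheet giving patient, tissue (`N`/`T`) and size class (`S`/`L`). All
samples are quantile normalized jointly (not per group): each column is
forced onto the common distribution of per-rank row means, ties receiving
the mean of their tied rank means (`limma::normalizeQuantiles`, which
implements exactly this tie rule). The operation is idempotent; the suite
checks column multisets agree to 1e-9 after one pass.

For each contrast $c \in \{S, L\}$ the per-feature paired statistics are

$$\mathrm{log_2FC}_g = \frac{1}{n}\sum_{i=1}^{n} (x_{g,T_i} - x_{g,N_i}),
\qquad t_g = \frac{\bar d_g}{s_{d_g}/\sqrt n},\; \mathrm{df} = n - 1,$$

over the $n$ matched tumor–normal pairs, with a two-sided p-value. A
feature is called **up** when $\mathrm{log_2FC} \ge +1$ (inclusive
boundary, i.e. fold change of at least 2) *and* $p < 0.05$ (strict);
**down** symmetrically. The fold threshold and alpha are parameters
(`fcThreshold`, `alpha`); the inclusive-FC/strict-p convention is a
documented choice because "2-fold change" and "fold change > 2" are both
in circulation for this analysis. P-values are raw by default, matching
the original convention; Benjamini–Hochberg adjustment is available via
`adjust = "BH"`. Zero-variance differences never raise: a nonzero-mean
degenerate feature reports the smallest positive double as its p-value
and a zero-mean one reports $p = 1$, both flagged in a `degenerate`
column.

Calls in the two contrasts are combined three ways:

* `vennPartition()` — disjoint \{S-only, L-only, both\} x \{up, down\}
  buckets, with direction-discordant features in their own bucket rather
  than silently merged; bucket sizes always sum to the union of called
  features.
* `signatureSets()` — set 1 (mRNA) / set 3 (lncRNA): called in L but not
  in S (large-tumor specific). Set 2 / set 4: called in L, concordant (or
  sub-threshold) in S, with $|\mathrm{log_2FC}_L - \mathrm{log_2FC}_S|
  \ge 1$, i.e. a large-vs-small fold change above 2 — the only
  quantitative reading of "more dramatically changed" available.
* `fcDensitySummary()` — normalized fold-change histograms and up/down
  sign mass, the numeric content of the usual density plots.

Heatmap row ordering (`featureClusterOrder()`) is average-linkage
clustering on 1 − Pearson distance with a deterministic id tie-break;
it orders only and never cuts.

# lncRNA subtype classification

Each lncRNA is classified against the protein-coding transcripts on its
chromosome by testing six rules in a fixed priority order — sense before
antisense, exon before intron, overlap before proximity:

1. **exon sense-overlapping** — overlaps an exon of a same-strand gene;
2. **intron sense-overlapping** — wholly contained in an intron of a
   same-strand gene;
3. **natural antisense** — overlaps an exon of an opposite-strand gene;
4. **intronic antisense** — contained in an intron of an opposite-strand
   gene;
5. **bidirectional** — no gene overlap, divergent (head-to-head)
   orientation, TSS-to-TSS gap at most `bidirWindow`;
6. **intergenic** — otherwise.

Containment (not mere overlap) is required for the intronic categories; a
transcript straddling an exon/intron boundary overlaps the exon and so
resolves to the exon category. The TSS is the start for `+` features and
the end for `-` features, measured half-open so that abutting divergent
promoters have gap 0. `bidirWindow` defaults to 1,000 bp — the
conventional promoter-sharing window used by array annotation vendors;
no published value exists for this analysis, so it is configurable and
recorded in pipeline metadata. Partner ties break deterministically:
largest exonic overlap, then smallest TSS gap, then lexicographic id.
The classifier assumes one transcript model per gene; multi-isoform
collapse (union of exons) is the caller's responsibility.

The implementation is vectorized over `findOverlaps()`; the test suite
proves it identical to a naive all-pairs brute-force implementation of
the same rules on hundreds of random genomes, including overlapping and
nested genes. Cis partner pairs for the correlation profile are the
lncRNAs of subtypes 2–5 excluding exon sense-overlapping (whose
correlation is confounded by shared exonic sequence) and intergenic
(no partner).

One geometric subtlety is worth recording: reversing a lncRNA's strand
swaps each *relationship* with its antisense counterpart, but when a
lncRNA relates to several genes the priority order can re-rank the
winners, and head-to-head geometry becomes tail-to-tail, so only the
overlap labels swap cleanly and \{intergenic, bidirectional\} is closed
as a set. The suite tests exactly that form of the symmetry.

# The correlation matrix and relevance score

Pearson correlations are computed between every dysregulated mRNA (rows:
called in S or L) and every dysregulated lncRNA (columns) across all
samples. Pooling normal, small and large arrays maximizes $n$ (15 in the
emulated design); since the original sample span is not recorded
anywhere, the span is explicit (`span = "all"` or `"tumor"`) and stored
in the object. The matrix is then trichotomized with **strict**
inequalities at a symmetric cutoff (default 0.8): $+1$ if $r > 0.8$, $-1$
if $r < -0.8$, else $0$ — a coefficient of exactly 0.8 is "no
correlation". Zero-variance features yield undefined cells, excluded and
tallied under a separate `undefined` count so that
positive + negative + none + undefined always equals rows x cols.

For a designated lncRNA set $L$ (typically signature set 3 or 4), each
mRNA $g$ receives the relevance score

$$S_g = \sum_{l \in L,\; |r_{gl}| > 0.8} |r_{gl}|,$$

the sum of absolute cutoff-passing correlation coefficients — filtering
first, then scoring. An unfiltered variant (`filtered = FALSE`) exists
behind a flag. Genes are ranked by descending score with an id
tie-break; selection is explicit (`selectTop()`: top-$k$ or minimum
score) because no published rule fixes the count of "top" genes — the
pipeline default keeps every gene with a positive score.

# Enrichment

Pathway enrichment of a gene list is the upper-tail hypergeometric
probability against a user-supplied GMT collection:
$p = P(X \ge k)$, $X \sim \mathrm{Hypergeometric}(N, K, n)$, with the
universe $N$ defaulting to all detected features of the matching biotype
(the least anti-conservative choice), sets intersected with the universe
before counting, and BH adjustment across all tested sets. Up- and
down-regulated query lists are tested separately and tagged. This
replaces the web-service enrichment step used in the original analysis;
the EASE-score variant (hypergeometric on $n-1$) is deliberately not
replicated. The implementation is `phyper`; the suite proves it equal to
exhaustive enumeration of every draw for all universes up to $N = 12$.

# Cross-dataset concordance

Independent datasets are compared on three axes: exact common-gene
intersection after canonicalization (whitespace/case only — silent alias
mapping is worse than a smaller intersection); the relative Euclidean
distance matrix among samples, every pairwise distance divided by the
dataset maximum so the largest entry is exactly 1; and the Pearson
correlation of per-gene log2 fold changes over the common genes. The
replicate-attenuation identity
$r \to \tau^2/(\tau^2 + \sigma^2)$ for two noisy measurements of shared
effects (effect SD $\tau$, measurement SD $\sigma$) serves as the
closed-form oracle for the fold-change correlation.

# The synthetic-data generator

`simulateStudy()` emulates the study, not the platform. Its defaults are
the emulated conditions: 5 patients per tumor-size group; mostly-down DE
mRNAs (`downBiasMrna = 0.75`) versus mostly-up DE lncRNAs
(`upBiasLncrna = 0.75`); more and stronger dysregulation in large tumors
(`fracDe* = 0.08/0.15`, mean |log2FC| `effectSmall = 1.2` /
`effectLarge = 2.0`, chosen so small-contrast power at 5 pairs is
moderate and large-contrast power high, matching the reported pattern of
a few hundred calls growing with size); an intergenic-majority subtype
mixture; and subtype-specific cis correlation signs (intron
sense-overlapping overwhelmingly positive at 0.95, intronic antisense
negative-leaning at 0.30, natural antisense 0.35 and bidirectional 0.65
to give the two opposite-leaning intermediate profiles). Values that no
source states — noise SD 0.4, patient SD 0.3, baseline N(8, 1.5²) on the
log2 intensity scale — are fixed once at magnitudes typical of
normalized two-color array data.

The expression model for feature $g$ in sample $s$ of patient $p$ is

$$x_{gs} = \mu_g + \eta_{gp} + \Delta_{g,c(s)}\,\mathbb{1}[s\ \mathrm{tumor}]
 + \gamma_g f_{m(g),s} + \varepsilon_{gs},$$

with per-feature-per-patient effects $\eta_{gp} \sim N(0,
\sigma_p^2)$ shared by a patient's tumor and normal columns (so paired
contrasts cancel them; drawing them per feature keeps features
independent apart from planted factors), DE shifts $\Delta$ with
Gamma-distributed magnitudes and the stated direction biases, and iid
noise. Planted correlations use shared standard-normal factors $f$: both
members of a cis pair (or all members of an optional module) load on one
factor with loading

$$\gamma = \sqrt{\frac{\rho\,\sigma^2}{1-\rho}},\qquad
\sigma^2 = \sigma_\varepsilon^2 + \sigma_p^2,$$

which makes the *pair* correlation exactly
$\gamma^2/(\gamma^2+\sigma^2) = \rho$ — an exact population parameter,
so recovery tests can use Fisher-z confidence intervals. The sign comes
from a Bernoulli draw per the subtype sign profile (the negative member
loads $-\gamma$). Features planted DE in both contrasts share one
direction and get the large-contrast magnitude by scaling the small one,
so size-monotonicity holds by construction.

Annotation geometry is adversarial-safe: each gene (three 1-kb exons
over 5 kb) owns a 40-kb territory and hosts at most one lncRNA, placed
so that exactly one subtype rule fires and every other gene is tens of
kilobases away — far beyond the 1-kb bidirectional window. The exon
sense-overlapping placement deliberately straddles an exon/intron
boundary to exercise the priority rule. Intended subtypes, partners, DE
calls, cis signs, module membership and the planted enriched gene set
(80% of whose members are drawn from the down-regulated DE mRNAs) are
recorded in a `TruthManifest`.

Two patient designs exist because the original design is ambiguous: 15
arrays in three groups of five is consistent both with matched triplets
(each patient contributing normal, small and large samples) and with
disjoint small- and large-tumor patients. The default is `"disjoint"`;
`"triplet"` reproduces the 15-array layout and is what the
recovery tests use when they need $n = 15$ pooled samples. One RNG
stream is forked into named substreams (annotation, DE assignment,
signs, baseline, patient effects, factors, noise, gene sets), so adding
draws to one substep never perturbs another and identical parameters
give byte-identical output.

What the generator does **not** emulate — and therefore what passing
tests do not establish about real arrays: probe-level intensities,
background correction or probe-to-gene collapsing; realistic feature
counts (hundreds, not tens of thousands); gene–gene co-expression beyond
the planted factors (real transcriptomes are pervasively correlated, so
real correlation matrices are denser than the null-plus-planted
structure here); and any relationship between genomic position and
expression other than the planted cis pairs.

# Numerical and design choices

* Internal coordinates are GRanges convention (1-based closed)
  everywhere; only serializers know dialects (BED12 written 0-based
  half-open with exon blocks plus a 13th `biotype` column; GTF 1-based
  closed with `transcript_id` and `biotype` attributes). One convention
  internally kills off-by-one bugs at the boundary.
* Readers reject rather than coerce: duplicate ids, non-numeric cells
  (named by row and column), zero-width records, unknown strands and
  short GMT lines are typed errors; writers emit 17 significant digits so
  a write/read cycle is bit-identical.
* Quantile-normalization agreement and idempotence are asserted to 1e-9;
  relevance-score oracle agreement to 1e-12 (summation order differs
  between `rowSums` and the naive loop by design).
* Undefined correlations are NA sentinels, never exceptions, and always
  tallied.
* Every ranking and partner assignment has a deterministic tie-break, so
  outputs are reproducible byte-for-byte given a config and seed; the
  pipeline writes md5 checksums of its own outputs into the run manifest.
* Test problem sizes: 2,000 features x 5 pairs for t-test calibration;
  200 random genomes (up to 50 genes, 30 lncRNAs) for the classifier
  oracle; 1,000 random 20x20 matrices for the score oracle; 20–50 seeded
  studies for the recovery rates. These sizes give the binomial/Fisher
  confidence intervals used in the assertions reasonable power while
  keeping the default suite to a few minutes.

# Limitations

The pipeline operates at whatever feature level it is given and is
silent about probe collapsing; p-values are per-feature and unadjusted
by default; there is no moderated-variance testing, batch correction,
partial correlation or network inference; enrichment is plain
hypergeometric (no weighted KS walk / GSEA); cross-dataset comparison
requires caller-harmonized gene ids. The classifier scores genomic
context only — it does not assess coding potential or assemble
transcripts.
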