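---
title: "Genotyping indels from read evidence: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping indels from read evidence: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indelgt)
```

## The genotyping model

A diploid individual carries 0, 1 or 2 copies of a given indel allele.
`indelgt` treats genotype calling at a *known* site as a classification
problem: each (individual, site) pair becomes a point in a 5-dimensional
feature space built from read evidence, and an RBF-kernel support vector
machine trained on labeled examples assigns the class. The premise is that
no single evidence type is reliable at low coverage, but their combination
is: evidence *for* the indel (discordant encompassing pairs, split and
breakpoint-clipped reads, depleted interval depth, single-end-mapped
pairs) and evidence *against* it (concordant pairs, fully mapped spanning
reads, normal depth) push a point toward opposite corners of the space,
with heterozygotes in between.

The classifier makes two modelling assumptions worth stating. First,
breakpoints are approximately correct — split/clip features tolerate a
slack `c` (below) but degrade if discovery coordinates are hundreds of
bases off; depth and pair features are more forgiving. Second, sites are
biallelic and far enough apart that their evidence windows do not overlap;
overlapping sites are rejected by the simulator and will contaminate each
other's features if present in real site lists.

### Evidence rules

With library insert mean $\mu$, SD $\sigma$, read length $l$, indel length
$L$ and breakpoints $p_1 \le p_2$ (0-based half-open internally; for
insertions $p_1 = p_2$):

* **Relevant reads** start within $[p_1 - D,\ p_2 + D]$,
  $D = \mu + n\sigma$: a read can belong to an indel-overlapping pair only
  if it starts within one maximal insert of a breakpoint.
* **Pair classes.** A both-mapped forward–reverse pair whose outer span
  strictly contains a breakpoint is *encompassing*. It is discordant
  support when $|\mathrm{insert} - \mu - L_{adj}| \le n\sigma$ with
  $L_{adj} = +L$ for deletions and $-L$ for insertions; concordant when
  $|\mathrm{insert} - \mu| \le n\sigma$; invalid (discarded as likely
  mismapped) when the insert exceeds both windows' upper bounds,
  $\max(\mu, \mu + L_{adj}) + n\sigma$. Discordance is tested first: for
  deletions shorter than $n\sigma$ the two windows overlap, and the
  precedence deliberately routes ambiguous pairs to the indel-support
  count — the classifier recovers short-deletion genotypes mainly from
  split/full/depth features, which is also what the feature-ablation
  comparison shows.
* **Spanning-read classes.** A deletion read mapped as two segments whose
  inner edges land within $c$ of $p_1$ and $p_2$ is split; a soft-clipped
  read whose clip boundary lands within $c$ of either breakpoint is
  partial; a read mapped end-to-end (clips $\le c$) with at least one
  aligned base on each side of a breakpoint is full. Split reads are not
  used at insertion sites (two reference segments cannot flank inserted
  sequence); partial reads are not informative for deletions' feature
  vector but are for insertions.
* **Depth.** The deletion feature vector carries the mean per-base depth
  of $[p_1, p_2)$, counting aligned bases only (clipped bases do not
  contribute). Read depth is omitted for insertions: nothing is missing
  from the reference, so interval depth carries no signal.

### Local-coverage normalization

Raw counts scale with sequencing depth, which varies between individuals
and along the genome. Every feature component is therefore divided by the
site's local coverage $\lambda$: the mean of the mean depths of the two
flanking windows $[p_1 - w, p_1)$ and $[p_2, p_2 + w)$, $w = \mu +
n\sigma$ — the same width as the pair-evidence window, so the flanks
measure coverage over exactly the locality the counts come from. After
division the normalized interval depth of a wild-type site sits near 1
regardless of coverage, and a duplicated-input experiment (every read pair
twice) leaves normalized features essentially unchanged. Normalizing *all*
components (rather than leaving depth raw) keeps every coordinate
scale-free; the scale information itself is deliberately discarded, since
it is what varies between training and test cohorts.

Degenerate case: when $\lambda < \varepsilon$ (default 0.5×, e.g. a site
inside a coverage hole) the sample-wide mean coverage is used instead, and
an error is raised if no fallback is available — silent division by ~0
would manufacture huge features.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `n_sigma` | 3 | – | conventional ±3σ window of the discordant-pair literature; <0.3% of normal pairs misclassified under Gaussian inserts |
| `clip_slack` (`-c`) | 15 | bp | breakpoint coordinates from discovery tools and clip positions from mappers are both a few bases noisy |
| `mapq_min` | 20 | phred | standard "well-mapped" cutoff; a pair survives if either mate clears it |
| `window_pad` | μ + 3σ | bp | one maximal insert; larger pads only add uninformative reads |
| scaler range | [−1, 1] | – | customary SVM preconditioning; constant training columns map to 0 |
| grid | C ∈ 2^{−5,−3,…,15}, γ ∈ 2^{−15,…,3} | – | the canonical coarse RBF lattice |
| CV folds | 10 | – | stratified by class, seed-deterministic |

Grid-search ties are broken toward smaller C, then smaller γ — the
smoother of two equally accurate models. Per-class inverse-frequency
weights are available (`class_weights = TRUE`) for heavily skewed cohorts
(genotype 0 dominates at low allele frequency) but are off by default:
at the package's standard study conditions the unweighted SVM is already
accurate, and weighting changes the implied prior.

Deletions and insertions always get separate models: the five feature
slots mean different things for the two kinds, and mixing them would let
the classifier exploit accidental correlations between the two layouts.

## The simulator

The simulator exists so the full train → call → evaluate loop runs without
real data, and so the classifier can be trained on simulated cohorts when
no labeled genotypes exist. It emulates a low-coverage population
sequencing design: diploid individuals; per-site genotypes drawn i.i.d.
from configurable frequencies (default 70% / 20% / 10% for 0/1/2) or from
per-site allele frequencies via Binomial(2, af); heterozygous indels
placed on one seed-chosen haplotype; 100 bp paired reads with
insert ∼ Normal(500, 50) truncated at $2l$; per-base substitution errors
at 2%. The pair count per individual is $c \cdot G / (2l)$ for coverage
$c$ and reference length $G$, split binomially between haplotypes.

Two output modes share one fragment stream. *Truth placements* lift each
mate's haplotype interval back to reference coordinates and emit the
records an ideal soft-clipping aligner would produce — clean split
records when both pieces of a junction-crossing read are ≥ 20 bp,
breakpoint soft-clips otherwise, unmapped mates for reads inside inserted
sequence. *FASTQ mode* materializes base sequences (mate 2
reverse-complemented) with substitution errors for use with a real
aligner. Placements are independent of the error process, so the two
modes describe the same fragments.

What the simulator does **not** model: alignment ambiguity and mapping
error (truth placements have MAPQ 60 everywhere), indel sequencing
errors, quality-score structure, GC and mappability bias, PCR duplicates,
and repetitive sequence (the random reference is i.i.d. uniform
A/C/G/T). Passing the synthetic benchmarks therefore demonstrates that
the feature rules and classifier recover genotypes from correctly mapped
reads at realistic coverage and error rates — not that the method is
robust to the mapping artifacts of real repetitive genomes, where
accuracy on real cohorts is expected to be somewhat lower.

A trio mode draws parents from the genotype frequencies and builds the
child by sampling one allele from each parent, so truth trios are
Mendelian-consistent by construction; the eight impossible
(parent, parent, child) triples are then a pure function of call errors.

## Numerical and interface choices

* Coordinates are 0-based half-open internally; VCF/TSV input is 1-based
  inclusive and converted at the boundary. A VCF deletion record with
  POS and END becomes $p_1 = POS - 1$, $p_2 = END$, $L = p_2 - p_1$.
* Insert size is the aligner-reported template length (outer distance),
  absolute value; only forward–reverse pairs enter pair evidence.
* Multi-aligned templates are deduplicated by (template, mate) per site,
  so one physical pair contributes at most once per category.
* Library stats estimation trims inserts with $|x - \mathrm{median}| >
  5\,\mathrm{mad}$ before taking mean and *sample* SD, and takes the
  modal read length.
* With probabilities requested, the reported genotype is the probability
  argmax (ties toward the smaller genotype), so calls and probabilities
  never disagree; libsvm's pairwise-coupling probabilities and its raw
  decision rule can otherwise differ on borderline points.
* Model files are JSON with doubles printed as shortest exact decimals
  (17 significant digits); loading refits libsvm and then restores the
  stored support vectors, coefficients and probability calibration, so a
  loaded model reproduces the saved model's predictions bit-for-bit.
  A feature-order or format-version mismatch is a hard error.
* Empty regions, empty flanks and empty strata all degrade to explicit
  zeros/`NA`s rather than errors; genuinely degenerate inputs (no
  classes, zero-length regions, overlapping sites) abort with messages
  naming the offender.

## Problem sizes

The package's standard synthetic study — used by the test suite and by
`scripts/acceptance.R` — is 60 deletions (log-uniform 50–5000 bp) on a
1 Mbp reference, 20 individuals at 6× with per-site allele frequency
uniform on (0, 0.5), and 10 rounds of 15-train/5-test splits; the
downsampling experiment uses the same design at 12× versus a 25% template
fraction. These sizes give ~1.2 M alignment records and 1200 genotypes
per experiment, large enough that accuracy estimates are stable to a few
tenths of a percent while a full run stays in the minutes range on one
core. Unit tests use smaller cohorts (e.g. 30 sites × 10 individuals at
8×) where only qualitative behaviour is asserted.

## Known limitations

* Sites must be non-overlapping and biallelic; nested or adjacent events
  are not modelled.
* Insertion features assume the inserted sequence is absent from the
  reference; mobile-element insertions with close paralogs will leak
  mapped mates and dilute the single-end-mapped signal.
* The genotyper needs labeled training data (real or simulated) per indel
  kind; there is no unsupervised fallback.
* Breakpoint errors beyond `clip_slack` suppress split/partial features;
  only pair and depth evidence then remains.
* Accuracy floors established on the synthetic benchmark transfer to real
  data only to the extent the simulator's idealizations hold (see above).
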