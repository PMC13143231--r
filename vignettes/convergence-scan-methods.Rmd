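---
title: "Detecting convergent amino acid substitutions: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting convergent amino acid substitutions: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(convscan)
```

## The problem

Lineages that independently evolve the same phenotype — here the motivating
system is insects from three orders that tolerate toxic cardiac glycosides —
may do so partly through the same molecular changes. A genome-wide scan for
such changes asks, for every site of every single-copy ortholog alignment:
did two or more of the focal ("foreground") lineages independently acquire
the exact same derived amino acid, which no other sampled taxon carries?

`convscan` implements that scan as a pipeline of small, separately testable
stages: quality control of alignments and coding sequences, delineation of
single-copy ortholog sets from gene trees, maximum-likelihood reconstruction
of ancestral states, the substitution scan itself, and statistical
post-processing. A sequence-evolution simulator generates every input the
pipeline consumes with known ground truth, so each stage is validated
without any external data, and the whole scan can be calibrated against a
neutral null.

## Substitution model and likelihoods

Sequence evolution is modelled as a reversible continuous-time Markov chain
over the 20 amino acids. Given a symmetric exchangeability matrix $S$ and
stationary frequencies $\pi$, the generator is $Q_{ij} = S_{ij}\pi_j$
($i \ne j$), with the diagonal set so rows sum to zero and the whole matrix
scaled so $-\sum_i \pi_i Q_{ii} = 1$: branch lengths are expected
substitutions per site. Transition matrices $P(t) = e^{Qt}$ come from a
symmetric eigendecomposition of $D^{1/2} Q D^{-1/2}$ ($D = \mathrm{diag}\,
\pi$), which is numerically stable for any $t \ge 0$; entries below
$-10^{-12}$ are an error, smaller negative round-off is clipped and rows
renormalized.

The package ships the LG, WAG and JTT empirical matrices as PAML-format
`.dat` text files and parses that format itself, so user-supplied matrices
work the same way. The default for the scan is LG with alignment-derived
("+F") frequencies, counted with a pseudocount of one so no frequency is
zero. No published description of the original analysis fixes a model
choice for ancestral reconstruction, so the model is a configuration
parameter recorded in the run manifest rather than a constant.

Site likelihoods use Felsenstein pruning with per-node column rescaling.
Gaps, `X` and `*` at tips are uninformative partials (a vector of ones).
An optional discrete-gamma model (`gamma_shape`, 4 categories by default,
median-of-bin discretization renormalized to mean one) averages the site
likelihood over rate categories; it is off by default because rate
heterogeneity is an assumption the scan does not need and the original
analysis does not state. A global branch-length multiplier can be fitted by
one-dimensional maximum likelihood (`fit_branch_scale`) for trees whose
lengths are not in substitution units; for an alignment with no variable
site that likelihood is flat and the function returns 1 with a warning.

## Marginal ancestral reconstruction

For every internal node $v$ and site, the posterior
$P(x_v = s \mid \text{tips})$ is computed by inside–outside passes: the
inside (pruning) pass gives the likelihood of the data below $v$ given each
state, the outside pass the likelihood of everything else; their normalized
product is the marginal posterior. The MAP state is recorded with its
posterior. Two states whose posteriors are within $10^{-9}$ of the maximum
are a tie: the MAP is then the alphabetically first state, the site is
flagged, and tied reconstructions disqualify the branch in the scan, so no
call ever depends on an arbitrary tie choice. Marginal (per-node) rather
than joint reconstruction is used because the scan only ever consumes
per-branch parent states; the two differ exactly where reconstruction is
uncertain, which is where calls are excluded anyway.

## The identical-method scan

For each terminal foreground branch and site, a substitution is the pair
(parent MAP state, tip residue) when the two differ, the tip residue is a
standard amino acid and the parent MAP is untied. A site is called when at
least two foreground branches carry substitutions to the *same* derived
amino acid. Calls are classified `parallel` (all ancestral states
identical), `convergent` (all pairwise different) or `mixed`; the method
counts all of them, since what matters is independent arrival at the same
derived state.

Exclusivity (`require_exclusive`, on by default) demands that no
non-foreground tip carry the derived residue at the site, and that at least
`min_outgroup_residues = 2` non-foreground tips have data there — an
exclusivity claim supported by zero or one outgroup observations is not a
claim. Exclusivity is assessed over extant non-foreground tips only, not
reconstructed outgroup ancestors: the criterion names taxa, and extending
it to ancestors would make calls depend on reconstruction confidence deep
in the tree (a flag could add this, but it is deliberately not the
default). Only maximal foreground subsets are emitted — a three-way hit is
not additionally reported as its three pairs — while the summary table
reports both the exact and the inclusive counting conventions, because
published tallies are ambiguous about whether a three-way site also counts
in pairwise totals.

A minimum ancestral MAP posterior (`min_anc_posterior`) is available but
defaults to 0, since the original analysis states no such threshold.

## Quality control

Filters run in the order the upstream protocols apply them:

* **Premature stops**: coding sequences are translated in frame 1 under the
  standard code; one terminal stop is trimmed, any earlier stop removes the
  record; out-of-frame lengths are removed with reason `frame`, not an
  exception.
* **Sequence cleaning** (`-m 20 -p 0.30 -t 2`): fewer than 20 non-gap
  residues, or non-gap coverage below 30%, removes a sequence; fewer than 2
  survivors drops the orthogroup.
* **Block masking**: a deterministic dialect of the Gblocks parameter
  family with `b3 = 2`, `b4 = 5`, gap mode *half*. Column conservation is
  defined by the count of the single most frequent residue against
  `b1 = \lfloor 0.75n \rfloor + 1` and `b2 = \lceil 0.85n \rceil`; columns
  with more than `floor(n/2)` gaps are disqualified; nonconserved stretches
  longer than `b3` are removed, blocks are trimmed to highly conserved
  anchors and must reach length `b4`. The original program's internal tie
  rules are unpublished, so this dialect trades byte-compatibility for
  determinism and idempotence (applying any filter to its own output is the
  identity — a tested invariant).
* **Missing data**: sequences with at least 90% gaps-or-`X` are removed.
  The boundary is inclusive ("90% missing" removes a sequence at exactly
  0.90); an `inclusive = FALSE` flag flips this reading.

All column removals compose through a `column_map`, and each cell
additionally remembers its residue's index in the ungapped source sequence,
so reported coordinates are always 1-based positions in the original
alignment and backtranslation to codon alignments commutes with masking.

## Ortholog delineation

From each gene tree, maximal clades are extracted whose support is at least
0.95, which span at least four species, and in which — after collapsing
maximal same-species monophyletic tip groups into one unit ("in-paralogs
allowed") — every species occurs at most once. Three choices had to be made
where the upstream tool's behaviour is undocumented, and all are
conservative: unlabeled nodes count as support 0 and cannot anchor a clade;
trees are taken as rooted as read (an optional midpoint-rooting flag exists
because the original rooting protocol is unstated); and a qualifying clade
nested in a larger qualifying clade is absorbed by the larger one, so
returned sets are leaf-disjoint. The in-paralog representative is the
longest sequence, reusing the longest-isoform convention from genome
preprocessing. Orthogroups then pass the single-copy rule: exactly one copy
in every target species, at least two outgroup species. Gene families with
more than 100 members are excluded wherever family-size tables are
processed. Correctness of the whole delineation is checked against a
brute-force enumerator of all clades on random trees with random grafted
duplications.

## The synthetic study design

The generator's defaults emulate the statistical structure the scan
assumes: a nine-taxon rooted tree with three foreground taxa in three
separate clades and six outgroups (mirroring three orders with one
CG-adapted representative each), cherry branch lengths 0.05 and deeper
branches 0.05–0.1 expected substitutions per site — a strong-conservation
regime in which ancestral states are confidently reconstructable — with
200-column LG alignments. Root states are drawn from $\pi$ and branches
evolve by $P(Qt)$; the full internal-node labeling is kept as truth.

Planted sites overwrite foreground tips with a chosen derived residue after
verifying the simulated history is compatible with the requested mode
(parallel: parent states identical; convergent: pairwise different; in both
modes all parents must differ from the derived residue), re-drawing the
site's history when it is not. Outgroup tips are scrubbed of the derived
residue (exclusive plants) or given one copy of it (non-exclusive plants).
Planting edits tip states only; ancestral truth refers to the accepted
pre-edit history, since planting necessarily breaks the generative model at
that site. Contaminant injection produces records that each targeted filter
must catch (truncation below 20 residues, gap-flooding above 90% missing,
internal stop codons, grafted within-species duplicate tips), with a
manifest the filters are tested against exactly.

The recovery benchmark plants parallel-mode sites. This is deliberate:
requiring all three parents to differ (convergent mode) forces the planted
site onto an intrinsically variable history, and at variable sites the
marginal reconstruction of a short terminal branch's parent is pulled
toward the planted derived state carried by the tip — the scan then sees no
substitution and misses the site. The analysis scripts measure this
directly: parallel-mode plants on conserved backgrounds are recovered at
0.9 or better, convergent-mode plants much more rarely, and in the full
pipeline some planted (hence variable) columns are removed by the block
filter before the scan ever sees them. These are properties of the method
being reproduced, not of this implementation; they quantify why
identical-method scans are conservative about different-ancestor
convergence and why masking trades sensitivity for alignment reliability.

What the simulator does not emulate: indels (gaps enter only via
contaminant injection), rate variation across sites unless a gamma model is
configured, codon-level evolution, and among-lineage compositional
heterogeneity. Passing tests therefore demonstrate correctness of the
machinery and calibration under the model, not robustness to real-data
violations of it.

## Neutral null calibration

Even with no planting, neutral substitution produces identical-method calls
at some rate — the standard caveat against over-interpreting convergence
counts. `null_convergence_distribution` runs simulate → reconstruct → scan
per replicate and returns the empirical count distribution; an observed
count's empirical p is the fraction of replicates at least as large. On a
four-taxon, two-foreground, two-state configuration (branch lengths 0.3,
$\pi = (0.6, 0.4)$) the exact expectation is computable by enumerating all
$2^4$ site patterns — pattern probabilities by brute-force summation over
ancestral states, the scan rule applied to each pattern — and the
Monte-Carlo mean over 2,000 replicates is required to fall within three
standard errors of it. Replicate $r$ uses seed $\mathit{seed} + r$, so any
subset of a run reproduces in isolation.

## Statistics

Branch-site likelihood-ratio statistics from external ML fits are converted
to p-values under the boundary null: a 50:50 mixture of $\chi^2_1$ and a
point mass at zero, so $p = 1$ at $x = 0$ and
$p = \tfrac12 \Pr(\chi^2_1 \ge x)$ otherwise. Multiple testing uses
Benjamini–Hochberg step-up q-values at FDR 0.05; BH is an assumption, as
the original description says only "FDR". Enrichment is the classical
hypergeometric upper tail against a caller-supplied background (customized
to the single-copy gene set, not the whole genome) — graph-based
decorrelation across ontology terms is out of scope and results are labeled
classical to avoid implying otherwise. Ontology propagation of
term-to-gene maps is likewise the caller's responsibility.

## Numerical choices and degenerate inputs

* Posterior vectors are normalized per column; validation requires them to
  sum to 1 within $10^{-8}$, and model invariants hold to $10^{-10}$ or
  better (tested).
* Likelihood columns are rescaled by their maximum at every internal node,
  so alignments of hundreds of taxa would not underflow.
* Supports on a 0–100 scale are divided by 100 at parse time, making the
  0.95 threshold scale-free.
* A zero-column alignment after masking, or an orthogroup dropped by
  cleaning or delineation, is a logged, skipped outcome — never an error
  that aborts a run; per-orthogroup failures are logged with a reason.
* The pipeline uses no random numbers, so reruns under a fixed
  configuration are byte-identical (tested); simulation seeds are split
  deterministically per stage and orthogroup.

## Problem sizes

The validation suite chooses sizes where exhaustive oracles are feasible
and informative: all two-state patterns on all four-leaf shapes plus random
five-leaf amino-acid cases for the pruning oracle; four-leaf trees for the
Bayes ASR oracle; trees of up to 12 leaves for the delineation oracle (100
random trees); 200-site alignments with 10 planted sites for recovery;
2,000 replicates of 50-site alignments for null calibration; and a
20-orthogroup synthetic study for the end-to-end workflow. These scales
exercise every code path the method has; the per-orthogroup machinery is
dimension-independent and the pipeline is linear in orthogroups.

## Known limitations

* Substitutions are assessed on terminal foreground branches only; internal
  foreground branches (e.g. shared ancestors of two foreground taxa) are
  out of scope, matching a species-level foreground definition.
* Agreement with other marginal-reconstruction implementations on real data
  is expected but not guaranteed, since their model and rate choices are
  configurable and sometimes undocumented.
* The block-masking dialect preserves the published parameters but not the
  original program's unpublished tie handling; masked column sets can
  differ in edge cases.
* Branch-site model fitting, gene-family birth–death rate estimation, GO
  graph algorithms, alignment computation and tree inference are external
  to this package by design: their outputs are inputs here.
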