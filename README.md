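# convscan

Genome-wide detection of convergent amino acid substitutions in lineages
that share a derived phenotype.

When distantly related lineages independently evolve the same trait — the
motivating case is insects from three orders (a butterfly, a true bug and a
beetle) that all tolerate toxic cardiac glycosides — part of the answer may
be written in their proteins as *convergent substitutions*: sites where the
foreground lineages independently arrived at the exact same derived amino
acid that no other sampled taxon carries. `convscan` is an R package for
running that scan end to end on per-orthogroup protein alignments and gene
trees, aimed at molecular evolution researchers who have orthology,
alignment and tree inference done elsewhere and need the downstream scan to
be transparent, deterministic and testable.

## What it computes

For each site of each single-copy ortholog alignment, and each terminal
foreground branch, a substitution is inferred when the marginal
maximum-likelihood ancestral state at the branch's parent differs from the
tip residue. Under a reversible amino-acid model with exchangeabilities
*S* and stationary frequencies *π* (rate matrix *Q*<sub>ij</sub> =
*S*<sub>ij</sub>*π*<sub>j</sub>, normalized so branch lengths are expected
substitutions/site), ancestral posteriors are computed by inside–outside
pruning passes. A site is called when ≥ 2 foreground branches substitute to
the **same** derived amino acid — from the same ancestral state
(*parallel*), all-different states (*convergent*) or a mixture — and, under
the default exclusivity rule, no non-foreground tip carries that residue
while at least two have data at the site.

Around the scan sit the stages such an analysis needs:

* **QC filters** — premature-stop exclusion, sequence cleaning
  (`-m 20 -p 0.30 -t 2`), deterministic conserved-block masking
  (`b3 = 2, b4 = 5`, gap mode half), 90%-missing exclusion, and
  backtranslation of protein alignments to codon alignments, all with
  original-coordinate bookkeeping.
* **Ortholog delineation** — maximal gene-tree clades with support ≥ 0.95
  and ≥ 4 species, in-paralogs collapsed; single-copy selection (exactly
  one copy per target species, ≥ 2 outgroups); >100-member family-size
  filter.
* **Statistics** — branch-site LRT p-values under the 50:50
  χ²₁/point-mass mixture null, Benjamini–Hochberg FDR, and classical
  hypergeometric enrichment against a custom (single-copy) background.
* **A simulator** — sequence evolution along any tree under LG/WAG/JTT or
  custom PAML-format matrices, with planted convergent sites, injected QC
  contaminants, truth manifests, and Monte-Carlo neutral nulls for
  convergence counts.

## A worked example

Two foreground bugs reach asparagine from different ancestral residues
(serine on one side, valine on the other), while six outgroups carry S, V
or G — the classic different-ancestor, same-derived pattern:

```r
library(convscan)

tree <- parse_newick(paste0(
  "(((bugA:0.1,out1:0.02,out2:0.02)0.99:0.2,",
  "(bugB:0.1,out3:0.02,out4:0.02)0.99:0.2)0.99:0.1,",
  "(out5:0.1,out6:0.1)0.99:0.1)0.99;"))
aln <- msa(c("bugA","out1","out2","bugB","out3","out4","out5","out6"),
           c("NKLMS","SKLMS","SKLMS","NKLMS","VKLMS","VKLMS","GKLMS","GKLMS"))

model <- load_model("LG", frequencies = aln)   # LG with +F frequencies
asr   <- marginal_asr(tree, aln, model)
hits  <- scan_identical(tree, asr, aln, foreground = c("bugA", "bugB"))
hits[, c("site","foreground","anc_states","derived","class","exclusive")]
#>   site foreground anc_states derived      class exclusive
#> 1    1  bugA,bugB        S,V       N convergent      TRUE
```

Site 1 is called: both foreground branches substituted to N (`S→N` and
`V→N`, hence class `convergent`), no outgroup carries N, and the reported
coordinate refers to the original alignment even after masking. The other
four columns are identical across taxa and produce nothing.

## The analysis workflow

The `analysis/` directory holds the numbered drivers of the full synthetic
study (run them in order from the repository root; outputs land in
`results/`):

| script | what it does |
| --- | --- |
| `01_simulate_dataset.R` | 20 ground-truthed orthogroups on the 9-taxon design, 5 with planted three-way convergence, 2 with grafted in-paralogs |
| `02_run_scan.R` | the full pipeline: QC → delineation → ASR → scan → summary |
| `03_evaluate_recovery.R` | sensitivity against the truth manifest, split by planting mode and by survival of block masking |
| `04_null_calibration.R` | Monte-Carlo neutral null vs. the exact expectation from exhaustive site-pattern enumeration |
| `05_selection_stats.R` | mixture-LRT p-values, FDR and enrichment on simulated branch-site fits |

`run_pipeline()` drives the same workflow from a YAML or list config on any
directory of `<orthogroup>.faa` / `<orthogroup>.nwk` (+ optional `.fna`)
files with a `species_map.tsv`; reruns under a fixed config are
byte-identical.

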