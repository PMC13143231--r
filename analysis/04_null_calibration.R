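#!/usr/bin/env Rscript
## Neutral-convergence null: how many identical-method calls does purely
## neutral substitution produce? On a four-taxon two-state configuration the
## exact expectation is computable by enumerating all site patterns; the
## Monte-Carlo null (simulate -> reconstruct -> scan) should agree. This is
## the quantitative form of the standard caveat that stochastic neutral
## events inflate apparent convergence.

library(convscan)

cfg <- default_null_config(n_sites = 50L, seed = 11L)

## exact expectation by exhaustive site-pattern enumeration
tips <- cfg$tree$tip_labels
grid <- expand.grid(rep(list(cfg$model$states), 4), stringsAsFactors = FALSE)
names(grid) <- tips
p_hit <- 0
for (i in seq_len(nrow(grid))) {
  pattern <- unlist(grid[i, ])
  x <- msa(tips, unname(pattern))
  prob <- site_likelihood(cfg$tree, stats::setNames(pattern, tips), cfg$model)
  a <- marginal_asr(cfg$tree, x, cfg$model)
  r <- scan_identical(cfg$tree, a, x, cfg$foreground)
  p_hit <- p_hit + prob * nrow(r)
}
exact <- cfg$n_sites * p_hit

nd <- null_convergence_distribution(cfg, n_reps = 1000)
se <- stats::sd(nd$counts) / sqrt(nd$n_reps)

out <- data.frame(
  n_sites = cfg$n_sites, n_reps = nd$n_reps,
  exact_expectation = exact, mc_mean = nd$mean, mc_se = se,
  z = (nd$mean - exact) / se,
  q025 = nd$quantiles[[1]], median = nd$quantiles[[2]],
  q975 = nd$quantiles[[3]])
utils::write.table(out, "results/null_calibration.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat(sprintf("exact expected calls per %d-site alignment: %.4f\n",
            cfg$n_sites, exact))
cat(sprintf("Monte-Carlo mean over %d replicates:        %.4f (se %.4f)\n",
            nd$n_reps, nd$mean, se))
cat(sprintf("z against the exact value:                  %.2f\n",
            (nd$mean - exact) / se))
cat(sprintf("null 95%% interval of per-alignment counts:  [%g, %g]\n",
            nd$quantiles[[1]], nd$quantiles[[3]]))
cat("even with zero planted convergence, neutral substitution alone",
    "produces calls at this rate; observed counts should be judged",
    "against it.\n")
cat("table written to results/null_calibration.tsv\n")
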