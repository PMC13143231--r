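## Eight-taxon fixture: two foreground tips (fgA, fgB) whose clades carry
## clearly reconstructable but different ancestral states (S and V), both
## derived to N -- the same-or-different-ancestor to same-derived pattern.
scan_fixture <- function(fgA = "N", fgB = "N", o3 = "G", o4 = "G") {
  txt <- paste0(
    "(((fgA:0.1,o1:0.02,o5:0.02)0.9:0.2,",
    "(fgB:0.1,o2:0.02,o6:0.02)0.9:0.2)0.9:0.1,",
    "(o3:0.1,o4:0.1)0.9:0.1)0.9;")
  tr <- parse_newick(txt)
  pat <- c(fgA = fgA, o1 = "S", o5 = "S", fgB = fgB, o2 = "V", o6 = "V",
           o3 = o3, o4 = o4)
  x <- msa(names(pat), unname(pat))
  m <- load_model("LG")
  list(tree = tr, msa = x, asr = marginal_asr(tr, x, m), model = m)
}

test_that("branch substitutions report parent-MAP versus tip differences", {
  f <- scan_fixture()
  sub <- branch_substitutions(f$tree, f$asr, f$msa, "fgA", 1)
  expect_equal(sub$ancestral, "S")
  expect_equal(sub$derived, "N")
  expect_gt(sub$posterior, 0.5)
  ## no substitution when tip matches its reconstructed ancestor
  expect_null(branch_substitutions(f$tree, f$asr, f$msa, "o1", 1))
  ## missing tip residue yields no substitution
  g <- scan_fixture(fgA = "-")
  expect_null(branch_substitutions(g$tree, g$asr, g$msa, "fgA", 1))
  expect_error(branch_substitutions(f$tree, f$asr, f$msa, "fgA", 99),
               "out of range")
})

test_that("different-ancestor same-derived sites are called convergent", {
  f <- scan_fixture()
  rec <- scan_identical(f$tree, f$asr, f$msa, c("fgA", "fgB"))
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$class, "convergent")
  expect_equal(rec$anc_states, "S,V")
  expect_equal(rec$derived, "N")
  expect_true(rec$exclusive)
  expect_equal(rec$n_outgroup_residues, 6L)
})

test_that("outgroup sharing of the derived state breaks exclusivity", {
  f <- scan_fixture(o3 = "N")
  rec_strict <- scan_identical(f$tree, f$asr, f$msa, c("fgA", "fgB"),
                               require_exclusive = TRUE)
  expect_equal(nrow(rec_strict), 0L)
  rec_loose <- scan_identical(f$tree, f$asr, f$msa, c("fgA", "fgB"),
                              require_exclusive = FALSE)
  expect_equal(nrow(rec_loose), 1L)
  expect_false(rec_loose$exclusive)
})

test_that("all-constant alignments yield no records", {
  tr <- default_scan_tree()
  x <- msa(tr$tip_labels, rep(strrep("K", 10), tr$n_tip))
  asr <- marginal_asr(tr, x, load_model("LG"))
  rec <- scan_identical(tr, asr, x, c("fg1", "fg2", "fg3"))
  expect_equal(nrow(rec), 0L)
})

test_that("a three-way hit is emitted once, not as its pairwise sub-hits", {
  m <- load_model("LG")
  tr <- default_scan_tree()
  fg <- c("fg1", "fg2", "fg3")
  cfg <- sim_config(tr, m, n_sites = 40, seed = 6, foreground = fg,
                    planted_sites = data.frame(
                      site = 7, subset = "fg1,fg2,fg3", derived = "W",
                      mode = "parallel", exclusive = TRUE))
  sim <- plant_convergence(simulate_alignment(cfg), cfg)
  asr <- marginal_asr(tr, sim$msa, m)
  rec <- scan_identical(tr, asr, sim$msa, fg)
  at7 <- rec[rec$site == 7, ]
  expect_equal(nrow(at7), 1L)
  expect_equal(at7$foreground, "fg1,fg2,fg3")
  expect_equal(at7$class, "parallel")
})

test_that("exclusivity and posterior thresholds are monotone restrictions", {
  m <- load_model("LG")
  tr <- default_scan_tree()
  fg <- c("fg1", "fg2", "fg3")
  key <- function(df) paste(df$site, df$foreground, df$derived)
  for (seed in c(21, 22)) {
    cfg <- sim_config(tr, m, n_sites = 150, seed = seed, foreground = fg)
    sim <- simulate_alignment(cfg)
    asr <- marginal_asr(tr, sim$msa, m)
    strict <- scan_identical(tr, asr, sim$msa, fg, require_exclusive = TRUE)
    loose <- scan_identical(tr, asr, sim$msa, fg, require_exclusive = FALSE)
    expect_true(all(key(strict) %in% key(loose)))
    lo <- scan_identical(tr, asr, sim$msa, fg, require_exclusive = FALSE,
                         min_anc_posterior = 0)
    hi <- scan_identical(tr, asr, sim$msa, fg, require_exclusive = FALSE,
                         min_anc_posterior = 0.9)
    expect_true(all(key(hi) %in% key(lo)))
    ## maximal-subset emission: no record's subset is contained in another's
    ## at the same site with the same derived state
    if (nrow(loose) > 1) {
      for (i in seq_len(nrow(loose))) for (j in seq_len(nrow(loose))) {
        if (i == j) next
        if (loose$site[i] != loose$site[j]) next
        if (loose$derived[i] != loose$derived[j]) next
        si <- strsplit(loose$foreground[i], ",")[[1]]
        sj <- strsplit(loose$foreground[j], ",")[[1]]
        expect_false(all(si %in% sj) && length(si) < length(sj))
      }
    }
  }
})

test_that("foreground taxa must exist in tree and alignment", {
  f <- scan_fixture()
  expect_error(scan_identical(f$tree, f$asr, f$msa, c("fgA", "nope")),
               "absent")
})

test_that("scan summaries count sites and distinct genes per subset", {
  fg <- c("fg1", "fg2", "fg3")
  empty <- summarize_scan(empty_site_records <- data.frame(
    orthogroup = character(0), site = integer(0), foreground = character(0),
    anc_states = character(0), anc_posteriors = character(0),
    derived = character(0), class = character(0), exclusive = logical(0),
    n_outgroup_residues = integer(0)), fg)
  expect_true(all(empty$n_sites_exact == 0))
  expect_equal(nrow(empty), 4L)  # three pairs + the triple

  rec <- data.frame(
    orthogroup = c("g1", "g1", "g2", "g3"),
    site = c(5L, 9L, 5L, 2L),
    foreground = c("fg1,fg2", "fg1,fg2", "fg1,fg2", "fg1,fg2,fg3"),
    anc_states = "S,V", anc_posteriors = "1,1", derived = "N",
    class = "convergent", exclusive = TRUE, n_outgroup_residues = 2L,
    stringsAsFactors = FALSE)
  s <- summarize_scan(rec, fg)
  pair <- s[s$subset == "fg1+fg2", ]
  expect_equal(pair$n_sites_exact, 3L)
  expect_equal(pair$n_genes_exact, 2L)
  ## the triple also counts for each pair under the inclusive convention
  expect_equal(pair$n_sites_inclusive, 4L)
  expect_equal(pair$n_genes_inclusive, 3L)
  triple <- s[s$subset == "fg1+fg2+fg3", ]
  expect_equal(triple$n_sites_exact, 1L)
  expect_equal(triple$n_genes_exact, 1L)
})
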