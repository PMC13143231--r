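fg3 <- c("fg1", "fg2", "fg3")

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(default_scan_tree(), load_model("LG"), n_sites = 50,
                    seed = 77, foreground = fg3)
  a <- simulate_alignment(cfg)
  b <- simulate_alignment(cfg)
  expect_identical(a$msa$mat, b$msa$mat)
  expect_identical(a$truth, b$truth)
  cfg2 <- cfg; cfg2$seed <- 78L
  expect_false(identical(simulate_alignment(cfg2)$msa$mat, a$msa$mat))
})

test_that("zero branch lengths copy the root draw to every tip", {
  tr <- parse_newick("((A:0,B:0)0.9:0,(C:0,D:0)0.9:0)0.9;")
  cfg <- sim_config(tr, two_state_model(), n_sites = 30, seed = 4)
  sim <- simulate_alignment(cfg)
  root <- sim$truth[paste0("n", tr$root), ]
  for (tip in tr$tip_labels)
    expect_equal(unname(sim$msa$mat[tip, ]), unname(root))
})

test_that("long branches drive tip frequencies to the stationary dist", {
  tr <- parse_newick("((A:15,B:15)0.9:1,(C:15,D:15)0.9:1)0.9;")
  m <- two_state_model(freqs = c(0.6, 0.4))
  cfg <- sim_config(tr, m, n_sites = 5000, seed = 10)
  sim <- simulate_alignment(cfg)
  freqA <- mean(sim$msa$mat == "A")
  se <- sqrt(0.6 * 0.4 / (4 * 5000))
  expect_lt(abs(freqA - 0.6), 4 * se)
})

test_that("planting honors mode constraints and exclusivity by construction", {
  tr <- default_scan_tree()
  m <- load_model("LG")
  ps <- data.frame(site = seq(5, 95, by = 10),
                   subset = "fg1,fg2,fg3",
                   derived = rep(c("W", "C"), 5),
                   mode = rep(c("parallel", "convergent"), 5),
                   exclusive = TRUE, stringsAsFactors = FALSE)
  cfg <- sim_config(tr, m, n_sites = 100, seed = 15, foreground = fg3,
                    planted_sites = ps)
  sim <- plant_convergence(simulate_alignment(cfg), cfg)
  expect_equal(nrow(sim$manifest), 10L)
  og_tips <- setdiff(tr$tip_labels, fg3)
  parents <- paste0("n", tr$parent[match(fg3, tr$tip_labels)])
  for (i in seq_len(nrow(sim$manifest))) {
    s <- sim$manifest$site[i]
    d <- sim$manifest$derived[i]
    expect_true(all(sim$msa$mat[fg3, s] == d))
    expect_false(any(sim$msa$mat[og_tips, s] == d))
    anc <- strsplit(sim$manifest$anc_states[i], ",")[[1]]
    expect_false(any(anc == d))
    if (sim$manifest$mode[i] == "parallel") {
      expect_equal(length(unique(anc)), 1L)
    } else {
      expect_equal(length(unique(anc)), 3L)
    }
    ## manifest ancestral states reflect the accepted simulated history
    expect_equal(unname(sim$truth[parents, s]), anc)
  }
})

test_that("non-exclusive planting shares the derived state with an outgroup", {
  tr <- default_scan_tree()
  ps <- data.frame(site = 3, subset = "fg1,fg2,fg3", derived = "W",
                   mode = "parallel", exclusive = FALSE)
  cfg <- sim_config(tr, load_model("LG"), n_sites = 10, seed = 23,
                    foreground = fg3, planted_sites = ps)
  sim <- plant_convergence(simulate_alignment(cfg), cfg)
  og_tips <- setdiff(tr$tip_labels, fg3)
  expect_equal(sum(sim$msa$mat[og_tips, 3] == "W"), 1L)
})

test_that("invalid planting configurations are rejected", {
  tr <- default_scan_tree()
  m <- load_model("LG")
  expect_error(sim_config(tr, m, 10, 1, foreground = fg3,
                          planted_sites = data.frame(
                            site = c(2, 2), subset = "fg1,fg2",
                            derived = "W", mode = "parallel")),
               "distinct")
  expect_error(sim_config(tr, m, 10, 1, foreground = fg3,
                          planted_sites = data.frame(
                            site = 99, subset = "fg1,fg2",
                            derived = "W", mode = "parallel")),
               "n_sites")
  expect_error(sim_config(tr, m, 10, 1, foreground = c("fg1", "nope")),
               "absent")
})

test_that("contaminant injection is exactly caught by the matching filters", {
  tr <- default_scan_tree()
  m <- load_model("LG")
  cfg <- sim_config(tr, m, n_sites = 120, seed = 33, foreground = fg3,
                    contaminants = list(short_seq = 2 / 9, high_missing = 2 / 9,
                                        premature_stop = 0.4))
  sim <- simulate_alignment(cfg)
  inj <- inject_contaminants(sim$msa, cfg)
  counts <- table(inj$manifest$defect)
  expect_equal(as.integer(counts[c("short_seq", "high_missing")]), c(2L, 2L))

  cl <- clean_alignment(inj$msa)
  short_ids <- inj$manifest$id[inj$manifest$defect == "short_seq"]
  expect_setequal(cl$removed$id[cl$removed$reason %in% c("short", "low_coverage")],
                  inj$manifest$id)
  expect_true(all(short_ids %in% cl$removed$id))
  ## high-missing flooding is also caught by the 90% rule on the original
  hm <- drop_high_missing(inj$msa)
  expect_true(all(inj$manifest$id[inj$manifest$defect == "high_missing"]
                  %in% hm$removed$id))

  ## premature stops: exactly the injected records are removed
  codon_of <- c(A="GCT",R="CGT",N="AAT",D="GAT",C="TGT",Q="CAA",E="GAA",
                G="GGT",H="CAT",I="ATT",L="CTT",K="AAA",M="ATG",F="TTT",
                P="CCT",S="TCT",T="ACT",W="TGG",Y="TAT",V="GTT")
  cds <- cds_set(sim$msa$ids, vapply(msa_strings(sim$msa), function(s)
    paste(codon_of[strsplit(s, "")[[1]]], collapse = ""), character(1)))
  injc <- inject_contaminants(cds, cfg)
  expect_equal(nrow(injc$manifest), round(0.4 * 9))
  res <- remove_premature_stops(injc$cds)
  expect_setequal(res$removed$id, injc$manifest$id)

  ## zero rates leave inputs untouched
  cfg0 <- sim_config(tr, m, n_sites = 120, seed = 33, foreground = fg3)
  expect_identical(inject_contaminants(sim$msa, cfg0)$msa$mat, sim$msa$mat)
  expect_equal(nrow(inject_contaminants(sim$msa, cfg0)$manifest), 0L)
})

test_that("in-paralog grafting duplicates tips within the same species", {
  tr <- default_scan_tree()
  g <- graft_inparalog_tips(tr, c("og2", "og5"))
  expect_setequal(setdiff(g$tree$tip_labels, tr$tip_labels),
                  c("og2_dup", "og5_dup"))
  expect_equal(unname(species_of(g$tree, "og2_dup")), "og2")
  ## duplicates collapse during delineation: still one clade of 9 species
  sets <- extract_ortholog_clades(g$tree, min_support = 0.95, min_species = 4)
  expect_length(sets, 1L)
  expect_equal(sets[[1]]$n_species, 9L)
  expect_length(sets[[1]]$members, 11L)
})

test_that("the neutral null is empty without substitutions and scales with sites", {
  ## near-zero branch lengths: no substitutions, no convergence calls
  tr <- parse_newick("((t1:1e-9,t2:1e-9)0.9:1e-9,(t3:1e-9,t4:1e-9)0.9:1e-9)0.9;")
  cfg <- sim_config(tr, two_state_model(), n_sites = 40, seed = 2,
                    foreground = c("t1", "t3"))
  nd <- null_convergence_distribution(cfg, n_reps = 20)
  expect_true(all(nd$counts == 0))

  ## doubling the number of sites doubles the mean count (within MC error)
  cfg1 <- default_null_config(n_sites = 40, seed = 40)
  cfg2 <- default_null_config(n_sites = 80, seed = 80)
  n1 <- null_convergence_distribution(cfg1, n_reps = 400)
  n2 <- null_convergence_distribution(cfg2, n_reps = 400)
  se <- sqrt(stats::var(n2$counts) / 400 + 4 * stats::var(n1$counts) / 400)
  expect_lt(abs(n2$mean - 2 * n1$mean), 4 * se)
  expect_equal(null_empirical_p(n1, 0), 1)
})

test_that("the Monte-Carlo null mean matches exhaustive enumeration", {
  cfg <- default_null_config(n_sites = 30, seed = 55)
  exact <- exact_null_expectation(cfg)
  nd <- null_convergence_distribution(cfg, n_reps = 400)
  se <- stats::sd(nd$counts) / sqrt(nd$n_reps)
  expect_lt(abs(nd$mean - exact), 3 * se)
})

test_that("synthetic datasets are written with a faithful truth manifest", {
  dir <- withr::local_tempdir()
  truth <- write_synthetic_dataset(dir, n_orthogroups = 4, n_planted_genes = 2,
                                   sites_per_gene = 2, n_sites = 40, seed = 9,
                                   inparalog_orthogroups = 4)
  expect_length(list.files(dir, pattern = "\\.faa$"), 4L)
  expect_length(list.files(dir, pattern = "\\.nwk$"), 4L)
  expect_true(file.exists(file.path(dir, "species_map.tsv")))
  expect_equal(nrow(truth$og001), 2L)
  expect_length(truth$og003, 0L)
  ## planted residues really are in the written alignments
  x <- read_fasta(file.path(dir, "og001.faa"), type = "msa")
  for (i in seq_len(nrow(truth$og001)))
    expect_true(all(x$mat[fg3, truth$og001$site[i]] == truth$og001$derived[i]))
  ## the grafted orthogroup has duplicate rows and tree tips
  x4 <- read_fasta(file.path(dir, "og004.faa"), type = "msa")
  expect_true(all(c("og2_dup", "og5_dup") %in% x4$ids))
})
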