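test_that("shipped empirical models satisfy the rate-matrix invariants", {
  for (nm in c("LG", "WAG", "JTT")) {
    m <- load_model(nm)
    expect_equal(sum(m$pi), 1, tolerance = 1e-12)
    expect_lt(max(abs(rowSums(m$Q))), 1e-10)
    expect_equal(-sum(m$pi * diag(m$Q)), 1, tolerance = 1e-10)
    for (t in c(0, 0.01, 0.5, 3, 50)) {
      P <- transition_matrix(m, t)
      expect_true(all(P >= 0))
      expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-10,
                   ignore_attr = TRUE)
    }
  }
})

test_that("+F frequencies from a uniform-composition alignment are uniform", {
  x <- msa("s1", paste(AA_STATES, collapse = ""))
  m <- load_model("LG", frequencies = x)
  expect_equal(m$pi, rep(1 / 20, 20), tolerance = 1e-12)
  expect_match(m$name, "\\+F")
})

test_that("non-amino-acid alphabets work through the same machinery", {
  m <- two_state_model(freqs = c(0.7, 0.3))
  expect_equal(length(m$states), 2L)
  expect_equal(-sum(m$pi * diag(m$Q)), 1, tolerance = 1e-12)
  P <- transition_matrix(m, 0.4)
  expect_equal(m$pi %*% P, t(m$pi), tolerance = 1e-12)  # stationarity
})

test_that("invalid model inputs are rejected", {
  S <- matrix(c(0, 1, 2, 0), 2, 2)  # asymmetric
  expect_error(substitution_model(S, c(0.5, 0.5), states = c("A", "R")),
               "symmetric")
  expect_error(substitution_model(matrix(c(0, 1, 1, 0), 2), c(0.9, 0.3),
                                  states = c("A", "R")), "sum to 1")
})

test_that("degenerate site likelihoods match closed forms", {
  m <- load_model("LG")
  ## two leaves, both branch lengths 0
  tr <- parse_newick("(A:0.0,B:0.0);")
  expect_equal(site_likelihood(tr, c(A = "A", B = "A"), m),
               m$pi[match("A", m$states)], tolerance = 1e-12)
  expect_equal(site_likelihood(tr, c(A = "A", B = "C"), m), 0,
               tolerance = 1e-15)
  ## a fully missing pattern integrates to 1
  expect_equal(site_likelihood(tr, c(A = "-", B = "X"), m), 1,
               tolerance = 1e-10)
})

test_that("pruning equals brute-force summation over ancestral states", {
  m2 <- two_state_model()
  shapes <- c("(((A:0.3,B:0.2)0.9:0.25,C:0.4)0.9:0.15,D:0.5)0.9;",
              "((A:0.3,B:0.2)0.9:0.25,(C:0.4,D:0.1)0.9:0.15)0.9;")
  patterns <- expand.grid(rep(list(c("A", "R")), 4), stringsAsFactors = FALSE)
  for (shape in shapes) {
    tr <- parse_newick(shape)
    total <- 0
    for (i in seq_len(nrow(patterns))) {
      pat <- stats::setNames(unlist(patterns[i, ]), c("A", "B", "C", "D"))
      got <- site_likelihood(tr, pat, m2)
      want <- brute_force_site_lik(tr, pat, m2)
      expect_equal(got, want, tolerance = 1e-10)
      total <- total + got
    }
    expect_equal(total, 1, tolerance = 1e-10)  # pattern probabilities sum to 1
  }

  ## random amino-acid cases on 5-leaf trees
  m <- load_model("LG")
  set.seed(3)
  for (i in 1:6) {
    phy <- ape::rtree(5)
    tr <- phylo_tree(phy)
    pat <- stats::setNames(sample(AA_STATES, 5, replace = TRUE), tr$tip_labels)
    got <- site_likelihood(tr, pat, m)
    want <- brute_force_site_lik(tr, pat, m)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("likelihood is invariant to re-rooting under a reversible model", {
  m <- load_model("WAG")
  set.seed(5)
  for (i in 1:5) {
    phy <- ape::rtree(5)
    pat <- stats::setNames(sample(AA_STATES, 5, replace = TRUE), phy$tip.label)
    x <- msa(names(pat), unname(pat))
    un <- ape::unroot(phy)
    ll <- vapply(phy$tip.label[1:3], function(og) {
      r <- ape::root(un, outgroup = og, resolve.root = TRUE)
      tree_loglik(phylo_tree(r), x, m)
    }, numeric(1))
    expect_lt(max(ll) - min(ll), 1e-8)
  }
})

test_that("marginal ASR matches brute-force Bayes on small trees", {
  ## exhaustive two-state check on a 4-leaf tree
  m2 <- two_state_model()
  tr <- parse_newick("((A:0.3,B:0.2)0.9:0.25,(C:0.4,D:0.1)0.9:0.15)0.9;")
  patterns <- expand.grid(rep(list(c("A", "R")), 4), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(patterns))) {
    pat <- stats::setNames(unlist(patterns[i, ]), c("A", "B", "C", "D"))
    x <- msa(names(pat), unname(pat))
    asr <- marginal_asr(tr, x, m2)
    want <- brute_force_asr(tr, pat, m2)
    for (v in as.character(asr$nodes)) {
      expect_equal(unname(asr$posterior[[v]][, 1]), unname(want[, v]),
                   tolerance = 1e-8)
      expect_equal(sum(asr$posterior[[v]][, 1]), 1, tolerance = 1e-8)
    }
  }

  ## amino-acid spot checks on a 3-leaf tree (closed-form Bayes over root)
  m <- load_model("LG")
  tr3 <- parse_newick("((A:0.2,B:0.3)0.9:0.1,C:0.4)0.9;")
  set.seed(8)
  for (i in 1:5) {
    pat <- stats::setNames(sample(c(AA_STATES, "-"), 3, replace = TRUE),
                           c("A", "B", "C"))
    x <- msa(names(pat), unname(pat))
    asr <- marginal_asr(tr3, x, m)
    want <- brute_force_asr(tr3, pat, m)
    for (v in as.character(asr$nodes))
      expect_equal(unname(asr$posterior[[v]][, 1]), unname(want[, v]),
                   tolerance = 1e-8)
  }
})

test_that("ASR is confident on conserved sites and diffuse on saturated ones", {
  m <- load_model("LG")
  tr <- parse_newick("((A:0.02,B:0.02)0.9:0.02,(C:0.02,D:0.02)0.9:0.02)0.9;")
  x <- msa(c("A", "B", "C", "D"), rep("K", 4))
  asr <- marginal_asr(tr, x, m)
  expect_true(all(asr$map == "K"))
  expect_true(all(asr$map_posterior > 0.99))

  ## very long tip branches: root posterior approaches the stationary dist
  sat <- parse_newick("((A:30,B:30)0.9:0.01,(C:30,D:30)0.9:0.01)0.9;")
  asr2 <- marginal_asr(sat, x, m)
  root <- as.character(sat$root)
  expect_equal(unname(asr2$posterior[[root]][, 1]), m$pi, tolerance = 1e-3)
})

test_that("MAP ties are flagged and broken lexicographically", {
  m2 <- two_state_model(freqs = c(0.5, 0.5))
  tr <- parse_newick("((A:0.3,B:0.3)0.9:0.1,(C:0.3,D:0.3)0.9:0.1)0.9;")
  ## perfectly symmetric pattern: the two cherry nodes mirror each other
  x <- msa(c("A", "B", "C", "D"), c("A", "A", "R", "R"))
  asr <- marginal_asr(tr, x, m2)
  root <- as.character(tr$root)
  expect_true(asr$tie[root, 1])
  expect_equal(unname(asr$map[root, 1]), "A")  # lexicographic tie break
})

test_that("branch-scale fitting recovers truth and scales equivariantly", {
  m <- load_model("LG")
  tr <- default_scan_tree()
  cfg <- sim_config(tr, m, n_sites = 1000, seed = 31,
                    foreground = c("fg1", "fg2", "fg3"))
  sim <- simulate_alignment(cfg)
  c1 <- fit_branch_scale(tr, sim$msa, m)
  expect_gt(c1, 0.5); expect_lt(c1, 2)

  ## data simulated on a doubled tree fits ~2x the scale on the original
  phy2 <- tr$phylo; phy2$edge.length <- phy2$edge.length * 2
  tr2 <- phylo_tree(phy2, species = tr$species)
  cfg2 <- sim_config(tr2, m, n_sites = 1000, seed = 31,
                     foreground = c("fg1", "fg2", "fg3"))
  sim2 <- simulate_alignment(cfg2)
  c2 <- fit_branch_scale(tr, sim2$msa, m)
  expect_gt(c2 / c1, 1.4); expect_lt(c2 / c1, 2.8)

  const <- msa(tr$tip_labels, rep(strrep("K", 30), tr$n_tip))
  expect_warning(cc <- fit_branch_scale(tr, const, m), "constant")
  expect_equal(cc, 1)
})

test_that("gamma rate categories have mean one and spread with shape", {
  r <- discrete_gamma_rates(0.5, 4)
  expect_equal(mean(r), 1, tolerance = 1e-12)
  expect_gt(diff(range(discrete_gamma_rates(0.5, 4))),
            diff(range(discrete_gamma_rates(5, 4))))
  ## gamma model likelihood is the mean over categories
  m <- load_model("LG", gamma_shape = 0.8)
  tr <- parse_newick("((A:0.2,B:0.3)0.9:0.1,C:0.4)0.9;")
  pat <- c(A = "K", B = "K", C = "R")
  per_cat <- vapply(m$rates, function(r) {
    mr <- load_model("LG")
    brute_force_site_lik(tr, pat, mr, scale = r)
  }, numeric(1))
  expect_equal(site_likelihood(tr, pat, m), mean(per_cat), tolerance = 1e-10)
})

test_that("paml .dat parsing validates structure", {
  tmp <- withr::local_tempfile(fileext = ".dat")
  writeLines("0.5 0.5", tmp)
  expect_error(parse_paml_dat(tmp), "210")
  m <- load_model(system.file("extdata", "models", "lg.dat",
                              package = "convscan"))
  expect_equal(m$name, "lg")
  expect_error(load_model("NOPE"), "no shipped model")
})
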