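## Independent oracles: brute-force enumeration implementations used to
## validate the pruning, ASR, delineation and statistics code paths.

## Likelihood of one site pattern by exhaustive summation over all internal
## node state assignments: sum_anc pi(root) * prod_edges P(t)[parent, child].
brute_force_site_lik <- function(tree, pattern, model, scale = 1) {
  states <- model$states
  k <- length(states)
  internals <- (tree$n_tip + 1L):(tree$n_tip + tree$n_node)
  tip_idx <- match(pattern[tree$tip_labels], states)
  Pm <- lapply(seq_len(tree$n_tip + tree$n_node), function(v) {
    if (v == tree$root) return(NULL)
    transition_matrix(model, scale * tree$edge_length[v])
  })
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internals))))
  colnames(grid) <- as.character(internals)
  state_of <- function(v) {
    if (v <= tree$n_tip) rep(tip_idx[v], nrow(grid))
    else grid[, as.character(v)]
  }
  prob <- model$pi[grid[, as.character(tree$root)]]
  for (v in seq_len(tree$n_tip + tree$n_node)) {
    if (v == tree$root) next
    sv <- state_of(v)
    if (v <= tree$n_tip && is.na(tip_idx[v])) next  # missing tip: sums out
    prob <- prob * Pm[[v]][cbind(state_of(tree$parent[v]), sv)]
  }
  sum(prob)
}

## Marginal ancestral posteriors by brute-force Bayes: joint probability of
## each full internal assignment, marginalized per node.
brute_force_asr <- function(tree, pattern, model) {
  states <- model$states
  k <- length(states)
  internals <- (tree$n_tip + 1L):(tree$n_tip + tree$n_node)
  tip_idx <- match(pattern[tree$tip_labels], states)
  Pm <- lapply(seq_len(tree$n_tip + tree$n_node), function(v) {
    if (v == tree$root) return(NULL)
    transition_matrix(model, tree$edge_length[v])
  })
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internals))))
  colnames(grid) <- as.character(internals)
  state_of <- function(v) {
    if (v <= tree$n_tip) rep(tip_idx[v], nrow(grid))
    else grid[, as.character(v)]
  }
  prob <- model$pi[grid[, as.character(tree$root)]]
  for (v in seq_len(tree$n_tip + tree$n_node)) {
    if (v == tree$root) next
    if (v <= tree$n_tip && is.na(tip_idx[v])) next
    prob <- prob * Pm[[v]][cbind(state_of(tree$parent[v]), state_of(v))]
  }
  post <- sapply(as.character(internals), function(v) {
    tapply(prob, factor(grid[, v], levels = seq_len(k)), sum)
  })
  post[is.na(post)] <- 0
  sweep(post, 2L, colSums(post), "/")  # columns = internal nodes
}

## Benjamini-Hochberg q-values straight from the step-up definition.
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m))
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

## Hypergeometric upper-tail p by exhaustive enumeration of all possible
## study-set draws of size n from a background of size N.
brute_force_hyper_p <- function(N, K, n, k) {
  bg <- seq_len(N)
  term <- seq_len(K)
  draws <- utils::combn(bg, n)
  hits <- apply(draws, 2L, function(d) sum(d %in% term))
  mean(hits >= k)
}

## All qualifying ortholog clades by direct enumeration over internal nodes,
## using ape primitives rather than the package's traversal.
brute_force_clades <- function(tree, min_support = 0.95, min_species = 4L,
                               allow_inparalogs = TRUE) {
  phy <- tree$phylo
  n_tip <- tree$n_tip
  internals <- (n_tip + 1L):(n_tip + tree$n_node)
  qualifies <- vapply(internals, function(v) {
    sup <- tree$support[v]
    if (is.na(sup) || sup < min_support) return(FALSE)
    sub <- ape::extract.clade(phy, v)
    labs <- sub$tip.label
    sp <- unname(tree$species[labs])
    if (length(unique(sp)) < min_species) return(FALSE)
    for (s in unique(sp)) {
      stips <- labs[sp == s]
      if (length(stips) == 1L) next
      if (!allow_inparalogs) return(FALSE)
      if (length(stips) == length(labs)) next
      if (!ape::is.monophyletic(sub, stips)) return(FALSE)
    }
    TRUE
  }, logical(1))
  qual_nodes <- internals[qualifies]
  ## maximality: drop nodes with a qualifying strict ancestor
  keep <- vapply(qual_nodes, function(v) {
    p <- tree$parent[v]
    while (!is.na(p)) {
      if (p %in% qual_nodes) return(FALSE)
      p <- tree$parent[p]
    }
    TRUE
  }, logical(1))
  lapply(qual_nodes[keep], function(v)
    sort(ape::extract.clade(phy, v)$tip.label))
}

## Random gene tree with supports, a species map, and optional within-species
## duplicate tips (fixture generator).
random_gene_tree <- function(n_tips = 8L, n_species = 5L, n_dups = 0L) {
  phy <- ape::rtree(n_tips)
  phy$node.label <- as.character(sample(c(0.5, 0.8, 0.9, 0.96, 0.99),
                                        phy$Nnode, replace = TRUE))
  sp <- stats::setNames(paste0("sp", sample(seq_len(n_species), n_tips,
                                            replace = TRUE)),
                        phy$tip.label)
  tr <- phylo_tree(phy, species = sp)
  if (n_dups > 0L) {
    dup <- sample(tr$tip_labels, min(n_dups, n_tips))
    tr <- graft_inparalog_tips(tr, dup)$tree
  }
  tr
}

## Random aligned residue strings over the amino-acid alphabet with gaps.
random_gappy_msa <- function(n_seq = 6L, n_col = 40L, gap_p = 0.15) {
  mat <- matrix(sample(AA_STATES, n_seq * n_col, replace = TRUE), n_seq, n_col)
  mat[matrix(stats::runif(n_seq * n_col) < gap_p, n_seq, n_col)] <- "-"
  msa(paste0("s", seq_len(n_seq)), apply(mat, 1L, paste, collapse = ""))
}

## Exact expected convergent-site count per alignment for a small
## configuration, by enumerating every possible site pattern: probability by
## brute-force summation, scan indicator by applying ASR + scan to the
## single-column pattern.
exact_null_expectation <- function(cfg, require_exclusive = TRUE,
                                   min_outgroup_residues = 2L) {
  tree <- cfg$tree; model <- cfg$model
  states <- model$states
  tips <- tree$tip_labels
  grid <- expand.grid(rep(list(states), length(tips)), stringsAsFactors = FALSE)
  names(grid) <- tips
  p_hit <- 0
  for (i in seq_len(nrow(grid))) {
    pattern <- unlist(grid[i, ])
    prob <- brute_force_site_lik(tree, pattern, model)
    x <- msa(tips, unname(pattern))
    asr <- marginal_asr(tree, x, model)
    rec <- scan_identical(tree, asr, x, cfg$foreground,
                          require_exclusive = require_exclusive,
                          min_outgroup_residues = min_outgroup_residues)
    p_hit <- p_hit + prob * nrow(rec)
  }
  cfg$n_sites * p_hit
}
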