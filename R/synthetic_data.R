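## Sequence-evolution simulator with known ground truth: planted convergent
## sites, QC contaminants, and neutral null distributions of convergence
## counts.

#' Simulation configuration
#'
#' Bundles everything one replicate needs: the tree, the substitution model,
#' the number of sites, the master seed, the foreground taxa, an optional
#' table of sites to plant, and contaminant rates. A single master seed is
#' split deterministically per stage and per replicate (`seed + offset`), so
#' any subset of a run is reproducible in isolation.
#'
#' @param tree a `phylo_tree`.
#' @param model a `substitution_model`.
#' @param n_sites number of alignment columns to simulate.
#' @param seed integer master seed.
#' @param foreground tip labels of the foreground lineages.
#' @param planted_sites optional data frame with columns `site`, `subset`
#'   (comma-joined foreground tip labels), `derived` (single letter),
#'   `mode` (`"parallel"` or `"convergent"`), and optionally `exclusive`
#'   (default `TRUE`; `FALSE` plants the derived residue in one outgroup tip
#'   as well).
#' @param contaminants named list of rates in `[0,1]`: `short_seq`,
#'   `high_missing`, `premature_stop`, `inparalog`.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(tree, model, n_sites, seed,
                       foreground = character(0),
                       planted_sites = NULL,
                       contaminants = list()) {
  stopifnot(inherits(tree, "phylo_tree"), inherits(model, "substitution_model"),
            n_sites >= 1L)
  default_rates <- list(short_seq = 0, high_missing = 0,
                        premature_stop = 0, inparalog = 0)
  contaminants <- utils::modifyList(default_rates, contaminants)
  if (any(unlist(contaminants) < 0 | unlist(contaminants) > 1))
    stop("contaminant rates must lie in [0,1]")
  if (!is.null(planted_sites)) {
    stopifnot(all(c("site", "subset", "derived", "mode") %in% names(planted_sites)))
    if (anyDuplicated(planted_sites$site))
      stop("planted sites must be distinct")
    if (any(planted_sites$site < 1L | planted_sites$site > n_sites))
      stop("planted site outside [1, n_sites]")
    if (!all(planted_sites$mode %in% c("parallel", "convergent")))
      stop("planted mode must be 'parallel' or 'convergent'")
    if (is.null(planted_sites$exclusive)) planted_sites$exclusive <- TRUE
  }
  absent <- setdiff(foreground, tree$tip_labels)
  if (length(absent))
    stop("foreground taxon absent from tree: ", paste(absent, collapse = ", "))
  structure(list(tree = tree, model = model, n_sites = as.integer(n_sites),
                 seed = as.integer(seed), foreground = foreground,
                 planted_sites = planted_sites, contaminants = contaminants),
            class = "sim_config")
}

## Draw states for all nodes; columns = sites. Uses the current RNG stream.
simulate_states <- function(tree, model, n_sites) {
  states <- model$states
  n_all <- tree$n_tip + tree$n_node
  truth <- matrix(NA_character_, n_all, n_sites)
  truth[tree$root, ] <- sample(states, n_sites, replace = TRUE, prob = model$pi)
  for (v in preorder_nodes(tree)) {
    if (v == tree$root) next
    P <- transition_matrix(model, tree$edge_length[v])
    ps <- truth[tree$parent[v], ]
    for (s in unique(ps)) {
      idx <- which(ps == s)
      truth[v, idx] <- sample(states, length(idx), replace = TRUE,
                              prob = P[match(s, states), ])
    }
  }
  rownames(truth) <- c(tree$tip_labels,
                       paste0("n", (tree$n_tip + 1L):n_all))
  truth
}

#' Simulate an alignment along a tree
#'
#' Root states are drawn from the stationary frequencies and each branch
#' evolves by the model's transition probabilities; the full ancestral
#' labeling is returned alongside the tip alignment. Identical seeds give
#' identical output.
#'
#' @param cfg a [sim_config()].
#' @return list with `msa` (tips), `truth` (character matrix, all nodes x
#'   sites; internal rows named `n<index>`), `tree`, `model`.
#' @export
simulate_alignment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  truth <- simulate_states(cfg$tree, cfg$model, cfg$n_sites)
  tips <- truth[cfg$tree$tip_labels, , drop = FALSE]
  x <- msa(rownames(tips), apply(tips, 1L, paste, collapse = ""))
  list(msa = x, truth = truth, tree = cfg$tree, model = cfg$model)
}

#' Plant foreground-convergent substitutions into a simulated alignment
#'
#' For each planted site the foreground tips of the subset are set to the
#' derived amino acid. The site's simulated history must be compatible with
#' the requested mode -- ancestral (parent-of-tip) states all identical and
#' different from the derived residue for `parallel`, pairwise different and
#' all different from the derived residue for `convergent` -- and no
#' foreground tip may already carry the derived residue; otherwise the
#' site's history is re-drawn (up to `max_attempts`). Outgroup tips carrying
#' the derived residue at an exclusive planted site are re-drawn from the
#' stationary frequencies excluding that residue; for a non-exclusive plant
#' one outgroup tip is set to the derived residue instead. Planting edits
#' tip states (truth rows for tips are re-labeled accordingly); ancestral
#' truth refers to the accepted pre-edit history of the site.
#'
#' @param sim result of [simulate_alignment()].
#' @param cfg the [sim_config()] with a non-`NULL` `planted_sites`.
#' @param max_attempts re-draws allowed per site before erroring.
#' @return list as from [simulate_alignment()] plus `manifest`, a data frame
#'   with one row per planted site (`site`, `subset`, `derived`, `mode`,
#'   `exclusive`, `anc_states`).
#' @export
plant_convergence <- function(sim, cfg, max_attempts = 500L) {
  stopifnot(inherits(cfg, "sim_config"), !is.null(cfg$planted_sites))
  set.seed(cfg$seed + 1L)
  tree <- cfg$tree; model <- cfg$model
  truth <- sim$truth
  mat <- sim$msa$mat
  bg_tips <- setdiff(tree$tip_labels, cfg$foreground)
  manifest <- list()
  for (i in seq_len(nrow(cfg$planted_sites))) {
    row <- cfg$planted_sites[i, ]
    s <- row$site
    subset <- sort(strsplit(row$subset, ",")[[1]])
    stopifnot(all(subset %in% cfg$foreground), length(subset) >= 2L)
    parents <- paste0("n", tree$parent[match(subset, tree$tip_labels)])
    d <- row$derived
    ok <- function(col) {
      anc <- col[parents]
      if (any(anc == d)) return(FALSE)
      if (any(col[subset] == d)) return(FALSE)
      if (row$mode == "parallel") length(unique(anc)) == 1L
      else length(unique(anc)) == length(anc)
    }
    attempt <- 0L
    while (!ok(truth[, s])) {
      attempt <- attempt + 1L
      if (attempt > max_attempts)
        stop("could not satisfy '", row$mode, "' planting at site ", s,
             " with derived ", d, " after ", max_attempts, " attempts")
      truth[, s] <- simulate_states(tree, model, 1L)
    }
    anc <- truth[parents, s]
    mat[tree$tip_labels, s] <- truth[tree$tip_labels, s]
    mat[subset, s] <- d
    if (isTRUE(row$exclusive)) {
      clash <- bg_tips[mat[bg_tips, s] == d]
      for (tip in clash) {
        alt <- setdiff(model$states, d)
        mat[tip, s] <- sample(alt, 1L, prob = model$pi[match(alt, model$states)])
      }
    } else {
      tip <- if (length(bg_tips) == 1L) bg_tips else sample(bg_tips, 1L)
      mat[tip, s] <- d
    }
    truth[tree$tip_labels, s] <- mat[tree$tip_labels, s]
    manifest[[length(manifest) + 1L]] <- data.frame(
      site = s, subset = paste(subset, collapse = ","), derived = d,
      mode = row$mode, exclusive = isTRUE(row$exclusive),
      anc_states = paste(anc, collapse = ","), stringsAsFactors = FALSE)
  }
  sim$msa <- new_msa_from_matrix(mat, sim$msa$column_map)
  sim$truth <- truth
  sim$manifest <- do.call(rbind, manifest)
  sim
}

#' Inject quality-control contaminants with a manifest
#'
#' Perturbs records so that each defect is caught by exactly one filter:
#' truncation below 20 residues (`clean_alignment`), gap-flooding above 90
#' percent missing (`drop_high_missing`), or an internal stop codon
#' (`remove_premature_stops`). Counts are `round(rate * n)` records sampled
#' without replacement; a rate of zero leaves the input unchanged.
#'
#' @param x an [msa()] (rates `short_seq`, `high_missing`) or a [cds_set()]
#'   (rate `premature_stop`).
#' @param cfg a [sim_config()] whose `contaminants` rates apply.
#' @param seed optional seed (defaults to `cfg$seed + 2`).
#' @return list with the perturbed object (`msa` or `cds`) and `manifest`
#'   (data frame `id`, `defect`).
#' @export
inject_contaminants <- function(x, cfg, seed = cfg$seed + 2L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  if (inherits(x, "msa")) {
    mat <- x$mat
    n <- nrow(mat); S <- ncol(mat)
    manifest <- list()
    n_short <- round(cfg$contaminants$short_seq * n)
    n_miss <- round(cfg$contaminants$high_missing * n)
    pick <- sample(x$ids, min(n, n_short + n_miss))
    short_ids <- pick[seq_len(min(n_short, length(pick)))]
    miss_ids <- setdiff(pick, short_ids)
    for (id in short_ids) {
      nong <- which(mat[id, ] != "-")
      if (length(nong) > 10L) mat[id, nong[-seq_len(10L)]] <- "-"
      manifest[[length(manifest) + 1L]] <- data.frame(id = id, defect = "short_seq")
    }
    for (id in miss_ids) {
      keep <- ceiling(0.05 * S)
      nong <- which(mat[id, ] != "-")
      if (length(nong) > keep) mat[id, nong[-seq_len(keep)]] <- "-"
      manifest[[length(manifest) + 1L]] <- data.frame(id = id, defect = "high_missing")
    }
    manifest <- if (length(manifest)) do.call(rbind, manifest)
                else data.frame(id = character(0), defect = character(0))
    return(list(msa = new_msa_from_matrix(mat, x$column_map), manifest = manifest))
  }
  if (inherits(x, "cds_set")) {
    seqs <- x$seqs
    n_stop <- round(cfg$contaminants$premature_stop * length(seqs))
    ids <- sample(x$ids, n_stop)
    for (id in ids) {
      s <- seqs[[id]]
      ncod <- nchar(s) %/% 3L
      if (ncod < 3L) next
      at <- max(2L, ncod %/% 2L)   # internal codon
      substr(s, 3L * (at - 1L) + 1L, 3L * at) <- "TAA"
      seqs[[id]] <- s
    }
    manifest <- data.frame(id = ids,
                           defect = rep("premature_stop", length(ids)),
                           stringsAsFactors = FALSE)
    return(list(cds = cds_set(names(seqs), unname(seqs)), manifest = manifest))
  }
  stop("unsupported input class")
}

#' Graft within-species in-paralog duplicate tips into a gene tree
#'
#' Each selected tip is replaced by a cherry of itself and a `<tip>_dup`
#' copy (short internal branches, support 1), emulating a post-speciation
#' duplication; the species map assigns the duplicate to the same species.
#'
#' @param tree a `phylo_tree` with a species map.
#' @param tips tip labels to duplicate.
#' @return list with `tree` (grafted) and `manifest` (data frame `id`,
#'   `defect`).
#' @export
graft_inparalog_tips <- function(tree, tips) {
  stopifnot(inherits(tree, "phylo_tree"), !is.null(tree$species))
  txt <- write_newick(tree)
  sp <- tree$species
  for (tip in tips) {
    stopifnot(tip %in% tree$tip_labels)
    pat <- paste0("([(,])", tip, ":([0-9.eE+-]+)")
    rep <- paste0("\\1(", tip, ":0.01,", tip, "_dup:0.01)1:\\2")
    txt <- sub(pat, rep, txt)
    sp[paste0(tip, "_dup")] <- sp[[tip]]
  }
  list(tree = parse_newick(txt, species = sp),
       manifest = data.frame(id = paste0(tips, "_dup"),
                             defect = rep("inparalog", length(tips)),
                             stringsAsFactors = FALSE))
}

#' Monte-Carlo null distribution of convergent-site counts
#'
#' Simulates neutral (no planting) alignments, reconstructs ancestral states
#' and applies the identical-method scan to each replicate, giving the null
#' distribution of convergence counts that stochastic substitution alone
#' produces -- the empirical check on how often neutral evolution mimics
#' adaptive convergence. The empirical p of an observed count is the
#' fraction of replicates at least as large.
#'
#' @param cfg a [sim_config()] (its `planted_sites` are ignored).
#' @param n_reps number of replicates.
#' @param require_exclusive,min_outgroup_residues,min_anc_posterior passed
#'   to [scan_identical()].
#' @return object of class `null_dist`: `counts` (per replicate), `mean`,
#'   `quantiles`, `n_reps`, `n_sites`.
#' @export
null_convergence_distribution <- function(cfg, n_reps,
                                          require_exclusive = TRUE,
                                          min_outgroup_residues = 2L,
                                          min_anc_posterior = 0) {
  stopifnot(inherits(cfg, "sim_config"), n_reps >= 1L, length(cfg$foreground) >= 2L)
  counts <- integer(n_reps)
  for (r in seq_len(n_reps)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r
    sim <- simulate_alignment(cfg_r)
    asr <- marginal_asr(cfg$tree, sim$msa, cfg$model)
    rec <- scan_identical(cfg$tree, asr, sim$msa, cfg$foreground,
                          require_exclusive = require_exclusive,
                          min_outgroup_residues = min_outgroup_residues,
                          min_anc_posterior = min_anc_posterior)
    counts[r] <- nrow(rec)
  }
  structure(list(counts = counts, mean = mean(counts),
                 quantiles = stats::quantile(counts, c(0.025, 0.5, 0.975)),
                 n_reps = n_reps, n_sites = cfg$n_sites),
            class = "null_dist")
}

#' Empirical p-value of an observed count under a null distribution
#' @param nd a `null_dist`.
#' @param observed observed convergent-site count.
#' @export
null_empirical_p <- function(nd, observed) mean(nd$counts >= observed)

#' @export
print.null_dist <- function(x, ...) {
  cat("null_dist: ", x$n_reps, " replicates, mean count ",
      format(x$mean, digits = 4), "\n", sep = "")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Packaged synthetic study design
## ---------------------------------------------------------------------------

#' Default scan topology: three foreground lineages in separate clades
#'
#' A nine-taxon rooted tree with three foreground taxa (`fg1`-`fg3`), each
#' sister to a different outgroup, plus six outgroups in total; all supports
#' 0.99. Cherry branches are short (0.05) and deeper branches moderate
#' (0.05-0.1), a strong-conservation regime in which ancestral states are
#' confidently reconstructable. Species are identical to tip labels (single
#' copy per species).
#' @export
default_scan_tree <- function() {
  txt <- paste0(
    "(((fg1:0.05,og1:0.05)0.99:0.1,(fg2:0.05,og2:0.05)0.99:0.1)0.99:0.05,",
    "((fg3:0.05,og3:0.05)0.99:0.1,((og4:0.05,og5:0.05)0.99:0.05,og6:0.1)",
    "0.99:0.05)0.99:0.05)0.99;")
  labels <- c("fg1", "fg2", "fg3", paste0("og", 1:6))
  parse_newick(txt, species = stats::setNames(labels, labels))
}

#' Two-state toy substitution model
#'
#' Binary-alphabet model (states `A`/`R` by default) used for exhaustive
#' enumeration checks and null-calibration runs where every site pattern can
#' be enumerated.
#' @param freqs stationary frequencies (length 2).
#' @param states two state labels.
#' @export
two_state_model <- function(freqs = c(0.6, 0.4), states = c("A", "R")) {
  substitution_model(matrix(c(0, 1, 1, 0), 2, 2), freqs,
                     states = states, name = "two_state")
}

#' Default two-foreground null-calibration configuration
#'
#' Four taxa in two cherries, foreground `t1` and `t3` in different cherries,
#' branch lengths 0.3/0.15, two-state model: small enough that the exact
#' expected convergent-site count is computable by enumerating all site
#' patterns.
#' @param n_sites sites per replicate.
#' @param seed master seed.
#' @export
default_null_config <- function(n_sites = 50L, seed = 1L) {
  labels <- paste0("t", 1:4)
  tree <- parse_newick(
    "((t1:0.3,t2:0.3)0.9:0.15,(t3:0.3,t4:0.3)0.9:0.15)0.9;",
    species = stats::setNames(labels, labels))
  sim_config(tree, two_state_model(), n_sites = n_sites, seed = seed,
             foreground = c("t1", "t3"))
}

#' Write a ground-truthed synthetic orthogroup dataset to disk
#'
#' Emits, for each orthogroup, a protein alignment (`<og>.faa`) and a gene
#' tree (`<og>.nwk`), plus a `species_map.tsv` and a `truth.json` manifest
#' recording every planted site. The first `n_planted_genes` orthogroups
#' receive `sites_per_gene` exclusive three-way planted sites (alternating
#' parallel/convergent modes); a configurable set of orthogroups carries
#' grafted in-paralog duplicates on outgroup tips to exercise delineation.
#'
#' @param dir output directory (created).
#' @param n_orthogroups total orthogroups.
#' @param n_planted_genes orthogroups with planted convergence.
#' @param sites_per_gene planted sites per planted orthogroup.
#' @param n_sites alignment columns per orthogroup.
#' @param seed master seed; orthogroup `i` uses `seed + 1000 + i` offsets.
#' @param tree scan topology (default [default_scan_tree()]).
#' @param model substitution model (default LG).
#' @param inparalog_orthogroups indices of orthogroups whose gene trees get
#'   duplicate outgroup tips.
#' @return invisible list with the per-orthogroup truth manifest.
#' @export
write_synthetic_dataset <- function(dir, n_orthogroups = 20L,
                                    n_planted_genes = 5L,
                                    sites_per_gene = 2L,
                                    n_sites = 200L, seed = 1L,
                                    tree = default_scan_tree(),
                                    model = load_model("LG"),
                                    inparalog_orthogroups = integer(0)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fg <- tree$tip_labels[startsWith(tree$tip_labels, "fg")]
  truth <- list()
  species <- tree$species
  for (i in seq_len(n_orthogroups)) {
    og <- sprintf("og%03d", i)
    og_seed <- seed + 1000L * i
    planted <- NULL
    if (i <= n_planted_genes) {
      set.seed(og_seed - 1L)
      sites <- sort(sample(seq_len(n_sites), sites_per_gene))
      planted <- data.frame(
        site = sites,
        subset = rep(paste(fg, collapse = ","), sites_per_gene),
        derived = sample(c("W", "H", "M", "C", "Y"), sites_per_gene,
                         replace = TRUE),
        mode = rep(c("parallel", "convergent"),
                   length.out = sites_per_gene),
        exclusive = TRUE, stringsAsFactors = FALSE)
    }
    cfg <- sim_config(tree, model, n_sites = n_sites, seed = og_seed,
                      foreground = fg, planted_sites = planted)
    sim <- simulate_alignment(cfg)
    if (!is.null(planted)) sim <- plant_convergence(sim, cfg)
    gene_tree <- tree
    x <- sim$msa
    if (i %in% inparalog_orthogroups) {
      dup_tips <- c("og2", "og5")
      grafted <- graft_inparalog_tips(tree, dup_tips)
      gene_tree <- grafted$tree
      strs <- msa_strings(x)
      strs[paste0(dup_tips, "_dup")] <- strs[dup_tips]
      x <- msa(names(strs), unname(strs))
      species[paste0(dup_tips, "_dup")] <- species[dup_tips]
    }
    write_fasta(x, file.path(dir, paste0(og, ".faa")))
    write_newick(gene_tree, file.path(dir, paste0(og, ".nwk")))
    truth[[og]] <- if (is.null(sim$manifest)) list() else sim$manifest
  }
  utils::write.table(
    data.frame(id = names(species), species = unname(species)),
    file.path(dir, "species_map.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(truth)
}
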