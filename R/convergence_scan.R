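## Detection of parallel/convergent amino-acid substitutions on terminal
## foreground branches, with a foreground-exclusivity rule.

#' Substitution on a terminal branch at one site
#'
#' Compares the MAP ancestral state at the parent of a tip with the tip's
#' residue. Returns `NULL` when the two agree, when the tip residue is
#' missing or not a standard amino acid, or when the parent MAP is tied
#' (tied reconstructions disqualify the branch rather than forcing an
#' arbitrary choice).
#'
#' @param tree a `phylo_tree`.
#' @param asr an `asr_table` for `tree` and the same alignment.
#' @param x the [msa()] the ASR was computed from.
#' @param branch a tip label.
#' @param site current (internal) column index.
#' @return `NULL`, or list with `ancestral`, `derived`, `posterior`.
#' @export
branch_substitutions <- function(tree, asr, x, branch, site) {
  stopifnot(inherits(tree, "phylo_tree"), inherits(asr, "asr_table"))
  if (site < 1L || site > ncol(x$mat)) stop("site out of range: ", site)
  tip <- match(branch, tree$tip_labels)
  if (is.na(tip)) stop("tip not in tree: ", branch)
  parent <- as.character(tree$parent[tip])
  derived <- unname(x$mat[branch, site])
  if (!(derived %in% asr$states)) return(NULL)
  if (asr$tie[parent, site]) return(NULL)
  anc <- unname(asr$map[parent, site])
  if (anc == derived) return(NULL)
  list(ancestral = anc, derived = derived,
       posterior = unname(asr$map_posterior[parent, site]))
}

#' Scan an orthogroup for identical convergent substitutions
#'
#' Implements the "identical method": a site is called when two or more
#' foreground terminal branches each carry a substitution (parent MAP state
#' differs from tip residue) to the exact same derived amino acid. The call
#' is classified `parallel` when all ancestral states are identical,
#' `convergent` when all are pairwise different, `mixed` otherwise. With
#' `require_exclusive` the derived amino acid must occur in no non-foreground
#' tip at that site, and at least `min_outgroup_residues` non-foreground tips
#' must have a non-missing residue there for exclusivity to be assessable.
#' Only maximal foreground subsets are emitted: a three-way hit is not also
#' reported as its three pairwise sub-hits.
#'
#' @param tree a `phylo_tree`.
#' @param asr an `asr_table` computed on `tree` and `x`.
#' @param x the [msa()].
#' @param foreground tip labels of the foreground lineages (>= 2).
#' @param require_exclusive drop non-exclusive calls (default `TRUE`).
#' @param min_outgroup_residues minimum non-missing outgroup residues for an
#'   exclusivity call.
#' @param min_anc_posterior minimum MAP posterior of each ancestral state.
#' @param orthogroup orthogroup identifier recorded in the records.
#' @return data frame of convergent-site records (see
#'   [write_site_report()]); `site` is in original alignment coordinates.
#' @export
scan_identical <- function(tree, asr, x, foreground,
                           require_exclusive = TRUE,
                           min_outgroup_residues = 2L,
                           min_anc_posterior = 0,
                           orthogroup = NA_character_) {
  stopifnot(length(foreground) >= 2L)
  absent <- setdiff(foreground, tree$tip_labels)
  if (length(absent))
    stop("foreground taxon absent from tree: ", paste(absent, collapse = ", "))
  absent <- setdiff(foreground, x$ids)
  if (length(absent))
    stop("foreground taxon absent from alignment: ", paste(absent, collapse = ", "))
  foreground <- sort(foreground)
  background <- setdiff(x$ids, foreground)
  S <- ncol(x$mat)
  rows <- list()
  for (s in seq_len(S)) {
    subs <- lapply(foreground, function(b) branch_substitutions(tree, asr, x, b, s))
    names(subs) <- foreground
    ok <- !vapply(subs, is.null, logical(1))
    ok[ok] <- vapply(subs[ok], function(z) z$posterior >= min_anc_posterior,
                     logical(1))
    if (sum(ok) < 2L) next
    derived <- vapply(subs[ok], function(z) z$derived, character(1))
    og_res <- x$mat[background, s]
    og_res <- og_res[!is_missing_residue(og_res)]
    n_checked <- length(og_res)
    for (d in unique(derived)) {
      grp <- names(derived)[derived == d]
      if (length(grp) < 2L) next
      exclusive <- n_checked >= min_outgroup_residues && !(d %in% og_res)
      if (require_exclusive && !exclusive) next
      ancs <- vapply(subs[grp], function(z) z$ancestral, character(1))
      posts <- vapply(subs[grp], function(z) z$posterior, numeric(1))
      cls <- if (length(unique(ancs)) == 1L) "parallel"
             else if (length(unique(ancs)) == length(ancs)) "convergent"
             else "mixed"
      rows[[length(rows) + 1L]] <- data.frame(
        orthogroup = orthogroup,
        site = x$column_map[s],
        foreground = paste(grp, collapse = ","),
        anc_states = paste(ancs, collapse = ","),
        anc_posteriors = paste(formatC(posts, format = "g", digits = 6),
                               collapse = ","),
        derived = d,
        class = cls,
        exclusive = exclusive,
        n_outgroup_residues = n_checked,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_site_records())
  do.call(rbind, rows)
}

#' Summarize a scan by foreground subset
#'
#' Counts detected sites and distinct genes for every foreground subset of
#' size two or more, under both counting conventions: `exact` counts a
#' record only for the subset it was emitted with, while `inclusive` also
#' counts a larger hit for each of its contained subsets (so a three-way
#' site contributes to all three pairs).
#'
#' @param records scan records (possibly pooled over orthogroups).
#' @param foreground foreground tip labels the scan was run with.
#' @return data frame with columns `subset`, `size`, `n_sites_exact`,
#'   `n_genes_exact`, `n_sites_inclusive`, `n_genes_inclusive`.
#' @export
summarize_scan <- function(records, foreground) {
  foreground <- sort(foreground)
  subsets <- list()
  for (sz in 2:length(foreground))
    subsets <- c(subsets, utils::combn(foreground, sz, simplify = FALSE))
  rec_sets <- if (nrow(records)) strsplit(records$foreground, ",") else list()
  genes <- if (nrow(records)) records$orthogroup else character(0)
  do.call(rbind, lapply(subsets, function(ss) {
    exact <- vapply(rec_sets, function(r) setequal(r, ss), logical(1))
    incl <- vapply(rec_sets, function(r) all(ss %in% r), logical(1))
    data.frame(
      subset = paste(ss, collapse = "+"),
      size = length(ss),
      n_sites_exact = sum(exact),
      n_genes_exact = length(unique(genes[exact])),
      n_sites_inclusive = sum(incl),
      n_genes_inclusive = length(unique(genes[incl])),
      stringsAsFactors = FALSE)
  }))
}
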