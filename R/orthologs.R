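## Ortholog clade delineation from gene trees and single-copy selection.

#' Delineate ortholog sets from a rooted gene tree
#'
#' Scans clades root-ward and returns the maximal clades that (i) have
#' support `>= min_support` (unsupported nodes count as support 0 and cannot
#' anchor a clade), (ii) contain each species at most once after collapsing
#' maximal same-species monophyletic tip groups into one operational unit
#' (in-paralogs, when allowed), and (iii) span at least `min_species`
#' distinct species. A qualifying clade nested inside a larger qualifying
#' clade is absorbed by the larger one, so the returned sets are leaf
#' disjoint. Each set reports one representative per species: the longest
#' sequence among in-paralogs when `seq_lengths` is supplied, otherwise the
#' lexicographically first label.
#'
#' @param gene_tree a `phylo_tree` whose leaves carry a species map.
#' @param min_support minimum clade support in `[0,1]`.
#' @param min_species minimum number of distinct species in a clade.
#' @param allow_inparalogs collapse same-species monophyletic tip groups;
#'   when `FALSE` any species with more than one tip disqualifies the clade.
#' @param seq_lengths optional named integer vector of ungapped sequence
#'   lengths used to pick in-paralog representatives.
#' @return list of `ortholog_set` objects.
#' @export
extract_ortholog_clades <- function(gene_tree, min_support = 0.95,
                                    min_species = 4L,
                                    allow_inparalogs = TRUE,
                                    seq_lengths = NULL) {
  stopifnot(inherits(gene_tree, "phylo_tree"))
  if (is.null(gene_tree$species)) stop("leaf without species mapping")
  tr <- gene_tree
  qualifies <- function(node) {
    if (node <= tr$n_tip) return(FALSE)
    sup <- tr$support[node]
    if (is.na(sup) || sup < min_support) return(FALSE)
    tips <- clade_tips(tr, node)
    labs <- tr$tip_labels[tips]
    sp <- species_of(tr, labs)
    if (length(unique(sp)) < min_species) return(FALSE)
    for (s in unique(sp)) {
      stips <- tips[sp == s]
      if (length(stips) == 1L) next
      if (!allow_inparalogs) return(FALSE)
      ## in-paralogs must form one monophyletic tip group inside the clade
      m <- mrca_node(tr, stips)
      if (!setequal(clade_tips(tr, m), stips)) return(FALSE)
    }
    TRUE
  }
  sets <- list()
  visit <- function(node) {
    if (qualifies(node)) {
      sets[[length(sets) + 1L]] <<- build_ortholog_set(
        tr, node, seq_lengths, sprintf("clade_%d", node))
      return(invisible(NULL))
    }
    for (ch in tr$children[[node]]) visit(ch)
  }
  visit(tr$root)
  sets
}

mrca_node <- function(tree, tips) {
  paths <- lapply(tips, function(t) {
    p <- t
    while (!is.na(tree$parent[p[length(p)]])) p <- c(p, tree$parent[p[length(p)]])
    p
  })
  common <- Reduce(intersect, paths)
  common[1L]  # paths are tip-to-root ordered, first common = MRCA
}

build_ortholog_set <- function(tree, node, seq_lengths, id) {
  tips <- clade_tips(tree, node)
  labs <- tree$tip_labels[tips]
  sp <- species_of(tree, labs)
  counts <- table(sp)
  reps <- vapply(unique(sp), function(s) {
    cand <- sort(labs[sp == s])
    if (!is.null(seq_lengths)) {
      len <- seq_lengths[cand]
      len[is.na(len)] <- -1L
      cand <- cand[order(-len, cand)]
    }
    cand[1L]
  }, character(1))
  structure(list(
    orthogroup_id = id,
    node = node,
    members = labs,
    species_counts = stats::setNames(as.integer(counts), names(counts)),
    representatives = reps,
    n_species = length(unique(sp))
  ), class = "ortholog_set")
}

#' @export
print.ortholog_set <- function(x, ...) {
  cat("ortholog_set ", x$orthogroup_id, ": ", length(x$members),
      " sequences, ", x$n_species, " species\n", sep = "")
  invisible(x)
}

#' Retain single-copy orthogroups suitable for convergence analyses
#'
#' Keeps sets with exactly one gene copy in every target species and at
#' least `min_outgroups` distinct non-target species represented.
#'
#' @param sets list of `ortholog_set` objects.
#' @param target_species character vector of foreground species.
#' @param min_outgroups minimum number of distinct outgroup species.
#' @param species_universe all species of the run; defaults to the union of
#'   species seen in `sets`. Target species absent from the universe raise a
#'   configuration error.
#' @return the retained subset of `sets`.
#' @export
select_single_copy <- function(sets, target_species, min_outgroups = 2L,
                               species_universe = NULL) {
  if (is.null(species_universe))
    species_universe <- unique(unlist(lapply(sets, function(s) names(s$species_counts))))
  missing <- setdiff(target_species, species_universe)
  if (length(missing))
    stop("config error: target species not in species universe: ",
         paste(missing, collapse = ", "))
  Filter(function(s) {
    counts <- s$species_counts
    tgt <- counts[target_species]
    tgt[is.na(tgt)] <- 0L
    if (!all(tgt == 1L)) return(FALSE)
    n_og <- length(setdiff(names(counts), target_species))
    n_og >= min_outgroups
  }, sets)
}

#' Exclude oversized gene families
#'
#' Families whose total member count exceeds `max_members` are removed
#' (copy-number variation in very large families makes downstream model
#' estimates uninformative).
#'
#' @param families a numeric matrix or data frame of copy counts
#'   (rows = families, columns = species), or a list of such count vectors.
#' @param max_members families with total count strictly greater than this
#'   are removed.
#' @return `families` with oversized rows/elements removed.
#' @export
family_size_filter <- function(families, max_members = 100L) {
  if (is.matrix(families) || is.data.frame(families)) {
    tot <- rowSums(families)
    families[tot <= max_members, , drop = FALSE]
  } else {
    Filter(function(f) sum(f) <= max_members, families)
  }
}

#' Read an OrthoFinder-style Orthogroups.tsv into a copy-count matrix
#'
#' Expects a tab-separated table whose first column is the orthogroup id and
#' whose remaining columns hold comma-separated gene lists per species.
#'
#' @param path TSV file.
#' @return integer matrix (families x species) of copy counts.
#' @export
read_orthogroup_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  og <- df[[1]]
  counts <- vapply(df[-1], function(col) {
    vapply(col, function(cell) {
      cell <- trimws(cell)
      if (!nzchar(cell)) 0L
      else length(strsplit(cell, ",")[[1]])
    }, integer(1), USE.NAMES = FALSE)
  }, integer(nrow(df)))
  counts <- matrix(counts, nrow = nrow(df),
                   dimnames = list(og, names(df)[-1]))
  counts
}
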