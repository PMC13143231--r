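#' Amino-acid alphabet in the conventional empirical-matrix order
#'
#' The 20 standard one-letter amino-acid codes in the row/column order used
#' by PAML-format empirical matrix files (ARNDCQEGHILKMFPSTWYV).
#' @export
AA_STATES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Symbols treated as missing data at alignment positions
#' @export
MISSING_RESIDUES <- c("-", "X", "*", "?", ".")

is_missing_residue <- function(x) x %in% MISSING_RESIDUES

## ---------------------------------------------------------------------------
## PhyloTree
## ---------------------------------------------------------------------------

#' Rooted phylogenetic tree with supports and a species map
#'
#' Wraps an [ape::read.tree()] `phylo` object and precomputes parent/child
#' indices, per-node branch lengths, normalized internal-node supports and an
#' optional leaf-to-species map. Node indices follow the ape convention: tips
#' `1..n`, root `n+1`, further internal nodes above.
#'
#' @param phy an object of class `phylo` (rooted as read).
#' @param species optional named character vector mapping tip label to
#'   species identifier, or `NULL`.
#' @return an object of class `phylo_tree`.
#' @export
phylo_tree <- function(phy, species = NULL) {
  if (!inherits(phy, "phylo")) stop("`phy` must be an ape 'phylo' object")
  if (anyDuplicated(phy$tip.label))
    stop("validation error: duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  n_tip <- length(phy$tip.label)
  n_node <- phy$Nnode
  n_all <- n_tip + n_node
  if (is.null(phy$edge.length)) phy$edge.length <- rep(0, nrow(phy$edge))
  if (any(phy$edge.length < 0))
    stop("validation error: negative branch length")
  parent <- rep(NA_integer_, n_all)
  edge_length <- rep(NA_real_, n_all)
  children <- vector("list", n_all)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
    parent[ch] <- p
    edge_length[ch] <- phy$edge.length[e]
    children[[p]] <- c(children[[p]], ch)
  }
  root <- n_tip + 1L
  support <- rep(NA_real_, n_all)
  if (!is.null(phy$node.label)) {
    lab <- phy$node.label
    num <- suppressWarnings(as.numeric(lab))
    num[!nzchar(trimws(lab))] <- NA_real_
    ## bootstrap values on a 0-100 scale are normalized to [0,1]
    if (any(num > 1, na.rm = TRUE)) num <- num / 100
    if (any(num < 0 | num > 1, na.rm = TRUE))
      stop("validation error: node supports outside [0,1] after scaling")
    support[(n_tip + 1L):n_all] <- num
  }
  if (!is.null(species)) {
    if (is.null(names(species)))
      stop("`species` must be named by tip label")
    missing_sp <- setdiff(phy$tip.label, names(species))
    if (length(missing_sp))
      stop("leaf without species mapping: ", paste(missing_sp, collapse = ", "))
    species <- species[phy$tip.label]
  }
  structure(list(
    phylo = phy,
    n_tip = n_tip,
    n_node = n_node,
    root = root,
    parent = parent,
    children = children,
    edge_length = edge_length,
    support = support,
    tip_labels = phy$tip.label,
    species = species
  ), class = "phylo_tree")
}

#' Parse a Newick string into a `phylo_tree`
#'
#' Internal-node labels that are numeric are interpreted as support values;
#' values on a 0-100 scale are divided by 100 so the delineation threshold
#' is scale-free.
#'
#' @param text a single rooted Newick string.
#' @param species optional named character vector (tip label -> species).
#' @return a `phylo_tree`.
#' @export
parse_newick <- function(text, species = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy))
    stop("parse error: malformed Newick string")
  phylo_tree(phy, species = species)
}

#' Read a Newick file
#' @param path file containing one Newick tree.
#' @param species optional named character vector or path to a TSV species map.
#' @export
read_newick <- function(path, species = NULL) {
  if (is.character(species) && length(species) == 1L && file.exists(species))
    species <- read_species_map(species)
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""), species = species)
}

#' Serialize a `phylo_tree` to Newick
#'
#' Supports are written back as internal node labels (unit scale);
#' `parse_newick(write_newick(x))` preserves topology, branch lengths and
#' supports.
#'
#' @param tree a `phylo_tree`.
#' @param path optional output file; when `NULL` the Newick string is returned.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo_tree"))
  phy <- tree$phylo
  sup <- tree$support[(tree$n_tip + 1L):(tree$n_tip + tree$n_node)]
  phy$node.label <- ifelse(is.na(sup), "", formatC(sup, format = "g", digits = 10))
  txt <- ape::write.tree(phy, digits = 10)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a two-column (id, species) TSV into a named vector
#' @param path TSV file with columns `id` and `species` (header optional).
#' @export
read_species_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("id", "species") %in% names(df))) {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    names(df)[1:2] <- c("id", "species")
  }
  stats::setNames(as.character(df$species), as.character(df$id))
}

#' Species of each leaf
#' @param tree a `phylo_tree` with a species map.
#' @param labels leaf labels (default all).
#' @export
species_of <- function(tree, labels = tree$tip_labels) {
  if (is.null(tree$species)) stop("tree carries no species map")
  unname(tree$species[labels])
}

#' Restrict a tree to a set of tips
#'
#' Prunes to `labels`, collapsing internal nodes of outdegree one; supports
#' of retained nodes are preserved.
#' @param tree a `phylo_tree`.
#' @param labels tip labels to keep (>= 2).
#' @export
keep_tips <- function(tree, labels) {
  stopifnot(inherits(tree, "phylo_tree"), length(labels) >= 2L)
  missing <- setdiff(labels, tree$tip_labels)
  if (length(missing)) stop("tips not in tree: ", paste(missing, collapse = ", "))
  phy <- tree$phylo
  sup <- tree$support[(tree$n_tip + 1L):(tree$n_tip + tree$n_node)]
  phy$node.label <- ifelse(is.na(sup), "", formatC(sup, format = "g", digits = 10))
  phy2 <- ape::keep.tip(phy, labels)
  sp <- if (!is.null(tree$species)) tree$species[phy2$tip.label] else NULL
  phylo_tree(phy2, species = sp)
}

## Leaf set below each node, as tip indices.
clade_tips <- function(tree, node) {
  if (node <= tree$n_tip) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    kids <- tree$children[[v]]
    tips <- kids[kids <= tree$n_tip]
    out <- c(out, tips)
    stack <- c(stack, kids[kids > tree$n_tip])
  }
  sort(out)
}

## Postorder of all nodes (children before parents).
postorder_nodes <- function(tree) {
  ord <- integer(0)
  walk <- function(v) {
    for (ch in tree$children[[v]]) walk(ch)
    ord <<- c(ord, v)
  }
  walk(tree$root)
  ord
}

preorder_nodes <- function(tree) rev(postorder_nodes(tree))

## ---------------------------------------------------------------------------
## Msa
## ---------------------------------------------------------------------------

#' Construct a multiple sequence alignment object
#'
#' Stores the alignment as a character matrix (rows = records) plus a
#' `column_map` giving, for each current column, its 1-based position in the
#' original input alignment. All masking operations compose through this map,
#' so reported site coordinates always refer to the pre-masking alignment.
#'
#' @param ids unique record identifiers.
#' @param seqs character vector of aligned residue strings (equal length).
#' @param column_map integer vector of original 1-based column indices.
#' @return an object of class `msa`.
#' @export
msa <- function(ids, seqs, column_map = NULL) {
  stopifnot(length(ids) == length(seqs))
  if (anyDuplicated(ids)) stop("validation error: duplicate sequence ids")
  if (length(seqs) == 0L) stop("validation error: empty alignment")
  seqs <- toupper(seqs)
  n <- unique(nchar(seqs))
  if (length(n) != 1L)
    stop("validation error: aligned sequences have unequal lengths")
  mat <- if (n == 0L) matrix(character(0), nrow = length(seqs), ncol = 0L)
         else do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- ids
  if (is.null(column_map)) column_map <- seq_len(n)
  stopifnot(length(column_map) == n)
  if (n > 1L && any(diff(column_map) <= 0L))
    stop("validation error: column_map must be strictly increasing")
  structure(list(ids = ids, mat = mat, column_map = as.integer(column_map),
                 residue_index = residue_index_matrix(mat)),
            class = "msa")
}

## Per-cell index of each residue within its row's ungapped sequence (NA at
## gaps). Computed at construction and carried through column subsetting, so
## masked alignments still know which original residue each cell holds.
residue_index_matrix <- function(mat) {
  idx <- matrix(NA_integer_, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  if (ncol(mat) == 0L) return(idx)
  for (i in seq_len(nrow(mat))) {
    nong <- mat[i, ] != "-"
    idx[i, nong] <- seq_len(sum(nong))
  }
  idx
}

new_msa_from_matrix <- function(mat, column_map, residue_index = NULL) {
  if (is.null(residue_index)) residue_index <- residue_index_matrix(mat)
  structure(list(ids = rownames(mat), mat = mat,
                 column_map = as.integer(column_map),
                 residue_index = residue_index), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("msa: ", nrow(x$mat), " sequences x ", ncol(x$mat), " columns\n", sep = "")
  invisible(x)
}

#' Number of alignment columns
#' @param x an `msa`.
#' @export
n_columns <- function(x) ncol(x$mat)

#' Alignment rows as named strings
#' @param x an `msa`.
#' @export
msa_strings <- function(x) {
  if (ncol(x$mat) == 0L)
    return(stats::setNames(rep("", nrow(x$mat)), x$ids))
  stats::setNames(apply(x$mat, 1L, paste, collapse = ""), x$ids)
}

#' Keep a subset of alignment columns, composing the column map
#' @param x an `msa`.
#' @param idx strictly increasing current column indices to keep.
#' @export
msa_select_columns <- function(x, idx) {
  idx <- as.integer(idx)
  stopifnot(all(idx >= 1L), all(idx <= ncol(x$mat)))
  new_msa_from_matrix(x$mat[, idx, drop = FALSE], x$column_map[idx],
                      x$residue_index[, idx, drop = FALSE])
}

#' Keep a subset of alignment rows
#' @param x an `msa`.
#' @param ids record identifiers to keep.
#' @export
msa_select_rows <- function(x, ids) {
  missing <- setdiff(ids, x$ids)
  if (length(missing)) stop("ids not in alignment: ", paste(missing, collapse = ", "))
  new_msa_from_matrix(x$mat[ids, , drop = FALSE], x$column_map,
                      x$residue_index[ids, , drop = FALSE])
}

drop_allgap_columns <- function(x) {
  if (ncol(x$mat) == 0L || nrow(x$mat) == 0L) return(x)
  keep <- which(colSums(x$mat != "-") > 0L)
  msa_select_columns(x, keep)
}

## ---------------------------------------------------------------------------
## CdsSet
## ---------------------------------------------------------------------------

#' Construct a set of coding sequences
#' @param ids unique identifiers.
#' @param seqs nucleotide strings over `A,C,G,T,N` (lowercase accepted).
#' @return an object of class `cds_set`.
#' @export
cds_set <- function(ids, seqs) {
  stopifnot(length(ids) == length(seqs))
  if (anyDuplicated(ids)) stop("validation error: duplicate sequence ids")
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("validation error: non-ACGTN characters in records: ",
         paste(ids[bad], collapse = ", "))
  structure(list(ids = ids, seqs = stats::setNames(seqs, ids),
                 genetic_code = "standard"), class = "cds_set")
}

#' @export
print.cds_set <- function(x, ...) {
  cat("cds_set: ", length(x$ids), " records\n", sep = "")
  invisible(x)
}

## ---------------------------------------------------------------------------
## FASTA IO
## ---------------------------------------------------------------------------

#' Read a FASTA file
#'
#' Residues are uppercased on read. `type = "msa"` validates that all records
#' have equal length; `type = "cds"` returns a [cds_set()]; `"auto"` decides
#' by alphabet.
#'
#' @param path FASTA file.
#' @param type one of `"auto"`, `"msa"`, `"cds"`.
#' @export
read_fasta <- function(path, type = c("auto", "msa", "cds")) {
  type <- match.arg(type)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (type == "auto") {
    type <- if (all(!grepl("[^ACGTN]", seqs))) "cds" else "msa"
  }
  if (type == "cds") cds_set(ids, seqs) else msa(ids, seqs)
}

#' Write sequences to FASTA
#' @param x an `msa` or `cds_set`.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(x, path, width = 60L) {
  seqs <- if (inherits(x, "msa")) msa_strings(x) else x$seqs
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    if (nchar(s) == 0L) next
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## Site report IO
## ---------------------------------------------------------------------------

site_report_columns <- c("orthogroup", "site", "foreground", "anc_states",
                         "anc_posteriors", "derived", "class", "exclusive",
                         "n_outgroup_residues")

empty_site_records <- function() {
  data.frame(orthogroup = character(0), site = integer(0),
             foreground = character(0), anc_states = character(0),
             anc_posteriors = character(0), derived = character(0),
             class = character(0), exclusive = logical(0),
             n_outgroup_residues = integer(0), stringsAsFactors = FALSE)
}

#' Write convergent-site records to TSV
#'
#' One row per detected site; `site` is the 1-based column in the original
#' (pre-masking) alignment; per-branch ancestral states and posteriors are
#' comma-joined in foreground order.
#'
#' @param records a data frame of convergent-site records (possibly empty).
#' @param path output TSV.
#' @export
write_site_report <- function(records, path) {
  if (is.null(records) || nrow(records) == 0L) records <- empty_site_records()
  stopifnot(all(site_report_columns %in% names(records)))
  utils::write.table(records[, site_report_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Re-read a convergent-site TSV written by [write_site_report()]
#' @param path TSV file.
#' @export
read_site_report <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(orthogroup = "character",
                                         site = "integer",
                                         foreground = "character",
                                         anc_states = "character",
                                         anc_posteriors = "character",
                                         derived = "character",
                                         class = "character",
                                         exclusive = "logical",
                                         n_outgroup_residues = "integer"))
  df
}
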