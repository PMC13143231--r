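## Sequence- and alignment-level quality filters, and backtranslation of
## protein alignments to codon alignments.

translate_codons <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3L == 0L)
  if (n == 0L) return("")
  codons <- substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"   # ambiguous (N-containing) codons
  paste(aa, collapse = "")
}

#' Remove coding sequences with premature stop codons
#'
#' Translates each record in frame 1 under the standard genetic code. A
#' single terminal stop codon is permitted and trimmed; any earlier stop
#' removes the record (reason `"premature_stop"`). Records whose length is
#' not divisible by three are removed with reason `"frame"` rather than
#' raising an error.
#'
#' @param cds a [cds_set()].
#' @return list with elements `cds` (kept records, terminal stops trimmed),
#'   `proteins` (named translations of kept records) and `removed`
#'   (data frame `id`, `reason`).
#' @export
remove_premature_stops <- function(cds) {
  stopifnot(inherits(cds, "cds_set"))
  keep <- character(0); prot <- character(0)
  removed <- list()
  for (id in cds$ids) {
    s <- cds$seqs[[id]]
    if (nchar(s) %% 3L != 0L) {
      removed[[length(removed) + 1L]] <- data.frame(id = id, reason = "frame")
      next
    }
    p <- translate_codons(s)
    if (endsWith(p, "*")) {
      p <- substr(p, 1L, nchar(p) - 1L)
      s <- substr(s, 1L, nchar(s) - 3L)
    }
    if (grepl("*", p, fixed = TRUE)) {
      removed[[length(removed) + 1L]] <- data.frame(id = id, reason = "premature_stop")
      next
    }
    keep[id] <- s
    prot[id] <- p
  }
  removed <- if (length(removed)) do.call(rbind, removed)
             else data.frame(id = character(0), reason = character(0))
  kept <- if (length(keep)) cds_set(names(keep), unname(keep)) else NULL
  list(cds = kept, proteins = prot, removed = removed)
}

#' Clean an alignment by length, coverage and taxon-count rules
#'
#' Removes sequences with fewer than `min_len` non-gap residues, then
#' sequences whose non-gap coverage is below `min_cov`; columns left all-gap
#' are deleted (with the column map updated). If fewer than `min_taxa`
#' sequences remain the alignment is dropped. Defaults (20, 0.30, 2) are the
#' standard filter setting `-m 20 -p 0.30 -t 2`.
#'
#' @param x an [msa()].
#' @param min_len minimum number of non-gap residues per sequence.
#' @param min_cov minimum non-gap fraction per sequence.
#' @param min_taxa minimum number of surviving sequences.
#' @return list with `msa` (cleaned alignment, or `NULL` when dropped),
#'   `dropped` (logical) and `removed` (data frame `id`, `reason`).
#' @export
clean_alignment <- function(x, min_len = 20L, min_cov = 0.30, min_taxa = 2L) {
  stopifnot(inherits(x, "msa"), nrow(x$mat) > 0L)
  nongap <- rowSums(x$mat != "-")
  ncols <- ncol(x$mat)
  cov <- if (ncols > 0L) nongap / ncols else rep(0, nrow(x$mat))
  short <- nongap < min_len
  lowcov <- !short & cov < min_cov
  removed <- data.frame(
    id = c(x$ids[short], x$ids[lowcov]),
    reason = c(rep("short", sum(short)), rep("low_coverage", sum(lowcov))),
    stringsAsFactors = FALSE)
  keep <- x$ids[!(short | lowcov)]
  if (length(keep) < min_taxa) {
    removed <- rbind(removed, data.frame(id = keep, reason = "alignment_dropped"))
    return(list(msa = NULL, dropped = TRUE, removed = removed))
  }
  out <- drop_allgap_columns(msa_select_rows(x, keep))
  list(msa = out, dropped = FALSE, removed = removed)
}

#' Remove sequences with excessive missing data
#'
#' Missing means gap or `X`. With `inclusive = TRUE` (default) a sequence is
#' removed when its missing fraction is `>= max_missing`, i.e. a sequence
#' "with 90 percent missing data" is removed at exactly 0.90.
#'
#' @param x an [msa()].
#' @param max_missing missing-fraction threshold.
#' @param inclusive whether the boundary itself is removed.
#' @return list with `msa` and `removed` (data frame `id`, `reason`).
#' @export
drop_high_missing <- function(x, max_missing = 0.90, inclusive = TRUE) {
  stopifnot(inherits(x, "msa"), nrow(x$mat) > 0L)
  ncols <- ncol(x$mat)
  frac <- if (ncols > 0L) rowSums(x$mat == "-" | x$mat == "X") / ncols
          else rep(0, nrow(x$mat))
  bad <- if (inclusive) frac >= max_missing else frac > max_missing
  removed <- data.frame(id = x$ids[bad],
                        reason = rep("high_missing", sum(bad)),
                        stringsAsFactors = FALSE)
  keep <- x$ids[!bad]
  out <- if (length(keep)) drop_allgap_columns(msa_select_rows(x, keep))
         else new_msa_from_matrix(x$mat[0, , drop = FALSE], integer(0))
  list(msa = out, removed = removed)
}

#' Conserved-block masking of an alignment (explicit dialect)
#'
#' A deterministic block filter in the Gblocks parameter family. Column
#' status is defined by the count of the single most frequent residue
#' (gaps and `X` not counted as residues): `highly_conserved` when the count
#' is `>= b2`, `conserved` when `>= b1`, otherwise `nonconserved`. Under
#' `gap_mode = "half"` a column in which more than `floor(n/2)` sequences are
#' gapped is nonconserved regardless of residue counts ("all" disqualifies
#' any gapped column; "none" ignores gaps). Stretches of more than `b3`
#' contiguous nonconserved columns are removed; each remaining segment is
#' trimmed inward to its first and last highly conserved column; segments
#' shorter than `b4` are removed. The surviving columns (a subsequence of the
#' input, column map updated) are returned. This is a named dialect, not a
#' byte-exact reimplementation of the original program, whose internal tie
#' rules are unpublished; determinism and idempotence are prioritized.
#'
#' @param x an [msa()] with at least 2 sequences.
#' @param b3 maximum length of a kept nonconserved stretch.
#' @param b4 minimum block length.
#' @param gap_mode `"half"`, `"all"` or `"none"`.
#' @param b1 minimum majority-residue count for a conserved column
#'   (default `floor(0.75 n) + 1`).
#' @param b2 minimum count for a highly conserved column
#'   (default `ceiling(0.85 n)`, raised to `b1` if smaller).
#' @return the masked `msa` (possibly 0 columns).
#' @export
mask_blocks <- function(x, b3 = 2L, b4 = 5L,
                        gap_mode = c("half", "all", "none"),
                        b1 = NULL, b2 = NULL) {
  gap_mode <- match.arg(gap_mode)
  stopifnot(inherits(x, "msa"))
  n <- nrow(x$mat)
  stopifnot(n >= 2L)
  if (is.null(b1)) b1 <- floor(n * 0.75) + 1L
  if (is.null(b2)) b2 <- ceiling(n * 0.85)
  b2 <- max(b1, b2)
  if (b1 > n) stop("b1 exceeds the number of sequences")
  S <- ncol(x$mat)
  if (S == 0L) return(x)

  status <- character(S)
  for (j in seq_len(S)) {
    col <- x$mat[, j]
    gaps <- sum(col == "-")
    res <- col[!is_missing_residue(col)]
    m <- if (length(res)) max(table(res)) else 0L
    gap_bad <- switch(gap_mode,
                      half = gaps > floor(n / 2),
                      all  = gaps > 0L,
                      none = FALSE)
    status[j] <- if (gap_bad) "non"
                 else if (m >= b2) "high"
                 else if (m >= b1) "cons"
                 else "non"
  }

  keep <- rep(TRUE, S)
  r <- rle(status == "non")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$lengths))
    if (r$values[i] && r$lengths[i] > b3) keep[starts[i]:ends[i]] <- FALSE

  ## segment pass: trim flanks to highly conserved anchors, enforce b4
  final <- logical(S)
  idx <- which(keep)
  if (length(idx)) {
    breaks <- c(0L, which(diff(idx) > 1L), length(idx))
    for (i in seq_len(length(breaks) - 1L)) {
      seg <- idx[(breaks[i] + 1L):breaks[i + 1L]]
      hc <- seg[status[seg] == "high"]
      if (!length(hc)) next
      seg <- seg[seg >= min(hc) & seg <= max(hc)]
      if (length(seg) >= b4) final[seg] <- TRUE
    }
  }
  msa_select_columns(x, which(final))
}

#' Backtranslate a protein alignment to a codon alignment
#'
#' Each amino-acid column becomes one codon triplet from the matching CDS
#' record; gaps become `---`. Every protein record must have an in-frame CDS
#' whose translation (after terminal-stop trimming) equals the ungapped
#' protein row; a mismatch raises an error naming the record and the first
#' mismatching residue position.
#'
#' @param protein_msa an [msa()] of amino acids.
#' @param cds a [cds_set()] keyed by the same identifiers.
#' @return codon alignment as an `msa` (nucleotide columns; column map gives,
#'   for each nucleotide column, the original protein column it belongs to,
#'   expressed in nucleotide coordinates `3*(col-1)+1..3`).
#' @export
backtranslate <- function(protein_msa, cds) {
  stopifnot(inherits(protein_msa, "msa"), inherits(cds, "cds_set"))
  rows <- msa_strings(protein_msa)
  out <- character(length(rows))
  names(out) <- names(rows)
  for (id in names(rows)) {
    if (!id %in% cds$ids) stop("no CDS record for ", id)
    s <- cds$seqs[[id]]
    if (nchar(s) %% 3L != 0L) stop("CDS length not divisible by 3 for ", id)
    p <- translate_codons(s)
    if (endsWith(p, "*")) {
      p <- substr(p, 1L, nchar(p) - 1L)
      s <- substr(s, 1L, nchar(s) - 3L)
    }
    aligned <- protein_msa$mat[id, ]
    ridx <- protein_msa$residue_index[id, ]
    ptr <- strsplit(p, "")[[1]]
    nong <- which(aligned != "-")
    ## each retained residue must match the CDS translation at its original
    ## (pre-masking) residue position
    bad <- nong[ridx[nong] > length(ptr) | aligned[nong] != ptr[pmin(ridx[nong], length(ptr))]]
    if (length(bad))
      stop("backtranslation mismatch for record ", id, " at position ",
           ridx[bad[1L]])
    if (all(protein_msa$column_map == seq_along(protein_msa$column_map)) &&
        length(nong) && max(ridx[nong]) < length(ptr))
      stop("backtranslation mismatch for record ", id, " at position ",
           max(ridx[nong]) + 1L)
    codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    trip <- ifelse(aligned == "-", "---", codons[ridx])
    out[id] <- paste(trip, collapse = "")
  }
  cm <- as.vector(vapply(protein_msa$column_map,
                         function(c0) 3L * (c0 - 1L) + 1:3, integer(3)))
  msa(names(out), unname(out), column_map = cm)
}
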