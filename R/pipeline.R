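## Orchestration: qc -> delineate -> asr -> scan -> summary, with per-stage
## removal logs and a machine-readable run manifest.

#' Default analysis parameters
#'
#' The standard thresholds used throughout: sequence cleaning `-m 20 -p 0.30
#' -t 2`, block masking `b3 = 2, b4 = 5`, gap mode half, 90 percent missing
#' exclusion, clade support 0.95 with at least four species, single-copy
#' selection with at least two outgroups, family-size cap 100, FDR 0.05.
#' @export
scan_defaults <- function() {
  list(
    min_len = 20L, min_cov = 0.30, min_taxa = 2L,
    b3 = 2L, b4 = 5L, gap_mode = "half",
    max_missing = 0.90,
    min_support = 0.95, min_species = 4L, min_outgroups = 2L,
    allow_inparalogs = TRUE,
    max_family_members = 100L,
    fdr = 0.05,
    require_exclusive = TRUE, min_outgroup_residues = 2L,
    min_anc_posterior = 0,
    model = "LG", plus_f = TRUE, fit_scale = FALSE,
    seed = 1L
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(scan_defaults(), config)
  for (field in c("input_dir", "foreground", "out_dir"))
    if (is.null(cfg[[field]])) stop("config error: missing field '", field, "'")
  cfg$foreground <- unlist(cfg$foreground)  # YAML lists flatten to a vector
  cfg
}

#' Run the full convergence-scan pipeline
#'
#' Reads per-orthogroup protein alignments (`<og>.faa`), gene trees
#' (`<og>.nwk`) and optional coding sequences (`<og>.fna`) from
#' `config$input_dir`, together with a `species_map.tsv`; applies the QC
#' filters in order (premature-stop exclusion, sequence cleaning, block
#' masking, missing-data exclusion), delineates single-copy ortholog sets
#' from the gene trees, reconstructs ancestral states under the configured
#' model, scans for foreground-exclusive identical substitutions and writes
#' the pooled site records, per-subset summary (foreground subsets at the
#' species level), removal log, per-orthogroup status and a JSON run
#' manifest into `config$out_dir`. Rerunning with the same configuration
#' reproduces identical outputs; per-orthogroup failures are logged and
#' skipped rather than aborting the run.
#'
#' @param config a list or path to a YAML file. Required fields:
#'   `input_dir`, `foreground` (species identifiers), `out_dir`. A
#'   `species_map` path may override `<input_dir>/species_map.tsv`. All
#'   thresholds default to [scan_defaults()].
#' @return (invisibly) list with `records`, `summary`, `status`, `log`,
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  faa <- sort(list.files(cfg$input_dir, pattern = "\\.faa$", full.names = TRUE))
  if (!length(faa))
    stop("qc stage: no orthogroup alignments (*.faa) found in ", cfg$input_dir)
  sp_path <- if (!is.null(cfg$species_map)) cfg$species_map
             else file.path(cfg$input_dir, "species_map.tsv")
  if (!file.exists(sp_path))
    stop("qc stage: species map not found: ", sp_path)
  species_map <- read_species_map(sp_path)
  missing_fg <- setdiff(cfg$foreground, unique(species_map))
  if (length(missing_fg))
    stop("config error: foreground species not in species map: ",
         paste(missing_fg, collapse = ", "))

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_rows <- list()
  status_rows <- list()
  all_records <- list()
  note <- function(og, stage, id, reason)
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      orthogroup = og, stage = stage, id = id, reason = reason,
      stringsAsFactors = FALSE)
  finish <- function(og, status, n = 0L)
    status_rows[[length(status_rows) + 1L]] <<- data.frame(
      orthogroup = og, status = status, n_records = n,
      stringsAsFactors = FALSE)

  for (path in faa) {
    og <- tools::file_path_sans_ext(basename(path))
    res <- tryCatch(
      process_orthogroup(og, path, cfg, species_map, note),
      error = function(e) structure(list(message = conditionMessage(e)),
                                    class = "og_failure"))
    if (inherits(res, "og_failure")) {
      note(og, "pipeline", NA_character_, res$message)
      finish(og, "failed")
    } else if (is.character(res)) {
      finish(og, res)
    } else {
      all_records[[og]] <- res
      finish(og, "scanned", nrow(res))
    }
  }

  records <- if (length(all_records)) do.call(rbind, c(all_records, make.row.names = FALSE))
             else empty_site_records()
  summary <- summarize_scan(records, sort(cfg$foreground))
  log_df <- if (length(log_rows)) do.call(rbind, log_rows)
            else data.frame(orthogroup = character(0), stage = character(0),
                            id = character(0), reason = character(0))
  status_df <- do.call(rbind, status_rows)

  write_site_report(records, file.path(cfg$out_dir, "sites.tsv"))
  utils::write.table(summary, file.path(cfg$out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(log_df, file.path(cfg$out_dir, "removal_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(status_df, file.path(cfg$out_dir, "orthogroup_status.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    parameters = cfg[setdiff(names(cfg), c("input_dir", "out_dir", "species_map"))],
    input_dir = cfg$input_dir,
    n_orthogroups_in = length(faa),
    n_orthogroups_scanned = sum(status_df$status == "scanned"),
    status_counts = as.list(table(status_df$status)),
    n_site_records = nrow(records))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  invisible(list(records = records, summary = summary, status = status_df,
                 log = log_df, out_dir = cfg$out_dir))
}

## One orthogroup through qc -> delineation -> asr -> scan. Returns a record
## data frame, or a character status string when the orthogroup drops out.
process_orthogroup <- function(og, faa_path, cfg, species_map, note) {
  x <- read_fasta(faa_path, type = "msa")

  fna_path <- sub("\\.faa$", ".fna", faa_path)
  if (file.exists(fna_path)) {
    cds <- read_fasta(fna_path, type = "cds")
    stops <- remove_premature_stops(cds)
    for (i in seq_len(nrow(stops$removed)))
      note(og, "premature_stop", stops$removed$id[i], stops$removed$reason[i])
    keep <- intersect(x$ids, if (is.null(stops$cds)) character(0) else stops$cds$ids)
    if (length(keep) < 2L) return("dropped_premature_stop")
    x <- drop_allgap_columns(msa_select_rows(x, keep))
  }

  cl <- clean_alignment(x, cfg$min_len, cfg$min_cov, cfg$min_taxa)
  for (i in seq_len(nrow(cl$removed)))
    note(og, "clean_alignment", cl$removed$id[i], cl$removed$reason[i])
  if (cl$dropped) return("dropped_clean")
  x <- cl$msa

  x <- mask_blocks(x, b3 = cfg$b3, b4 = cfg$b4, gap_mode = cfg$gap_mode)
  if (ncol(x$mat) == 0L) {
    note(og, "mask_blocks", NA_character_, "no_conserved_blocks")
    return("dropped_masked_empty")
  }

  hm <- drop_high_missing(x, cfg$max_missing)
  for (i in seq_len(nrow(hm$removed)))
    note(og, "drop_high_missing", hm$removed$id[i], hm$removed$reason[i])
  x <- hm$msa
  if (nrow(x$mat) < 2L) return("dropped_high_missing")

  tree_path <- sub("\\.faa$", ".nwk", faa_path)
  if (!file.exists(tree_path))
    stop("delineation stage: gene tree not found: ", tree_path)
  gene_tree <- read_newick(tree_path)
  tips_in_msa <- intersect(gene_tree$tip_labels, x$ids)
  if (length(tips_in_msa) < max(2L, cfg$min_species)) return("dropped_few_tips")
  gene_tree <- keep_tips(phylo_tree(gene_tree$phylo,
                                    species = species_map[gene_tree$tip_labels]),
                         tips_in_msa)
  x <- msa_select_rows(x, gene_tree$tip_labels)

  seq_lengths <- rowSums(x$mat != "-")
  sets <- extract_ortholog_clades(gene_tree, min_support = cfg$min_support,
                                  min_species = cfg$min_species,
                                  allow_inparalogs = cfg$allow_inparalogs,
                                  seq_lengths = seq_lengths)
  sets <- select_single_copy(sets, cfg$foreground,
                             min_outgroups = cfg$min_outgroups,
                             species_universe = unique(species_map))
  if (!length(sets)) return("dropped_no_single_copy")
  set <- sets[[order(-vapply(sets, function(s) s$n_species, integer(1)))[1L]]]

  reps <- set$representatives
  if (!all(cfg$foreground %in% names(reps))) return("dropped_no_single_copy")
  sub_tree <- keep_tips(gene_tree, unname(reps))
  sub_msa <- msa_select_rows(x, sub_tree$tip_labels)

  model <- load_model(cfg$model,
                      frequencies = if (isTRUE(cfg$plus_f)) sub_msa else NULL)
  scale <- if (isTRUE(cfg$fit_scale))
    suppressWarnings(fit_branch_scale(sub_tree, sub_msa, model)) else 1
  asr <- marginal_asr(sub_tree, sub_msa, model, scale = scale)

  fg_tips <- unname(reps[cfg$foreground])
  records <- scan_identical(sub_tree, asr, sub_msa, fg_tips,
                            require_exclusive = cfg$require_exclusive,
                            min_outgroup_residues = cfg$min_outgroup_residues,
                            min_anc_posterior = cfg$min_anc_posterior,
                            orthogroup = og)
  if (nrow(records)) {
    tip_species <- stats::setNames(names(reps), unname(reps))
    records <- relabel_records_by_species(records, tip_species)
  }
  records
}

## Rewrite record foreground tip labels as species names, keeping the
## per-branch ancestral-state order aligned with the re-sorted subset.
relabel_records_by_species <- function(records, tip_species) {
  for (i in seq_len(nrow(records))) {
    tips <- strsplit(records$foreground[i], ",")[[1]]
    sp <- unname(tip_species[tips])
    ord <- order(sp)
    records$foreground[i] <- paste(sp[ord], collapse = ",")
    for (col in c("anc_states", "anc_posteriors")) {
      parts <- strsplit(records[[col]][i], ",")[[1]]
      records[[col]][i] <- paste(parts[ord], collapse = ",")
    }
  }
  records
}
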