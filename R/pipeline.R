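#' Configure a census pipeline run
#'
#' Exactly one input mode must be active: per-gene mode (`genes` +
#' `metadata` paths) or pre-counted mode (`supplementary` path with an
#' optional column `mapping`). Pre-counted tables carry no per-gene
#' lengths, so the length-profile stage is only available in per-gene mode.
#'
#' @param genes path to a gene annotation TSV (per-gene mode).
#' @param metadata path to an organism metadata TSV (per-gene mode).
#' @param supplementary path to a pre-counted census table.
#' @param mapping column mapping for `supplementary`
#'   (see [read_supplementary_census()]).
#' @param tree optional Newick file for the phylogeny stage.
#' @param out_dir output directory for the report bundle.
#' @param cutoff length cutoff in residues (default 200).
#' @param ternary_step ternary bin step in percent (default 10).
#' @param pairwise_threshold abundance threshold for quadrant fractions
#'   (default 4).
#' @param bandwidth KDE bandwidth in residues, or `"auto"`.
#' @param min_prominence mode-detection prominence fraction (default 0.05).
#' @param seed integer seed recorded in the manifest and used for ternary
#'   boundary resolution.
#' @return object of class `pec_run_config`.
#' @export
pec_run_config <- function(genes = NULL, metadata = NULL,
                           supplementary = NULL, mapping = NULL,
                           tree = NULL, out_dir,
                           cutoff = 200L, ternary_step = 10L,
                           pairwise_threshold = 4L, bandwidth = "auto",
                           min_prominence = 0.05, seed = 1L) {
  gene_mode <- !is.null(genes)
  supp_mode <- !is.null(supplementary)
  if (gene_mode == supp_mode)
    stop("exactly one of 'genes' or 'supplementary' must be given", call. = FALSE)
  if (gene_mode && is.null(metadata))
    stop("per-gene mode requires a 'metadata' table", call. = FALSE)
  for (p in c(genes, metadata, supplementary, tree))
    if (!file.exists(p))
      stop("input file not found: ", p, call. = FALSE)
  structure(
    list(genes = genes, metadata = metadata, supplementary = supplementary,
         mapping = mapping, tree = tree, out_dir = out_dir,
         cutoff = check_count(cutoff, "cutoff", 1L),
         ternary_step = check_count(ternary_step, "ternary_step", 1L),
         pairwise_threshold = check_count(pairwise_threshold,
                                          "pairwise_threshold", 1L),
         bandwidth = bandwidth, min_prominence = min_prominence,
         seed = check_count(seed, "seed", 0L)),
    class = "pec_run_config"
  )
}

#' Run the census pipeline end to end
#'
#' Executes every stage the input mode supports and writes a report bundle
#' of tab-separated tables plus a `manifest.json` recording the parameters,
#' every emitted file, the warning tallies (unmatched organisms, unknown
#' accessions, unbinned niche labels) and any skipped stages. Given the
#' same inputs, configuration and seed, reruns are byte-identical. A stage
#' failure aborts the run with the stage name in the error message.
#'
#' @param config a [pec_run_config()].
#' @return invisibly, a list with the `census`, the `manifest` and the
#'   output `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pec_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  map <- pec_signature_map(length_cutoff = config$cutoff)
  paths <- character(0)
  skipped <- character(0)
  warnings <- list()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  emit <- function(name, df) {
    p <- file.path(config$out_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    paths[[name]] <<- p
    p
  }

  gene_mode <- !is.null(config$genes)
  genes <- NULL
  if (gene_mode) {
    census <- stage("ingest", {
      genes <- read_gene_annotations(config$genes)
      meta <- read_organism_metadata(config$metadata)
      build_census(genes, meta, map)
    })
    diag <- attr(census, "diagnostics")
    warnings$n_genes_unmatched_organism <- nrow(diag$unmatched_organism_genes)
    warnings$n_unknown_accession_hits <-
      sum(as.integer(diag$unknown_accessions))
    warnings$n_multi_family_genes <- diag$n_multi_family
  } else {
    census <- stage("ingest",
                    read_supplementary_census(config$supplementary,
                                              mapping = config$mapping))
  }
  warnings$n_unbinned_o2 <- sum(census_niche_axis(census, "o2") == "unbinned")
  warnings$n_unbinned_temperature <-
    sum(census_niche_axis(census, "temperature") == "unbinned")

  stage("census", {
    emit("census.tsv", as.data.frame(census))
    emit("group_summary_domain.tsv", summarize_by_group(census, "domain"))
    emit("group_summary_phylum.tsv", summarize_by_group(census, "phylum"))
    for (w in c("total", "fd4", "fd2", "fld"))
      emit(sprintf("histogram_%s.tsv", w), abundance_histogram(census, w))
    pairs <- list(c("fld", "fd2"), c("fd4", "fld"), c("fd4", "fd2"))
    quad_rows <- lapply(pairs, function(pr) {
      pw <- pairwise_matrix(census, pr[1], pr[2], config$pairwise_threshold)
      emit(sprintf("pairwise_%s_%s.tsv", pr[1], pr[2]), pw$matrix)
      data.frame(family_a = pr[1], family_b = pr[2],
                 t(pw$quadrants), check.names = FALSE)
    })
    emit("pairwise_quadrants.tsv", do.call(rbind, quad_rows))
    sf <- strategy_fractions(census)
    emit("strategy_fractions.tsv",
         data.frame(strategy = names(sf), fraction = as.numeric(sf)))
    tern <- ternary_bins(census, step = config$ternary_step,
                         seed = config$seed)
    emit("ternary.tsv", tern$bins)
  })

  stage("niche", {
    emit("niche_profile_o2.tsv", niche_profile(census, "o2"))
    emit("niche_profile_temperature.tsv", niche_profile(census, "temperature"))
    for (f in c("fd4", "fd2", "fld")) {
      grid <- niche_grid(census, f)
      long <- expand.grid(temp_class = rownames(grid$values),
                          o2_class = colnames(grid$values),
                          stringsAsFactors = FALSE)
      long$mean_count <- as.vector(grid$values)
      long$display <- as.vector(grid$display)
      long$n_genomes <- as.vector(grid$counts)
      emit(sprintf("niche_grid_%s.tsv", f), long)
    }
    emit("seven_fe_fractions.tsv", seven_fe_fractions(census))
    prof <- ph_profile(census)
    emit("ph_profile.tsv", prof)
    if (nrow(prof) >= 2L) {
      stats <- ph_weighted_comparison(prof)
      p <- file.path(config$out_dir, "ph_stats.json")
      jsonlite::write_json(
        list(families = stats$families, pairs = stats$pairs,
             n_bins = stats$n_bins, weights = stats$weights,
             sd_convention = stats$sd_convention),
        p, auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null")
      paths[["ph_stats.json"]] <- p
    } else {
      skipped <- c(skipped,
                   "ph_stats: fewer than 2 pH bins; comparison not computable")
    }
  })

  if (gene_mode) {
    stage("lengths", {
      lt <- gene_length_table(genes, census, map)
      dens_rows <- list()
      mode_rows <- list()
      for (grp in c("total_pec", "o2_class", "temp_class")) {
        for (f in c("fd4", "fd2", "fld")) {
          dl <- suppressMessages(
            length_density_by(lt, f, grp, bandwidth = config$bandwidth))
          for (d in dl) {
            dens_rows[[length(dens_rows) + 1L]] <-
              data.frame(axis = grp, family = f, group = d$group,
                         grid = d$grid, density = d$density,
                         n_genes = d$n_genes)
            modes <- detect_modes(d, config$min_prominence)
            if (nrow(modes))
              mode_rows[[length(mode_rows) + 1L]] <-
                cbind(data.frame(axis = grp, family = f, group = d$group),
                      modes)
          }
        }
      }
      emit("length_densities.tsv", do.call(rbind, dens_rows))
      emit("length_modes.tsv",
           if (length(mode_rows)) do.call(rbind, mode_rows)
           else data.frame(axis = character(), family = character(),
                           group = character(), position = numeric(),
                           height = numeric(), rel_height = numeric()))
      emit("pdb_reference_summary.tsv", pdb_reference()$summary)
    })
  } else {
    skipped <- c(skipped,
                 "lengths: pre-counted input carries no per-gene lengths")
  }

  if (!is.null(config$tree)) {
    stage("phylo", {
      pruned <- prune_to_census(config$tree, census)
      p <- file.path(config$out_dir, "pruned_tree.nwk")
      ape::write.tree(pruned, file = p)
      paths[["pruned_tree.nwk"]] <- p
      ann <- export_leaf_annotations(
        pruned, census, file = file.path(config$out_dir, "itol_annotations.txt"))
      paths[["itol_annotations.txt"]] <-
        file.path(config$out_dir, "itol_annotations.txt")
      warnings$n_unmatched_tree_tips <-
        length(attr(pruned, "unmatched_tips"))
      invisible(ann)
    })
  } else {
    skipped <- c(skipped, "phylo: no tree supplied")
  }

  manifest <- list(
    mode = if (gene_mode) "per-gene" else "pre-counted",
    parameters = list(cutoff = config$cutoff,
                      ternary_step = config$ternary_step,
                      pairwise_threshold = config$pairwise_threshold,
                      bandwidth = config$bandwidth,
                      min_prominence = config$min_prominence,
                      seed = config$seed),
    n_organisms = nrow(census),
    files = as.list(vapply(paths, basename, character(1))),
    skipped_stages = as.list(skipped),
    warnings = warnings
  )
  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths[["manifest.json"]] <- mpath
  invisible(list(census = census, manifest = manifest, paths = paths))
}
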