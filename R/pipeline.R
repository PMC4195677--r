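# End-to-end orchestration over synthetic or user-provided bundles:
# curation, splice projection, synteny and per-class trees, with plain-text
# reports and a reproducibility manifest.

#' Pipeline configuration
#'
#' Bundles every tunable threshold of the curation, splice and phylo stages;
#' serializable to a plain-text `key = value` file and back without loss.
#'
#' @param curation a [curation_config()].
#' @param splice a [splice_config()].
#' @param phylo_k Jukes-Cantor alphabet size for protein trees.
#' @param seed integer seed recorded in the manifest.
#' @param out_dir output directory.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(curation = curation_config(),
                            splice = splice_config(),
                            phylo_k = 20, seed = 1L, out_dir = "results") {
  structure(list(curation = curation, splice = splice, phylo_k = phylo_k,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as plain text
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return the config (read) or `path` invisibly (write).
#' @export
write_pipeline_config <- function(config, path) {
  kv <- c(
    k_max = config$curation$k_max, max_edits = config$curation$max_edits,
    length_frac = config$curation$length_frac,
    full_frac = config$curation$full_frac,
    rescue_window_nt = config$curation$rescue_window_nt,
    min_n_run = config$curation$min_n_run,
    identity_floor = config$curation$identity_floor,
    min_intron = config$splice$min_intron,
    anchor_floor = config$splice$anchor_floor,
    canonical_policy = config$splice$canonical_policy,
    phylo_k = config$phylo_k, seed = config$seed, out_dir = config$out_dir)
  writeLines(sprintf("%s = %s", names(kv), kv), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, " = ", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  num <- function(k) as.numeric(vals[[k]])
  int <- function(k) as.integer(vals[[k]])
  pipeline_config(
    curation = curation_config(k_max = int("k_max"),
                               max_edits = int("max_edits"),
                               length_frac = num("length_frac"),
                               full_frac = num("full_frac"),
                               rescue_window_nt = int("rescue_window_nt"),
                               min_n_run = int("min_n_run"),
                               identity_floor = num("identity_floor")),
    splice = splice_config(min_intron = int("min_intron"),
                           anchor_floor = num("anchor_floor"),
                           canonical_policy = vals[["canonical_policy"]]),
    phylo_k = num("phylo_k"), seed = int("seed"), out_dir = vals[["out_dir"]])
}

#' Write a curation report as TSV (+ JSON mirror and corrected GFF3)
#'
#' @param report data.frame from [curate_panel()].
#' @param dir output directory.
#' @param prefix file prefix.
#' @return written paths, invisibly.
#' @export
write_curation_report <- function(report, dir, prefix = "curation") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, paste0(prefix, ".tsv"))
  utils::write.table(report, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  json <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(report, json, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  verdicts <- attr(report, "verdicts")
  corrected <- Filter(Negate(is.null),
                      lapply(verdicts, `[[`, "corrected_model"))
  gff <- file.path(dir, paste0(prefix, "_corrected.gff3"))
  if (length(corrected)) {
    status <- vapply(Filter(function(v) !is.null(v$corrected_model),
                            verdicts),
                     function(v) sprintf("curation_status=%s/%s",
                                         v$category, v$subtype), "")
    names(status) <- vapply(corrected, `[[`, "", "gene_id")
    write_gff3(corrected, gff, extra_gene_attrs = status)
  } else writeLines("##gff-version 3", gff)
  invisible(c(tsv, json, gff))
}

#' Run the full pipeline on a template bundle and target bundles
#'
#' Per target: curation TSV/JSON/GFF3, splice-support TSV, synteny event TSV
#' and per-class Newick trees of the curated proteins, plus a run manifest.
#'
#' @param template bundle from [generate_family()].
#' @param targets named list of target bundles (see [evolve_target()]).
#' @param config a [pipeline_config()].
#' @return named list of per-target report file sets, invisibly; reports are
#'   written under `config$out_dir`.
#' @export
run_pipeline <- function(template, targets, config = pipeline_config()) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  ref_map <- bundle_gene_map(template)
  results <- list()
  for (tn in names(targets)) {
    tgt <- targets[[tn]]
    tdir <- file.path(out, tn)
    dir.create(tdir, showWarnings = FALSE, recursive = TRUE)
    plain <- Filter(function(m) is.na(m$transcripts[[1L]]$isoform_tag) ||
                      length(m$transcripts) == 1L, tgt$models)
    rep <- curate_panel(tgt$genome, plain, template$proteins,
                        template$anchors, config$curation)
    files <- write_curation_report(rep, tdir)

    sup <- list()
    for (lab in names(template$isoform_templates)) {
      it <- template$isoform_templates[[lab]]
      tmpl_locus <- template$genome$scaffolds[[it$locus]]
      tgt_locus <- tgt$genome$scaffolds[[it$locus]]
      if (is.null(tgt_locus)) next
      pr <- project_isoforms(it, tmpl_locus, tgt_locus, config$splice)
      s <- pr$support; s$gene <- lab
      sup[[lab]] <- s
    }
    sp_tsv <- file.path(tdir, "splice_support.tsv")
    utils::write.table(
      if (length(sup)) do.call(rbind, sup) else
        data.frame(isoform = character()),
      sp_tsv, sep = "\t", quote = FALSE, row.names = FALSE)

    ev <- call_rearrangements(ref_map, bundle_gene_map(tgt))
    ev_tsv <- file.path(tdir, "synteny_events.tsv")
    utils::write.table(ev, ev_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cat(sprintf("# breakpoints\t%d\n", attr(ev, "breakpoints")),
        file = ev_tsv, append = TRUE)

    trees <- character()
    verdicts <- attr(rep, "verdicts")
    classes <- vapply(plain, `[[`, "", "class_label")
    for (cl in unique(classes)) {
      labs <- vapply(plain[classes == cl], `[[`, "", "ortholog_label")
      prots <- c(
        stats::setNames(unlist(template$proteins[labs]),
                        paste0(template$genome$species_tag, "_", labs)),
        stats::setNames(unlist(tgt$proteins[paste0(
          tgt$genome$species_tag, "_", labs)]), paste0(tn, "_", labs)))
      prots <- prots[nchar(prots) > 0]
      if (length(prots) < 3L) next
      tr <- tryCatch(neighbor_joining(distance_matrix(
        prots, k = config$phylo_k)), error = function(e) NULL)
      if (is.null(tr)) next
      nf <- file.path(tdir, sprintf("tree_%s.nwk", cl))
      writeLines(to_newick(tr), nf)
      trees <- c(trees, nf)
    }
    results[[tn]] <- c(files, sp_tsv, ev_tsv, trees)
  }
  manifest <- file.path(out, "manifest.txt")
  cfg_file <- file.path(out, "config.txt")
  write_pipeline_config(config, cfg_file)
  writeLines(c(
    sprintf("gstcurate %s", as.character(utils::packageVersion("gstcurate"))),
    sprintf("seed %d", config$seed),
    sprintf("config_hash %s", paste0("sum", sum(utf8ToInt(paste(
      readLines(cfg_file), collapse = "\n"))))),
    sprintf("targets %s", paste(names(targets), collapse = ","))),
    manifest)
  invisible(results)
}
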