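## End-to-end orchestration: run the comparative stages over a cohort of
## annotated mitogenomes and write one report bundle. Stages communicate via
## files so each piece remains independently usable; a parse failure of one
## genome is collected and skipped rather than aborting the cohort.

provenance_header <- function(config) {
  ser <- tempfile()
  on.exit(unlink(ser))
  ## hash analytic parameters only, not where the reports happen to go
  config <- config[setdiff(names(config), "out_dir")]
  writeLines(yaml::as.yaml(config[sort(names(config))]), ser)
  h <- unname(tools::md5sum(ser))
  c(sprintf("# mitocompare %s",
            as.character(utils::packageVersion("mitocompare"))),
    sprintf("# config_md5 %s", h),
    sprintf("# date %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")))
}

write_report_tsv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a pipeline configuration
#'
#' @param genomes Character vector of GenBank file paths, or a directory
#'   containing `.gb`/`.gbk`/`.gbf` files.
#' @param out_dir Output directory for the report bundle.
#' @param transl_table Genetic code for codon audits and coding effects.
#' @param junction_pairs List of 2-vectors of gene symbols to type.
#' @param references Named list of reference sequences for intron naming.
#' @param variation_fasta Optional FASTA of near-identical individuals to
#'   align and tally (first record = reference; its annotation is taken from
#'   the genome whose id matches, else the first parsed genome).
#' @param aligned Logical: `variation_fasta` is already aligned.
#' @param band Alignment band half-width.
#' @param tree,states Optional newick path (rooted, branch lengths) and
#'   states TSV path (columns `taxon`, `state`) for ancestral
#'   reconstruction; alternatively pass `character_from = "pattern"` or a
#'   junction pair name (e.g. `"nad2/nad3"`) to derive states from the
#'   parsed cohort.
#' @param character_from How to derive ancestral character states when
#'   `states` is `NULL`.
#' @return List of class `run_config`.
#' @export
run_config <- function(genomes, out_dir, transl_table = 4L,
                       junction_pairs = list(c("nad2", "nad3"),
                                             c("nad4L", "nad5")),
                       references = list(), variation_fasta = NULL,
                       aligned = FALSE, band = 200L, tree = NULL,
                       states = NULL, character_from = "pattern") {
  cfg <- list(genomes = genomes, out_dir = out_dir,
              transl_table = transl_table, junction_pairs = junction_pairs,
              references = references, variation_fasta = variation_fasta,
              aligned = aligned, band = band, tree = tree, states = states,
              character_from = character_from)
  class(cfg) <- "run_config"
  cfg
}

validate_config <- function(config) {
  g <- config$genomes
  if (length(g) == 1L && dir.exists(g)) {
    g <- list.files(g, pattern = "\\.(gb|gbk|gbf|genbank)$", full.names = TRUE)
  }
  if (length(g) == 0L) stop("empty input set: no GenBank files found")
  missing <- g[!file.exists(g)]
  if (length(missing)) stop("input file(s) not found: ",
                            paste(missing, collapse = ", "))
  config$genomes <- g
  config
}

#' Run the comparative mitogenomics pipeline
#'
#' Executes the stages in dependency order - parse, per-genome summary,
#' gene-order pattern classification, junction typing, intron catalog, and
#' optionally intraspecific variation and ancestral-state reconstruction -
#' and writes a TSV report bundle (with provenance headers) into the
#' configured output directory. Genomes that fail to parse are collected in
#' `$errors` and skipped.
#'
#' @param config A [run_config] (or a path to a YAML file of its fields).
#' @return Invisibly, a list with the per-stage results and `errors`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- do.call(run_config, yaml::read_yaml(config))
  }
  stopifnot(inherits(config, "run_config"))
  config <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- provenance_header(unclass(config))
  writeLines(yaml::as.yaml(unclass(config)),
             file.path(config$out_dir, "config.yaml"))

  errors <- character(0)
  genomes <- list()
  for (p in config$genomes) {
    g <- tryCatch(read_genbank(p), error = function(e) e)
    if (inherits(g, "error")) {
      errors <- c(errors, sprintf("%s: %s", p, conditionMessage(g)))
    } else {
      genomes[[g$id]] <- g
    }
  }
  if (length(genomes) == 0L) stop("no genome could be parsed:\n  ",
                                  paste(errors, collapse = "\n  "))

  ## per-genome summary + feature tables
  summaries <- lapply(genomes, region_accounting,
                      transl_table = config$transl_table)
  write_report_tsv(summary_table(unname(summaries)),
                   file.path(config$out_dir, "summary.tsv"), hdr)
  for (g in genomes) {
    write_feature_table(g, file.path(config$out_dir,
                                     sprintf("features_%s.tsv", g$id)))
  }

  ## gene order patterns
  sigs <- lapply(genomes, extract_order, with_trn = TRUE)
  patterns <- classify_patterns(unname(sigs))
  write_report_tsv(pattern_table(patterns),
                   file.path(config$out_dir, "patterns.tsv"), hdr)
  desc <- vapply(patterns, function(p)
    sprintf("pattern %s (n=%d): %s", p$pattern_label, length(p$member_taxa),
            p$description), "")
  writeLines(c(hdr, desc), file.path(config$out_dir, "patterns_description.txt"))
  trn_clusters <- tryCatch(trn_cluster_report(unname(sigs)),
                           error = function(e) NULL)
  if (!is.null(trn_clusters)) {
    write_report_tsv(trn_clusters,
                     file.path(config$out_dir, "trn_clusters.tsv"), hdr)
  }

  ## junction typing
  junction_results <- list()
  jrows <- list()
  for (pair in config$junction_pairs) {
    recs <- lapply(genomes, function(g) {
      tryCatch(junction_interval(g, pair), error = function(e) {
        r <- list(taxon = g$id, upstream_gene = pair[1L],
                  downstream_gene = pair[2L], interval_nt = NA_integer_,
                  flag = conditionMessage(e))
        class(r) <- "junction_record"
        r
      })
    })
    cls <- classify_joining(unname(recs))
    key <- paste(pair, collapse = "/")
    junction_results[[key]] <- cls
    a <- cls$assignments
    a$pair <- key
    jrows[[key]] <- a
  }
  write_report_tsv(do.call(rbind, jrows),
                   file.path(config$out_dir, "junctions.tsv"), hdr)

  ## intron catalog
  introns <- do.call(rbind, lapply(genomes, function(g) {
    ic <- intron_catalog(g, references = config$references,
                         transl_table = config$transl_table)
    if (nrow(ic)) cbind(taxon = g$id, ic) else NULL
  }))
  if (!is.null(introns)) {
    write_report_tsv(introns, file.path(config$out_dir, "introns.tsv"), hdr)
  }

  ## intraspecific variation
  variation <- NULL
  if (!is.null(config$variation_fasta)) {
    seqs <- read_fasta(config$variation_fasta)
    aln <- if (isTRUE(config$aligned)) as_mito_alignment(seqs)
           else align_high_identity(seqs, band = config$band)
    ref_id <- intersect(names(seqs), names(genomes))
    ref <- if (length(ref_id)) genomes[[ref_id[1L]]] else genomes[[1L]]
    variation <- tally_sites(aln, ref, transl_table = config$transl_table)
    write_report_tsv(variation$sites,
                     file.path(config$out_dir, "variation_sites.tsv"), hdr)
    stats_df <- data.frame(
      item = c("n_sequences", "alignment_length", "indel_sites",
               "variable_sites", "divergence_percent",
               "indel_genic", "indel_intergenic", "variable_genic",
               "variable_intergenic", "n_synonymous", "n_nonsynonymous"),
      value = c(variation$n_sequences, variation$alignment_length,
                variation$indel_sites, variation$variable_sites,
                round(variation$divergence_percent, 4),
                variation$indel_genic, variation$indel_intergenic,
                variation$variable_genic, variation$variable_intergenic,
                variation$n_synonymous, variation$n_nonsynonymous))
    write_report_tsv(stats_df, file.path(config$out_dir, "variation.tsv"), hdr)
  }

  ## ancestral reconstruction
  ancestral <- NULL
  if (!is.null(config$tree)) {
    tree <- ape::read.tree(config$tree)
    if (!is.null(config$states)) {
      st <- utils::read.delim(config$states, stringsAsFactors = FALSE)
    } else if (identical(config$character_from, "pattern")) {
      st <- pattern_table(patterns)[, c("taxon", "pattern")]
      names(st) <- c("taxon", "state")
    } else {
      cls <- junction_results[[config$character_from]]
      if (is.null(cls)) stop("no junction results for character_from = ",
                             config$character_from)
      st <- cls$assignments[, c("taxon", "state")]
    }
    est <- estimate_rate(tree, st)
    ancestral <- marginal_ancestral(tree, st, est$rate,
                                    alphabet = est$alphabet)
    write_report_tsv(ancestral$nodes,
                     file.path(config$out_dir, "ancestral.tsv"), hdr)
    write_ancestral_newick(ancestral,
                           file.path(config$out_dir, "ancestral.nwk"))
  }

  out <- list(genomes = genomes, summaries = summaries, patterns = patterns,
              junctions = junction_results, introns = introns,
              variation = variation, ancestral = ancestral, errors = errors,
              out_dir = config$out_dir)
  if (length(errors)) {
    warning("pipeline finished with ", length(errors), " skipped input(s)")
  }
  invisible(out)
}
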