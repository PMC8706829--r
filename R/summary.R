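## Genome-level composition and region accounting: AT content and strand
## skews, the genic/intergenic partition of the molecule, intron totals,
## and a start/stop codon audit of the coding genes.

#' Nucleotide composition of a genome
#'
#' AT percentage and strand skews. Definitions: `at_percent =
#' 100 (A+T)/(A+C+G+T)`, `at_skew = (A-T)/(A+T)`, `gc_skew = (G-C)/(G+C)`.
#' `N` bases are excluded from all denominators (they still count toward
#' genome size). Reports round to 1 decimal for percentages and 2 for skews.
#'
#' @param x A [mito_genome] or a DNA string.
#' @return List with `at_percent`, `at_skew`, `gc_skew` (unrounded).
#' @export
composition <- function(x) {
  s <- if (inherits(x, "mito_genome")) x$sequence else toupper(as.character(x))
  if (!nzchar(s)) stop("sequence is empty")
  cnt <- Biostrings::letterFrequency(Biostrings::DNAString(s),
                                     c("A", "C", "G", "T"))
  a <- cnt[["A"]]; c_ <- cnt[["C"]]; g <- cnt[["G"]]; t <- cnt[["T"]]
  if (a + c_ + g + t == 0) stop("composition undefined: sequence is all N")
  list(
    at_percent = 100 * (a + t) / (a + c_ + g + t),
    at_skew = if (a + t > 0) (a - t) / (a + t) else NA_real_,
    gc_skew = if (g + c_ > 0) (g - c_) / (g + c_) else NA_real_
  )
}

## Genic region of the genome as reduced IRanges (0-based half-open stored as
## 1-based IRanges internally). Gene spans include their introns: the hull of
## each PCG/rRNA/tRNA/free ORF is taken from first to last boundary.
genic_ranges <- function(genome) {
  feats <- Filter(function(f) f$kind %in% GENE_LEVEL_KINDS, genome$features)
  if (length(feats) == 0L) return(IRanges::IRanges())
  pieces <- do.call(rbind, lapply(feats, feature_hull,
                                  genome_length = genome$length_bp))
  IRanges::reduce(IRanges::IRanges(start = pieces[, 1L] + 1L,
                                   end = pieces[, 2L]))
}

#' Is a genome position genic?
#'
#' @param genome A [mito_genome].
#' @param pos Integer vector of 1-based positions.
#' @return Logical vector; `TRUE` where the position falls within the hull of
#'   any gene-level feature (PCG, rRNA, tRNA, free ORF, introns included).
#' @export
is_genic <- function(genome, pos) {
  gr <- genic_ranges(genome)
  IRanges::overlapsAny(IRanges::IRanges(start = pos, width = 1L), gr)
}

#' Region accounting and feature census
#'
#' Computes the composition, the genic/intergenic partition, intron totals,
#' feature counts by kind, and the start/stop codon audit. Genic nucleotides
#' are the union of all gene spans (overlapping genes counted once; introns
#' are inside host spans and therefore included); intergenic is the
#' complement, so `genic_nt + intergenic_nt == size_bp` exactly. Intronic
#' nucleotides total all intron lengths, intronic ORFs included.
#'
#' @param genome A [mito_genome].
#' @param transl_table NCBI genetic code id for the codon audit (default 4,
#'   the mold mitochondrial code).
#' @return An object of class `genome_summary`.
#' @export
region_accounting <- function(genome, transl_table = 4L) {
  L <- genome$length_bp
  comp <- composition(genome)
  gr <- genic_ranges(genome)
  genic_nt <- sum(IRanges::width(gr))
  kinds <- feature_kinds(genome)
  nms <- feature_names(genome)
  introns <- Filter(function(f) f$kind == "intron", genome$features)
  intronic_nt <- as.integer(sum(vapply(introns, function(f) {
    h <- feature_hull(f, L); sum(h[, 2L] - h[, 1L])
  }, numeric(1))))
  core <- sum(kinds == "PCG" & sub("_[0-9]+$", "", nms) %in% CORE_PCGS)
  out <- list(
    id = genome$id,
    size_bp = L,
    at_percent = comp$at_percent,
    at_skew = comp$at_skew,
    gc_skew = comp$gc_skew,
    n_core_pcg = core,
    n_pcg = sum(kinds == "PCG"),
    n_free_orf = sum(kinds == "free_ORF"),
    n_rrna = sum(kinds == "rRNA"),
    n_trna = sum(kinds == "tRNA"),
    n_intron = sum(kinds == "intron"),
    n_intronic_orf = sum(kinds == "intronic_ORF"),
    intronic_nt = intronic_nt,
    genic_nt = genic_nt,
    genic_percent = 100 * genic_nt / L,
    intergenic_nt = L - genic_nt,
    intergenic_percent = 100 * (L - genic_nt) / L,
    start_stop_audit = start_stop_audit(genome, transl_table)
  )
  class(out) <- "genome_summary"
  out
}

#' @rdname region_accounting
#' @export
genome_summary <- region_accounting

#' Start/stop codon audit of coding genes
#'
#' Reports the first and last codon of every spliced coding sequence (core
#' PCGs, free-standing ORFs, intronic ORFs) and flags nonstandard starts
#' (not ATG), nonstandard stops (not TAA/TAG), lengths not divisible by 3,
#' and internal stop codons under the requested genetic code.
#'
#' @inheritParams region_accounting
#' @return Data frame with one row per coding gene.
#' @export
start_stop_audit <- function(genome, transl_table = 4L) {
  gc <- Biostrings::getGeneticCode(as.character(transl_table))
  stops <- names(gc)[gc == "*"]
  feats <- Filter(function(f) f$kind %in% c("PCG", "free_ORF", "intronic_ORF"),
                  genome$features)
  rows <- lapply(feats, function(f) {
    s <- feature_seq(genome, f)
    n <- nchar(s)
    frame_ok <- n %% 3L == 0L
    first <- substr(s, 1L, 3L)
    last <- substr(s, n - 2L, n)
    internal_stop <- FALSE
    if (frame_ok && n >= 9L) {
      cod <- substring(s, seq(4L, n - 5L, 3L), seq(6L, n - 3L, 3L))
      internal_stop <- any(cod %in% stops)
    }
    data.frame(
      gene = f$name, kind = f$kind, length_nt = n,
      start_codon = first, stop_codon = last,
      nonstandard_start = first != "ATG",
      nonstandard_stop = !last %in% c("TAA", "TAG"),
      frame_flag = !frame_ok,
      internal_stop = internal_stop,
      stringsAsFactors = FALSE
    )
  })
  if (length(rows) == 0L) {
    return(data.frame(gene = character(0), kind = character(0),
                      length_nt = integer(0), start_codon = character(0),
                      stop_codon = character(0), nonstandard_start = logical(0),
                      nonstandard_stop = logical(0), frame_flag = logical(0),
                      internal_stop = logical(0)))
  }
  do.call(rbind, rows)
}

#' @export
print.genome_summary <- function(x, ...) {
  cat(sprintf("<genome_summary> %s\n", x$id))
  cat(sprintf("  size %s bp | AT%% %.1f | AT skew %.2f | GC skew %.2f\n",
              format(x$size_bp, big.mark = ","), x$at_percent,
              x$at_skew, x$gc_skew))
  cat(sprintf("  genes: %d core PCG + %d free ORF + %d rRNA + %d tRNA; %d intron(s), %d intronic ORF(s)\n",
              x$n_core_pcg, x$n_free_orf, x$n_rrna, x$n_trna,
              x$n_intron, x$n_intronic_orf))
  cat(sprintf("  genic %s nt (%.1f%%) | intergenic %s nt (%.1f%%) | intronic %s nt\n",
              format(x$genic_nt, big.mark = ","), x$genic_percent,
              format(x$intergenic_nt, big.mark = ","), x$intergenic_percent,
              format(x$intronic_nt, big.mark = ",")))
  flagged <- x$start_stop_audit[x$start_stop_audit$nonstandard_start |
                                x$start_stop_audit$nonstandard_stop, , drop = FALSE]
  if (nrow(flagged)) {
    cat("  codon flags:",
        paste(sprintf("%s (%s/%s)", flagged$gene, flagged$start_codon,
                      flagged$stop_codon), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Summary table in the layout of a mitogenome comparison table
#'
#' One column per genome, one row per summary item (size, AT%, skews, feature
#' counts, region totals and percentages), percentages rounded to 1 decimal
#' and skews to 2, matching the conventional presentation of mitogenome
#' comparison tables.
#'
#' @param summaries List of `genome_summary` objects.
#' @return Data frame with an `item` column plus one column per genome.
#' @export
summary_table <- function(summaries) {
  if (inherits(summaries, "genome_summary")) summaries <- list(summaries)
  cols <- lapply(summaries, function(s) {
    c(`Mitogenome size (bp)` = format(s$size_bp),
      `AT%` = sprintf("%.1f", s$at_percent),
      `AT skew` = sprintf("%.2f", s$at_skew),
      `GC skew` = sprintf("%.2f", s$gc_skew),
      `No. standard PCGs` = format(s$n_core_pcg),
      `No. free-standing ORFs` = format(s$n_free_orf),
      `No. rRNAs` = format(s$n_rrna),
      `No. tRNAs` = format(s$n_trna),
      `No. introns` = format(s$n_intron),
      `No. intronic ORFs` = format(s$n_intronic_orf),
      `Intronic region (nt)` = format(s$intronic_nt),
      `Genic region (nt)` = format(s$genic_nt),
      `Genic region (%)` = sprintf("%.1f", s$genic_percent),
      `Intergenic regions (nt)` = format(s$intergenic_nt),
      `Intergenic regions (%)` = sprintf("%.1f", s$intergenic_percent))
  })
  out <- data.frame(item = names(cols[[1]]), stringsAsFactors = FALSE)
  for (i in seq_along(cols)) out[[summaries[[i]]$id]] <- unname(cols[[i]])
  out
}
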