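## Intraspecific variation: banded high-identity alignment of whole
## mitogenomes, indel/variable site tallies, genic/intergenic partition of
## the sites, and synonymous/nonsynonymous calls under the mold
## mitochondrial code.

#' Progressive banded global alignment of near-identical sequences
#'
#' Aligns every sequence to the first (the anchor) by banded global dynamic
#' programming with affine gap penalties, then merges the pairwise alignments
#' on the anchor's coordinates into one multiple alignment. Intended for
#' intraspecific mitogenome sets with expected identity of roughly 95% or
#' more, where the optimal path stays near the main diagonal; when it touches
#' the band edge the band is doubled automatically (up to four times the
#' requested width) before giving up. Deterministic for fixed inputs and
#' parameters.
#'
#' @param seqs Named character vector (or `DNAStringSet`) of two or more
#'   unaligned sequences; the first is the anchor.
#' @param band Half-width of the DP band around the diagonal, default 200.
#' @param gap_open,gap_ext Affine gap penalties (defaults 10 and 0.5; a gap
#'   of length k costs `gap_open + k * gap_ext`).
#' @param match,mismatch Match/mismatch scores (defaults +1/-1).
#' @return An object of class `mito_alignment`: named character vector of
#'   gapped rows (`$rows`) plus the parameters used (`$params`).
#' @export
align_high_identity <- function(seqs, band = 200L, gap_open = 10,
                                gap_ext = 0.5, match = 1, mismatch = -1) {
  if (methods::is(seqs, "XStringSet")) seqs <- setNames(as.character(seqs), names(seqs))
  if (length(seqs) < 2L) stop("need at least two sequences")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    names(seqs) <- paste0("seq", seq_along(seqs))
  }
  seqs <- toupper(seqs)
  anchor <- seqs[[1L]]
  n <- nchar(anchor)
  pairs <- vector("list", length(seqs) - 1L)
  for (k in seq_along(pairs)) {
    other <- seqs[[k + 1L]]
    b <- as.integer(band)
    repeat {
      res <- .banded_align_cpp(anchor, other, b, gap_open, gap_ext,
                               match, mismatch)
      if (!res$band_hit) break
      if (b >= 4L * band) {
        stop("band overflow aligning '", names(seqs)[k + 1L],
             "': optimal path leaves band even at 4x width (", b, ")")
      }
      b <- 2L * b
    }
    pairs[[k]] <- res
  }
  ## merge on anchor coordinates: per anchor slot s (0..n, before base s+1),
  ## the merged alignment carries max_k(gap columns at s) insertion columns
  slot_of <- function(pa) {
    ap <- cumsum(pa != "-")
    list(ap = ap, ins = which(pa == "-"))
  }
  pa_chars <- lapply(pairs, function(p) strsplit(p$aligned_a, "")[[1]])
  pb_chars <- lapply(pairs, function(p) strsplit(p$aligned_b, "")[[1]])
  gslot <- integer(n + 1L)
  infos <- vector("list", length(pairs))
  for (k in seq_along(pairs)) {
    info <- slot_of(pa_chars[[k]])
    infos[[k]] <- info
    if (length(info$ins)) {
      tab <- tabulate(info$ap[info$ins] + 1L, nbins = n + 1L)
      gslot <- pmax(gslot, tab)
    }
  }
  CS <- c(0L, cumsum(gslot))               # insertions in slots < s
  N <- n + sum(gslot)
  pos_base <- CS[seq_len(n) + 1L] + seq_len(n)
  rows <- matrix("-", nrow = length(seqs), ncol = N)
  rows[1L, pos_base] <- strsplit(anchor, "")[[1]]
  for (k in seq_along(pairs)) {
    info <- infos[[k]]
    pb <- pb_chars[[k]]
    basecols <- which(pa_chars[[k]] != "-")
    rows[k + 1L, pos_base[info$ap[basecols]]] <- pb[basecols]
    if (length(info$ins)) {
      s <- info$ap[info$ins]
      r <- sequence(rle(s)$lengths)
      rows[k + 1L, CS[s + 1L] + s + r] <- pb[info$ins]
    }
  }
  out <- list(
    rows = setNames(apply(rows, 1L, paste, collapse = ""), names(seqs)),
    params = list(method = "banded_progressive", band = band,
                  gap_open = gap_open, gap_ext = gap_ext,
                  match = match, mismatch = mismatch)
  )
  class(out) <- "mito_alignment"
  out
}

#' Wrap a pre-computed multiple alignment
#'
#' Accepts externally aligned FASTA rows (all equal length, gaps as `-`) so
#' site tallies can be run on alignments from other aligners.
#'
#' @param rows Named character vector of gapped rows.
#' @return A `mito_alignment`.
#' @export
as_mito_alignment <- function(rows) {
  if (methods::is(rows, "XStringSet")) rows <- setNames(as.character(rows), names(rows))
  if (length(unique(nchar(rows))) != 1L) {
    stop("aligned rows differ in length")
  }
  structure(list(rows = toupper(rows),
                 params = list(method = "precomputed")),
            class = "mito_alignment")
}

#' @export
print.mito_alignment <- function(x, ...) {
  cat(sprintf("<mito_alignment> %d sequences x %d columns (%s)\n",
              length(x$rows), nchar(x$rows[[1]]), x$params$method))
  invisible(x)
}

## map a 1-based reference position to its innermost coding feature and
## spliced-CDS offset; NULL when not coding
locate_coding <- function(genome, ref_pos) {
  pos0 <- ref_pos - 1L
  best <- NULL
  best_len <- Inf
  for (f in genome$features) {
    if (!f$kind %in% c("PCG", "free_ORF", "intronic_ORF")) next
    segs <- f$segments
    offset <- 0L
    for (i in seq_len(nrow(segs))) {
      s <- segs[i, 1L]; e <- segs[i, 2L]
      if (pos0 >= s && pos0 < e) {
        spliced_idx <- if (f$strand > 0L) offset + (pos0 - s)
                       else offset + (e - 1L - pos0)
        fl <- feature_length(f)
        if (fl < best_len) {
          best <- list(feature = f, spliced_idx = spliced_idx)
          best_len <- fl
        }
      }
      offset <- offset + e - s
    }
  }
  best
}

#' Synonymous/nonsynonymous call for a substitution
#'
#' Translates the reference codon and the codon carrying the alternate base
#' under the requested genetic code (default 4, the mold mitochondrial code,
#' under which TGA encodes tryptophan). Synonymous iff all translations are
#' identical. Sites outside coding features return `NA`.
#'
#' @param genome Reference [mito_genome].
#' @param ref_pos 1-based position on the reference sequence.
#' @param alt_bases Character vector of alternate bases observed at the site
#'   (genome strand).
#' @param transl_table NCBI genetic code id (default 4).
#' @return List: `effect` (`"synonymous"`/`"nonsynonymous"`/`NA`), `gene`,
#'   `codon`, `alt_codons`, `aa`, `alt_aas`.
#' @export
coding_effect <- function(genome, ref_pos, alt_bases, transl_table = 4L) {
  hit <- locate_coding(genome, ref_pos)
  if (is.null(hit)) {
    return(list(effect = NA_character_, gene = NA_character_))
  }
  f <- hit$feature
  gc <- Biostrings::getGeneticCode(as.character(transl_table))
  spliced <- feature_seq(genome, f)
  idx <- hit$spliced_idx                    # 0-based within spliced CDS
  cstart <- (idx %/% 3L) * 3L + 1L          # 1-based codon start
  codon <- substr(spliced, cstart, cstart + 2L)
  if (nchar(codon) < 3L) {
    return(list(effect = NA_character_, gene = f$name))  # trailing partial codon
  }
  off <- idx %% 3L
  alt_bases <- toupper(alt_bases)
  if (f$strand < 0L) {
    alt_bases <- vapply(alt_bases, revcomp, "")
  }
  alt_codons <- vapply(alt_bases, function(b) {
    x <- codon
    substr(x, off + 1L, off + 1L) <- b
    x
  }, "")
  tr <- function(cod) {
    if (grepl("[^ACGT]", cod)) NA_character_ else unname(gc[[cod]])
  }
  aa <- tr(codon)
  alt_aas <- vapply(alt_codons, tr, "")
  effect <- if (is.na(aa) || anyNA(alt_aas)) NA_character_
            else if (all(alt_aas == aa)) "synonymous" else "nonsynonymous"
  list(effect = effect, gene = f$name, codon = codon, alt_codons = alt_codons,
       aa = aa, alt_aas = alt_aas)
}

#' Tally indel and variable sites of an alignment
#'
#' Classifies every alignment column: columns containing at least one gap are
#' indel sites; gap-free columns with two or more distinct bases are variable
#' sites (the two tallies are disjoint by construction). Reported divergence
#' is `100 * (indel_sites + variable_sites) / alignment_length`; the
#' substitutions-only rate is reported alongside. Each site is mapped through
#' the reference row's ungapped coordinate to genic/intergenic space, and
#' every variable site inside a coding feature receives a
#' synonymous/nonsynonymous call unless its codon is disrupted by an
#' alignment gap, in which case it is flagged `indel_adjacent` and excluded
#' from the coding census.
#'
#' @param aln A `mito_alignment`.
#' @param reference_annotation [mito_genome] whose sequence is one of the
#'   aligned rows.
#' @param reference Name of the reference row (default: the row matching the
#'   genome id, else the first row).
#' @param transl_table NCBI genetic code id (default 4).
#' @return An object of class `variation_report`.
#' @export
tally_sites <- function(aln, reference_annotation, reference = NULL,
                        transl_table = 4L) {
  rows <- aln$rows
  if (is.null(reference)) {
    reference <- if (reference_annotation$id %in% names(rows))
      reference_annotation$id else names(rows)[1L]
  }
  if (!reference %in% names(rows)) {
    stop("reference row '", reference, "' absent from alignment")
  }
  if (gsub("-", "", rows[[reference]]) != reference_annotation$sequence) {
    stop("reference row does not match the annotated genome sequence")
  }
  m <- do.call(rbind, strsplit(unname(rows), ""))
  rownames(m) <- names(rows)
  ncol_aln <- ncol(m)
  gapcol <- colSums(m == "-") > 0L
  distinct <- apply(m, 2L, function(col) length(unique(col)))
  varcol <- !gapcol & distinct > 1L
  refrow <- m[reference, ]
  refpos <- cumsum(refrow != "-")           # 1-based ungapped ref coordinate
  refpos[refpos == 0L] <- 1L                # leading-gap columns -> first base
  genic <- is_genic(reference_annotation, refpos)
  aln_col_of_ref <- match(seq_len(reference_annotation$length_bp),
                          cumsum(refrow != "-") * (refrow != "-"))

  site_rows <- list()
  n_syn <- 0L; n_nonsyn <- 0L; n_indel_adj <- 0L
  for (col in which(varcol | gapcol)) {
    type <- if (gapcol[col]) "indel" else "variable"
    effect <- NA_character_
    gene <- NA_character_
    if (type == "variable" && genic[col]) {
      hit <- locate_coding(reference_annotation, refpos[col])
      if (!is.null(hit)) {
        gene <- hit$feature$name
        idx <- hit$spliced_idx
        ## reference positions of the codon's three bases, via the feature
        cod_sp <- (idx %/% 3L) * 3L + 0:2
        disrupted <- FALSE
        segs <- hit$feature$segments
        for (sp in cod_sp) {
          off <- 0L; rp <- NA_integer_
          for (i in seq_len(nrow(segs))) {
            w <- segs[i, 2L] - segs[i, 1L]
            if (sp < off + w) {
              rp <- if (hit$feature$strand > 0L) segs[i, 1L] + (sp - off) + 1L
                    else segs[i, 2L] - (sp - off)
              break
            }
            off <- off + w
          }
          if (!is.na(rp) && !is.na(aln_col_of_ref[rp]) &&
              gapcol[aln_col_of_ref[rp]]) disrupted <- TRUE
        }
        if (disrupted) {
          effect <- "indel_adjacent"
          n_indel_adj <- n_indel_adj + 1L
        } else {
          ref_base <- refrow[col]
          alts <- setdiff(unique(m[, col]), ref_base)
          ce <- coding_effect(reference_annotation, refpos[col], alts,
                              transl_table)
          effect <- ce$effect
          if (identical(effect, "synonymous")) n_syn <- n_syn + 1L
          if (identical(effect, "nonsynonymous")) n_nonsyn <- n_nonsyn + 1L
        }
      }
    }
    site_rows[[length(site_rows) + 1L]] <- data.frame(
      column = col, ref_pos = refpos[col], type = type,
      region = if (genic[col]) "genic" else "intergenic",
      bases = paste(m[, col], collapse = ""), gene = gene, effect = effect,
      stringsAsFactors = FALSE)
  }
  sites <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(column = integer(0), ref_pos = integer(0), type = character(0),
               region = character(0), bases = character(0),
               gene = character(0), effect = character(0))
  indel_sites <- sum(gapcol)
  variable_sites <- sum(varcol)
  out <- list(
    n_sequences = nrow(m),
    alignment_length = ncol_aln,
    indel_sites = indel_sites,
    variable_sites = variable_sites,
    divergence_percent = 100 * (indel_sites + variable_sites) / ncol_aln,
    divergence_percent_substitutions_only = 100 * variable_sites / ncol_aln,
    indel_genic = sum(sites$type == "indel" & sites$region == "genic"),
    indel_intergenic = sum(sites$type == "indel" & sites$region == "intergenic"),
    variable_genic = sum(sites$type == "variable" & sites$region == "genic"),
    variable_intergenic = sum(sites$type == "variable" &
                                sites$region == "intergenic"),
    n_synonymous = n_syn,
    n_nonsynonymous = n_nonsyn,
    n_indel_adjacent = n_indel_adj,
    sites = sites,
    reference = reference,
    params = aln$params
  )
  class(out) <- "variation_report"
  out
}

#' @export
print.variation_report <- function(x, ...) {
  cat(sprintf("<variation_report> %d sequences, %d columns (ref %s)\n",
              x$n_sequences, x$alignment_length, x$reference))
  cat(sprintf("  indel sites %d (%d genic / %d intergenic)\n",
              x$indel_sites, x$indel_genic, x$indel_intergenic))
  cat(sprintf("  variable sites %d (%d genic / %d intergenic)\n",
              x$variable_sites, x$variable_genic, x$variable_intergenic))
  cat(sprintf("  divergence %.2f%% (substitutions only %.2f%%)\n",
              x$divergence_percent, x$divergence_percent_substitutions_only))
  cat(sprintf("  coding: %d synonymous, %d nonsynonymous, %d indel-adjacent\n",
              x$n_synonymous, x$n_nonsynonymous, x$n_indel_adjacent))
  invisible(x)
}
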