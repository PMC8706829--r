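## Internal data model: annotated circular mitochondrial genome.
## Coordinates are 0-based half-open internally; all I/O is 1-based inclusive
## (GenBank convention). Origin-spanning features are stored as multiple
## segments, never with coordinates beyond the sequence length.

FEATURE_KINDS <- c("PCG", "rRNA", "tRNA", "free_ORF", "intron", "intronic_ORF")

## Kinds that define the genic region of the molecule. Introns and intronic
## ORFs sit inside host gene spans and must not be double counted.
GENE_LEVEL_KINDS <- c("PCG", "rRNA", "tRNA", "free_ORF")

#' Construct a gene feature
#'
#' A single named feature of a mitochondrial genome: a protein-coding gene,
#' rRNA, tRNA, free-standing ORF, intron, or intron-encoded ORF. Coordinates
#' are 0-based half-open genome intervals, listed in transcription order; a
#' feature spanning the circular origin is represented by two (or more)
#' segments, each within `[0, genome length)`.
#'
#' @param name Normalized gene symbol (e.g. `"nad4L"`, `"cob"`, `"rnl"`,
#'   `"trnM_1"`, `"orf350"`).
#' @param kind One of `"PCG"`, `"rRNA"`, `"tRNA"`, `"free_ORF"`, `"intron"`,
#'   `"intronic_ORF"`.
#' @param segments Two-column integer matrix of `(start, end)` 0-based
#'   half-open intervals in transcription order.
#' @param strand `+1` or `-1`.
#' @param anticodon Optional anticodon string for tRNAs.
#' @param notes Free-text annotation carried through to reports.
#' @return An object of class `gene_feature`.
#' @export
gene_feature <- function(name, kind, segments, strand = 1L,
                         anticodon = NA_character_, notes = NA_character_) {
  if (is.numeric(segments) && is.null(dim(segments))) {
    segments <- matrix(as.integer(segments), ncol = 2, byrow = TRUE)
  }
  segments <- matrix(as.integer(segments), ncol = 2,
                     dimnames = list(NULL, c("start", "end")))
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!kind %in% FEATURE_KINDS) {
    stop("unknown feature kind '", kind, "' for feature '", name, "'")
  }
  if (nrow(segments) == 0L) stop("feature '", name, "' has no segments")
  if (any(segments[, 2L] <= segments[, 1L])) {
    stop("feature '", name, "' has a segment with end <= start")
  }
  if (kind == "tRNA" && !startsWith(name, "trn")) {
    stop("tRNA feature '", name, "' must be named trn<AA>")
  }
  strand <- as.integer(strand)
  if (!strand %in% c(1L, -1L)) stop("strand must be +1 or -1")
  structure(
    list(name = name, kind = kind, segments = segments, strand = strand,
         anticodon = anticodon, notes = notes),
    class = "gene_feature"
  )
}

#' Construct an annotated mitochondrial genome
#'
#' Container for one circular (or linear) mitochondrial genome: its sequence,
#' its features, and free-form metadata. Features are validated against the
#' sequence bounds and sorted by their lowest genomic coordinate.
#'
#' @param id Accession or label.
#' @param sequence DNA string over `A/C/G/T/N` (case-insensitive input).
#' @param is_circular Logical; circular topology.
#' @param features List of [gene_feature] objects.
#' @param metadata Named list of free-form strings (organism, isolate, ...).
#' @return An object of class `mito_genome`.
#' @export
mito_genome <- function(id, sequence, is_circular = TRUE, features = list(),
                        metadata = list()) {
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || !nzchar(sequence)) {
    stop("sequence must be a single non-empty string")
  }
  if (grepl("[^ACGTN]", sequence)) {
    bad <- unique(strsplit(gsub("[ACGTN]", "", sequence), "")[[1]])
    stop("sequence contains non-ACGTN characters: ",
         paste(bad, collapse = " "))
  }
  len <- nchar(sequence)
  bad <- character(0)
  for (f in features) {
    if (!inherits(f, "gene_feature")) stop("features must be gene_feature objects")
    if (any(f$segments < 0L) || any(f$segments[, 2L] > len)) {
      bad <- c(bad, sprintf("%s [%s]", f$name,
                            paste(apply(f$segments, 1L, paste, collapse = ".."),
                                  collapse = ",")))
    }
  }
  if (length(bad)) {
    stop("feature(s) outside sequence bounds [0, ", len, "): ",
         paste(bad, collapse = "; "))
  }
  if (length(features)) {
    starts <- vapply(features, function(f) min(f$segments[, 1L]), numeric(1))
    features <- features[order(starts)]
  }
  structure(
    list(id = id, sequence = sequence, length_bp = len,
         is_circular = isTRUE(is_circular), features = features,
         metadata = metadata),
    class = "mito_genome"
  )
}

#' @export
print.mito_genome <- function(x, ...) {
  kinds <- table(factor(vapply(x$features, `[[`, "", "kind"),
                        levels = FEATURE_KINDS))
  cat(sprintf("<mito_genome> %s: %s bp, %s\n", x$id,
              format(x$length_bp, big.mark = ","),
              if (x$is_circular) "circular" else "linear"))
  cat("  features:", paste(sprintf("%s %s", kinds, names(kinds))[kinds > 0],
                           collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.gene_feature <- function(x, ...) {
  loc <- paste(apply(x$segments, 1L,
                     function(s) sprintf("%d-%d", s[1L], s[2L])),
               collapse = ",")
  cat(sprintf("<gene_feature> %s (%s) %s strand %+d\n",
              x$name, x$kind, loc, x$strand))
  invisible(x)
}

## Reverse complement for plain character DNA.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Extract the genomic sequence of one segment (0-based half-open).
segment_seq <- function(genome, seg) {
  substr(genome$sequence, seg[1L] + 1L, seg[2L])
}

#' Spliced sequence of a feature
#'
#' Concatenates the feature's segments in transcription order. For minus-strand
#' features each segment is reverse-complemented, so the result reads 5'->3'
#' on the coding strand.
#'
#' @param genome A [mito_genome].
#' @param feature A [gene_feature] from that genome (or its name).
#' @return A character DNA string.
#' @export
feature_seq <- function(genome, feature) {
  if (is.character(feature)) feature <- get_feature(genome, feature)
  parts <- apply(feature$segments, 1L, function(s) segment_seq(genome, s))
  if (feature$strand < 0L) parts <- vapply(parts, revcomp, "")
  paste(parts, collapse = "")
}

## Look up a feature by exact name; error mentions the gene when absent.
get_feature <- function(genome, name) {
  hits <- Filter(function(f) f$name == name, genome$features)
  if (length(hits) == 0L) {
    stop("gene '", name, "' absent from genome '", genome$id, "'")
  }
  if (length(hits) > 1L) {
    stop("gene '", name, "' duplicated in genome '", genome$id, "'")
  }
  hits[[1]]
}

feature_names <- function(genome) vapply(genome$features, `[[`, "", "name")
feature_kinds <- function(genome) vapply(genome$features, `[[`, "", "kind")

## Total length of a feature's segments (spliced length).
feature_length <- function(feature) {
  sum(feature$segments[, 2L] - feature$segments[, 1L])
}

## Hull of a feature on the circle: the span from its first to its last
## transcription-order boundary with internal gaps (introns) filled. Returned
## as a 2-column matrix of non-wrapping 0-based half-open pieces. Consecutive
## segments that step backwards are interpreted as crossing the origin.
feature_hull <- function(feature, genome_length) {
  seg <- feature$segments
  if (feature$strand < 0L) {
    ## genomic left-to-right order for hull computation
    seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
  }
  starts <- seg[, 1L]
  ends <- seg[, 2L]
  off <- 0L
  for (i in seq_along(starts)) {
    starts[i] <- starts[i] + off
    if (i > 1L && starts[i] < ends[i - 1L]) {
      off <- off + genome_length
      starts[i] <- starts[i] + genome_length
    }
    ends[i] <- ends[i] + off
  }
  a <- min(starts); b <- max(ends)
  if (b <= genome_length) {
    matrix(c(a, b), ncol = 2)
  } else {
    ## wraps the origin: split at the origin
    matrix(c(a, genome_length, 0L, b - genome_length), ncol = 2, byrow = TRUE)
  }
}

## Rotate a genome's origin by `offset` bases (new origin = old position
## offset). Used by the generator and by rotation-invariance tests.
#' Rotate the origin of a circular genome
#'
#' Moves the sequence origin to position `offset`, rewriting all feature
#' coordinates modulo the genome length. Analyses on circular genomes are
#' expected to be invariant under this operation.
#'
#' @param genome A circular [mito_genome].
#' @param offset Integer in `[0, length_bp)`.
#' @return A rotated [mito_genome].
#' @export
rotate_genome <- function(genome, offset) {
  offset <- as.integer(offset) %% genome$length_bp
  if (offset == 0L) return(genome)
  if (!genome$is_circular) stop("cannot rotate a linear genome")
  L <- genome$length_bp
  seq2 <- paste0(substr(genome$sequence, offset + 1L, L),
                 substr(genome$sequence, 1L, offset))
  feats <- lapply(genome$features, function(f) {
    segs <- f$segments
    out <- list()
    for (i in seq_len(nrow(segs))) {
      s <- (segs[i, 1L] - offset) %% L
      e <- segs[i, 2L] - segs[i, 1L] + s
      if (e <= L) {
        out[[length(out) + 1L]] <- c(s, e)
      } else {  # segment now crosses the new origin: split
        out[[length(out) + 1L]] <- c(s, L)
        out[[length(out) + 1L]] <- c(0L, e - L)
      }
    }
    ## re-merge splits that no longer cross the origin
    m <- do.call(rbind, out)
    merged <- list(m[1L, ])
    for (i in seq_len(nrow(m))[-1L]) {
      last <- merged[[length(merged)]]
      ## former origin splits become contiguous after rotation and are
      ## re-merged; fresh origin splits end at L / start at 0 and never match
      if (m[i, 1L] == last[2L] && last[2L] < L) {
        merged[[length(merged)]] <- c(last[1L], m[i, 2L])
      } else {
        merged[[length(merged) + 1L]] <- m[i, ]
      }
    }
    gene_feature(f$name, f$kind, do.call(rbind, merged), f$strand,
                 f$anticodon, f$notes)
  })
  mito_genome(genome$id, seq2, TRUE, feats, genome$metadata)
}
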