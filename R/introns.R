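## Group I intron cataloguing: positional naming by homologous insertion
## site on a reference gene, boundary diagnostics (upstream exon ends T,
## intron ends G), intronic/intergenic ORF detection, and inter-taxon intron
## identity.

align_global <- function(a, b, gap_open = 10, gap_ext = 0.5) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -2,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = gap_open, gapExtension = gap_ext)
}

aligned_identity <- function(aln) {
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  100 * sum(p == s & p != "-") / length(p)
}

#' Locate an intron insertion site on a reference gene
#'
#' Positional intron nomenclature names an intron by the coordinate, on a
#' homologous reference gene, of the base immediately 5' of the insertion.
#' The spliced (exon-only) host sequence is globally aligned to the reference
#' with affine gap penalties; the returned position is the 1-based reference
#' coordinate of the host base preceding the intron, or, when that base
#' aligns to a reference gap, the nearest upstream reference-aligned base.
#'
#' @param spliced_host Exon-only host gene sequence (intron removed).
#' @param junction Number of host bases 5' of the insertion point.
#' @param reference Reference gene sequence (e.g. the E. coli rnl used for
#'   mL-numbering of large-subunit rRNA introns).
#' @param min_identity Reject alignments below this percent identity
#'   (default 40): positions from unreliable alignments are errors, not
#'   numbers.
#' @param gap_open,gap_ext Affine gap penalties.
#' @return Integer 1-based reference coordinate.
#' @export
locate_insertion <- function(spliced_host, junction, reference,
                             min_identity = 40, gap_open = 10, gap_ext = 0.5) {
  junction <- as.integer(junction)
  stopifnot(junction >= 1L, junction <= nchar(spliced_host))
  aln <- align_global(spliced_host, reference, gap_open, gap_ext)
  idy <- aligned_identity(aln)
  if (idy < min_identity) {
    stop(sprintf("unreliable insertion position: host/reference identity %.1f%% < %g%%",
                 idy, min_identity))
  }
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  host_count <- cumsum(p != "-")
  ref_count <- cumsum(s != "-")
  col <- match(junction, host_count)
  if (is.na(col)) stop("junction index beyond aligned host sequence")
  as.integer(ref_count[col])
}

#' Positional intron name
#'
#' `rnl` introns use the `mL` prefix and `rns` introns `mS` (ribosomal
#' nomenclature); protein-gene introns use the host symbol plus `P`.
#'
#' @param host Host gene symbol.
#' @param position 1-based insertion coordinate on the reference gene.
#' @return Character name, e.g. `mL2450`, `cox1P1125`.
#' @export
intron_name <- function(host, position) {
  stopifnot(position > 0)
  prefix <- switch(host, rnl = "mL", rns = "mS", paste0(host, "P"))
  paste0(prefix, position)
}

#' Group I intron boundary check
#'
#' Group I introns characteristically follow an upstream exon ending in `T`
#' and themselves end in `G`.
#'
#' @param intron_seq Intron sequence.
#' @param upstream_exon_seq Upstream exon sequence.
#' @return Named logical vector `c(upstream_T, intron_G)`.
#' @export
boundary_check <- function(intron_seq, upstream_exon_seq) {
  stopifnot(nzchar(intron_seq), nzchar(upstream_exon_seq))
  c(upstream_T = toupper(substr(upstream_exon_seq, nchar(upstream_exon_seq),
                                nchar(upstream_exon_seq))) == "T",
    intron_G = toupper(substr(intron_seq, nchar(intron_seq),
                              nchar(intron_seq))) == "G")
}

#' Find ORFs on the transcribed strand of a region
#'
#' Scans the three sense-strand frames for ATG-to-stop open reading frames of
#' at least `min_nt` nucleotides (stop codon included) under the requested
#' genetic code. Within a frame the longest ORF per stop codon is kept, and
#' ORFs nested inside a longer ORF's span are suppressed. Names follow the
#' `orf<aa>` convention, where `<aa>` is the encoded protein length.
#'
#' @param region_seq DNA string (transcribed strand).
#' @param min_nt Minimum ORF length in nucleotides, default 300.
#' @param transl_table NCBI genetic code id (default 4).
#' @return Data frame: `name`, `start`, `end` (0-based half-open within the
#'   region), `length_nt`, `aa`, `frame`.
#' @export
find_orfs <- function(region_seq, min_nt = 300L, transl_table = 4L) {
  s <- toupper(as.character(region_seq))
  gc <- Biostrings::getGeneticCode(as.character(transl_table))
  stops <- names(gc)[gc == "*"]
  empty <- data.frame(name = character(0), start = integer(0), end = integer(0),
                      length_nt = integer(0), aa = integer(0), frame = integer(0))
  n <- nchar(s)
  if (n < min_nt) return(empty)
  rows <- list()
  for (fr in 0:2) {
    starts <- seq(fr + 1L, n - 2L, by = 3L)
    if (length(starts) == 0L) next
    cod <- substring(s, starts, starts + 2L)
    open_at <- NA_integer_
    for (i in seq_along(cod)) {
      if (is.na(open_at) && cod[i] == "ATG") open_at <- i
      if (cod[i] %in% stops) {
        if (!is.na(open_at)) {
          len <- (i - open_at + 1L) * 3L
          if (len >= min_nt) {
            rows[[length(rows) + 1L]] <- data.frame(
              name = sprintf("orf%d", len %/% 3L - 1L),
              start = starts[open_at] - 1L, end = starts[i] + 2L,
              length_nt = len, aa = len %/% 3L - 1L, frame = fr)
          }
        }
        open_at <- NA_integer_
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  orfs <- do.call(rbind, rows)
  orfs <- orfs[order(-orfs$length_nt), , drop = FALSE]
  keep <- rep(TRUE, nrow(orfs))
  for (i in seq_len(nrow(orfs))[-1L]) {
    prior <- which(keep[seq_len(i - 1L)])
    nested <- any(orfs$start[i] >= orfs$start[prior] &
                    orfs$end[i] <= orfs$end[prior])
    if (nested) keep[i] <- FALSE
  }
  orfs <- orfs[keep, , drop = FALSE]
  orfs <- orfs[order(orfs$start), , drop = FALSE]
  rownames(orfs) <- NULL
  orfs
}

#' Heuristic homing-endonuclease class of an ORF
#'
#' Intronic ORFs of group I introns typically encode LAGLIDADG or GIY-YIG
#' homing endonucleases, or ribosomal protein S3. Classification here is a
#' simple translated-motif match (literal LAGLIDADG block, or GIY...YIG with
#' a 6-12 residue spacer) and is flagged as heuristic: absence of a motif
#' match returns `"unknown"`, never evidence of absence.
#'
#' @param orf_seq ORF nucleotide sequence (ATG..stop).
#' @param transl_table NCBI genetic code id (default 4).
#' @return One of `"LAGLIDADG"`, `"GIY-YIG"`, `"unknown"`.
#' @export
orf_protein_class <- function(orf_seq, transl_table = 4L) {
  gc <- Biostrings::getGeneticCode(as.character(transl_table))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(toupper(orf_seq)), genetic.code = gc,
    if.fuzzy.codon = "X"))
  if (grepl("LAGL[IV][DN]ADG", aa)) return("LAGLIDADG")
  if (grepl("GIY.{6,12}YIG", aa)) return("GIY-YIG")
  "unknown"
}

#' Catalog the introns of an annotated genome
#'
#' Collects intron features with their host gene, spliced-host insertion
#' index, boundary diagnostics, positional name against a reference (when a
#' reference sequence for the host gene is supplied; otherwise the insertion
#' index on the host itself is used and flagged), and any embedded ORF with
#' its heuristic protein class. Group I subgroup (IA/IB) is metadata
#' passthrough from the annotation, never inferred.
#'
#' @param genome A [mito_genome].
#' @param references Named list of reference gene sequences (name = host gene
#'   symbol) used for positional naming.
#' @param transl_table NCBI genetic code id (default 4).
#' @return Data frame, one row per intron: `host_gene`, `name`,
#'   `insertion_ref_pos`, `reference`, `boundary_upstream_T`,
#'   `boundary_intron_G`, `orf`, `orf_class`, `group`, `length_nt`.
#' @export
intron_catalog <- function(genome, references = list(), transl_table = 4L) {
  introns <- Filter(function(f) f$kind == "intron", genome$features)
  rows <- lapply(introns, function(intr) {
    L <- genome$length_bp
    hull <- feature_hull(intr, L)
    i_start <- hull[1L, 1L]; i_end <- hull[nrow(hull), 2L]
    ## host = gene-level multi-segment feature whose hull contains the intron
    host <- NULL
    for (f in genome$features) {
      if (!f$kind %in% GENE_LEVEL_KINDS || nrow(f$segments) < 2L) next
      h <- feature_hull(f, L)
      if (i_start >= min(h[, 1L]) && i_end <= max(h[, 2L])) { host <- f; break }
    }
    host_name <- if (is.null(host)) NA_character_ else sub("_[0-9]+$", "", host$name)
    intron_seq <- feature_seq(genome, intr)
    junction <- NA_integer_
    upstream_T <- NA
    if (!is.null(host)) {
      ## exon bases transcribed before the intron
      segs <- host$segments
      before <- 0L
      for (i in seq_len(nrow(segs))) {
        seg_end_txn <- if (host$strand > 0L) segs[i, 2L] else segs[i, 1L]
        if (host$strand > 0L && segs[i, 2L] <= i_start) {
          before <- before + segs[i, 2L] - segs[i, 1L]
        } else if (host$strand < 0L && segs[i, 1L] >= i_end) {
          before <- before + segs[i, 2L] - segs[i, 1L]
        }
      }
      junction <- before
      spliced <- feature_seq(genome, host)
      upstream <- substr(spliced, 1L, junction)
      bc <- boundary_check(intron_seq, upstream)
      upstream_T <- unname(bc["upstream_T"])
    }
    ref_pos <- junction
    ref_used <- "host"
    if (!is.null(host) && host_name %in% names(references)) {
      spliced <- feature_seq(genome, host)
      ref_pos <- locate_insertion(spliced, junction, references[[host_name]])
      ref_used <- host_name
    }
    orfs <- Filter(function(f) {
      f$kind == "intronic_ORF" && min(f$segments[, 1L]) >= i_start &&
        max(f$segments[, 2L]) <= i_end
    }, genome$features)
    orf_name <- if (length(orfs)) orfs[[1L]]$name else NA_character_
    orf_class <- if (length(orfs)) {
      if (sub("_[0-9]+$", "", orf_name) == "rps3") "rps3"
      else orf_protein_class(feature_seq(genome, orfs[[1L]]), transl_table)
    } else NA_character_
    grp <- NA_character_
    if (!is.na(intr$notes)) {
      m <- regmatches(intr$notes, regexec("group I([AB])", intr$notes))[[1]]
      if (length(m) == 2L) grp <- paste0("I", m[2])
    }
    data.frame(
      host_gene = host_name,
      name = if (!is.null(host) && !is.na(ref_pos))
        intron_name(host_name, ref_pos) else intr$name,
      insertion_ref_pos = ref_pos,
      reference = ref_used,
      boundary_upstream_T = upstream_T,
      boundary_intron_G = unname(boundary_check(intron_seq, "N")["intron_G"]),
      orf = orf_name, orf_class = orf_class, group = grp,
      length_nt = feature_length(intr),
      stringsAsFactors = FALSE
    )
  })
  if (length(rows)) {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    return(out)
  }
  data.frame(host_gene = character(0), name = character(0),
             insertion_ref_pos = integer(0), reference = character(0),
             boundary_upstream_T = logical(0), boundary_intron_G = logical(0),
             orf = character(0), orf_class = character(0),
             group = character(0), length_nt = integer(0))
}

#' Pairwise identity of homologous introns across taxa
#'
#' For each intron name the same-named sequences from different taxa are
#' globally aligned pairwise; identity is `matches / alignment columns * 100`.
#' Taxa lacking an intron are `NA` cells (absent, not zero identity).
#'
#' @param introns Data frame with columns `name`, `taxon`, `sequence`.
#' @return Named list of taxon-by-taxon identity matrices, one per intron
#'   name.
#' @export
intron_identity_matrix <- function(introns) {
  stopifnot(all(c("name", "taxon", "sequence") %in% names(introns)))
  taxa <- unique(introns$taxon)
  out <- list()
  for (nm in unique(introns$name)) {
    sub <- introns[introns$name == nm, , drop = FALSE]
    m <- matrix(NA_real_, length(taxa), length(taxa),
                dimnames = list(taxa, taxa))
    for (i in seq_len(nrow(sub))) {
      m[sub$taxon[i], sub$taxon[i]] <- 100
      if (i < nrow(sub)) for (j in (i + 1L):nrow(sub)) {
        idy <- aligned_identity(align_global(sub$sequence[i], sub$sequence[j]))
        m[sub$taxon[i], sub$taxon[j]] <- idy
        m[sub$taxon[j], sub$taxon[i]] <- idy
      }
    }
    out[[nm]] <- m
  }
  out
}
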