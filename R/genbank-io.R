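## GenBank flat-file reader/writer for annotated mitogenomes, plus FASTA and
## TSV feature-table I/O. The flat-file feature grammar handled here is the
## subset emitted for organelle records: LOCUS topology, CDS/tRNA/rRNA/intron
## feature keys, join()/complement() locations (including joins across the
## circular origin), and quoted qualifiers spanning multiple lines.

## ---- location strings -----------------------------------------------------

## Parse a GenBank location into 1-based inclusive segments plus strand.
parse_location <- function(loc, genome_length = NA_integer_) {
  strand <- 1L
  loc <- gsub("[<>]", "", gsub("[[:space:]]", "", loc))
  while (grepl("^complement\\(", loc)) {
    strand <- -strand
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  segs <- lapply(parts, function(p) {
    p <- sub("^complement\\((.*)\\)$", "\\1", p)
    n <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    if (length(n) == 1L) n <- c(n, n)
    if (anyNA(n)) stop("unparseable location part: ", p)
    n
  })
  segs <- do.call(rbind, segs)
  ## a single span written with end < start crosses the circular origin
  out <- list()
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, 1L]; e <- segs[i, 2L]
    if (e < s && !is.na(genome_length)) {
      out[[length(out) + 1L]] <- c(s, genome_length)
      out[[length(out) + 1L]] <- c(1L, e)
    } else {
      out[[length(out) + 1L]] <- c(s, e)
    }
  }
  segs <- do.call(rbind, out)
  if (strand < 0L) segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
  list(segments = segs, strand = strand)
}

## 1-based inclusive -> 0-based half-open
to_internal_segments <- function(segs) {
  cbind(start = segs[, 1L] - 1L, end = segs[, 2L])
}

## ---- flat-file reader -----------------------------------------------------

#' Read a GenBank flat file into a `mito_genome`
#'
#' Parses the LOCUS line (length, circular/linear topology), the feature
#' table, and the ORIGIN sequence. Gene names are normalized through the
#' synonym table; coordinates become 0-based half-open; `join` locations that
#' cross the circular origin are stored as multiple segments. CDS features
#' are classified as core protein-coding genes, intronic ORFs (when contained
#' in an annotated intron, or recognized by product keywords such as
#' "ribosomal protein S3"), or free-standing ORFs.
#'
#' @param path Path to a GenBank flat file.
#' @param name_map Synonym table, see [default_gene_name_map()].
#' @return A [mito_genome].
#' @export
read_genbank <- function(path, name_map = default_gene_name_map()) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L) stop("not a GenBank flat file (no LOCUS line): ", path)
  toks <- strsplit(trimws(locus[1]), "[[:space:]]+")[[1]]
  id <- toks[2]
  len <- suppressWarnings(as.integer(toks[which(toks == "bp") - 1L]))
  is_circular <- any(tolower(toks) == "circular")
  acc <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc)) {
    a <- strsplit(trimws(acc[1]), "[[:space:]]+")[[1]]
    if (length(a) >= 2L) id <- a[2]
  }

  ## ORIGIN block
  oi <- grep("^ORIGIN", lines)
  if (length(oi) == 0L) stop("GenBank record has no ORIGIN sequence: ", path)
  endi <- grep("^//", lines)
  endi <- endi[endi > oi[1]][1]
  if (is.na(endi)) endi <- length(lines) + 1L
  seqlines <- lines[(oi[1] + 1L):(endi - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seqlines, collapse = "")))
  if (!nzchar(sequence)) stop("GenBank record has an empty sequence: ", path)
  if (is.na(len)) len <- nchar(sequence)

  ## FEATURES block: key starts in column 6, qualifiers/locations from col 22
  fi <- grep("^FEATURES", lines)
  feats_raw <- list()
  if (length(fi)) {
    block <- lines[(fi[1] + 1L):(oi[1] - 1L)]
    cur <- NULL
    for (ln in block) {
      if (grepl("^ {5}\\S", ln)) {
        if (!is.null(cur)) feats_raw[[length(feats_raw) + 1L]] <- cur
        key <- trimws(substr(ln, 1L, 20L))
        rest <- trimws(substr(ln, 21L, nchar(ln)))
        cur <- list(key = key, loc = rest, quals = character(0))
      } else if (!is.null(cur) && grepl("^ {10,}", ln)) {
        txt <- trimws(ln)
        if (startsWith(txt, "/")) {
          cur$quals <- c(cur$quals, txt)
        } else if (length(cur$quals) == 0L) {
          cur$loc <- paste0(cur$loc, txt)           # continued location
        } else {
          n <- length(cur$quals)                    # continued qualifier text
          cur$quals[n] <- paste(cur$quals[n], txt)
        }
      }
    }
    if (!is.null(cur)) feats_raw[[length(feats_raw) + 1L]] <- cur
  }

  qual_value <- function(quals, name) {
    pat <- paste0("^/", name, "=")
    hit <- grep(pat, quals, value = TRUE)
    if (length(hit) == 0L) return(NA_character_)
    gsub("^\"|\"$", "", sub(pat, "", hit[1]))
  }

  metadata <- list()
  features <- list()
  errors <- character(0)
  for (fr in feats_raw) {
    if (fr$key == "source") {
      for (q in c("organism", "isolate", "strain", "country", "geo_loc_name")) {
        v <- qual_value(fr$quals, q)
        if (!is.na(v)) metadata[[q]] <- v
      }
      next
    }
    if (!fr$key %in% c("CDS", "tRNA", "rRNA", "intron", "gene")) next
    loc <- tryCatch(parse_location(fr$loc, len), error = function(e) e)
    if (inherits(loc, "error")) {
      errors <- c(errors, sprintf("%s %s: %s", fr$key, fr$loc, conditionMessage(loc)))
      next
    }
    gene <- qual_value(fr$quals, "gene")
    product <- qual_value(fr$quals, "product")
    note <- qual_value(fr$quals, "note")
    raw_name <- if (!is.na(gene)) gene else if (!is.na(product)) product else
      if (!is.na(note)) note else fr$key
    name <- normalize_gene_name(raw_name, name_map)
    anticodon <- NA_character_
    ac <- qual_value(fr$quals, "anticodon")
    if (!is.na(ac)) {
      m <- regmatches(ac, regexec("seq:([A-Za-z]{3,4})", ac))[[1]]
      if (length(m) == 2L) anticodon <- tolower(m[2])
    }
    features[[length(features) + 1L]] <- list(
      key = fr$key, name = as.character(name),
      nonstandard = isTRUE(attr(name, "nonstandard")),
      segments = to_internal_segments(loc$segments), strand = loc$strand,
      anticodon = anticodon, product = product, note = note
    )
  }
  if (length(errors)) {
    stop("unparseable feature location(s) in ", path, ":\n  ",
         paste(errors, collapse = "\n  "))
  }

  ## drop bare 'gene' keys shadowed by a typed feature with the same name
  typed_names <- vapply(Filter(function(f) f$key != "gene", features),
                        `[[`, "", "name")
  features <- Filter(function(f) f$key != "gene" || !(f$name %in% typed_names),
                     features)

  ## classify kinds
  intron_spans <- lapply(Filter(function(f) f$key == "intron", features),
                         function(f) f$segments)
  contained_in_intron <- function(segs) {
    any(vapply(intron_spans, function(sp) {
      all(segs[, 1L] >= min(sp[, 1L])) && all(segs[, 2L] <= max(sp[, 2L]))
    }, logical(1)))
  }
  gene_objs <- lapply(features, function(f) {
    nm <- f$name
    kind <- switch(
      f$key,
      tRNA = "tRNA",
      rRNA = "rRNA",
      intron = "intron",
      CDS = {
        prod <- tolower(paste(f$product, f$note))
        if (nm %in% CORE_PCGS) "PCG"
        else if (contained_in_intron(f$segments)) "intronic_ORF"
        else if (grepl("ribosomal protein s3|laglidadg|giy-yig|homing endonuclease",
                       prod)) "intronic_ORF"
        else "free_ORF"
      },
      gene = {
        if (nm %in% CORE_PCGS) "PCG"
        else if (nm %in% c("rnl", "rns")) "rRNA"
        else if (startsWith(nm, "trn")) "tRNA"
        else "free_ORF"
      }
    )
    if (kind == "intronic_ORF" &&
        grepl("ribosomal protein s3", tolower(paste(f$product, f$note)))) {
      nm <- "rps3"
    }
    if (kind == "tRNA" && !startsWith(nm, "trn")) nm <- paste0("trn", nm)
    note <- if (f$nonstandard && kind != "intron" &&
                !isTRUE(grepl("nonstandard name", f$note))) {
      paste(stats::na.omit(c(f$note, "nonstandard name")), collapse = "; ")
    } else f$note
    gene_feature(nm, kind, f$segments, f$strand, f$anticodon,
                 if (is.na(note) || !nzchar(note)) NA_character_ else note)
  })
  starts <- vapply(gene_objs, function(f) min(f$segments[, 1L]), numeric(1))
  gene_objs <- dedup_feature_names(gene_objs[order(starts)])
  mito_genome(id, sequence, is_circular, gene_objs, metadata)
}

#' Write a `mito_genome` to a GenBank flat file
#'
#' Emits LOCUS/FEATURES/ORIGIN sections sufficient to round-trip through
#' [read_genbank()]: coordinates back in 1-based inclusive form, multi-segment
#' features as `join(...)`, minus strand as `complement(...)`.
#'
#' @param genome A [mito_genome].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  L <- genome$length_bp
  out <- c(sprintf("LOCUS       %-17s %d bp    DNA     %-9s PLN",
                   genome$id, L, if (genome$is_circular) "circular" else "linear"),
           sprintf("ACCESSION   %s", genome$id),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", L))
  org <- genome$metadata$organism
  if (!is.null(org)) out <- c(out, sprintf("                     /organism=\"%s\"", org))
  key_for <- c(PCG = "CDS", free_ORF = "CDS", intronic_ORF = "CDS",
               rRNA = "rRNA", tRNA = "tRNA", intron = "intron")
  for (f in genome$features) {
    segs <- f$segments
    if (f$strand < 0L) segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
    loc <- paste(sprintf("%d..%d", segs[, 1L] + 1L, segs[, 2L]), collapse = ",")
    if (nrow(segs) > 1L) loc <- sprintf("join(%s)", loc)
    if (f$strand < 0L) loc <- sprintf("complement(%s)", loc)
    out <- c(out, sprintf("     %-15s %s", key_for[[f$kind]], loc),
             sprintf("                     /gene=\"%s\"", f$name))
    if (!is.na(f$anticodon)) {
      out <- c(out, sprintf("                     /anticodon=\"(seq:%s)\"", f$anticodon))
    }
    if (!is.na(f$notes)) {
      out <- c(out, sprintf("                     /note=\"%s\"", f$notes))
    }
  }
  out <- c(out, "ORIGIN")
  s <- tolower(genome$sequence)
  pos <- seq(1L, nchar(s), by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, nchar(s)))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", p, paste(groups, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

## ---- feature table --------------------------------------------------------

#' Write the feature table of a genome as TSV
#'
#' One row per feature: name, kind, 1-based inclusive segment coordinates in
#' transcription order (`start..end` pairs separated by `;`), strand, spliced
#' length, anticodon, notes. Round-trips through [read_feature_table()].
#'
#' @param genome A [mito_genome].
#' @param path Optional output path; when `NULL` the table is returned only.
#' @return Data frame, invisibly when written to `path`.
#' @export
write_feature_table <- function(genome, path = NULL) {
  rows <- lapply(genome$features, function(f) {
    data.frame(
      name = f$name, kind = f$kind,
      location = paste(sprintf("%d..%d", f$segments[, 1L] + 1L, f$segments[, 2L]),
                       collapse = ";"),
      strand = ifelse(f$strand > 0L, "+", "-"),
      length = feature_length(f),
      anticodon = f$anticodon, notes = f$notes,
      stringsAsFactors = FALSE
    )
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(0), kind = character(0), location = character(0),
               strand = character(0), length = integer(0),
               anticodon = character(0), notes = character(0))
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path TSV path.
#' @return List of [gene_feature] objects.
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  lapply(seq_len(nrow(tab)), function(i) {
    segs <- do.call(rbind, lapply(strsplit(tab$location[i], ";")[[1]], function(p) {
      n <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
      c(n[1] - 1L, n[2])
    }))
    gene_feature(tab$name[i], tab$kind[i], segs,
                 if (tab$strand[i] == "+") 1L else -1L,
                 as.character(tab$anticodon[i]), as.character(tab$notes[i]))
  })
}

## ---- FASTA ----------------------------------------------------------------

#' Read a FASTA file of DNA sequences
#'
#' Preserves record order and headers, uppercases, and rejects duplicate
#' headers and non-IUPAC characters. Alignment gaps (`-`) are allowed.
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  nms <- names(x)
  if (anyDuplicated(nms)) {
    stop("duplicate FASTA headers: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  seqs <- toupper(as.character(x))
  iupac <- paste0(paste(names(Biostrings::IUPAC_CODE_MAP), collapse = ""), "-")
  bad <- grepl(sprintf("[^%s]", iupac), seqs)
  if (any(bad)) {
    stop("non-IUPAC characters in record(s): ", paste(nms[bad], collapse = ", "))
  }
  setNames(seqs, nms)
}

#' Write DNA sequences to FASTA
#'
#' @param seqs Named character vector (or `XStringSet`).
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (methods::is(seqs, "XStringSet")) seqs <- setNames(as.character(seqs), names(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    writeLines(substring(s, seq(1L, nchar(s), width),
                         pmin(seq(width, nchar(s) + width - 1L, width), nchar(s))),
               con)
  }
  invisible(path)
}
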