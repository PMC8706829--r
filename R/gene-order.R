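## Signed circular gene orders. A genome's arrangement is reduced to the
## circular order of its core genes with strand recorded as sign, put into a
## canonical form (rotation to rnl, orientation by majority sign), and
## genomes are grouped into discrete arrangement patterns by exact canonical
## equality. The field compares arrangements as named discrete patterns, not
## as rearrangement distances, so pattern identity is equality.

#' Extract the signed circular gene order of a genome
#'
#' Lists the genes of `gene_set` in circular genomic order starting from the
#' sequence origin, with transcription strand recorded as sign (a leading
#' `-`). Genes of the set absent from the annotation are reported in
#' `missing`; a duplicated core gene is an error naming the gene. With
#' `with_trn = TRUE` an additional track including tRNA genes is kept for
#' cluster reports.
#'
#' @param genome A [mito_genome].
#' @param gene_set Canonical symbols to track (default the 16 core genes).
#' @param with_trn Keep a second track that also lists tRNA genes.
#' @return An object of class `gene_order_signature` with fields `taxon`,
#'   `symbols`, `trn_track`, `missing`.
#' @export
extract_order <- function(genome, gene_set = core_gene_set(), with_trn = FALSE) {
  nms <- feature_names(genome)
  base <- sub("_[0-9]+$", "", nms)
  dup_core <- unique(base[base %in% gene_set][duplicated(base[base %in% gene_set])])
  if (length(dup_core)) {
    stop("duplicated core gene(s) in annotation of '", genome$id, "': ",
         paste(dup_core, collapse = ", "))
  }
  sel <- which(base %in% gene_set)
  feats <- genome$features[sel]
  starts <- vapply(feats, function(f) min(f$segments[, 1L]), numeric(1))
  ord <- order(starts)
  symbols <- vapply(feats[ord], function(f) {
    paste0(if (f$strand < 0L) "-" else "", sub("_[0-9]+$", "", f$name))
  }, "")
  trn_track <- NULL
  if (with_trn) {
    sel2 <- which(base %in% gene_set |
                    vapply(genome$features, `[[`, "", "kind") == "tRNA")
    feats2 <- genome$features[sel2]
    starts2 <- vapply(feats2, function(f) min(f$segments[, 1L]), numeric(1))
    trn_track <- vapply(feats2[order(starts2)], function(f) {
      paste0(if (f$strand < 0L) "-" else "", f$name)
    }, "")
  }
  structure(
    list(taxon = genome$id, symbols = symbols, trn_track = trn_track,
         missing = setdiff(gene_set, base)),
    class = "gene_order_signature"
  )
}

#' Build a signature from a signed symbol vector
#'
#' Convenience constructor for precomputed orders (e.g. read from a TSV):
#' symbols with a leading `-` are minus strand.
#'
#' @param taxon Label.
#' @param symbols Signed symbol vector (e.g. `c("rnl", "cox1", "-nad4")`).
#' @param gene_set Set used to compute `missing`.
#' @param trn_track Optional signed track including tRNAs.
#' @return A `gene_order_signature`.
#' @export
gene_order_signature <- function(taxon, symbols, gene_set = core_gene_set(),
                                 trn_track = NULL) {
  structure(
    list(taxon = taxon, symbols = symbols, trn_track = trn_track,
         missing = setdiff(gene_set, sub("^-", "", symbols))),
    class = "gene_order_signature"
  )
}

#' @export
print.gene_order_signature <- function(x, ...) {
  cat(sprintf("<gene_order_signature> %s\n  %s\n", x$taxon,
              paste(x$symbols, collapse = " ")))
  if (length(x$missing)) cat("  missing:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}

sym_name <- function(s) sub("^-", "", s)
sym_neg <- function(s) {
  ifelse(startsWith(s, "-"), sub("^-", "", s), paste0("-", s))
}

rotate_vec <- function(x, i) if (i <= 1L) x else c(x[i:length(x)], x[seq_len(i - 1L)])

## reverse order and negate signs: the same circular arrangement read from
## the opposite strand
reflect_vec <- function(x) sym_neg(rev(x))

#' Canonicalize a signed circular gene order
#'
#' Two genomes differing only by choice of sequence origin or strand share
#' one canonical form: orientation is normalized so that the majority of
#' genes carry `+` sign (reflecting when not), then the list is rotated to
#' start at `rnl`; when `rnl` is absent the lexicographically smallest
#' rotation is used.
#'
#' @param sig A `gene_order_signature` (or a signed symbol vector).
#' @return Canonicalized object of the same type.
#' @export
canonicalize <- function(sig) {
  vec <- if (inherits(sig, "gene_order_signature")) sig$symbols else sig
  if (length(vec) == 0L) stop("empty gene-order signature")
  n_neg <- sum(startsWith(vec, "-"))
  flipped <- n_neg > length(vec) - n_neg
  if (flipped) vec <- reflect_vec(vec)
  i <- match("rnl", sym_name(vec))
  vec <- if (!is.na(i)) {
    rotate_vec(vec, i)
  } else {
    rots <- vapply(seq_along(vec), function(j)
      paste(rotate_vec(vec, j), collapse = "\r"), "")
    rotate_vec(vec, which.min(rots))
  }
  if (!inherits(sig, "gene_order_signature")) return(vec)
  sig$symbols <- vec
  if (!is.null(sig$trn_track)) {
    tt <- sig$trn_track
    if (flipped) tt <- reflect_vec(tt)
    anchor <- sym_name(vec[1L])
    j <- match(anchor, sub("_[0-9]+$", "", sym_name(tt)))
    if (!is.na(j)) sig$trn_track <- rotate_vec(tt, j)
  }
  sig
}

canonical_key <- function(sig) {
  paste(canonicalize(sig)$symbols, collapse = "|")
}

## adjacency multiset of a circular signed order: ordered pairs of unsigned
## names for each consecutive pair, wrap included
adjacencies <- function(symbols) {
  nm <- sym_name(symbols)
  paste(nm, c(nm[-1L], nm[1L]), sep = ">")
}

## human-readable note describing a pattern relative to the dominant one
describe_vs_dominant <- function(rep_sig, dom_sig) {
  a <- canonicalize(rep_sig)$symbols
  b <- canonicalize(dom_sig)$symbols
  if (!setequal(sym_name(a), sym_name(b))) {
    extra <- setdiff(sym_name(a), sym_name(b))
    miss <- setdiff(sym_name(b), sym_name(a))
    parts <- c(if (length(miss)) paste("lacking", paste(miss, collapse = ", ")),
               if (length(extra)) paste("extra", paste(extra, collapse = ", ")))
    return(paste(parts, collapse = "; "))
  }
  inverted <- sym_name(a)[startsWith(a, "-")]
  inverted <- setdiff(inverted, sym_name(b)[startsWith(b, "-")])
  nm_a <- sym_name(a); nm_b <- sym_name(b)
  pred_a <- setNames(c(nm_a[length(nm_a)], nm_a[-length(nm_a)]), nm_a)
  succ_a <- setNames(c(nm_a[-1L], nm_a[1L]), nm_a)
  pred_b <- setNames(c(nm_b[length(nm_b)], nm_b[-length(nm_b)]), nm_b)
  succ_b <- setNames(c(nm_b[-1L], nm_b[1L]), nm_b)
  moved <- nm_a[pred_a[nm_a] != pred_b[nm_a] & succ_a[nm_a] != succ_b[nm_a]]
  notes <- character(0)
  if (length(moved)) {
    notes <- c(notes, vapply(moved, function(g) {
      sprintf("%s relocated between %s and %s (was between %s and %s)",
              g, pred_a[[g]], succ_a[[g]], pred_b[[g]], succ_b[[g]])
    }, ""))
  }
  if (length(inverted)) {
    notes <- c(notes, paste("inverted:", paste(inverted, collapse = ", ")))
  }
  if (length(notes) == 0L) notes <- "rearranged relative to dominant pattern"
  paste(notes, collapse = "; ")
}

#' Classify gene arrangement patterns across genomes
#'
#' Groups signatures by exact equality of their canonical core order and
#' labels the groups `A`, `B`, ... by descending size (ties broken by first
#' occurrence in the input). A signature with missing core genes joins the
#' pattern whose order, after deletion of those genes, matches it; such
#' members are recorded with a partial-match note rather than founding a new
#' pattern. Each non-dominant pattern carries a minimal edit note relative to
#' the dominant pattern, derived from the difference of gene adjacencies.
#'
#' @param sigs List of `gene_order_signature` objects.
#' @return An object of class `pattern_classification`: list of pattern
#'   assignments (fields `pattern_label`, `member_taxa`, `representative`,
#'   `description`, `partial_members`).
#' @export
classify_patterns <- function(sigs) {
  if (length(sigs) == 0L) stop("need at least one gene-order signature")
  complete <- Filter(function(s) length(s$missing) == 0L, sigs)
  partial <- Filter(function(s) length(s$missing) > 0L, sigs)
  keys <- vapply(complete, canonical_key, "")
  groups <- split(seq_along(complete), factor(keys, levels = unique(keys)))
  pats <- lapply(groups, function(idx) {
    list(member_taxa = vapply(complete[idx], `[[`, "", "taxon"),
         representative = canonicalize(complete[[idx[1L]]]),
         partial_members = character(0))
  })
  ## attach signatures with missing genes to the pattern they reduce to
  orphans <- list()
  for (s in partial) {
    skey <- canonical_key(s)
    hit <- NA_integer_; hit_size <- -1L
    for (i in seq_along(pats)) {
      rep_syms <- pats[[i]]$representative$symbols
      reduced <- rep_syms[!sym_name(rep_syms) %in% s$missing]
      if (length(reduced) &&
          paste(canonicalize(reduced), collapse = "|") == skey) {
        if (length(pats[[i]]$member_taxa) > hit_size) {
          hit <- i; hit_size <- length(pats[[i]]$member_taxa)
        }
      }
    }
    if (is.na(hit)) {
      orphans[[length(orphans) + 1L]] <- s
    } else {
      pats[[hit]]$member_taxa <- c(pats[[hit]]$member_taxa, s$taxon)
      pats[[hit]]$partial_members <-
        c(pats[[hit]]$partial_members,
          sprintf("%s (partial match; lacking %s)", s$taxon,
                  paste(s$missing, collapse = ", ")))
    }
  }
  for (s in orphans) {
    pats[[length(pats) + 1L]] <- list(
      member_taxa = s$taxon, representative = canonicalize(s),
      partial_members = character(0))
  }
  sizes <- vapply(pats, function(p) length(p$member_taxa), integer(1))
  ord <- order(-sizes, seq_along(pats))
  pats <- pats[ord]
  dom <- pats[[1L]]$representative
  labels <- make.unique(c(LETTERS, paste0("Z", seq_len(max(0, length(pats) - 26)))))
  out <- lapply(seq_along(pats), function(i) {
    p <- pats[[i]]
    p$pattern_label <- labels[i]
    p$description <- if (i == 1L) "dominant pattern" else
      describe_vs_dominant(p$representative, dom)
    p[c("pattern_label", "member_taxa", "representative", "description",
        "partial_members")]
  })
  structure(out, class = "pattern_classification")
}

#' @export
print.pattern_classification <- function(x, ...) {
  for (p in x) {
    cat(sprintf("pattern %s (n=%d): %s\n", p$pattern_label,
                length(p$member_taxa), p$description))
  }
  invisible(x)
}

#' Tabulate a pattern classification
#'
#' @param patterns A `pattern_classification`.
#' @return Data frame with one row per taxon: `taxon`, `pattern`, `note`.
#' @export
pattern_table <- function(patterns) {
  rows <- lapply(patterns, function(p) {
    partial <- sub(" .*$", "", p$partial_members)
    data.frame(taxon = p$member_taxa, pattern = p$pattern_label,
               note = ifelse(p$member_taxa %in% partial, "partial match", ""),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' tRNA cluster report across taxa
#'
#' For each inter-core interval (keyed by the upstream core gene of the
#' canonical track) counts the consecutive tRNA genes per taxon and flags
#' intervals whose counts vary across taxa. Mitochondrial tRNAs cluster at a
#' few intergenic hotspots (downstream of rnl, rns, nad6), so these counts
#' are the natural summary of tRNA-level rearrangement.
#'
#' @param sigs List of `gene_order_signature` objects built with
#'   `with_trn = TRUE`.
#' @return Data frame: `after_gene`, one count column per taxon, `variable`.
#' @export
trn_cluster_report <- function(sigs) {
  if (any(vapply(sigs, function(s) is.null(s$trn_track), logical(1)))) {
    stop("all signatures must carry a trn_track (use with_trn = TRUE)")
  }
  counts <- lapply(sigs, function(s) {
    tt <- canonicalize(s)$trn_track
    nm <- sub("_[0-9]+$", "", sym_name(tt))
    is_trn <- startsWith(nm, "trn")
    core_pos <- which(!is_trn)
    cl <- setNames(integer(length(core_pos)), nm[core_pos])
    for (j in seq_along(core_pos)) {
      a <- core_pos[j]
      b <- if (j < length(core_pos)) core_pos[j + 1L] else core_pos[1L] + length(tt)
      idx <- if (b - a <= 1L) integer(0) else
        ((seq(a + 1L, b - 1L) - 1L) %% length(tt)) + 1L
      cl[j] <- sum(is_trn[idx])
    }
    cl
  })
  genes <- unique(unlist(lapply(counts, names)))
  tab <- data.frame(after_gene = genes, stringsAsFactors = FALSE)
  for (i in seq_along(sigs)) {
    tab[[sigs[[i]]$taxon]] <- vapply(genes, function(g) {
      v <- counts[[i]][g]
      if (is.na(v)) NA_integer_ else as.integer(v)
    }, integer(1))
  }
  cnt <- as.matrix(tab[, -1L, drop = FALSE])
  tab$variable <- apply(cnt, 1L, function(r) length(unique(stats::na.omit(r))) > 1L)
  tab
}
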