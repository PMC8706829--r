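## Synthetic annotated mitogenomes with known ground truth. The generator
## emulates the architecture of small hypocrealean mitogenomes: a circular
## molecule around 30 kb, AT-rich, every gene transcribed on one strand,
## 14 core PCGs + 2 rRNAs + 28 tRNAs + free-standing ORFs, configurable
## junction intervals (e.g. the invariant nad4L/nad5 one-base overlap),
## and group I introns with T/G boundaries and embedded ORFs. Every planted
## property is logged so downstream reports can be predicted exactly.

#' Default gene order of the synthetic mitogenome
#'
#' A single-strand arrangement with cox1 between rnl and nad2 (the
#' Stachybotryaceae-like configuration), a large tRNA cluster downstream of
#' rnl, smaller clusters after rns and nad6, single tRNAs upstream of nad4L
#' and after cob/cox3, and two free-standing ORFs at the nad3/atp9 and
#' cox2/nad4L intergenic regions. 28 tRNAs covering all 20 amino acids.
#'
#' @param pattern `"B"` (default, cox1 after rnl) or `"A"` (cox1 between cob
#'   and nad1, the arrangement dominant across Hypocreales).
#' @return Character vector of gene symbols in circular order.
#' @export
default_gene_order <- function(pattern = c("B", "A")) {
  pattern <- match.arg(pattern)
  cluster_rnl <- c("trnT", "trnE", "trnM_1", "trnM_2", "trnL_1", "trnA",
                   "trnF_1", "trnK", "trnL_2", "trnQ", "trnH")
  cluster_rns <- c("trnY", "trnD", "trnS_1", "trnN_1")
  cluster_nad6 <- c("trnM_3", "trnP", "trnW", "trnI", "trnS_2")
  tail_trn <- c("trnV", "trnR_2", "trnN_2", "trnF_2", "trnG_2")
  mid <- c("nad2", "nad3", "orf204", "atp9", "cox2", "orf350", "trnR_1",
           "nad4L", "nad5", "cob", "trnC")
  if (pattern == "B") {
    c("rnl", cluster_rnl, "cox1", mid, "nad1", "nad4", "atp8", "atp6",
      "rns", cluster_rns, "cox3", "trnG_1", "nad6", cluster_nad6, tail_trn)
  } else {
    c("rnl", cluster_rnl, mid, "cox1", "nad1", "nad4", "atp8", "atp6",
      "rns", cluster_rns, "cox3", "trnG_1", "nad6", cluster_nad6, tail_trn)
  }
}

default_gene_lengths <- function() {
  c(nad1 = 1104L, nad2 = 1686L, nad3 = 423L, nad4 = 1482L, nad4L = 270L,
    nad5 = 1998L, nad6 = 627L, cob = 1161L, cox1 = 1608L, cox2 = 750L,
    cox3 = 810L, atp6 = 774L, atp8 = 147L, atp9 = 225L,
    rnl = 3200L, rns = 1550L, orf204 = 618L, orf350 = 1056L)
}

#' Specification for a synthetic mitogenome
#'
#' Defaults describe the "stachybotrys-like" fixture: ~30.7 kb circular
#' genome, AT 73.7% with AT skew -0.02 and GC skew 0.12, the gene order of
#' [default_gene_order()], a nad4L/nad5 overlap of one base and an abutting
#' nad2/nad3 junction, and two group I introns - one in rnl at reference
#' position 2450 carrying an rps3-like ORF of 450 aa, one in cox1 at
#' position 1125 carrying a LAGLIDADG-motif ORF of 712 aa (intron lengths
#' 1600 + 2284 = 3884 intronic nucleotides). Nonstandard start/stop codons
#' mirror the audit cases typical of these genomes (cob GTG, cox3 TTG
#' starts; atp9 and nad5 TAG stops).
#'
#' @param id Genome label.
#' @param gene_order Symbols in circular order.
#' @param gene_lengths Named nt lengths (PCG lengths include the stop codon);
#'   tRNAs default to `trna_length`.
#' @param trna_length tRNA gene length (default 72).
#' @param spacer_range Intergenic spacer length range, default `c(60, 180)`.
#' @param junction_overrides Named list `"up|down" = interval`; `-1` builds a
#'   one-base overlap (upstream TAA sharing its last base with the
#'   downstream ATG), `0` abutting, positive an exact spacer.
#' @param introns List of intron plants: each a list with `host`, `position`
#'   (1-based base of the uncut host after which the intron sits), `length`,
#'   optional `orf_aa`, `orf_name`, `motif` (`"LAGLIDADG"` embeds the
#'   motif in the ORF).
#' @param at_percent,at_skew,gc_skew Base composition targets.
#' @param size_target,size_tol Realizability check on total length.
#' @param start_overrides,stop_overrides Named codon overrides per gene.
#' @param rotate Origin offset applied to the finished genome.
#' @return List of class `genome_spec`.
#' @export
genome_spec <- function(id = "synthetic_stachybotrys_like",
                        gene_order = default_gene_order("B"),
                        gene_lengths = default_gene_lengths(),
                        trna_length = 72L,
                        spacer_range = c(60L, 180L),
                        junction_overrides = list(`nad4L|nad5` = -1L,
                                                  `nad2|nad3` = 0L),
                        introns = list(
                          list(host = "rnl", position = 2450L, length = 1600L,
                               orf_aa = 450L, orf_name = "rps3", group = "IA"),
                          list(host = "cox1", position = 1125L, length = 2284L,
                               orf_aa = 712L, motif = "LAGLIDADG",
                               group = "IB")),
                        at_percent = 73.7, at_skew = -0.02, gc_skew = 0.12,
                        size_target = 30745L, size_tol = 3000L,
                        start_overrides = c(cob = "GTG", cox3 = "TTG"),
                        stop_overrides = c(atp9 = "TAG", nad5 = "TAG"),
                        rotate = 0L) {
  spec <- list(id = id, gene_order = gene_order, gene_lengths = gene_lengths,
               trna_length = as.integer(trna_length),
               spacer_range = as.integer(spacer_range),
               junction_overrides = junction_overrides, introns = introns,
               at_percent = at_percent, at_skew = at_skew, gc_skew = gc_skew,
               size_target = as.integer(size_target),
               size_tol = as.integer(size_tol),
               start_overrides = start_overrides,
               stop_overrides = stop_overrides, rotate = as.integer(rotate))
  class(spec) <- "genome_spec"
  spec
}

base_probs <- function(at_percent, at_skew, gc_skew) {
  f <- at_percent / 100
  c(A = f / 2 * (1 + at_skew), C = (1 - f) / 2 * (1 - gc_skew),
    G = (1 - f) / 2 * (1 + gc_skew), T = f / 2 * (1 - at_skew))
}

sample_bases <- function(n, probs) {
  if (n <= 0L) return("")
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

## codon sampler that never emits a stop codon: coding sequences stay open
## under the requested genetic code by construction
codon_table <- function(probs, transl_table = 4L) {
  gc <- Biostrings::getGeneticCode(as.character(transl_table))
  cods <- names(gc)[gc != "*"]
  w <- vapply(cods, function(cd) {
    prod(probs[strsplit(cd, "")[[1]]])
  }, numeric(1))
  list(codons = cods, weights = w / sum(w))
}

sample_codons <- function(n, ct) {
  if (n <= 0L) return("")
  paste(sample(ct$codons, n, replace = TRUE, prob = ct$weights), collapse = "")
}

make_cds <- function(nt_len, ct, start = "ATG", stop = "TAA") {
  stopifnot(nt_len %% 3L == 0L, nt_len >= 9L)
  paste0(start, sample_codons(nt_len %/% 3L - 2L, ct), stop)
}

## embed an ORF (and optionally a protein motif) inside an intron sequence
## ending in G; the base before the insertion point in the host must be T
make_intron <- function(len, ct, probs, orf_aa = NULL, motif = NULL,
                        transl_table = 4L) {
  if (is.null(orf_aa)) {
    s <- sample_bases(len - 1L, probs)
    return(list(seq = paste0(s, "G"), orf_start = NA_integer_,
                orf_len = NA_integer_))
  }
  orf_nt <- 3L * (orf_aa + 1L)   # aa residues + stop codon
  lead <- 90L
  if (len < orf_nt + lead + 30L) {
    stop("intron length ", len, " too short for a ", orf_aa, " aa ORF")
  }
  orf <- make_cds(orf_nt, ct)
  if (!is.null(motif) && motif == "LAGLIDADG") {
    ## overwrite codons 11..19 with the motif's codons
    aa2codon <- c(L = "TTA", A = "GCT", G = "GGT", I = "ATT", D = "GAT")
    mseq <- paste(aa2codon[strsplit("LAGLIDADG", "")[[1]]], collapse = "")
    substr(orf, 31L, 30L + nchar(mseq)) <- mseq
  }
  tail_len <- len - lead - orf_nt
  list(seq = paste0(sample_bases(lead, probs), orf,
                    sample_bases(tail_len - 1L, probs), "G"),
       orf_start = lead, orf_len = orf_nt)
}

element_kind <- function(name) {
  base <- sub("_[0-9]+$", "", name)
  if (base %in% CORE_PCGS) "PCG"
  else if (base %in% c("rnl", "rns")) "rRNA"
  else if (startsWith(base, "trn")) "tRNA"
  else if (grepl("^orf[0-9]+$", base)) "free_ORF"
  else stop("cannot classify synthetic element '", name, "'")
}

#' Generate a synthetic annotated mitogenome
#'
#' Builds the circular sequence and full annotation from a [genome_spec]:
#' protein-coding genes are generated codon-wise (no internal stops under
#' the mold mitochondrial code), junction overrides are honored exactly,
#' introns are inserted with the group I boundary signature (host base `T`
#' immediately 5' of the intron, intron ending `G`), and every planted
#' property is recorded in the returned plant log. Deterministic per seed.
#'
#' @param spec A [genome_spec].
#' @param seed Integer seed fixing all randomness.
#' @return List with `genome` (a [mito_genome]) and `log` (the plant log:
#'   gene coordinates, per-junction spacers/intervals, introns, composition
#'   targets, seed).
#' @export
generate_mitogenome <- function(spec = genome_spec(), seed = 1L) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(as.integer(seed))
  probs <- base_probs(spec$at_percent, spec$at_skew, spec$gc_skew)
  ct <- codon_table(probs)
  lens <- spec$gene_lengths
  order_ <- spec$gene_order
  kinds <- vapply(order_, element_kind, "")

  len_of <- function(name) {
    base <- sub("_[0-9]+$", "", name)
    if (kinds[[name]] == "tRNA") return(spec$trna_length)
    if (!base %in% names(lens)) stop("no length configured for '", name, "'")
    lens[[base]]
  }

  ## realizability before any sequence is emitted
  intron_total <- sum(vapply(spec$introns, `[[`, integer(1), "length"))
  min_total <- sum(vapply(order_, len_of, integer(1))) + intron_total +
    length(order_) * spec$spacer_range[1L]
  if (min_total > spec$size_target + spec$size_tol) {
    stop("unrealizable spec: minimum total length ", min_total,
         " exceeds size target ", spec$size_target, " + tolerance ",
         spec$size_tol)
  }
  for (ip in spec$introns) {
    if (!ip$host %in% order_) stop("intron host '", ip$host, "' not in gene order")
    if (ip$position >= len_of(ip$host)) {
      stop("unrealizable spec: intron position ", ip$position,
           " beyond host '", ip$host, "' length ", len_of(ip$host))
    }
  }

  intron_by_host <- setNames(spec$introns,
                             vapply(spec$introns, `[[`, "", "host"))
  pieces <- character(0)
  cursor <- 0L
  features <- list()
  gene_rows <- list()
  junction_rows <- list()
  intron_rows <- list()
  prev_name <- order_[length(order_)]   # circular predecessor
  prev_last_base <- NULL

  emit <- function(s) {
    pieces[[length(pieces) + 1L]] <<- s
    cursor <<- cursor + nchar(s)
  }

  for (name in order_) {
    kind <- kinds[[name]]
    base <- sub("_[0-9]+$", "", name)
    ## spacer / junction to the previous element
    key <- paste(sub("_[0-9]+$", "", prev_name), base, sep = "|")
    ov <- spec$junction_overrides[[key]]
    overlap <- 0L
    if (!is.null(ov)) {
      ov <- as.integer(ov)
      if (ov < -1L) stop("junction overlap deeper than -1 is not supported")
      if (ov >= 0L) emit(sample_bases(ov, probs)) else overlap <- 1L
      spacer_len <- max(ov, -1L)
    } else {
      spacer_len <- sample(spec$spacer_range[1L]:spec$spacer_range[2L], 1L)
      emit(sample_bases(spacer_len, probs))
    }
    ## gene sequence
    if (kind == "PCG" || kind == "free_ORF") {
      nt <- len_of(name)
      start_c <- if (base %in% names(spec$start_overrides))
        spec$start_overrides[[base]] else "ATG"
      stop_c <- if (base %in% names(spec$stop_overrides))
        spec$stop_overrides[[base]] else "TAA"
      gseq <- make_cds(nt, ct, start_c, stop_c)
    } else if (kind == "tRNA") {
      gseq <- sample_bases(spec$trna_length, probs)
    } else {
      gseq <- sample_bases(len_of(name), probs)
    }
    if (overlap == 1L) {
      ## one-base overlap: upstream's final base doubles as this gene's first
      if (is.null(prev_last_base) || prev_last_base != substr(gseq, 1L, 1L)) {
        stop("cannot overlap '", prev_name, "'/'", name,
             "': terminal bases disagree")
      }
      gseq_emit <- substr(gseq, 2L, nchar(gseq))
      gstart <- cursor - 1L
    } else {
      gseq_emit <- gseq
      gstart <- cursor
    }
    ip <- intron_by_host[[base]]
    if (!is.null(ip) && kind %in% c("PCG", "rRNA")) {
      pos <- as.integer(ip$position)
      ## enforce the group I boundary: host base at `pos` must be T
      if (substr(gseq, pos, pos) != "T") {
        if (kind == "PCG") {
          ## re-sample the containing codon among sense codons with T there
          ci <- (pos - 1L) %/% 3L            # 0-based codon index
          off <- (pos - 1L) %% 3L
          if (ci == 0L || ci >= nchar(gseq) %/% 3L - 1L) {
            stop("intron position ", pos, " falls on start/stop codon of ",
                 name)
          }
          ok <- ct$codons[substr(ct$codons, off + 1L, off + 1L) == "T"]
          cod <- sample(ok, 1L, prob = ct$weights[match(ok, ct$codons)])
          substr(gseq, ci * 3L + 1L, ci * 3L + 3L) <- cod
        } else {
          substr(gseq, pos, pos) <- "T"
        }
        if (overlap == 1L) gseq_emit <- substr(gseq, 2L, nchar(gseq))
        else gseq_emit <- gseq
      }
      intr <- make_intron(as.integer(ip$length), ct, probs,
                          orf_aa = ip$orf_aa, motif = ip$motif)
      ## positions are on the uncut gene; map onto the emitted string (the
      ## first base is shared with the upstream gene when overlapping)
      cut <- pos - ifelse(overlap == 1L, 1L, 0L)
      ex1 <- substr(gseq_emit, 1L, cut)
      ex2 <- substr(gseq_emit, cut + 1L, nchar(gseq_emit))
      emit(ex1); i_start <- cursor
      emit(intr$seq); i_end <- cursor
      emit(ex2)
      gend <- cursor
      features[[length(features) + 1L]] <- gene_feature(
        name, kind, rbind(c(gstart, i_start), c(i_end, gend)), 1L)
      iname <- intron_name(base, pos)
      features[[length(features) + 1L]] <- gene_feature(
        iname, "intron", c(i_start, i_end), 1L,
        notes = sprintf("group %s; synthetic",
                        if (!is.null(ip$group)) ip$group else "I"))
      orf_feat_name <- NA_character_
      if (!is.na(intr$orf_start)) {
        orf_feat_name <- if (!is.null(ip$orf_name)) ip$orf_name else
          sprintf("orf%d", intr$orf_len %/% 3L - 1L)
        features[[length(features) + 1L]] <- gene_feature(
          orf_feat_name, "intronic_ORF",
          c(i_start + intr$orf_start, i_start + intr$orf_start + intr$orf_len),
          1L)
      }
      intron_rows[[length(intron_rows) + 1L]] <- data.frame(
        host = base, name = iname, position = pos,
        length = as.integer(ip$length), orf = orf_feat_name,
        stringsAsFactors = FALSE)
    } else {
      emit(gseq_emit)
      gend <- cursor
      features[[length(features) + 1L]] <- gene_feature(name, kind,
                                                        c(gstart, gend), 1L)
    }
    gene_rows[[length(gene_rows) + 1L]] <- data.frame(
      name = name, kind = kind, start = gstart, end = cursor, strand = 1L,
      stringsAsFactors = FALSE)
    junction_rows[[length(junction_rows) + 1L]] <- data.frame(
      upstream = prev_name, downstream = name,
      interval = if (!is.null(ov)) as.integer(ov) else spacer_len,
      planted = !is.null(ov), stringsAsFactors = FALSE)
    prev_name <- name
    prev_last_base <- substr(gseq, nchar(gseq), nchar(gseq))
  }

  genome <- mito_genome(spec$id, paste(pieces, collapse = ""), TRUE, features,
                        metadata = list(organism = "synthetic taxon",
                                        note = "synthetic genome"))
  if (spec$rotate != 0L) genome <- rotate_genome(genome, spec$rotate)
  log <- list(
    spec = spec, seed = as.integer(seed),
    genes = do.call(rbind, gene_rows),
    junctions = do.call(rbind, junction_rows),
    introns = if (length(intron_rows)) do.call(rbind, intron_rows) else NULL,
    at_percent = spec$at_percent, at_skew = spec$at_skew,
    gc_skew = spec$gc_skew
  )
  list(genome = genome, log = log)
}

#' Plant mutations into near-identical individuals
#'
#' Produces `n_individuals` mutated copies of a reference genome with planted
#' substitutions and indels, logging every event with its ground truth:
#' position, alleles, genic/intergenic region, and - for substitutions in
#' coding genes - the synonymous/nonsynonymous effect computed at plant
#' time. Events are kept `min_sep` bases apart, away from region boundaries,
#' and indels never span a genic/intergenic boundary, so alignment columns
#' map back to events one-to-one and downstream tallies are predictable
#' exactly.
#'
#' @param genome Reference [mito_genome].
#' @param n_individuals Number of mutated individuals.
#' @param n_substitutions,n_indels Total event counts across all individuals.
#' @param genic_frac_sub Fraction of substitutions placed in genic regions
#'   (default 23/36, the split observed in intraspecific mitogenome
#'   comparisons of these fungi).
#' @param genic_frac_indel Fraction of indels in genic regions (default
#'   9/33).
#' @param indel_range Indel length range, default `c(1, 9)` nt.
#' @param indel_type `"deletion"` (default) or `"insertion"`.
#' @param min_sep Minimum distance between planted events, default 20.
#' @param seed Integer seed.
#' @return List with `sequences` (named character vector: reference first,
#'   then individuals) and `log` (data frame of planted events).
#' @export
mutate_individuals <- function(genome, n_individuals = 2L,
                               n_substitutions = 36L, n_indels = 33L,
                               genic_frac_sub = 23 / 36,
                               genic_frac_indel = 9 / 33,
                               indel_range = c(1L, 9L),
                               indel_type = c("deletion", "insertion"),
                               min_sep = 20L, seed = 1L) {
  indel_type <- match.arg(indel_type)
  set.seed(as.integer(seed))
  L <- genome$length_bp
  genic <- is_genic(genome, seq_len(L))
  ## positions whose +/-3 neighborhood has a constant region class, away
  ## from the sequence ends
  buf <- 3L
  ok <- rep(TRUE, L)
  for (d in -buf:buf) {
    idx <- pmin(pmax(seq_len(L) + d, 1L), L)
    ok <- ok & (genic[idx] == genic)
  }
  ok[seq_len(30L)] <- FALSE
  ok[(L - 30L):L] <- FALSE

  taken <- integer(0)   # centers of planted events
  too_close <- function(p, halfwidth = 0L) {
    length(taken) && any(abs(taken - p) < min_sep + halfwidth)
  }
  draw_pos <- function(want_genic, halfwidth = 0L) {
    pool <- which(ok & (genic == want_genic))
    for (i in seq_len(1000L)) {
      p <- sample(pool, 1L)
      if (halfwidth > 0L) {
        span <- p:(p + halfwidth)
        if (max(span) > L || !all(ok[span]) ||
            length(unique(genic[span])) != 1L) next
      }
      if (!too_close(p, halfwidth)) {
        taken <<- c(taken, p)
        return(p)
      }
    }
    stop("could not place a mutation after 1000 attempts; ",
         "reduce counts or min_sep")
  }

  n_sub_genic <- round(n_substitutions * genic_frac_sub)
  n_ind_genic <- round(n_indels * genic_frac_indel)
  events <- list()
  add_event <- function(df) events[[length(events) + 1L]] <<- df
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(n_substitutions)) {
    want <- i <= n_sub_genic
    p <- draw_pos(want)
    ref_b <- substr(genome$sequence, p, p)
    alt_b <- sample(setdiff(bases, ref_b), 1L)
    ind <- ((i - 1L) %% n_individuals) + 1L
    ce <- coding_effect(genome, p, alt_b)
    add_event(data.frame(
      individual = ind, type = "substitution", position = p, length = 1L,
      ref = ref_b, alt = alt_b, region = if (want) "genic" else "intergenic",
      gene = if (is.null(ce$gene)) NA_character_ else ce$gene,
      effect = ce$effect, stringsAsFactors = FALSE))
  }
  for (i in seq_len(n_indels)) {
    want <- i <= n_ind_genic
    len <- sample(indel_range[1L]:indel_range[2L], 1L)
    p <- draw_pos(want, halfwidth = len)
    ind <- ((i - 1L) %% n_individuals) + 1L
    add_event(data.frame(
      individual = ind, type = indel_type, position = p, length = len,
      ref = if (indel_type == "deletion") substr(genome$sequence, p, p + len - 1L)
            else "", alt = "",
      region = if (want) "genic" else "intergenic",
      gene = NA_character_, effect = NA_character_, stringsAsFactors = FALSE))
  }
  log <- if (length(events)) do.call(rbind, events) else
    data.frame(individual = integer(0), type = character(0),
               position = integer(0), length = integer(0), ref = character(0),
               alt = character(0), region = character(0), gene = character(0),
               effect = character(0), stringsAsFactors = FALSE)

  seqs <- setNames(rep(genome$sequence, n_individuals + 1L),
                   c(genome$id, sprintf("%s_ind%d", genome$id,
                                        seq_len(n_individuals))))
  for (j in seq_len(n_individuals)) {
    s <- genome$sequence
    ev <- log[log$individual == j, , drop = FALSE]
    for (r in which(ev$type == "substitution")) {
      substr(s, ev$position[r], ev$position[r]) <- ev$alt[r]
    }
    ev_id <- ev[ev$type != "substitution", , drop = FALSE]
    if (nrow(ev_id)) {
      for (r in order(-ev_id$position)) {
        p <- ev_id$position[r]; len <- ev_id$length[r]
        if (ev_id$type[r] == "deletion") {
          s <- paste0(substr(s, 1L, p - 1L), substr(s, p + len, nchar(s)))
        } else {
          ins <- sample_bases(len, c(A = .37, C = .13, G = .13, T = .37))
          s <- paste0(substr(s, 1L, p), ins, substr(s, p + 1L, nchar(s)))
        }
      }
    }
    seqs[[j + 1L]] <- s
  }
  list(sequences = seqs, log = log)
}

#' Evolve a discrete character on a tree under the Mk model
#'
#' Draws the root state from the uniform prior and evolves it along every
#' branch with the equal-rates Mk transition probability, recording the true
#' state of every internal node. The leaf matrix is the observable; the node
#' states are the ground truth for reconstruction tests.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param k Number of states (letters `A`, `B`, ...).
#' @param rate Mk rate (>= 0; 0 copies the root state everywhere).
#' @param seed Integer seed.
#' @return List: `tip_states` (named character), `node_states` (character,
#'   ancestral truth indexed by ape node id), `alphabet`, `rate`, `seed`.
#' @export
simulate_characters <- function(tree, k = 6L, rate = 0.05, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), k >= 2L, rate >= 0)
  set.seed(as.integer(seed))
  alphabet <- LETTERS[seq_len(k)]
  ntip <- length(tree$tip.label)
  states <- integer(ntip + tree$Nnode)
  root <- ntip + 1L
  states[root] <- sample.int(k, 1L)
  tr <- ape::reorder.phylo(tree, "postorder")
  for (e in rev(seq_len(nrow(tr$edge)))) {     # parents before children
    par <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
    t <- tr$edge.length[e]
    p_same <- if (rate == 0) 1 else
      1 / k + (1 - 1 / k) * exp(-k * rate * t / (k - 1))
    if (stats::runif(1L) <= p_same) {
      states[child] <- states[par]
    } else {
      states[child] <- sample(setdiff(seq_len(k), states[par]), 1L)
    }
  }
  list(
    tip_states = setNames(alphabet[states[seq_len(ntip)]], tree$tip.label),
    node_states = alphabet[states[(ntip + 1L):(ntip + tree$Nnode)]],
    alphabet = alphabet, rate = rate, seed = as.integer(seed)
  )
}
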