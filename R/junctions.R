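## Gene-junction intervals and joining states. The interval between two
## adjacent same-strand genes is the signed nucleotide count separating them
## along the transcription direction: negative = overlap, 0 = abutting,
## positive = spacer. The convention makes a one-base overlap (stop codon's
## last base doubling as the next start codon's first base) interval -1,
## the value mitogenome comparisons report for nad4L/nad5.

## transcription-direction terminal boundaries of a feature, intron-agnostic:
## junction arithmetic uses the outermost boundaries so internal introns do
## not perturb it.
txn_end <- function(feature) {
  segs <- feature$segments
  if (feature$strand > 0L) segs[nrow(segs), 2L] else segs[nrow(segs), 1L]
}
txn_start <- function(feature) {
  segs <- feature$segments
  if (feature$strand > 0L) segs[1L, 1L] else segs[1L, 2L]
}

#' Junction interval between two adjacent genes
#'
#' Signed distance from the end of `pair[1]` to the start of `pair[2]` along
#' the transcription direction, in 0-based half-open coordinates, unwrapped
#' across the circular origin: `0` means the downstream gene starts exactly
#' where the upstream one ends, `-1` a one-base overlap, positive values a
#' spacer. Genes on opposite strands are not comparable along one
#' transcription direction and are flagged rather than measured.
#'
#' @param genome A [mito_genome].
#' @param pair Character vector of two gene symbols, upstream then downstream.
#' @return An object of class `junction_record`: `taxon`, `upstream_gene`,
#'   `downstream_gene`, `interval_nt` (NA when flagged), `flag`.
#' @export
junction_interval <- function(genome, pair) {
  stopifnot(length(pair) == 2L)
  up <- get_feature(genome, pair[1L])
  dn <- get_feature(genome, pair[2L])
  rec <- list(taxon = genome$id, upstream_gene = pair[1L],
              downstream_gene = pair[2L], interval_nt = NA_integer_,
              flag = NA_character_)
  class(rec) <- "junction_record"
  if (up$strand != dn$strand) {
    rec$flag <- "opposite_strands"
    return(rec)
  }
  L <- genome$length_bp
  raw <- if (up$strand > 0L) txn_start(dn) - txn_end(up)
         else txn_end(up) - txn_start(dn)
  if (genome$is_circular) {
    raw <- raw %% L
    if (raw > L / 2) raw <- raw - L
  }
  rec$interval_nt <- as.integer(raw)
  rec
}

#' @export
print.junction_record <- function(x, ...) {
  cat(sprintf("<junction> %s: %s/%s interval = %s%s\n", x$taxon,
              x$upstream_gene, x$downstream_gene,
              ifelse(is.na(x$interval_nt), "NA", x$interval_nt),
              ifelse(is.na(x$flag), "", paste0(" [", x$flag, "]"))))
  invisible(x)
}

#' Default junction state map
#'
#' The conventional lettering of nad2/nad3 joining states: `A` interval 0 (no
#' overlap/separation), `B` interval -1 (1 bp overlap), `C` interval 1,
#' `D` interval 4, `E` interval 6.
#'
#' @return Named character vector, names = intervals as strings.
#' @export
default_state_map <- function() {
  c(`0` = "A", `-1` = "B", `1` = "C", `4` = "D", `6` = "E")
}

#' Classify joining states for one gene pair across taxa
#'
#' Assigns each taxon the letter its interval maps to; intervals not in the
#' map are allocated fresh letters in order of appearance. Returns the
#' per-taxon assignment and the state census.
#'
#' @param records List of `junction_record` for one gene pair.
#' @param state_map Named map interval -> letter, see [default_state_map()].
#' @return List with `assignments` (data frame `taxon`, `interval_nt`,
#'   `state`, `flag`) and `census` (table of counts per state).
#' @export
classify_joining <- function(records, state_map = default_state_map()) {
  if (inherits(records, "junction_record")) records <- list(records)
  pairs <- unique(vapply(records, function(r)
    paste(r$upstream_gene, r$downstream_gene, sep = "/"), ""))
  if (length(pairs) > 1L) {
    stop("records mix gene pairs: ", paste(pairs, collapse = ", "))
  }
  map <- state_map
  next_letters <- setdiff(LETTERS, map)
  assign_one <- function(interval) {
    key <- as.character(interval)
    if (!key %in% names(map)) {
      map[[key]] <<- next_letters[1L]
      next_letters <<- next_letters[-1L]
    }
    map[[key]]
  }
  rows <- lapply(records, function(r) {
    st <- if (is.na(r$interval_nt)) NA_character_ else assign_one(r$interval_nt)
    data.frame(taxon = r$taxon, interval_nt = r$interval_nt, state = st,
               flag = r$flag, stringsAsFactors = FALSE)
  })
  assignments <- do.call(rbind, rows)
  census <- table(assignments$state)
  list(assignments = assignments, census = census, state_map = map)
}

#' Audit a junction expected to be fixed across taxa
#'
#' Computes the junction for every genome and lists the taxa whose interval
#' deviates from the expected value. The nad4L/nad5 junction of Hypocreales
#' mitogenomes is the motivating case: a one-base overlap (`-1`) in every
#' examined genome.
#'
#' @param genomes List of [mito_genome] objects.
#' @param pair Gene pair, default `c("nad4L", "nad5")`.
#' @param expected Expected interval, default `-1`.
#' @return List with `records` (all junction records), `deviations` (data
#'   frame of taxa whose interval differs or is flagged).
#' @export
audit_fixed_junction <- function(genomes, pair = c("nad4L", "nad5"),
                                 expected = -1L) {
  records <- lapply(genomes, junction_interval, pair = pair)
  rows <- lapply(records, function(r) {
    data.frame(taxon = r$taxon, interval_nt = r$interval_nt, flag = r$flag,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  dev <- tab[is.na(tab$interval_nt) | tab$interval_nt != expected, , drop = FALSE]
  list(records = records, expected = expected, deviations = dev)
}
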