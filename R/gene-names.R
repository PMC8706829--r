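## Gene symbol normalization. Public fungal mitogenome records use a zoo of
## synonyms (ND4L, cytb, COX1, LSU rRNA, ...); analyses need one canonical
## vocabulary: the 14 core protein-coding genes, rnl/rns, and trn<AA> tRNAs.

CORE_PCGS <- c("atp6", "atp8", "atp9", "cob", "cox1", "cox2", "cox3",
               "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6")

#' The 16 core mitochondrial genes
#'
#' The 14 core protein-coding genes typical of fungal mitogenomes
#' (nad1-6, nad4L, cob, cox1-3, atp6/8/9) plus the two rRNA genes
#' (rnl, rns), in alphabetical order.
#'
#' @return Character vector of canonical symbols.
#' @export
core_gene_set <- function() c(CORE_PCGS, "rnl", "rns")

AA3_TO_1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
              Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
              Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
              Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
              Xaa = "X", OTHER = "X")

#' Default gene-name synonym table
#'
#' Maps the symbols encountered in public records to canonical names. The
#' mapping is total over the 16 core genes; unknown names pass through and
#' are flagged nonstandard by [normalize_gene_name()]. Users can extend it by
#' row-binding their own `synonym`/`canonical` pairs or by supplying a TSV
#' with those two columns via `extra`.
#'
#' @param extra Optional data frame (or path to a two-column TSV) with
#'   columns `synonym` and `canonical` appended to the defaults.
#' @return Data frame with columns `synonym` (lower case) and `canonical`.
#' @export
default_gene_name_map <- function(extra = NULL) {
  syn <- list(
    nad1 = c("nd1", "nadh1", "nadh dehydrogenase subunit 1"),
    nad2 = c("nd2", "nadh2"), nad3 = c("nd3", "nadh3"),
    nad4 = c("nd4", "nadh4"),
    nad4L = c("nd4l", "nad4l", "nadh4l"),
    nad5 = c("nd5", "nadh5"), nad6 = c("nd6", "nadh6"),
    cob = c("cytb", "cob1", "ctyb", "cytochrome b"),
    cox1 = c("co1", "coi", "coxi"), cox2 = c("co2", "coii", "coxii"),
    cox3 = c("co3", "coiii", "coxiii"),
    atp6 = c("atpase6", "atp_6"), atp8 = c("atpase8", "atp_8"),
    atp9 = c("atpase9", "atp_9", "oli"),
    rnl = c("lsu", "l-rrna", "rrnl", "lsu rrna", "large subunit ribosomal rna",
            "21s_rrna", "rrn26", "ml"),
    rns = c("ssu", "s-rrna", "rrns", "ssu rrna", "small subunit ribosomal rna",
            "15s_rrna", "rrn18", "ms"),
    rps3 = c("rps3", "ribosomal protein s3", "s3")
  )
  canon <- c(core_gene_set(), "rps3")
  map <- data.frame(
    synonym = c(tolower(canon), tolower(unlist(syn))),
    canonical = c(canon, rep(names(syn), lengths(syn))),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) {
    if (is.character(extra)) {
      extra <- utils::read.delim(extra, stringsAsFactors = FALSE)
    }
    stopifnot(all(c("synonym", "canonical") %in% names(extra)))
    extra$synonym <- tolower(extra$synonym)
    map <- rbind(map, extra[, c("synonym", "canonical")])
  }
  map[!duplicated(map$synonym), , drop = FALSE]
}

#' Normalize a gene symbol
#'
#' Case-insensitive lookup through the synonym table; tRNA product strings
#' such as `"tRNA-Met"` become `trnM`. Names with a trailing duplicate index
#' (`trnM_2`) keep their index. Unknown names pass through unchanged with
#' attribute `nonstandard = TRUE`.
#'
#' @param name Raw symbol or product string.
#' @param map Synonym table from [default_gene_name_map()].
#' @return Canonical symbol (character scalar, possibly with attribute
#'   `nonstandard`).
#' @export
normalize_gene_name <- function(name, map = default_gene_name_map()) {
  raw <- trimws(name)
  ## tRNA product strings: tRNA-Met, trn M (cat), trnM...
  m <- regmatches(raw, regexec("^t[Rr][Nn][Aa]?[-_ ]?([A-Za-z]{3})\\b", raw))[[1]]
  if (length(m) == 2L && m[2] %in% names(AA3_TO_1)) {
    return(paste0("trn", AA3_TO_1[[m[2]]]))
  }
  m <- regmatches(raw, regexec("^trn([A-Z])(_[0-9]+)?$", raw))[[1]]
  if (length(m) >= 2L) return(raw)
  ## split a duplicate suffix before lookup
  sfx <- ""
  m <- regmatches(raw, regexec("^(.*)(_[0-9]+)$", raw))[[1]]
  base <- raw
  if (length(m) == 3L) { base <- m[2]; sfx <- m[3] }
  hit <- match(tolower(base), map$synonym)
  if (!is.na(hit)) return(paste0(map$canonical[hit], sfx))
  if (grepl("^orf[0-9]+$", tolower(raw))) return(tolower(raw))
  structure(raw, nonstandard = TRUE)
}

## Disambiguate duplicated feature names with _1, _2, ... in genome order.
## Input features must already be sorted by genomic start.
dedup_feature_names <- function(features) {
  nms <- vapply(features, `[[`, "", "name")
  dup <- names(which(table(nms) > 1L))
  for (d in dup) {
    idx <- which(nms == d)
    for (j in seq_along(idx)) {
      features[[idx[j]]]$name <- sprintf("%s_%d", d, j)
    }
  }
  features
}
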