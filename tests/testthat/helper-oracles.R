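## Shared fixtures and independent oracles used across the test files.
## Oracles are deliberately naive (enumeration, brute-force scans, plain
## dynamic programming) and never call the code paths they check.

## ---- tiny handcrafted GenBank records ------------------------------------

## 120 bp circular record: one forward CDS at 1..9, one CDS joined across
## the origin, one minus-strand tRNA
tiny_gb_text <- function() {
  seq120 <- paste0(
    "atgaaataac", "gtacgtacgt", "acgtacgtac", "gtacgtacgt",  # 1-40
    "aaccggttaa", "ccggttaacc", "ggttaaccgg", "ttaaccggtt",  # 41-80
    "acgtacgtaa", "gggcccattt", "aaatttcccg", "atgtttaaag"   # 81-120
  )
  c("LOCUS       TINY01                 120 bp    DNA     circular PLN",
    "ACCESSION   TINY01",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    "                     /organism=\"Test fungus\"",
    "     CDS             1..9",
    "                     /gene=\"nad3\"",
    "     CDS             join(109..120,1..9)",
    "                     /gene=\"orf6\"",
    "     tRNA            complement(41..112)",
    "                     /product=\"tRNA-Met\"",
    "ORIGIN",
    paste0("        1 ", paste(substring(seq120, seq(1, 51, 10), seq(10, 60, 10)),
                               collapse = " ")),
    paste0("       61 ", paste(substring(seq120, seq(61, 111, 10), seq(70, 120, 10)),
                               collapse = " ")),
    "//")
}

write_tiny_gb <- function() {
  p <- tempfile(fileext = ".gb")
  writeLines(tiny_gb_text(), p)
  p
}

## small annotated genome built directly from the model (no parsing)
toy_genome <- function() {
  s <- paste(rep("ACGTTTGCAT", 10), collapse = "")  # 100 bp
  mito_genome("toy", s, TRUE, list(
    gene_feature("nad1", "PCG", c(0L, 40L)),
    gene_feature("nad2", "PCG", c(30L, 60L))
  ))
}

## ---- composition oracle ---------------------------------------------------

brute_composition <- function(s) {
  ch <- strsplit(toupper(s), "")[[1]]
  a <- sum(ch == "A"); t <- sum(ch == "T")
  g <- sum(ch == "G"); c_ <- sum(ch == "C")
  list(at_percent = 100 * (a + t) / (a + t + g + c_),
       at_skew = (a - t) / (a + t), gc_skew = (g - c_) / (g + c_))
}

## ---- Mk enumeration oracles ----------------------------------------------

mk_P_oracle <- function(k, rate, t) {
  e <- exp(-k * rate * t / (k - 1))
  m <- matrix((1 - e) / k, k, k)
  diag(m) <- 1 / k + (1 - 1 / k) * e
  m
}

enum_loglik <- function(tree, states, rate, alphabet) {
  k <- length(alphabet)
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  Pe <- lapply(tree$edge.length, function(t) mk_P_oracle(k, rate, t))
  tipidx <- match(states[tree$tip.label], alphabet)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nn)))
  tot <- 0
  for (r in seq_len(nrow(grid))) {
    asgn <- c(tipidx, grid[r, ])
    lik <- 1 / k
    for (e in seq_len(nrow(tree$edge))) {
      b <- asgn[tree$edge[e, 2L]]
      if (is.na(b)) next                     # missing tip: marginalized
      lik <- lik * Pe[[e]][asgn[tree$edge[e, 1L]], b]
    }
    tot <- tot + lik
  }
  log(tot)
}

## marginal probability of each state at one internal node, by enumeration
enum_marginal <- function(tree, states, rate, alphabet, node) {
  k <- length(alphabet)
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  Pe <- lapply(tree$edge.length, function(t) mk_P_oracle(k, rate, t))
  tipidx <- match(states[tree$tip.label], alphabet)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), nn)))
  acc <- numeric(k)
  for (r in seq_len(nrow(grid))) {
    asgn <- c(tipidx, grid[r, ])
    lik <- 1 / k
    for (e in seq_len(nrow(tree$edge))) {
      b <- asgn[tree$edge[e, 2L]]
      if (is.na(b)) next
      lik <- lik * Pe[[e]][asgn[tree$edge[e, 1L]], b]
    }
    acc[asgn[node]] <- acc[asgn[node]] + lik
  }
  acc / sum(acc)
}

## ---- ORF scan oracle ------------------------------------------------------

## O(n^2) scan: every ATG extended to its first in-frame stop
brute_orfs <- function(s, min_nt = 300L, stops = c("TAA", "TAG")) {
  s <- toupper(s)
  n <- nchar(s)
  hits <- list()
  for (i in seq_len(max(0L, n - 2L))) {
    if (substr(s, i, i + 2L) != "ATG") next
    j <- i + 3L
    while (j + 2L <= n) {
      cod <- substr(s, j, j + 2L)
      if (cod %in% stops) break
      j <- j + 3L
    }
    if (j + 2L > n) next                     # no stop: not an ORF
    len <- j + 2L - i + 1L
    if (len >= min_nt) {
      hits[[length(hits) + 1L]] <- c(start = i - 1L, end = j + 2L, len = len)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(0), end = integer(0), len = integer(0)))
  }
  df <- as.data.frame(do.call(rbind, hits))
  ## same nesting rule: drop ORFs contained in a longer ORF's span
  df <- df[order(-df$len), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))[-1L]) {
    prior <- which(keep[seq_len(i - 1L)])
    if (any(df$start[i] >= df$start[prior] & df$end[i] <= df$end[prior])) {
      keep[i] <- FALSE
    }
  }
  df <- df[keep, , drop = FALSE]
  df[order(df$start), , drop = FALSE]
}

## ---- plain affine-gap global alignment (unbanded) -------------------------

## maximization DP with the same cost model as the banded aligner; returns
## only the optimal score
full_affine_score <- function(a, b, gap_open = 10, gap_ext = 0.5,
                              match = 1, mismatch = -1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -Inf
  gop <- gap_open + gap_ext
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (j in 2:(m + 1)) Y[1, j] <- -(gap_open + gap_ext * (j - 1))
  for (i in 2:(n + 1)) X[i, 1] <- -(gap_open + gap_ext * (i - 1))
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == bv[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - gop, X[i - 1, j] - gap_ext,
                     Y[i - 1, j] - gop)
      Y[i, j] <- max(M[i, j - 1] - gop, Y[i, j - 1] - gap_ext,
                     X[i, j - 1] - gop)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

## random DNA of given AT fraction
random_dna <- function(n, at = 0.6) {
  paste(sample(c("A", "T", "G", "C"), n, TRUE,
               c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)), collapse = "")
}

## strip the strand sign from a signed symbol
sym_name_test <- function(s) sub("^-", "", s)
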