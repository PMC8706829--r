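sig <- function(...) gene_order_signature("t", c(...))

test_that("extract_order recovers the configured order from a synthetic genome", {
  gen <- generate_mitogenome(genome_spec(), seed = 21)
  ord <- extract_order(gen$genome)
  core_cfg <- gen$log$genes$name[gen$log$genes$kind %in% c("PCG", "rRNA")]
  expect_identical(ord$symbols, core_cfg)
  expect_length(ord$missing, 0)
})

test_that("missing core genes are reported, duplicated ones are errors", {
  g <- mito_genome("m", random_dna(300), TRUE, list(
    gene_feature("rnl", "rRNA", c(0L, 50L)),
    gene_feature("cox1", "PCG", c(60L, 120L))
  ))
  ord <- extract_order(g)
  expect_setequal(ord$missing, setdiff(core_gene_set(), c("rnl", "cox1")))

  gdup <- mito_genome("d", random_dna(300), TRUE, list(
    gene_feature("cox1_1", "PCG", c(0L, 30L)),
    gene_feature("cox1_2", "PCG", c(60L, 90L))
  ))
  expect_error(extract_order(gdup), "cox1")
})

test_that("canonicalize rotates to rnl and is idempotent", {
  expect_identical(canonicalize(c("nad2", "rnl", "cox1")),
                   c("rnl", "cox1", "nad2"))
  v <- c("rnl", "cox1", "nad2")
  expect_identical(canonicalize(v), v)
})

test_that("all rotations and the reflection collapse to one canonical form", {
  set.seed(77)
  genes <- core_gene_set()
  for (rep in 1:50) {
    perm <- sample(genes)
    signs <- sample(c("", "-"), length(genes), TRUE, prob = c(0.8, 0.2))
    v <- paste0(signs, perm)
    canon <- canonicalize(v)
    forms <- c(
      lapply(seq_along(v), function(i) c(v[i:length(v)], v[seq_len(i - 1)])),
      local({
        r <- ifelse(startsWith(rev(v), "-"), sub("^-", "", rev(v)),
                    paste0("-", rev(v)))
        lapply(seq_along(r), function(i) c(r[i:length(r)], r[seq_len(i - 1)]))
      })
    )
    keys <- unique(vapply(forms, function(f)
      paste(canonicalize(f), collapse = "|"), ""))
    expect_identical(keys, paste(canon, collapse = "|"))
  }
})

test_that("identical inputs give one dominant pattern", {
  sigs <- lapply(1:4, function(i)
    gene_order_signature(paste0("t", i), core_gene_set()))
  pats <- classify_patterns(sigs)
  expect_length(pats, 1L)
  expect_equal(pats[[1]]$pattern_label, "A")
  expect_length(pats[[1]]$member_taxa, 4L)
})

test_that("a translocated cox1 founds pattern B with a description naming it", {
  base <- default_gene_order("A")
  core <- base[sub("_[0-9]+$", "", base) %in% core_gene_set()]
  moved <- default_gene_order("B")
  movedc <- moved[sub("_[0-9]+$", "", moved) %in% core_gene_set()]
  sigs <- c(lapply(1:3, function(i) gene_order_signature(paste0("a", i), core)),
            list(gene_order_signature("b1", movedc)))
  pats <- classify_patterns(sigs)
  expect_length(pats, 2L)
  expect_equal(pats[[1]]$pattern_label, "A")
  expect_length(pats[[1]]$member_taxa, 3L)
  expect_equal(pats[[2]]$pattern_label, "B")
  expect_match(pats[[2]]$description, "cox1")
})

test_that("labels order by descending size with ties broken by appearance", {
  o1 <- core_gene_set()
  o2 <- canonicalize(c(o1[1], rev(o1[-1])))
  sigs <- list(gene_order_signature("x", o2),
               gene_order_signature("y", o1),
               gene_order_signature("z", o1))
  pats <- classify_patterns(sigs)
  expect_equal(pats[[1]]$member_taxa, c("y", "z"))
  expect_equal(pats[[2]]$member_taxa, "x")
})

test_that("signatures with missing genes join the reduced pattern as partial matches", {
  full <- core_gene_set()
  partial <- gene_order_signature("p", setdiff(full, c("nad1", "nad4")))
  sigs <- c(lapply(1:3, function(i) gene_order_signature(paste0("t", i), full)),
            list(partial))
  pats <- classify_patterns(sigs)
  expect_length(pats, 1L)
  expect_true("p" %in% pats[[1]]$member_taxa)
  expect_match(pats[[1]]$partial_members, "nad1")
})

test_that("pattern grouping equals a brute-force all-pairs equality oracle", {
  set.seed(42)
  genes <- core_gene_set()
  arrangements <- list(genes,
                       c(genes[1], genes[3], genes[2], genes[-(1:3)]),
                       rev(genes))
  sigs <- lapply(1:18, function(i) {
    base <- arrangements[[sample(3, 1)]]
    rot <- sample(length(base), 1)
    v <- c(base[rot:length(base)], base[seq_len(rot - 1)])
    gene_order_signature(paste0("s", i), v)
  })
  pats <- classify_patterns(sigs)
  got <- integer(0)
  for (p in pats) got[p$member_taxa] <- match(p$pattern_label, LETTERS)
  ## oracle: pairwise same-group iff some rotation/reflection maps one to the
  ## other
  equivalent <- function(a, b) {
    if (length(a) != length(b)) return(FALSE)
    forms <- lapply(seq_along(a), function(i) c(a[i:length(a)], a[seq_len(i - 1)]))
    r <- ifelse(startsWith(rev(a), "-"), sub("^-", "", rev(a)), paste0("-", rev(a)))
    forms <- c(forms, lapply(seq_along(r), function(i)
      c(r[i:length(r)], r[seq_len(i - 1)])))
    any(vapply(forms, identical, logical(1), y = b))
  }
  for (i in seq_along(sigs)) for (j in seq_along(sigs)) {
    same_oracle <- equivalent(sigs[[i]]$symbols, sigs[[j]]$symbols)
    same_got <- got[sigs[[i]]$taxon] == got[sigs[[j]]$taxon]
    expect_identical(unname(same_got), same_oracle)
  }
})

test_that("pattern count never decreases as signatures accumulate", {
  set.seed(9)
  genes <- core_gene_set()
  pool <- lapply(1:12, function(i) {
    v <- if (i %% 4 == 0) sample(genes) else genes
    gene_order_signature(paste0("t", i), v)
  })
  prev <- 0
  for (n in seq_along(pool)) {
    k <- length(classify_patterns(pool[seq_len(n)]))
    expect_gte(k, prev)
    prev <- k
  }
})

test_that("classification is invariant under per-genome origin rotation", {
  gen <- generate_mitogenome(genome_spec(), seed = 13)$genome
  sigs <- list(extract_order(gen),
               extract_order(rotate_genome(gen, 12345L)),
               extract_order(rotate_genome(gen, 777L)))
  for (i in 2:3) sigs[[i]]$taxon <- paste0("rot", i)
  pats <- classify_patterns(sigs)
  expect_length(pats, 1L)
})

test_that("trn clusters are counted per inter-core interval and flagged when variable", {
  gen1 <- generate_mitogenome(genome_spec(), seed = 1)$genome
  s1 <- extract_order(gen1, with_trn = TRUE)
  tab <- trn_cluster_report(list(s1))
  expect_equal(sum(tab[[2]]), 28L)             # all tRNAs accounted for
  expect_equal(tab[[2]][tab$after_gene == "rnl"], 11L)
  expect_false(any(tab$variable))
  ## second genome with one tRNA moved between intervals -> flagged
  s2 <- s1
  s2$taxon <- "moved"
  tt <- s2$trn_track
  i <- which(sub("_[0-9]+$", "", sym_name_test(tt)) == "trnC")
  tt <- tt[-i]
  j <- which(sym_name_test(tt) == "rns")
  s2$trn_track <- append(tt, "trnC", after = j)
  tab2 <- trn_cluster_report(list(s1, s2))
  expect_true(tab2$variable[tab2$after_gene == "cob"])
  expect_true(tab2$variable[tab2$after_gene == "rns"])
  expect_false(tab2$variable[tab2$after_gene == "rnl"])
})
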