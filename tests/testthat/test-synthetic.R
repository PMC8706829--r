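test_that("the same seed reproduces byte-identical output", {
  g1 <- generate_mitogenome(genome_spec(), seed = 77)
  g2 <- generate_mitogenome(genome_spec(), seed = 77)
  expect_identical(g1$genome$sequence, g2$genome$sequence)
  expect_identical(g1$genome$features, g2$genome$features)
  expect_identical(g1$log$junctions, g2$log$junctions)
  g3 <- generate_mitogenome(genome_spec(), seed = 78)
  expect_false(identical(g1$genome$sequence, g3$genome$sequence))
})

test_that("generated genomes honor the configured order and junctions", {
  spec <- genome_spec()
  gen <- generate_mitogenome(spec, seed = 41)
  ord <- extract_order(gen$genome)
  want <- spec$gene_order[sub("_[0-9]+$", "", spec$gene_order) %in% core_gene_set()]
  expect_identical(ord$symbols, want)
  expect_equal(junction_interval(gen$genome, c("nad4L", "nad5"))$interval_nt, -1L)
  expect_equal(junction_interval(gen$genome, c("nad2", "nad3"))$interval_nt, 0L)
})

test_that("composition lands near its targets at 30 kb", {
  gen <- generate_mitogenome(genome_spec(), seed = 19)
  comp <- composition(gen$genome)
  expect_equal(comp$at_percent, 73.7, tolerance = 1.5 / 73.7)
  expect_lt(abs(comp$at_skew - (-0.02)), 0.03)
  expect_lt(abs(comp$gc_skew - 0.12), 0.05)
})

test_that("an unrealizable spec errors before emitting sequence", {
  spec <- genome_spec(size_target = 10000L, size_tol = 100L)
  expect_error(generate_mitogenome(spec, seed = 1), "unrealizable")
  spec2 <- genome_spec(introns = list(list(host = "cox1", position = 5000L,
                                           length = 500L)))
  expect_error(generate_mitogenome(spec2, seed = 1), "unrealizable")
})

test_that("a pattern-A spec produces the cox1-between-cob-and-nad1 order", {
  spec <- genome_spec(gene_order = default_gene_order("A"),
                      introns = list(list(host = "rnl", position = 2450L,
                                          length = 1600L, orf_aa = 450L,
                                          orf_name = "rps3", group = "IA")))
  gen <- generate_mitogenome(spec, seed = 61)
  ord <- canonicalize(extract_order(gen$genome))$symbols
  i <- match("cox1", ord)
  expect_equal(ord[i - 1], "cob")
  expect_equal(ord[i + 1], "nad1")
})

test_that("generator output satisfies all model invariants after reparsing", {
  gen <- generate_mitogenome(genome_spec(), seed = 37)
  p <- tempfile(fileext = ".gb")
  write_genbank(gen$genome, p)
  g <- read_genbank(p)
  s <- region_accounting(g)
  expect_identical(s$genic_nt + s$intergenic_nt, s$size_bp)
  expect_equal(s$n_core_pcg, 14L)
  expect_equal(s$n_rrna, 2L)
  expect_equal(s$n_trna, 28L)
  expect_equal(s$n_free_orf, 2L)
  expect_equal(s$n_intron, 2L)
  expect_equal(s$n_intronic_orf, 2L)
  aud <- s$start_stop_audit
  expect_false(any(aud$frame_flag))
  expect_false(any(aud$internal_stop))
})

test_that("zero mutations produce identical individuals", {
  gen <- generate_mitogenome(genome_spec(), seed = 2)
  mut <- mutate_individuals(gen$genome, n_individuals = 2,
                            n_substitutions = 0L, n_indels = 0L, seed = 3)
  expect_identical(unname(mut$sequences[2]), gen$genome$sequence)
  expect_identical(unname(mut$sequences[3]), gen$genome$sequence)
  expect_equal(nrow(mut$log), 0L)
})

test_that("planted nonsynonymous substitutions round-trip through coding_effect", {
  gen <- generate_mitogenome(genome_spec(), seed = 2)
  mut <- mutate_individuals(gen$genome, n_individuals = 1,
                            n_substitutions = 40L, n_indels = 0L, seed = 13)
  cod <- mut$log[!is.na(mut$log$effect), , drop = FALSE]
  expect_gt(nrow(cod), 0L)
  for (r in seq_len(nrow(cod))) {
    expect_equal(coding_effect(gen$genome, cod$position[r], cod$alt[r])$effect,
                 cod$effect[r])
  }
})

test_that("branch simulation frequencies match the Mk closed form within 2%", {
  library(ape)
  k <- 4; rate <- 0.8; t <- 0.9
  p_same_theory <- 1 / k + (1 - 1 / k) * exp(-k * rate * t / (k - 1))
  ## a two-leaf star with one zero branch exposes the root state directly
  tr <- read.tree(text = sprintf("(r:0,x:%f);", t))
  same <- 0L
  n <- 10000L
  for (i in seq_len(n)) {
    sim <- simulate_characters(tr, k = k, rate = rate, seed = i)
    if (sim$tip_states[["x"]] == sim$tip_states[["r"]]) same <- same + 1L
  }
  expect_equal(same / n, p_same_theory, tolerance = 0.02)
})

test_that("root states are uniform over the alphabet across seeds", {
  library(ape)
  tr <- read.tree(text = "(a:1,b:1);")
  k <- 6L
  roots <- vapply(1:600, function(i)
    simulate_characters(tr, k = k, rate = 0.01, seed = i)$node_states[1], "")
  tab <- table(factor(roots, levels = LETTERS[1:k]))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.01)
  expect_true(all(tab > 0))
})

test_that("rate zero copies the root state to every leaf", {
  library(ape)
  tr <- rcoal(12)
  sim <- simulate_characters(tr, k = 5, rate = 0, seed = 4)
  expect_equal(length(unique(sim$tip_states)), 1L)
  expect_equal(unname(unique(sim$tip_states)), sim$node_states[1])
})

test_that("full synthetic round trip: every stage report matches the plant log", {
  spec <- genome_spec()
  gen <- generate_mitogenome(spec, seed = 101)
  g <- gen$genome

  ## region accounting vs plan
  s <- region_accounting(g)
  expect_identical(s$size_bp, g$length_bp)
  expect_identical(s$intronic_nt, sum(gen$log$introns$length))
  genic_planned <- sum(gen$log$genes$end - gen$log$genes$start) -
    1L  # nad4L/nad5 share one base
  expect_identical(s$genic_nt, as.integer(genic_planned))

  ## gene order and patterns
  sigs <- list(extract_order(g),
               local({ o <- extract_order(rotate_genome(g, 9999L));
                       o$taxon <- "rot"; o }))
  expect_length(classify_patterns(sigs), 1L)

  ## junctions vs plan
  for (r in seq_len(nrow(gen$log$junctions))) {
    jl <- gen$log$junctions[r, ]
    expect_equal(junction_interval(g, c(jl$upstream, jl$downstream))$interval_nt,
                 as.integer(jl$interval))
  }

  ## intron catalog vs plan (host reference: names recover planted positions)
  cat_ <- intron_catalog(g)
  expect_identical(sort(cat_$name), sort(gen$log$introns$name))
  expect_identical(cat_$insertion_ref_pos[order(cat_$host_gene)],
                   gen$log$introns$position[order(gen$log$introns$host)])
  expect_true(all(cat_$boundary_upstream_T & cat_$boundary_intron_G))

  ## variation vs plant log
  mut <- mutate_individuals(g, n_individuals = 2, n_substitutions = 24,
                            n_indels = 12, seed = 5)
  rep_ <- tally_sites(align_high_identity(mut$sequences), g)
  expect_equal(rep_$variable_sites, 24L)
  expect_equal(rep_$indel_sites,
               sum(mut$log$length[mut$log$type != "substitution"]))
  expect_equal(rep_$n_nonsynonymous,
               sum(mut$log$effect == "nonsynonymous", na.rm = TRUE))
  expect_equal(rep_$n_synonymous,
               sum(mut$log$effect == "synonymous", na.rm = TRUE))
})
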