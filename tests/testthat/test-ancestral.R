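library(ape)

test_that("two identical leaves at rate ~0 give log-likelihood log(1/k)", {
  tr <- read.tree(text = "(a:1,b:1);")
  st <- c(a = "A", b = "A")
  for (k in 2:4) {
    ll <- mk_likelihood(tr, st, rate = 1e-12, alphabet = LETTERS[1:k])
    expect_equal(ll, log(1 / k), tolerance = 1e-6)
  }
})

test_that("the k=2 single-branch transition matches the closed form", {
  for (rate in c(0.1, 0.7)) for (t in c(0.2, 1.5)) {
    p_stay <- 0.5 + 0.5 * exp(-2 * rate * t)
    tr <- read.tree(text = sprintf("(a:%f,b:0.0);", t))
    ll_same <- mk_likelihood(tr, c(a = "A", b = "A"), rate, alphabet = c("A", "B"))
    ## P(b=A) = 1/2 at the root; conditional on root=b state, branch t to a
    expect_equal(exp(ll_same), 0.5 * p_stay, tolerance = 1e-12)
    ll_diff <- mk_likelihood(tr, c(a = "B", b = "A"), rate, alphabet = c("A", "B"))
    expect_equal(exp(ll_diff), 0.5 * (1 - p_stay), tolerance = 1e-12)
  }
})

test_that("pruning equals the enumeration oracle on small trees to 1e-10", {
  set.seed(11)
  for (rep in 1:12) {
    nt <- sample(3:6, 1)
    k <- sample(2:4, 1)
    tr <- rcoal(nt)
    tr$edge.length <- tr$edge.length * runif(1, 0.3, 3)
    alph <- LETTERS[1:k]
    st <- setNames(sample(alph, nt, TRUE), tr$tip.label)
    if (rep %% 3 == 0) st[1] <- NA            # a missing taxon
    rate <- runif(1, 0.05, 2)
    expect_equal(mk_likelihood(tr, st, rate, alph),
                 enum_loglik(tr, st, rate, alph), tolerance = 1e-10)
  }
})

test_that("multifurcations are handled natively in pruning", {
  tr <- read.tree(text = "(a:1,b:1,c:1,d:2);")   # root polytomy
  st <- c(a = "A", b = "A", c = "B", d = "A")
  expect_equal(mk_likelihood(tr, st, 0.3, c("A", "B")),
               enum_loglik(tr, st, 0.3, c("A", "B")), tolerance = 1e-10)
})

test_that("negative branch lengths and nonpositive rates are rejected", {
  tr <- read.tree(text = "(a:1,b:-0.1);")
  expect_error(mk_likelihood(tr, c(a = "A", b = "B"), 0.5), "negative")
  tr2 <- read.tree(text = "(a:1,b:1);")
  expect_error(mk_likelihood(tr2, c(a = "A", b = "B"), 0), "positive")
})

test_that("marginal reconstruction equals conditional enumeration", {
  set.seed(12)
  for (rep in 1:6) {
    nt <- sample(4:6, 1)
    k <- sample(2:3, 1)
    tr <- rcoal(nt)
    alph <- LETTERS[1:k]
    st <- setNames(sample(alph, nt, TRUE), tr$tip.label)
    rate <- runif(1, 0.1, 1.5)
    rep_ <- marginal_ancestral(tr, st, rate, alph)
    for (node in (nt + 1L):(nt + tr$Nnode)) {
      want <- enum_marginal(tr, st, rate, alph, node)
      got <- as.numeric(rep_$nodes[node, alph])
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("marginal probabilities sum to one at every node", {
  set.seed(13)
  tr <- rcoal(30)
  st <- setNames(sample(LETTERS[1:5], 30, TRUE), tr$tip.label)
  rep_ <- marginal_ancestral(tr, st, 0.4, LETTERS[1:5])
  p <- as.matrix(rep_$nodes[, LETTERS[1:5]])
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
})

test_that("a star tree with unanimous tips converges to the shared state", {
  tr <- read.tree(text = "(a:1,b:1,c:1,d:1,e:1);")
  st <- setNames(rep("A", 5), tr$tip.label)
  p_root <- numeric(0)
  for (rate in c(0.5, 0.1, 0.01, 0.001)) {
    rep_ <- marginal_ancestral(tr, st, rate, c("A", "B", "C"))
    p_root <- c(p_root, rep_$nodes$A[6])
  }
  expect_true(all(diff(p_root) > 0))
  expect_gt(p_root[length(p_root)], 0.999)
})

test_that("permuting state labels permutes the output identically", {
  set.seed(14)
  tr <- rcoal(12)
  alph <- c("A", "B", "C")
  st <- setNames(sample(alph, 12, TRUE), tr$tip.label)
  rep1 <- marginal_ancestral(tr, st, 0.3, alph)
  perm <- c(A = "C", B = "A", C = "B")
  st2 <- setNames(unname(perm[st]), names(st))
  rep2 <- marginal_ancestral(tr, st2, 0.3, alph)
  for (s in alph) {
    expect_equal(rep2$nodes[[unname(perm[s])]], rep1$nodes[[s]],
                 tolerance = 1e-12)
  }
})

test_that("the ML rate beats 100 random rates on the same data", {
  set.seed(15)
  tr <- rcoal(25)
  sim <- simulate_characters(tr, k = 4, rate = 0.6, seed = 2)
  est <- estimate_rate(tr, sim$tip_states)
  expect_false(est$flagged)
  lls <- vapply(exp(runif(100, log(1e-5), log(100))), function(r)
    mk_likelihood(tr, sim$tip_states, r, est$alphabet), numeric(1))
  expect_gte(est$loglik, max(lls) - 1e-6)
})

test_that("an invariant character is flagged as a boundary estimate", {
  tr <- rcoal(8)
  st <- setNames(rep("A", 8), tr$tip.label)
  est <- estimate_rate(tr, st, alphabet = c("A", "B"))
  expect_true(est$flagged)
  expect_equal(est$rate, 1e-6)
})

test_that("simulated rates are recovered within a factor of two usually", {
  ## rate chosen so the tree carries ~15 expected changes: the regime where
  ## a single discrete character is informative about its rate
  set.seed(16)
  tr <- rcoal(64)
  tr$edge.length <- tr$edge.length / max(node.depth.edgelength(tr))
  true_rate <- 3
  ok <- 0L; valid <- 0L; i <- 0L
  while (valid < 50L && i < 80L) {
    i <- i + 1L
    sim <- simulate_characters(tr, k = 4, rate = true_rate, seed = 1000 + i)
    if (length(unique(sim$tip_states)) < 2) next   # invariant: no information
    valid <- valid + 1L
    est <- estimate_rate(tr, sim$tip_states, alphabet = LETTERS[1:4])
    if (est$rate > true_rate / 2 && est$rate < true_rate * 2) ok <- ok + 1L
  }
  expect_equal(valid, 50L)
  expect_gte(ok, 0.9 * valid)
})

test_that("uniform tip states imply zero transition events", {
  tr <- rcoal(10)
  st <- setNames(rep("A", 10), tr$tip.label)
  rep_ <- marginal_ancestral(tr, st, 1e-6, c("A", "B"))
  expect_equal(nrow(count_transitions(rep_)), 0L)
})

test_that("derived clades imply one stem-branch event each", {
  ## two independent origins of the rare derived state B: the (a,b) clade
  ## and the single leaf e, against a dominant-A background
  tr <- read.tree(text = "(((a:1,b:1):1,(c:1,d:1):1):1,((e:1,f:1):1,(g:1,h:1):1):1);")
  st <- c(a = "B", b = "B", c = "A", d = "A", e = "B", f = "A",
          g = "A", h = "A")
  est <- estimate_rate(tr, st)
  rep_ <- marginal_ancestral(tr, st, est$rate)
  ev <- count_transitions(rep_)
  expect_equal(sum(ev$n_branches[ev$from == "A" & ev$to == "B"]), 2L)
  ## the dominant state is reconstructed as ancestral
  expect_equal(rep_$nodes$map_state[9], "A")
})

test_that("root state is recovered on slow Mk simulations almost always", {
  ## k = 6 states, 100 leaves, rate well below one change per tree depth
  set.seed(17)
  tr <- rcoal(100)
  tr$edge.length <- tr$edge.length / max(node.depth.edgelength(tr))
  ok <- 0L
  n_rep <- 50L
  for (i in seq_len(n_rep)) {
    sim <- simulate_characters(tr, k = 6, rate = 0.1, seed = 5000 + i)
    est <- estimate_rate(tr, sim$tip_states, alphabet = LETTERS[1:6])
    rep_ <- marginal_ancestral(tr, sim$tip_states, est$rate,
                               alphabet = LETTERS[1:6])
    root_map <- rep_$nodes$map_state[101]
    if (root_map == sim$node_states[1]) ok <- ok + 1L
  }
  expect_gte(ok, 0.95 * n_rep)
})

test_that("annotated newick output carries states and stays parseable", {
  tr <- rcoal(6)
  st <- setNames(sample(c("A", "B"), 6, TRUE), tr$tip.label)
  rep_ <- marginal_ancestral(tr, st, 0.2, c("A", "B"))
  p <- tempfile(fileext = ".nwk")
  write_ancestral_newick(rep_, p)
  back <- read.tree(p)
  expect_equal(Ntip(back), 6)
  expect_match(back$node.label[1], "^[AB]_[0-9.]+$")
})
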