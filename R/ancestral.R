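## Marginal ancestral-state reconstruction of discrete mitogenomic characters
## (gene arrangement pattern; junction joining state) on a rooted tree under
## the equal-rates Mk model:
##   P(i -> j, t) = 1/k + (delta_ij - 1/k) * exp(-k * rate * t / (k - 1))
## with a uniform root prior. Likelihoods by Felsenstein pruning; marginal
## node probabilities by the standard up/down message pass. Multifurcations
## are handled natively; taxa missing from the state matrix contribute
## all-ones partials (no information) rather than being dropped.

mk_transition <- function(k, rate, t) {
  e <- exp(-k * rate * t / (k - 1))
  p_same <- 1 / k + (1 - 1 / k) * e
  p_diff <- 1 / k - (1 / k) * e
  m <- matrix(p_diff, k, k)
  diag(m) <- p_same
  m
}

## normalize a states input (named vector or data.frame taxon/state) against
## the tree's tips; returns list(states: named character incl NA, alphabet)
prep_states <- function(tree, states, alphabet = NULL) {
  if (is.data.frame(states)) {
    stopifnot(all(c("taxon", "state") %in% names(states)))
    states <- setNames(as.character(states$state), states$taxon)
  }
  tips <- tree$tip.label
  if (anyDuplicated(tips)) stop("tree tip labels are not unique")
  out <- setNames(rep(NA_character_, length(tips)), tips)
  known <- intersect(names(states), tips)
  out[known] <- states[known]
  if (is.null(alphabet)) {
    alphabet <- sort(unique(stats::na.omit(unname(out))))
  }
  bad <- setdiff(stats::na.omit(unname(out)), alphabet)
  if (length(bad)) stop("states outside alphabet: ", paste(bad, collapse = ", "))
  if (length(alphabet) < 2L) stop("state alphabet must have k >= 2")
  list(states = out, alphabet = alphabet)
}

check_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  tree
}

## upward (pruning) pass; returns partials matrix, per-node log scalers, and
## the per-edge transition matrices
mk_up_pass <- function(tree, states, alphabet, rate) {
  k <- length(alphabet)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  partial <- matrix(1, ntip + nnode, k)
  for (i in seq_len(ntip)) {
    st <- states[[tree$tip.label[i]]]
    if (!is.na(st)) {
      partial[i, ] <- 0
      partial[i, match(st, alphabet)] <- 1
    }
  }
  tr <- ape::reorder.phylo(tree, "postorder")
  P <- vector("list", nrow(tr$edge))
  logscale <- 0
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
    P[[e]] <- mk_transition(k, rate, tr$edge.length[e])
    msg <- as.vector(P[[e]] %*% partial[child, ])
    partial[par, ] <- partial[par, ] * msg
    s <- max(partial[par, ])
    if (s > 0 && (s < 1e-100 || s > 1e100)) {
      partial[par, ] <- partial[par, ] / s
      logscale <- logscale + log(s)
    }
  }
  list(partial = partial, logscale = logscale, edges = tr$edge,
       P = P, k = k, root = ntip + 1L)
}

#' Mk log-likelihood of a discrete character on a tree
#'
#' Felsenstein pruning under the equal-rates k-state Markov model with a
#' uniform root prior. Leaves absent from the state assignment contribute no
#' information.
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param states Named character vector (taxon -> state letter) or data frame
#'   with columns `taxon`, `state`. Missing taxa allowed.
#' @param rate Substitution rate (> 0) of the Mk process.
#' @param alphabet Optional state alphabet; defaults to the sorted observed
#'   states.
#' @return Log-likelihood (scalar).
#' @export
mk_likelihood <- function(tree, states, rate, alphabet = NULL) {
  check_tree(tree)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("rate must be a positive scalar")
  }
  ps <- prep_states(tree, states, alphabet)
  up <- mk_up_pass(tree, ps$states, ps$alphabet, rate)
  lik <- sum(up$partial[up$root, ] / up$k)
  log(lik) + up$logscale
}

#' Maximum-likelihood Mk rate
#'
#' One-dimensional likelihood optimization over log-rate on
#' `[1e-6, 1e3]`. An invariant character (all observed leaves in one state)
#' has its likelihood maximized as rate tends to zero; the search interval's
#' lower bound is then returned with `flagged = TRUE`.
#'
#' @inheritParams mk_likelihood
#' @return List: `rate`, `loglik`, `flagged` (boundary estimate),
#'   `alphabet`.
#' @export
estimate_rate <- function(tree, states, alphabet = NULL) {
  check_tree(tree)
  ps <- prep_states(tree, states, alphabet)
  obs <- stats::na.omit(unname(ps$states))
  if (length(unique(obs)) <= 1L) {
    r <- 1e-6
    return(list(rate = r, loglik = mk_likelihood(tree, states, r, ps$alphabet),
                flagged = TRUE, alphabet = ps$alphabet))
  }
  f <- function(lr) -mk_likelihood(tree, states, exp(lr), ps$alphabet)
  opt <- stats::optimize(f, interval = log(c(1e-6, 1e3)), tol = 1e-6)
  list(rate = exp(opt$minimum), loglik = -opt$objective, flagged = FALSE,
       alphabet = ps$alphabet)
}

#' Marginal ancestral-state reconstruction
#'
#' Combines upward partials with downward messages to obtain, for every node,
#' the marginal posterior probability of each state given the leaf states,
#' the tree, and the Mk rate. The per-node "occurrence" of a state is this
#' probability expressed as a percentage.
#'
#' @inheritParams mk_likelihood
#' @param rate Mk rate; typically from [estimate_rate()].
#' @return An object of class `ancestral_report`: data frame `nodes` (node
#'   id, type, one probability column per state, `map_state`,
#'   `occurrence_percent` of the MAP state), plus `rate`, `alphabet`,
#'   `loglik`, and the tree.
#' @export
marginal_ancestral <- function(tree, states, rate, alphabet = NULL) {
  check_tree(tree)
  ps <- prep_states(tree, states, alphabet)
  alphabet <- ps$alphabet
  k <- length(alphabet)
  up <- mk_up_pass(tree, ps$states, alphabet, rate)
  ntip <- length(tree$tip.label)
  nnodes_all <- ntip + tree$Nnode
  edges <- up$edges
  ## children lists per parent (postorder edge indices)
  down <- matrix(NA_real_, nnodes_all, k)
  down[up$root, ] <- rep(1 / k, k)
  ## preorder: reverse postorder edge order guarantees parent before child
  for (e in rev(seq_len(nrow(edges)))) {
    par <- edges[e, 1L]; child <- edges[e, 2L]
    sib_edges <- which(edges[, 1L] == par)
    sib_edges <- sib_edges[edges[sib_edges, 2L] != child]
    excl <- down[par, ]
    for (se in sib_edges) {
      excl <- excl * as.vector(up$P[[se]] %*% up$partial[edges[se, 2L], ])
    }
    d <- as.vector(crossprod(up$P[[e]], excl))
    s <- sum(d)
    down[child, ] <- if (s > 0) d / s else d
  }
  probs <- up$partial * down
  probs <- probs / rowSums(probs)
  colnames(probs) <- alphabet
  map_idx <- apply(probs, 1L, which.max)
  nodes <- data.frame(
    node = seq_len(nnodes_all),
    label = c(tree$tip.label, if (!is.null(tree$node.label)) tree$node.label
              else paste0("node", seq_len(tree$Nnode))),
    type = rep(c("tip", "internal"), c(ntip, tree$Nnode)),
    stringsAsFactors = FALSE
  )
  nodes <- cbind(nodes, as.data.frame(probs))
  nodes$map_state <- alphabet[map_idx]
  nodes$occurrence_percent <- 100 * probs[cbind(seq_len(nnodes_all), map_idx)]
  out <- list(nodes = nodes, rate = rate, alphabet = alphabet,
              loglik = mk_likelihood(tree, states, rate, alphabet),
              tree = tree)
  class(out) <- "ancestral_report"
  out
}

#' @export
print.ancestral_report <- function(x, ...) {
  ntip <- length(x$tree$tip.label)
  root <- x$nodes[ntip + 1L, ]
  cat(sprintf("<ancestral_report> k=%d states {%s}, rate=%.4g, logLik=%.3f\n",
              length(x$alphabet), paste(x$alphabet, collapse = ","),
              x$rate, x$loglik))
  cat(sprintf("  root: state %s, occurrence %.1f%%\n",
              root$map_state, root$occurrence_percent))
  invisible(x)
}

#' Minimal state-transition events along the tree
#'
#' Counts branches on which the maximum-probability state changes between
#' parent and child, per ordered state pair: a parsimony-style lower bound on
#' the number of transition events implied by the reconstruction.
#'
#' @param report An `ancestral_report`.
#' @return Data frame: `from`, `to`, `n_branches`, plus attribute
#'   `branches` listing the implicated edges.
#' @export
count_transitions <- function(report) {
  tree <- report$tree
  map <- report$nodes$map_state
  edges <- tree$edge
  ev <- data.frame(parent = edges[, 1L], child = edges[, 2L],
                   from = map[edges[, 1L]], to = map[edges[, 2L]],
                   stringsAsFactors = FALSE)
  ev <- ev[ev$from != ev$to, , drop = FALSE]
  if (nrow(ev) == 0L) {
    out <- data.frame(from = character(0), to = character(0),
                      n_branches = integer(0))
  } else {
    agg <- stats::aggregate(list(n_branches = seq_len(nrow(ev))),
                            by = list(from = ev$from, to = ev$to), FUN = length)
    out <- agg[order(-agg$n_branches), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "branches") <- ev
  out
}

#' Write an annotated newick tree with ancestral states
#'
#' Node labels carry `state_occurrence%` so the reconstruction can be
#' inspected in any tree viewer.
#'
#' @param report An `ancestral_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ancestral_newick <- function(report, path) {
  tree <- report$tree
  ntip <- length(tree$tip.label)
  internal <- report$nodes[report$nodes$type == "internal", ]
  tree$node.label <- sprintf("%s_%.1f", internal$map_state,
                             internal$occurrence_percent)
  ape::write.tree(tree, file = path)
  invisible(path)
}
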