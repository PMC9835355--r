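# Independent oracles used to validate the graph algorithms.

# Brute-force seed prediction: boolean reachability closure; a compound
# is a seed iff its mutual-reachability class is not reachable from any
# node outside the class.
oracle_seeds <- function(edges, nodes) {
  n <- length(nodes)
  if (n == 0L) return(character(0))
  reach <- diag(TRUE, n)
  dimnames(reach) <- list(nodes, nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges) > 0L) adj[cbind(edges$from, edges$to)] <- TRUE
  repeat {
    nxt <- reach | (reach %*% adj) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  mutual <- reach & t(reach)
  vapply(seq_len(n), function(i) {
    members <- which(mutual[i, ])
    outside <- setdiff(which(reach[, i]), members)
    length(outside) == 0L
  }, logical(1)) |> which() |> (\(i) sort(nodes[i]))()
}

# Nodes reachable from a starting set by directed BFS over plain edges.
oracle_expandable_nodes <- function(edges, start) {
  seen <- start
  repeat {
    nxt <- unique(edges$to[edges$from %in% seen])
    new <- setdiff(nxt, seen)
    if (length(new) == 0L) break
    seen <- c(seen, new)
  }
  sort(seen)
}

# Naive expansion: repeatedly scan the reactions in a caller-supplied
# order, firing any feasible direction immediately, until a full pass
# adds nothing.
oracle_expand <- function(universe, ecs, seeds, order = NULL) {
  rx <- universe$reactions
  avail <- vapply(rx$ecs, function(e) any(e %in% ecs), logical(1))
  rx <- rx[avail, , drop = FALSE]
  dirs <- list()
  for (i in seq_len(nrow(rx))) {
    dirs[[length(dirs) + 1L]] <- list(s = rx$substrates[[i]],
                                      p = rx$products[[i]])
    if (rx$reversible[i]) {
      dirs[[length(dirs) + 1L]] <- list(s = rx$products[[i]],
                                        p = rx$substrates[[i]])
    }
  }
  if (is.null(order)) order <- seq_along(dirs)
  scope <- intersect(unique(seeds), universe_compounds(universe))
  repeat {
    added <- FALSE
    for (i in order) {
      d <- dirs[[i]]
      if (all(d$s %in% scope) && !all(d$p %in% scope)) {
        scope <- union(scope, d$p)
        added <- TRUE
      }
    }
    if (!added) break
  }
  sort(scope)
}

# Number of reaction directions available to an enzyme set.
oracle_n_dirs <- function(universe, ecs) {
  rx <- universe$reactions
  avail <- vapply(rx$ecs, function(e) any(e %in% ecs), logical(1))
  sum(avail) + sum(rx$reversible[avail])
}

# Exact hypergeometric upper tail by direct combinatorial summation.
oracle_hyper_p <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Standard BH rejection set.
oracle_bh_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  thresh <- alpha * seq_len(m) / m
  below <- which(p[o] <= thresh)
  if (length(below) == 0L) return(integer(0))
  sort(o[seq_len(max(below))])
}

# Random digraph as an edge data.frame over "n01".. node labels.
random_digraph <- function(n, density) {
  nodes <- sprintf("n%02d", seq_len(n))
  adj <- matrix(runif(n * n) < density, n, n)
  diag(adj) <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  list(nodes = nodes,
       edges = data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                          stringsAsFactors = FALSE))
}

# Wrap an arbitrary digraph as a reaction universe (one irreversible
# single-substrate reaction per edge) so the package graph code runs on
# it; isolated nodes are kept via an unused compound list.
universe_from_digraph <- function(dg) {
  if (nrow(dg$edges) == 0L) return(NULL)
  rx <- data.frame(reaction_id = sprintf("R%04d", seq_len(nrow(dg$edges))),
                   reversible = FALSE, stringsAsFactors = FALSE)
  rx$ecs <- rep(list("1.1.1.1"), nrow(dg$edges))
  rx$substrates <- as.list(dg$edges$from)
  rx$products <- as.list(dg$edges$to)
  reaction_universe(rx)
}

# Random reaction universe for expansion oracle checks.
random_universe <- function(n_compounds, n_reactions, p_reversible = 0.3,
                            n_ecs = 8) {
  cps <- sprintf("C%03d", seq_len(n_compounds))
  ecs <- sprintf("1.1.%d.%d", seq_len(n_ecs), seq_len(n_ecs))
  rx <- data.frame(reaction_id = sprintf("R%03d", seq_len(n_reactions)),
                   reversible = runif(n_reactions) < p_reversible,
                   stringsAsFactors = FALSE)
  rx$ecs <- lapply(seq_len(n_reactions), function(i)
    sample(ecs, sample(1:2, 1)))
  rx$substrates <- lapply(seq_len(n_reactions), function(i)
    sample(cps, sample(1:3, 1)))
  rx$products <- lapply(seq_len(n_reactions), function(i)
    sample(cps, sample(1:2, 1)))
  reaction_universe(rx)
}
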