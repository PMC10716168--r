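# Independent brute-force graph metrics for small weighted graphs (R <= 7).
# Distances and path multiplicities come from exhaustive simple-path
# enumeration; everything else is computed with direct loops, so nothing here
# shares code with the package implementations.

brute_paths <- function(W, tol = 1e-12) {
  R <- nrow(W)
  best <- matrix(Inf, R, R); diag(best) <- 0
  count <- matrix(0, R, R); diag(count) <- 1
  # interior[[s]][[t]]: per shortest path, vector of strictly interior nodes
  interior <- replicate(R, replicate(R, list(), simplify = FALSE), simplify = FALSE)
  for (s in seq_len(R)) {
    rec <- function(node, visited, len) {
      for (nb in which(W[node, ] > 0)) {
        if (nb %in% visited) next
        l2 <- len + 1 / W[node, nb]
        if (l2 > best[s, nb] + tol && is.finite(best[s, nb])) {
          # still recurse: longer prefixes may reach other nodes shortest
        } else if (l2 < best[s, nb] - tol) {
          best[s, nb] <<- l2
          count[s, nb] <<- 1
          interior[[s]][[nb]] <<- list(setdiff(visited, s))
        } else if (abs(l2 - best[s, nb]) <= tol) {
          count[s, nb] <<- count[s, nb] + 1
          interior[[s]][[nb]] <<- c(interior[[s]][[nb]], list(setdiff(visited, s)))
        }
        rec(nb, c(visited, nb), l2)
      }
    }
    rec(s, s, 0)
  }
  list(dist = best, count = count, interior = interior)
}

brute_metrics <- function(W) {
  R <- nrow(W)
  bp <- brute_paths(W)
  d <- bp$dist
  inv <- 1 / d; inv[!is.finite(inv)] <- 0; diag(inv) <- 0
  n_eglob <- rowSums(inv) / (R - 1)
  off <- d[row(d) != col(d)]
  lp <- mean(off[is.finite(off)])
  k_s <- rowSums(W)

  # Onnela clustering, direct triple loop
  mx <- max(W)
  cl <- numeric(R)
  if (mx > 0) {
    Wb <- W / mx
    for (i in seq_len(R)) {
      nb <- which(W[i, ] > 0)
      if (length(nb) < 2) next
      acc <- 0
      for (j in nb) for (l in nb) {
        if (j != l && W[j, l] > 0) acc <- acc + (Wb[i, j] * Wb[j, l] * Wb[l, i])^(1 / 3)
      }
      cl[i] <- acc / (length(nb) * (length(nb) - 1))
    }
  }

  # local efficiency on neighbour subgraphs
  le <- numeric(R)
  for (i in seq_len(R)) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) next
    sub <- W[nb, nb, drop = FALSE]
    if (all(sub == 0)) next
    dsub <- brute_paths(sub)$dist
    invs <- 1 / dsub; invs[!is.finite(invs)] <- 0; diag(invs) <- 0
    le[i] <- mean(rowSums(invs) / (length(nb) - 1))
  }

  # betweenness over ordered pairs with multiplicity splitting
  btw <- numeric(R)
  for (j in seq_len(R)) for (k in seq_len(R)) {
    if (j == k || !is.finite(bp$dist[j, k]) || bp$count[j, k] == 0) next
    paths <- bp$interior[[j]][[k]]
    for (i in seq_len(R)) {
      if (i == j || i == k) next
      hits <- sum(vapply(paths, function(p) i %in% p, TRUE))
      btw[i] <- btw[i] + hits / bp$count[j, k]
    }
  }
  btw <- btw / ((R - 1) * (R - 2))

  list(dist = d,
       e_glob = mean(n_eglob), n_eglob = n_eglob,
       e_loc = mean(le), n_eloc = le,
       l_p = lp,
       degree_strength = k_s, s_p = mean(k_s),
       c_nodal = cl, c_p = mean(cl),
       betweenness = btw)
}

# random connected-ish weighted graph fixture
random_weighted_graph <- function(R, density = 0.5) {
  repeat {
    W <- matrix(0, R, R)
    ut <- which(upper.tri(W))
    on <- ut[stats::runif(length(ut)) < density]
    if (length(on) < 1) next
    W[on] <- stats::runif(length(on), 0.2, 3)
    W <- W + t(W)
    if (all(rowSums(W) > 0)) return(W)
  }
}
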