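# Independent oracles used by the tests. These deliberately re-derive
# results by naive enumeration or via a different library routine than the
# implementation under test.

# Clades of a rooted tree as sorted label strings (root clade dropped),
# via ape::prop.part -- independent of the package's clade bookkeeping.
oracle_clades <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  out <- vapply(pp, function(idx) paste(sort(labs[idx]), collapse = "|"),
                character(1))
  setdiff(out, paste(sort(labs), collapse = "|"))
}

# Brute-force majority-rule clade filter: clade strings present in strictly
# more than `threshold` of the trees.
oracle_majority_clades <- function(trees, threshold = 0.5) {
  tab <- table(unlist(lapply(trees, oracle_clades)))
  names(tab)[tab / length(trees) > threshold]
}

# Naive patristic distance: sum edge lengths along the node path per pair.
oracle_patristic <- function(tree) {
  labs <- tree$tip.label
  n <- length(labs)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      path <- ape::nodepath(tree, i, j)
      len <- 0
      for (k in seq_len(length(path) - 1)) {
        e <- which(
          (tree$edge[, 1] == path[k] & tree$edge[, 2] == path[k + 1]) |
            (tree$edge[, 2] == path[k] & tree$edge[, 1] == path[k + 1])
        )
        len <- len + tree$edge.length[e]
      }
      d[i, j] <- d[j, i] <- len
    }
  }
  d
}

# Enumerate every candidate split of `rows` and return the best gain, with
# the same semantics as the engine: midpoint thresholds, nominal level
# subsets, missing values routed to the child with more non-missing rows
# (ties left), gain = SSE reduction over all node rows.
oracle_node_sse <- function(y) if (length(y) == 0) 0 else sum((y - mean(y))^2)

oracle_splits <- function(x, kind, y, rows, min_obs = 1) {
  out <- list()
  sse_all <- oracle_node_sse(y[rows])
  for (j in seq_len(ncol(x))) {
    xv <- x[rows, j]
    pres <- rows[!is.na(xv)]
    miss <- rows[is.na(xv)]
    if (length(pres) < 2) next
    partitions <- list()
    if (kind[j] == 0) {
      vals <- sort(unique(x[pres, j]))
      if (length(vals) >= 2) {
        for (k in seq_len(length(vals) - 1)) {
          thr <- (vals[k] + vals[k + 1]) / 2
          partitions[[length(partitions) + 1]] <-
            list(left = pres[x[pres, j] < thr], right = pres[x[pres, j] >= thr])
        }
      }
    } else {
      levs <- sort(unique(x[pres, j]))
      if (length(levs) >= 2) {
        for (s in seq_len(2^length(levs) - 2)) {
          inl <- levs[bitwAnd(s, 2^(seq_along(levs) - 1)) > 0]
          partitions[[length(partitions) + 1]] <-
            list(left = pres[x[pres, j] %in% inl],
                 right = pres[!x[pres, j] %in% inl])
        }
      }
    }
    for (pt in partitions) {
      if (length(pt$left) >= length(pt$right)) {
        pt$left <- c(pt$left, miss)
      } else {
        pt$right <- c(pt$right, miss)
      }
      if (length(pt$left) < min_obs || length(pt$right) < min_obs) next
      gain <- sse_all - oracle_node_sse(y[pt$left]) -
        oracle_node_sse(y[pt$right])
      if (gain > 1e-12) {
        out[[length(out) + 1]] <- list(gain = gain, left = pt$left,
                                       right = pt$right)
      }
    }
  }
  out
}

oracle_best_gain <- function(x, kind, y, rows, min_obs = 1) {
  cand <- oracle_splits(x, kind, y, rows, min_obs)
  if (length(cand) == 0) 0 else max(vapply(cand, `[[`, numeric(1), "gain"))
}

# Best-first growth with every step's split chosen by exhaustive candidate
# enumeration (the naive counterpart of the engine's scan-based search):
# at each step the best split over all current leaves is applied.
oracle_greedy_total <- function(x, kind, y, max_splits, min_obs = 1) {
  leaves <- list(seq_len(nrow(x)))
  total <- 0
  for (s in seq_len(max_splits)) {
    best <- NULL
    bg <- 1e-12
    for (li in seq_along(leaves)) {
      for (cand in oracle_splits(x, kind, y, leaves[[li]], min_obs)) {
        if (cand$gain > bg + 1e-12) {
          bg <- cand$gain
          best <- list(li = li, cand = cand)
        }
      }
    }
    if (is.null(best)) break
    total <- total + best$cand$gain
    leaves <- c(leaves[-best$li],
                list(best$cand$left), list(best$cand$right))
  }
  total
}
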