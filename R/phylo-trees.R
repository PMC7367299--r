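#' Read a set of Newick trees
#'
#' Parses a file containing one or more `;`-terminated Newick records (one
#' tree per line or spread over several lines) into an [ape::multiphylo]
#' tree set. All trees must share an identical set of unique tip labels.
#'
#' @param path Path to a Newick file.
#' @return A `multiPhylo` object with one `phylo` tree per record.
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines(c("(A:1,B:2);", "((A:1,B:1):1,C:2);"), tf)
#' \dontrun{read_newick_trees(tf)}  # errors: mismatched tip sets
#' writeLines(c("(A:1,(B:1,C:1):1);", "((A:1,B:1):1,C:2);"), tf)
#' trees <- read_newick_trees(tf)
#' length(trees)
#' @export
read_newick_trees <- function(path) {
  if (!file.exists(path)) {
    stop("tree file not found: ", path, call. = FALSE)
  }
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  records <- strsplit(txt, ";", fixed = TRUE)[[1]]
  records <- records[!grepl("^\\s*$", records)]
  if (length(records) == 0) {
    stop("no Newick records found in ", path, call. = FALSE)
  }
  trees <- vector("list", length(records))
  for (i in seq_along(records)) {
    tr <- tryCatch(
      ape::read.tree(text = paste0(records[[i]], ";")),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(tr) || !inherits(tr, "phylo")) {
      stop("malformed Newick in record ", i, " of ", path, call. = FALSE)
    }
    if (anyDuplicated(tr$tip.label)) {
      dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
      stop("duplicate tip labels in record ", i, ": ",
           paste(dup, collapse = ", "), call. = FALSE)
    }
    trees[[i]] <- tr
  }
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), ref)) {
      stop("record ", i, " has a different tip set from record 1",
           call. = FALSE)
    }
  }
  class(trees) <- "multiPhylo"
  trees
}

# Clades of a rooted tree as tip-index sets against a reference label order.
# Returns a list with keys (collapsed sorted indices), per-clade tip index
# vectors, and the length of the edge subtending each clade (NA if absent).
tree_clades <- function(tree, ref_labels) {
  tip_idx <- match(tree$tip.label, ref_labels)
  n_tip <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) desc[[i]] <- tip_idx[i]
  for (e in seq_len(nrow(post$edge))) {
    par <- post$edge[e, 1]; chi <- post$edge[e, 2]
    desc[[par]] <- c(desc[[par]], desc[[chi]])
  }
  root <- n_tip + 1L
  nodes <- setdiff(seq.int(n_tip + 1L, n_tip + tree$Nnode), root)
  has_len <- !is.null(tree$edge.length)
  clades <- lapply(nodes, function(nd) sort(desc[[nd]]))
  lens <- vapply(nodes, function(nd) {
    if (!has_len) return(NA_real_)
    tree$edge.length[which(tree$edge[, 2] == nd)]
  }, numeric(1))
  tip_lens <- vapply(seq_len(n_tip), function(i) {
    if (!has_len) return(NA_real_)
    tree$edge.length[which(tree$edge[, 2] == i)]
  }, numeric(1))[order(tip_idx)]
  list(
    keys = vapply(clades, paste, character(1), collapse = "."),
    clades = clades, lengths = lens, tip_lengths = tip_lens
  )
}

#' Clade (bipartition) frequencies across a tree set
#'
#' Counts, for every clade observed in any tree, the fraction of trees
#' containing it and the mean length of the subtending branch across those
#' trees. Trees are treated as rooted, so a clade is the tip set descending
#' from an internal node.
#'
#' @param trees A `multiPhylo` tree set with identical tip labels.
#' @return A tibble with columns `tips` (list of tip-label character
#'   vectors), `size`, `count`, `frequency`, and `mean_length`.
#' @export
bipartition_frequencies <- function(trees) {
  stopifnot(inherits(trees, "multiPhylo") || is.list(trees))
  if (length(trees) == 0) stop("empty tree set", call. = FALSE)
  ref <- sort(trees[[1]]$tip.label)
  counts <- new.env(parent = emptyenv())
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), ref)) {
      stop("tree ", i, " has a different tip set from tree 1", call. = FALSE)
    }
    cl <- tree_clades(trees[[i]], ref)
    for (k in seq_along(cl$keys)) {
      key <- cl$keys[k]
      cur <- counts[[key]]
      if (is.null(cur)) {
        counts[[key]] <- list(clade = cl$clades[[k]], count = 1L,
                              len_sum = cl$lengths[k])
      } else {
        cur$count <- cur$count + 1L
        cur$len_sum <- cur$len_sum + cl$lengths[k]
        counts[[key]] <- cur
      }
    }
  }
  keys <- ls(counts)
  rows <- lapply(keys, function(k) counts[[k]])
  tibble::tibble(
    tips = lapply(rows, function(r) ref[r$clade]),
    size = vapply(rows, function(r) length(r$clade), integer(1)),
    count = vapply(rows, function(r) r$count, integer(1)),
    frequency = vapply(rows, function(r) r$count, integer(1)) / length(trees),
    mean_length = vapply(rows, function(r) r$len_sum / r$count, numeric(1))
  )
}

#' Majority-rule consensus tree with averaged branch lengths
#'
#' Builds the consensus containing exactly the clades whose frequency across
#' the tree set is strictly greater than `threshold` (the classical 50%
#' majority rule at the default). Clades at exactly the threshold are
#' excluded, which guarantees mutual compatibility for `threshold >= 0.5`.
#' Consensus branch lengths are arithmetic means over the trees containing
#' each clade; tip branches average over all trees. Regions without a
#' majority clade collapse to polytomies.
#'
#' @param trees A `multiPhylo` tree set sharing one tip-label set.
#' @param threshold Clade-frequency cutoff in `[0.5, 1)`; a clade is kept
#'   when `count / n_trees > threshold`.
#' @return A `phylo` consensus tree (with branch lengths when every input
#'   tree has them).
#' @export
majority_rule_consensus <- function(trees, threshold = 0.5) {
  if (length(trees) == 0) stop("empty tree set", call. = FALSE)
  if (!is.numeric(threshold) || threshold < 0.5 || threshold >= 1) {
    stop("threshold must be in [0.5, 1)", call. = FALSE)
  }
  ref <- sort(trees[[1]]$tip.label)
  n <- length(ref)
  bp <- bipartition_frequencies(trees)
  has_len <- all(vapply(trees, function(t) !is.null(t$edge.length),
                        logical(1)))
  # mean pendant length per tip over all trees
  tip_len <- rep(0, n)
  if (has_len) {
    for (tr in trees) tip_len <- tip_len + tree_clades(tr, ref)$tip_lengths
    tip_len <- tip_len / length(trees)
  }

  keep <- bp$frequency > threshold & bp$size >= 2 & bp$size <= n - 1
  clades <- lapply(which(keep), function(i) match(bp$tips[[i]], ref))
  clade_len <- bp$mean_length[keep]
  ord <- order(vapply(clades, length, integer(1)), decreasing = TRUE)
  clades <- clades[ord]; clade_len <- clade_len[ord]

  # parent of each retained clade / tip = smallest retained clade strictly
  # containing it (0 = root); decreasing-size order makes containment a tree
  m <- length(clades)
  parent_of_clade <- integer(m)
  for (i in seq_len(m)) {
    parent_of_clade[i] <- 0L
    if (i > 1) for (j in seq.int(i - 1, 1)) {
      if (length(clades[[j]]) > length(clades[[i]]) &&
          all(clades[[i]] %in% clades[[j]])) {
        parent_of_clade[i] <- j  # scanning upward in size: first hit is smallest
        break
      }
    }
  }
  parent_of_tip <- integer(n)
  for (t in seq_len(n)) {
    parent_of_tip[t] <- 0L
    if (m > 0) for (j in seq.int(m, 1)) {
      if (t %in% clades[[j]]) { parent_of_tip[t] <- j; break }
    }
  }

  quote_label <- function(x) {
    ifelse(grepl("[ ()\\[\\]:;,']", x), paste0("'", gsub("'", "''", x), "'"), x)
  }
  emit <- function(node) {  # node 0 = root, else clade index
    kids_c <- which(parent_of_clade == node)
    kids_t <- which(parent_of_tip == node)
    parts <- c(
      vapply(kids_t, function(t) {
        lab <- quote_label(ref[t])
        if (has_len) paste0(lab, ":", format(tip_len[t], digits = 15)) else lab
      }, character(1)),
      vapply(kids_c, function(j) {
        inner <- emit(j)
        if (has_len) paste0(inner, ":", format(clade_len[j], digits = 15))
        else inner
      }, character(1))
    )
    paste0("(", paste(parts, collapse = ","), ")")
  }
  ape::read.tree(text = paste0(emit(0L), ";"))
}

#' Patristic distance matrix of a tree
#'
#' Sums branch lengths along the unique path between every pair of tips.
#'
#' @param tree A `phylo` tree with branch lengths on every edge.
#' @return A symmetric numeric matrix with tip labels as dimnames, zero
#'   diagonal, and entry `(i, j)` equal to the i-j path length.
#' @export
patristic_distance_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  bad <- which(is.na(tree$edge.length) | tree$edge.length < 0)
  if (length(bad) > 0) {
    child <- tree$edge[bad[1], 2]
    lab <- if (child <= length(tree$tip.label)) {
      tree$tip.label[child]
    } else {
      paste0("internal node ", child)
    }
    stop("missing or negative branch length above ", lab, call. = FALSE)
  }
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Write a tree to a Newick file
#'
#' @param tree A `phylo` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a distance matrix as CSV with a tip-label header row and column
#'
#' @param d A labeled symmetric matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  df <- tibble::as_tibble(d, rownames = "species")
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a distance matrix written by [write_distance_matrix()]
#'
#' @param path CSV path with a `species` label column.
#' @return A labeled symmetric matrix.
#' @export
read_distance_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
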