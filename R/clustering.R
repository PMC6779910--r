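# Agglomerative hierarchical clustering via the Lance-Williams recurrence,
# with the dendrogram operations the interactive workflow exposes: cutting,
# branch selection, Newick export.
#
# Node numbering: leaves are 0..n-1; the internal node created by merge k
# (k = 1..n-1) is n+k-1, so nodes run 0..2n-2 with the root 2n-2.

lw_coefficients <- function(linkage, ni, nj, nk) {
  switch(linkage,
    ward = {
      s <- ni + nj + nk
      c(ai = (ni + nk) / s, aj = (nj + nk) / s, beta = -nk / s, gamma = 0)
    },
    average = c(ai = ni / (ni + nj), aj = nj / (ni + nj), beta = 0, gamma = 0),
    complete = c(ai = 0.5, aj = 0.5, beta = 0, gamma = 0.5),
    single = c(ai = 0.5, aj = 0.5, beta = 0, gamma = -0.5)
  )
}

#' Hierarchical clustering of a distance matrix
#'
#' Standard agglomerative algorithm: start from singletons, repeatedly merge
#' the pair of clusters at minimum dissimilarity, and update dissimilarities
#' between the new cluster and the rest with the Lance-Williams recurrence
#' of the chosen linkage. For Ward linkage the coefficients are
#' `ai = (ni+nk)/(ni+nj+nk)`, `aj = (nj+nk)/(ni+nj+nk)`,
#' `beta = -nk/(ni+nj+nk)`, applied to the supplied dissimilarities as they
#' are (no squaring) — pairing Ward with cosine distances, as is common for
#' embedding vectors, is heuristic rather than variance-exact, and heights
#' may occasionally invert; the merge sequence is still well defined.
#' Exact ties in merge dissimilarity are broken deterministically toward the
#' pair with the smallest (min node id, max node id).
#'
#' @param D A `distance_matrix` (or plain symmetric matrix), `n >= 2`.
#' @param linkage `"ward"` (default), `"average"`, `"complete"` or
#'   `"single"`.
#' @return An `image_dendrogram`: `merges` data frame (`left`, `right` node
#'   ids with `left < right`, `height`, `size`), leaf count `n`, leaf
#'   `labels` (file stems) and the source `table`.
#' @export
hierarchical_cluster <- function(D, linkage = c("ward", "average", "complete", "single")) {
  linkage <- match.arg(linkage)
  if (!inherits(D, "distance_matrix")) {
    D <- new_distance_matrix(as.matrix(D), "custom",
                             new_image_table(sprintf("row%04d", seq_len(nrow(as.matrix(D)))),
                                             rep(NA_character_, nrow(as.matrix(D))),
                                             rep(NA_real_, nrow(as.matrix(D))), character()))
  }
  n <- nrow(D$values)
  if (n < 2L) abort_input("hierarchical clustering needs at least 2 images")

  d <- D$values
  active <- seq_len(n)           # matrix row indices of live clusters
  node_id <- seq_len(n) - 1L     # external node id per matrix row
  sizes <- rep(1L, n)
  merges <- data.frame(left = integer(n - 1L), right = integer(n - 1L),
                       height = numeric(n - 1L), size = integer(n - 1L))

  for (step in seq_len(n - 1L)) {
    # minimum over active pairs, ties broken toward smallest (min id, max id)
    best <- NULL
    best_d <- Inf
    for (a in seq_along(active)[-length(active)]) {
      i <- active[a]
      for (b in (a + 1L):length(active)) {
        j <- active[b]
        dij <- d[i, j]
        cand <- sort(c(node_id[i], node_id[j]))
        if (dij < best_d ||
            (dij == best_d && (cand[1L] < best$ids[1L] ||
                               (cand[1L] == best$ids[1L] && cand[2L] < best$ids[2L])))) {
          best_d <- dij
          best <- list(i = i, j = j, ids = cand)
        }
      }
    }
    i <- best$i
    j <- best$j
    merges$left[step] <- best$ids[1L]
    merges$right[step] <- best$ids[2L]
    merges$height[step] <- best_d
    merges$size[step] <- sizes[i] + sizes[j]

    # Lance-Williams update, new cluster stored in row i
    for (k in setdiff(active, c(i, j))) {
      co <- lw_coefficients(linkage, sizes[i], sizes[j], sizes[k])
      dnew <- co[["ai"]] * d[i, k] + co[["aj"]] * d[j, k] +
        co[["beta"]] * d[i, j] + co[["gamma"]] * abs(d[i, k] - d[j, k])
      d[i, k] <- dnew
      d[k, i] <- dnew
    }
    sizes[i] <- sizes[i] + sizes[j]
    node_id[i] <- n + step - 1L
    active <- setdiff(active, j)
  }

  labels <- make_leaf_labels(D$table)
  structure(list(merges = merges, n = n, labels = labels, table = D$table,
                 linkage = linkage, metric = D$metric),
            class = "image_dendrogram")
}

make_leaf_labels <- function(table) {
  stems <- tools::file_path_sans_ext(basename(table$path))
  dup <- duplicated(stems) | duplicated(stems, fromLast = TRUE)
  stems[dup] <- paste0(stems[dup], "_", table$id[dup]) # disambiguate
  stems
}

#' @method print image_dendrogram
#' @export
print.image_dendrogram <- function(x, ...) {
  cat(sprintf("<image_dendrogram> %d leaves, %s linkage on %s distances\n",
              x$n, x$linkage, x$metric))
  cat(sprintf("merge heights: %s\n",
              paste(signif(x$merges$height, 4), collapse = " ")))
  invisible(x)
}

# leaves (0-based ids) under a node, ascending
node_leaves <- function(dendro, node) {
  n <- dendro$n
  if (node < 0L || node > 2L * n - 2L) {
    abort_input(sprintf("invalid dendrogram node id %d (valid: 0..%d)",
                        node, 2L * n - 2L))
  }
  stack <- node
  leaves <- integer()
  while (length(stack)) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    if (v < n) {
      leaves <- c(leaves, v)
    } else {
      m <- v - n + 1L
      stack <- c(stack, dendro$merges$left[m], dendro$merges$right[m])
    }
  }
  sort(leaves)
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last `k - 1` merges and labels the resulting components
#' `0..k-1` in order of first appearance when scanning leaves in table
#' order.
#'
#' @param dendro An `image_dendrogram`.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Integer vector of cluster labels, aligned with the image table.
#' @export
cut_dendrogram <- function(dendro, k) {
  n <- dendro$n
  if (!is_count(k, min = 1L) || k > n) {
    abort_input(sprintf("`k` must be an integer in 1..%d", n))
  }
  parent <- seq_len(2L * n - 1L) # union-find over node ids + 1
  find <- function(v) {
    while (parent[v] != v) {
      parent[v] <<- parent[parent[v]]
      v <- parent[v]
    }
    v
  }
  keep <- seq_len(n - k) # undo the last k-1 merges
  for (m in keep) {
    a <- find(dendro$merges$left[m] + 1L)
    b <- find(dendro$merges$right[m] + 1L)
    top <- n + m # new internal node id + 1
    parent[a] <- top
    parent[b] <- top
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels <- integer(n)
  seen <- integer(0)
  for (i in seq_len(n)) {
    r <- roots[i]
    pos <- match(r, seen)
    if (is.na(pos)) {
      seen <- c(seen, r)
      pos <- length(seen)
    }
    labels[i] <- pos - 1L
  }
  labels
}

#' Select the images under a dendrogram branch
#'
#' The programmatic analogue of clicking a branch in an interactive
#' dendrogram: returns the image records that are leaves of the subtree
#' rooted at `node`, in original table order.
#'
#' @param dendro An `image_dendrogram`.
#' @param node Node id: leaves `0..n-1`, internal nodes `n..2n-2` (the root
#'   is `2n-2`).
#' @return An `image_table` subset.
#' @export
select_branch <- function(dendro, node) {
  stopifnot_count(node, "node")
  leaves <- node_leaves(dendro, as.integer(node))
  subset_image_table(dendro$table, leaves + 1L)
}

# convert to a stats::hclust object (for ape interop and plotting)
as_hclust_imagemine <- function(dendro) {
  n <- dendro$n
  merge <- matrix(0L, n - 1L, 2L)
  for (m in seq_len(n - 1L)) {
    enc <- function(v) if (v < n) -(v + 1L) else v - n + 1L
    merge[m, ] <- c(enc(dendro$merges$left[m]), enc(dendro$merges$right[m]))
  }
  order <- node_order(dendro)
  structure(list(merge = merge, height = dendro$merges$height,
                 order = order + 1L, labels = dendro$labels,
                 method = dendro$linkage,
                 call = match.call(), dist.method = dendro$metric),
            class = "hclust")
}

# left-to-right leaf order implied by the merge tree
node_order <- function(dendro) {
  n <- dendro$n
  rec <- function(v) {
    if (v < n) return(v)
    m <- v - n + 1L
    c(rec(dendro$merges$left[m]), rec(dendro$merges$right[m]))
  }
  rec(2L * n - 2L)
}

#' @method as.hclust image_dendrogram
#' @export
as.hclust.image_dendrogram <- function(x, ...) as_hclust_imagemine(x)

#' Export a dendrogram as a Newick string
#'
#' Leaf names are the image file stems (suffixed with the record id when
#' duplicated); branch lengths are parent height minus child height, leaves
#' sitting at height zero. The string is terminated by `";"` and reparses
#' with any standard Newick reader.
#'
#' @param dendro An `image_dendrogram`.
#' @return A single Newick string.
#' @export
to_newick <- function(dendro) {
  phy <- ape::as.phylo(as_hclust_imagemine(dendro))
  # as.phylo.hclust reads merge heights as cophenetic distances and halves
  # them; double the edge lengths to restore parent-minus-child heights
  phy$edge.length <- phy$edge.length * 2
  ape::write.tree(phy)
}
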