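# three collinear 1-D points {0, 1, 5}: the canonical worked example
collinear_dendrogram <- function(linkage = "single") {
  E <- synthetic_embedding(cbind(c(0, 1, 5), 0), NULL)
  hierarchical_cluster(pairwise_distances(E, "euclidean"), linkage)
}

test_that("single linkage on collinear points merges near pair first", {
  dendro <- collinear_dendrogram("single")
  expect_equal(dendro$merges$left, c(0L, 2L))
  expect_equal(dendro$merges$right, c(1L, 3L))
  expect_equal(dendro$merges$height, c(1, 4))
  expect_equal(dendro$merges$size, c(2L, 3L))
})

test_that("two points merge once at their distance under any linkage", {
  E <- synthetic_embedding(cbind(c(0, 3), 0), NULL)
  D <- pairwise_distances(E, "euclidean")
  for (linkage in c("ward", "average", "complete", "single")) {
    dendro <- hierarchical_cluster(D, linkage)
    expect_equal(nrow(dendro$merges), 1L)
    expect_equal(dendro$merges$height, 3)
  }
  expect_error(hierarchical_cluster(matrix(0, 1, 1)),
               class = "imagemine_input_error")
})

test_that("merge sequences match a naive reference agglomerator for all linkages", {
  set.seed(101)
  for (rep in 1:30) {
    n <- sample(5:8, 1)
    D <- random_distance_matrix(n)
    for (linkage in c("ward", "average", "complete", "single")) {
      dendro <- hierarchical_cluster(D, linkage)
      ref <- naive_linkage(D, linkage)
      expect_equal(dendro$merges$height, ref$heights, tolerance = 1e-10)
      for (step in seq_len(n - 1)) {
        expect_equal(dendro_partition(dendro, step), ref$partitions[[step]])
      }
    }
  }
})

test_that("merge heights and partitions agree with hclust on random inputs", {
  set.seed(202)
  method_of <- c(ward = "ward.D", average = "average",
                 complete = "complete", single = "single")
  for (rep in 1:10) {
    n <- sample(6:9, 1)
    D <- random_distance_matrix(n)
    for (linkage in names(method_of)) {
      dendro <- hierarchical_cluster(D, linkage)
      hc <- hclust(as.dist(D), method = method_of[[linkage]])
      expect_equal(sort(dendro$merges$height), sort(hc$height), tolerance = 1e-10)
      for (k in 2:(n - 1)) {
        expect_equal(canon_partition(cut_dendrogram(dendro, k)),
                     canon_partition(unname(cutree(hc, k))))
      }
    }
  }
})

test_that("cutting a dendrogram partitions the leaves", {
  dendro <- collinear_dendrogram("single")
  expect_equal(cut_dendrogram(dendro, 1), rep(0L, 3))
  expect_equal(cut_dendrogram(dendro, 3), 0:2)
  expect_equal(cut_dendrogram(dendro, 2), c(0L, 0L, 1L)) # {0,1} vs {5}
  expect_error(cut_dendrogram(dendro, 0), class = "imagemine_input_error")
  expect_error(cut_dendrogram(dendro, 4), class = "imagemine_input_error")

  set.seed(33)
  D <- random_distance_matrix(7)
  dendro7 <- hierarchical_cluster(D, "average")
  for (k in 1:7) {
    labels <- cut_dendrogram(dendro7, k)
    expect_length(labels, 7L)
    expect_equal(sort(unique(labels)), 0:(k - 1)) # every label used once
  }
})

test_that("branch selection returns the leaves under a node in table order", {
  dendro <- collinear_dendrogram("single")
  expect_equal(select_branch(dendro, 0)$path, dendro$table$path[1])   # leaf
  expect_equal(select_branch(dendro, 4)$path, dendro$table$path)      # root
  expect_equal(select_branch(dendro, 3)$path, dendro$table$path[1:2]) # {0,1}
  expect_equal(select_branch(dendro, 3)$id, 0:1) # ids renumbered in subset
  expect_error(select_branch(dendro, 5), class = "imagemine_input_error")
})

test_that("Newick export round-trips topology and heights through ape", {
  dendro <- collinear_dendrogram("single")
  nwk <- to_newick(dendro)
  expect_match(nwk, ";$")
  phy <- ape::read.tree(text = nwk)
  expect_equal(length(phy$tip.label), 3L)
  # depths: leaf 5 sits at the root height 4; leaves 0,1 split at height 1
  depths <- ape::node.depth.edgelength(phy)
  expect_equal(max(depths[1:3]), 4)
  coph <- ape::cophenetic.phylo(phy)
  labels <- dendro$labels
  expect_equal(coph[labels[1], labels[2]], 2)  # 2 * height 1
  expect_equal(coph[labels[1], labels[3]], 8)  # 2 * height 4

  # n = 2 minimal tree
  E2 <- synthetic_embedding(cbind(c(0, 1), 0), NULL)
  d2 <- hierarchical_cluster(pairwise_distances(E2, "euclidean"), "ward")
  phy2 <- ape::read.tree(text = to_newick(d2))
  expect_equal(sort(phy2$edge.length), c(1, 1))
})

test_that("duplicate leaf stems are disambiguated in Newick output", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "A"))
  dir.create(file.path(root, "B"))
  write_gray_png(matrix(runif(64), 8, 8), file.path(root, "A", "img.png"))
  write_gray_png(matrix(runif(64), 8, 8), file.path(root, "B", "img.png"))
  tbl <- scan_image_directory(root)
  dendro <- hierarchical_cluster(pairwise_distances(embed_images(tbl), "euclidean"))
  phy <- ape::read.tree(text = to_newick(dendro))
  expect_equal(sort(phy$tip.label), c("img_0", "img_1"))
})
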