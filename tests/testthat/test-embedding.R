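test_that("the backend registry exposes the expected entries", {
  reg <- list_backends()
  expect_true(all(c("inceptionv3", "squeezenet", "vgg16", "vgg19", "filterbank")
                  %in% reg$name))
  inc <- get_backend("inceptionv3")
  expect_equal(inc$feature_dim, 2048L) # penultimate layer of InceptionV3
  expect_equal(inc$input_size, 299L)
  expect_true(inc$requires_external_model)

  fb <- get_backend("filterbank")
  expect_equal(fb$feature_dim, 96L)
  expect_false(fb$requires_external_model)

  expect_error(get_backend("nosuch"), class = "imagemine_input_error")
})

test_that("deep backends demand an adapter before embedding", {
  root <- withr::local_tempdir()
  write_gray_png(matrix(0.5, 8, 8), file.path(root, "a.png"))
  tbl <- scan_image_directory(root)
  expect_error(embed_images(tbl, backend = "inceptionv3"),
               regexp = "inceptionv3.*model",
               class = "imagemine_input_error")
  # attaching an adapter makes the backend usable
  register_backend_adapter("squeezenet",
                           embed_fun = function(img) rep(mean(img), 8),
                           feature_dim = 8)
  E <- embed_images(tbl, backend = "squeezenet")
  expect_equal(dim(E$values), c(1L, 8L))
  imagemine:::register_default_backends() # restore pristine registry
})

test_that("filterbank features are deterministic with unit-sum histogram blocks", {
  set.seed(3)
  img <- array(runif(40 * 50 * 3), c(40, 50, 3))
  v1 <- filterbank_embed(img)
  v2 <- filterbank_embed(img)
  expect_identical(v1, v2)
  expect_length(v1, 96L)
  expect_equal(sum(v1[1:32]), 1)   # luminance histogram
  expect_equal(sum(v1[33:48]), 1)  # orientation histogram, full resolution
  expect_equal(sum(v1[49:64]), 1)  # orientation histogram, downsampled
  expect_true(all(is.finite(v1)))
})

test_that("a constant image degenerates gracefully", {
  img <- array(0.5, c(32, 32, 3))
  v <- filterbank_embed(img)
  expect_equal(sum(v[1:32] > 0), 1L)        # all mass in one luminance bin
  expect_equal(v[33:48], rep(0, 16))        # zero-gradient orientation blocks
  expect_equal(v[49:64], rep(0, 16))
  expect_equal(v[90], 0)                    # sd
  expect_equal(v[91], 0)                    # skewness convention
  expect_equal(v[92], 0)                    # kurtosis convention
  expect_equal(v[93], 0)                    # entropy of a point mass
  expect_equal(v[94], 0)                    # edge density
})

test_that("the ring-contrast feature separates SN from NSN exemplars", {
  out <- withr::local_tempdir()
  spec <- fixture_spec("ring_diffuse", n_per_class = 1, image_size = 128,
                       noise_sd = 0, seed = 1)
  tbl <- generate_ring_diffuse_set(spec, out)
  E <- embed_images(tbl)
  ring_contrast <- E$values[, 95]
  expect_gt(ring_contrast[tbl$label == "SN"], ring_contrast[tbl$label == "NSN"])
})

test_that("embedding rows align with table rows, including under permutation", {
  out <- withr::local_tempdir()
  spec <- fixture_spec("ring_diffuse", n_per_class = 3, image_size = 64,
                       noise_sd = 0.02, seed = 9)
  tbl <- generate_ring_diffuse_set(spec, out)
  E <- embed_images(tbl)
  expect_equal(dim(E$values), c(6L, 96L))
  expect_true(all(is.finite(E$values)))

  perm <- c(4L, 1L, 6L, 2L, 5L, 3L)
  E_perm <- embed_images(imagemine:::subset_image_table(tbl, perm))
  expect_equal(E_perm$values, E$values[perm, ])
})

test_that("the embedding cache serves bit-identical vectors without recomputing", {
  out <- withr::local_tempdir()
  cache <- withr::local_tempdir()
  spec <- fixture_spec("ring_diffuse", n_per_class = 2, image_size = 64,
                       noise_sd = 0.02, seed = 4)
  tbl <- generate_ring_diffuse_set(spec, out)
  E1 <- embed_images(tbl, cache_dir = cache)
  expect_equal(attr(E1, "n_computed"), 4L)
  expect_message(E2 <- embed_images(tbl, cache_dir = cache, verbose = TRUE),
                 "cache hit")
  expect_equal(attr(E2, "n_computed"), 0L)
  expect_identical(E1$values, E2$values)
})

test_that("embedding CSV round-trips values, paths and labels", {
  out <- withr::local_tempdir()
  spec <- fixture_spec("ring_diffuse", n_per_class = 2, image_size = 64,
                       noise_sd = 0.02, seed = 4)
  tbl <- generate_ring_diffuse_set(spec, out)
  E <- embed_images(tbl)
  csv <- file.path(out, "emb.csv")
  write_embedding_csv(E, csv)
  E2 <- read_embedding_csv(csv)
  expect_equal(E2$values, E$values, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(E2$table$path, E$table$path)
  expect_equal(E2$table$label, E$table$label)
  expect_equal(class_values(E2$table), class_values(E$table))
})
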