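test_that("a minimal visium directory reads into the right shape", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 1 2", "1 1 3", "2 1 5"),
             file.path(dir, "matrix.mtx"))
  writeLines("AAAC-1", file.path(dir, "barcodes.tsv"))
  writeLines(c("g1\tg1\tGene Expression", "g2\tg2\tGene Expression"),
             file.path(dir, "features.tsv"))
  writeLines(c("barcode,in_tissue,array_row,array_col,pxl_row,pxl_col",
               "AAAC-1,1,1,2,10,20"),
             file.path(dir, "tissue_positions.csv"))
  ds <- read_visium(dir)
  expect_s3_class(ds, "spot_dataset")
  expect_equal(dim(ds), c(1L, 2L))
  expect_equal(as.numeric(ds$counts[1, ]), c(3, 5))
  expect_equal(ds$platform, "visium")
})

test_that("visium round-trip is the identity on counts, coords and ids", {
  sim <- make_bands_fixture(seed = 7, rows = 6, cols = 6, n_genes = 20)
  dir <- withr::local_tempdir()
  write_visium(sim$dataset, dir)
  back <- read_visium(dir)
  expect_equal(back$spot_ids, sim$dataset$spot_ids)
  expect_equal(back$gene_ids, sim$dataset$gene_ids)
  expect_equal(as.matrix(back$counts), dense_mat <- {
    m <- as.matrix(sim$dataset$counts); storage.mode(m) <- "double"; m
  }, tolerance = 1e-12)
  expect_equal(unname(back$coords), unname(sim$dataset$coords),
               tolerance = 1e-12)
})

test_that("visium reader keeps position-table order and drops out-of-tissue", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 3 3", "1 1 1", "2 2 4", "1 3 2"),
             file.path(dir, "matrix.mtx"))
  writeLines(c("B1", "B2", "B3"), file.path(dir, "barcodes.tsv"))
  writeLines(c("g1\tg1\tG", "g2\tg2\tG"), file.path(dir, "features.tsv"))
  # order B3, B1, B2; B2 flagged out of tissue
  writeLines(c("barcode,in_tissue,array_row,array_col,pxl_row,pxl_col",
               "B3,1,3,3,0,0", "B1,1,1,1,0,0", "B2,0,2,2,0,0"),
             file.path(dir, "tissue_positions.csv"))
  ds <- read_visium(dir)
  expect_equal(ds$spot_ids, c("B3", "B1"))
  expect_equal(as.numeric(ds$counts["B3", ]), c(2, 0))
})

test_that("visium reader errors name missing components and bad barcodes", {
  dir <- withr::local_tempdir()
  expect_error(read_visium(dir), "tissue position")
  writeLines(c("barcode,in_tissue,array_row,array_col,pxl_row,pxl_col",
               "X,1,1,1,0,0"), file.path(dir, "tissue_positions.csv"))
  expect_error(read_visium(dir), "count matrix")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "1 1 1", "1 1 1"), file.path(dir, "matrix.mtx"))
  writeLines("Y", file.path(dir, "barcodes.tsv"))
  writeLines("g1\tg1\tG", file.path(dir, "features.tsv"))
  expect_error(read_visium(dir), "consistency error")
})

test_that("generic reader handles 2D and 3D coordinates and batch labels", {
  dir <- withr::local_tempdir()
  cf <- file.path(dir, "counts.csv"); xf <- file.path(dir, "coords.csv")
  write.csv(data.frame(row.names = paste0("s", 1:4),
                       g1 = 1:4, g2 = 0:3), cf)
  write.csv(data.frame(row.names = paste0("s", 1:4),
                       x = 1:4, y = 4:1), xf)
  ds <- read_generic(cf, xf)
  expect_equal(dim(ds$coords), c(4L, 2L))
  expect_equal(ds$platform, "generic")

  write.csv(data.frame(row.names = paste0("s", 1:6), x = 1:6, y = 1,
                       z = rep(1:3, each = 2),
                       slice = rep(c("a", "b", "c"), each = 2)), xf)
  write.csv(data.frame(row.names = paste0("s", 1:6), g1 = 1:6, g2 = 6:1), cf)
  ds3 <- read_generic(cf, xf, batch_col = "slice")
  expect_equal(dim(ds3$coords), c(6L, 3L))
  expect_equal(levels(ds3$batch), c("a", "b", "c"))

  write.csv(data.frame(row.names = paste0("s", 1:4), x = c("1", "oops", "3", "4"),
                       y = 1:4), xf)
  write.csv(data.frame(row.names = paste0("s", 1:4), g1 = 1:4, g2 = 1:4), cf)
  expect_error(read_generic(cf, xf), "parse error.*row 2")

  write.csv(data.frame(row.names = paste0("t", 1:4), x = 1:4, y = 1:4), xf)
  expect_error(read_generic(cf, xf), "consistency error")
})

test_that("write_outputs emits aligned files and records the resolution", {
  sim <- make_bands_fixture(seed = 8, rows = 5, cols = 5, n_genes = 20)
  n <- nrow(sim$dataset$coords)
  emb <- structure(list(z_joint = matrix(rnorm(n * 4), n)),
                   class = "latent_embedding")
  dom <- structure(list(labels = factor(rep(1:5, 5)), resolution = 0.73,
                        n_domains = 5L, mode = "fixed_k",
                        metrics = list()), class = "domain_assignment")
  out <- withr::local_tempdir()
  manifest <- write_outputs(sim$dataset, emb, dom, out,
                            config = list(seed = 1L))
  expect_length(manifest, 3L)
  expect_true(all(file.exists(manifest)))
  labs <- read.csv(manifest[2L])
  expect_equal(labs$domain, as.integer(dom$labels))
  cfg <- jsonlite::read_json(manifest[3L])
  expect_equal(cfg$resolution, 0.73)
  bad <- structure(list(z_joint = matrix(0, n - 1, 2)),
                   class = "latent_embedding")
  expect_error(write_outputs(sim$dataset, bad, dom, out), "consistency")
})
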