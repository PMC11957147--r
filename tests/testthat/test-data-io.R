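test_that("constructor validates per-cell fields and gene names", {
  expect_s3_class(tiny_dataset(), "spatial_dataset")
  expect_error(spatial_dataset(matrix(1, 2, 2), x = 1, y = c(0, 0),
                               cell_type = c("a", "b")),
               "out of register")
  expect_error(spatial_dataset(matrix(-1, 2, 2), x = c(0, 1), y = c(0, 0),
                               cell_type = c("a", "b")),
               "negative")
  expect_error(spatial_dataset(matrix(1, 2, 2), x = c(0, NaN), y = c(0, 0),
                               cell_type = c("a", "b")),
               "cell indices: 2")
  expect_error(spatial_dataset(matrix(1, 2, 2), x = c(0, 1), y = c(0, 0),
                               cell_type = c("a", "b"),
                               gene_names = c("g", "g")),
               "unique")
})

test_that("missing structure labels become background", {
  ds <- tiny_dataset()
  expect_equal(ds$structure, c("s1", "s1", "background"))
  ds2 <- spatial_dataset(matrix(1, 2, 2), x = c(0, 1), y = c(0, 0),
                         cell_type = c("a", "b"))
  expect_true(all(ds2$structure == "background"))
})

test_that("low-count filter keeps exactly the cells at or above threshold", {
  ds <- tiny_dataset()  # row sums 5, 10, 50
  kept <- filter_low_count_cells(ds, 10)
  expect_equal(n_cells(kept), 2L)
  expect_equal(rowSums(kept$counts), c(10, 50))
  expect_equal(kept$cell_type, c("a", "b"))
  # threshold 0 is the identity
  expect_equal(filter_low_count_cells(ds, 0), ds)
  # all cells removed
  expect_error(filter_low_count_cells(ds, 1000), "nothing left")
  # normalized input refused
  expect_error(filter_low_count_cells(normalize_log1p(ds)), "raw counts")
})

test_that("filter matches a brute-force row-sum scan and is idempotent", {
  ds <- random_dataset(n = 100, seed = 7)
  thr <- 95
  kept <- filter_low_count_cells(ds, thr)
  manual <- which(apply(ds$counts, 1, sum) >= thr)
  expect_equal(kept$counts, ds$counts[manual, ])
  expect_equal(kept$x, ds$x[manual])
  expect_equal(filter_low_count_cells(kept, thr), kept)
})

test_that("median normalization equalizes totals then applies log1p", {
  counts <- rbind(c(60, 40), c(200, 100))  # totals 100, 300
  ds <- spatial_dataset(counts, x = c(0, 1), y = c(0, 0),
                        cell_type = c("a", "b"))
  nds <- normalize_log1p(ds)
  expect_true(nds$normalized)
  expect_equal(rowSums(expm1(nds$counts)), c(200, 200))  # median of 100, 300
  expect_equal(dim(nds$counts), dim(ds$counts))
  # all-equal totals: scaling is the identity before log
  ds_eq <- spatial_dataset(rbind(c(3, 7), c(6, 4)), x = c(0, 1), y = c(0, 0),
                           cell_type = c("a", "b"))
  expect_equal(normalize_log1p(ds_eq)$counts, log1p(ds_eq$counts))
  expect_error(normalize_log1p(nds), "already normalized")
})

test_that("normalized per-cell totals equal the median total on a Poisson fixture", {
  ds <- random_dataset(n = 50, ng = 30, seed = 3)
  med <- median(rowSums(ds$counts))
  nds <- normalize_log1p(ds)
  expect_lt(max(abs(rowSums(expm1(nds$counts)) - med)), 1e-9)
})

test_that("delimited save/load round-trips all fields", {
  ds <- tiny_dataset()
  path <- file.path(withr::local_tempdir(), "t1.counts.tsv")
  save_dataset(ds, path)
  back <- load_dataset(path)
  expect_equal(back$counts, ds$counts, ignore_attr = FALSE)
  expect_equal(back$x, ds$x)
  expect_equal(back$y, ds$y)
  expect_equal(back$cell_type, ds$cell_type)
  expect_equal(back$structure, ds$structure)
  expect_equal(back$gene_names, ds$gene_names)
})

test_that("delimited loader reports missing components by name", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "c.tsv")
  meta <- file.path(dir, "c.meta.tsv")
  write.table(data.frame(g1 = 1:2, g2 = 2:3), path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(data.frame(cell_id = 1:2, y = c(0, 0),
                         cell_type = c("a", "b")),
              meta, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_dataset(path), "coordinate column 'x'")
  write.table(data.frame(cell_id = 1:2, x = c(0, 1), y = c(0, 0)),
              meta, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_dataset(path), "cell-type column")
  expect_error(load_dataset(file.path(dir, "absent.tsv")), "not found")
})

test_that("h5ad save/load round-trips all fields", {
  ds <- random_dataset(n = 12, ng = 6, seed = 5)
  path <- file.path(withr::local_tempdir(), "ds.h5ad")
  save_dataset(ds, path)
  back <- load_dataset(path)
  expect_equal(back$counts, ds$counts)
  expect_equal(back$x, ds$x)
  expect_equal(back$y, ds$y)
  expect_equal(back$cell_type, ds$cell_type)
  expect_equal(back$structure, ds$structure)
  expect_equal(back$gene_names, ds$gene_names)
  expect_equal(back$normalized, ds$normalized)
})

test_that("h5ad files interoperate with python anndata", {
  dir <- withr::local_tempdir()
  ours <- file.path(dir, "ours.h5ad")
  theirs <- file.path(dir, "theirs.h5ad")
  ds <- random_dataset(n = 8, ng = 4, seed = 9)
  save_dataset(ds, ours)
  script <- sprintf(paste0(
    "import anndata, numpy as np\n",
    "a = anndata.read_h5ad(%s)\n",
    "assert a.shape == (8, 4), a.shape\n",
    "assert a.obs['cell_type'].iloc[0] == %s\n",
    "a.write_h5ad(%s)\n"),
    shQuote(ours), shQuote(ds$cell_type[1]), shQuote(theirs))
  status <- suppressWarnings(
    system2("python", c("-c", shQuote(script)), stdout = TRUE, stderr = TRUE))
  expect_null(attr(status, "status"))
  back <- load_dataset(theirs)
  expect_equal(back$counts, ds$counts, ignore_attr = TRUE)
  expect_equal(back$x, ds$x)
  expect_equal(back$cell_type, ds$cell_type)
  expect_equal(back$structure, ds$structure)
})
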