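test_that("PHYLIP square matrices parse with labels and values intact", {
  f <- withr::local_tempfile(fileext = ".phy")
  writeLines(c("4",
               "A 0 1 2 1",
               "B 1 0 1 2",
               "C 2 1 0 1",
               "D 1 2 1 0"), f)
  d <- read_distance_matrix(f)
  expect_s3_class(d, "mcnet_dist")
  expect_equal(taxa_labels(d), c("A", "B", "C", "D"))
  expect_equal(unclass(d), unclass(cycle4_metric()), ignore_attr = TRUE)
})

test_that("the same matrix wrapped in NEXUS blocks reads identically", {
  f <- withr::local_tempfile(fileext = ".nex")
  writeLines(c("#NEXUS",
               "BEGIN TAXA;",
               "DIMENSIONS ntax=4;",
               "TAXLABELS A B C D;",
               "END;",
               "BEGIN DISTANCES;",
               "FORMAT triangle=both;",
               "MATRIX",
               "A 0 1 2 1",
               "B 1 0 1 2",
               "C 2 1 0 1",
               "D 1 2 1 0",
               ";",
               "END;"), f)
  d <- read_distance_matrix(f)
  expect_equal(d, cycle4_metric(), ignore_attr = TRUE)
  expect_equal(taxa_labels(d), c("A", "B", "C", "D"))

  # lower-triangle variant
  f2 <- withr::local_tempfile(fileext = ".nex")
  writeLines(c("#NEXUS",
               "BEGIN DISTANCES;",
               "FORMAT triangle=lower;",
               "MATRIX",
               "A 0",
               "B 1 0",
               "C 2 1 0",
               "D 1 2 1 0",
               ";",
               "END;"), f2)
  expect_equal(unclass(read_distance_matrix(f2)), unclass(d),
               ignore_attr = TRUE)
})

test_that("malformed rows are reported with their row number", {
  f <- withr::local_tempfile(fileext = ".phy")
  writeLines(c("4",
               "A 0 1 2 1",
               "B 1 0 1",
               "C 2 1 0 1",
               "D 1 2 1 0"), f)
  expect_error(read_distance_matrix(f), "row 2")
})

test_that("strict 10-character PHYLIP label fields are accepted", {
  f <- withr::local_tempfile(fileext = ".phy")
  writeLines(c("4",
               "taxon one 0 1 2 1",
               "taxon two 1 0 1 2",
               "taxon thr 2 1 0 1",
               "taxon fou 1 2 1 0"), f)
  d <- read_distance_matrix(f)
  expect_equal(taxa_labels(d),
               c("taxon one", "taxon two", "taxon thr", "taxon fou"))
  expect_equal(d[1, 3], 2)
})

test_that("data errors are rejected: asymmetry, duplicates, too few taxa", {
  m <- unclass(cycle4_metric())
  bad <- m; bad[1, 2] <- bad[1, 2] + 1e-3
  expect_error(distance_matrix(bad), "asymmetric")
  # small asymmetry is averaged away
  ok <- m; ok[1, 2] <- ok[1, 2] + 1e-8
  d <- distance_matrix(ok)
  expect_equal(d[1, 2], d[2, 1])
  expect_equal(d[1, 2], 1 + 5e-9, tolerance = 1e-12)
  expect_error(distance_matrix(m, labels = c("A", "A", "B", "C")),
               "duplicate")
  expect_error(distance_matrix(m[1:3, 1:3]), "at least 4")
  neg <- m; neg[1, 2] <- neg[2, 1] <- -0.5
  expect_error(distance_matrix(neg), "non-negative")
})

test_that("PHYLIP write -> read round-trips labels and values", {
  g <- random_tree_metric(7, seed = 11)
  f <- withr::local_tempfile(fileext = ".phy")
  write_distance_phylip(g$d, f)
  d2 <- read_distance_matrix(f)
  expect_equal(taxa_labels(d2), taxa_labels(g$d))
  expect_equal(unclass(d2), unclass(g$d), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("split systems round-trip through the NEXUS SPLITS dialect", {
  g <- random_tree_metric(6, seed = 5)
  sys <- filter_splits(weight_splits(g$d, initial_ordering(g$d)))
  f <- withr::local_tempfile(fileext = ".nex")
  write_splits_nexus(sys, f)
  txt <- readLines(f)
  expect_true(any(grepl(sprintf("nsplits=%d", length(sys$splits)), txt)))
  expect_true(any(grepl("^CYCLE", txt)))
  back <- read_splits_nexus(f)
  expect_equal(back$labels, sys$labels)
  expect_equal(canonical_ordering(back$cycle), sys$cycle)
  o <- order(split_keys(back$splits))
  o2 <- order(split_keys(sys$splits))
  expect_equal(split_keys(back$splits)[o], split_keys(sys$splits)[o2])
  expect_equal(back$weights[o], sys$weights[o2], tolerance = 1e-9)
})

test_that("degenerate and contract-violating split systems are handled", {
  g <- random_tree_metric(5, seed = 2)
  sys <- weight_splits(g$d, initial_ordering(g$d))
  empty <- filter_splits(sys, threshold = max(sys$weights) + 1)
  expect_length(empty$splits, 0)
  f <- withr::local_tempfile(fileext = ".nex")
  write_splits_nexus(empty, f)
  expect_true(any(grepl("nsplits=0", readLines(f))))
  bad <- sys  # unfiltered: contains exact-zero weights
  expect_true(any(bad$weights <= 0))
  expect_error(write_splits_nexus(bad, f), "positive")
})
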