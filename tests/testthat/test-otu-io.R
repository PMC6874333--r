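test_that("reading a delimited table preserves values and handles orientation", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tg__A\tg__B",
               "s1\t1\t2", "s2\t3\t4", "s3\t5\t6"), tsv)
  tab <- read_otu_table(tsv)
  expect_equal(dim(tab), c(3L, 2L))
  expect_equal(unname(tab$values), matrix(c(1, 3, 5, 2, 4, 6), 3, 2))
  expect_equal(rownames(tab$values), c("s1", "s2", "s3"))

  # same file interpreted as taxa-in-rows comes back transposed
  tab_t <- read_otu_table(tsv, orientation = "taxa_as_rows")
  expect_equal(dim(tab_t), c(2L, 3L))
  expect_equal(tab_t$values["g__A", "s2"], tab$values["s2", "g__A"])
})

test_that("write/read round-trip preserves IDs and values to 1e-12", {
  tab <- toy_table()
  tab$values[1, 1] <- pi * 1e3
  f <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(OTUTable(tab$values), f)
  back <- read_otu_table(f)
  expect_equal(rownames(back$values), rownames(tab$values))
  expect_equal(colnames(back$values), colnames(tab$values))
  expect_equal(back$values, tab$values, tolerance = 1e-12)
})

test_that("malformed cells and duplicate IDs are rejected with names", {
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tg__A", "s1\t1", "s2\tx7"), bad)
  expect_error(read_otu_table(bad), "s2.*g__A")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tg__Dialister\tg__Dialister",
               "s1\t1\t2"), dup)
  expect_error(read_otu_table(dup), "duplicate taxon ID.*g__Dialister")
  expect_error(OTUTable(matrix(1:4, 2, 2,
                               dimnames = list(c("a", "a"), c("x", "y")))),
               "duplicate sample ID")
})

test_that("metadata attaches labels by sample ID", {
  tab <- toy_table()
  md <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(sample_id = rev(sample_ids <- rownames(tab$values)),
                                label = rev(tab$labels)),
                     md, sep = "\t", quote = FALSE, row.names = FALSE)
  relabeled <- read_metadata(OTUTable(tab$values), md)
  expect_equal(relabeled$labels, tab$labels)
})

test_that("relative-abundance normalization divides rows by their sums", {
  m <- matrix(c(2, 2, 4, 5, 0, 0), 2, 3, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("t1", "t2", "t3")))
  norm <- to_relative_abundance(OTUTable(m))
  expect_equal(unname(norm$values[1, ]), c(0.25, 0.25, 0.5))
  expect_equal(unname(norm$values[2, ]), c(1, 0, 0))
  expect_true(norm$normalized)
  expect_equal(unname(rowSums(norm$values)), c(1, 1), tolerance = 1e-9)

  single <- OTUTable(matrix(5, 1, 1, dimnames = list("s1", "t1")))
  expect_equal(unname(to_relative_abundance(single)$values[1, 1]), 1)

  zero <- OTUTable(matrix(c(1, 0, 1, 0), 2, 2,
                          dimnames = list(c("s1", "s2"), c("t1", "t2"))))
  expect_error(to_relative_abundance(zero), "s2")
})

test_that("prevalence filter uses a ceiling on the required sample count", {
  m <- matrix(0, 4, 2, dimnames = list(paste0("s", 1:4), c("rare", "common")))
  m[1, "rare"] <- 3
  m[, "common"] <- 1
  tab <- OTUTable(m)
  # 1 nonzero sample of 4: kept at 25% (ceil(1) = 1), dropped at 50%
  expect_true("rare" %in% colnames(prevalence_filter(tab, 0.25)$values))
  expect_false("rare" %in% colnames(prevalence_filter(tab, 0.5)$values))
  expect_true("common" %in% colnames(prevalence_filter(tab, 1.0)$values))
  # idempotence
  once <- prevalence_filter(tab, 0.5)
  expect_identical(prevalence_filter(once, 0.5)$values, once$values)
})

test_that("phenotype split partitions samples and keeps all taxa", {
  tab <- toy_table(n_per_group = 5)
  tab$labels[1:2] <- "IBD"  # unbalance: 3 healthy, 7 IBD
  tab <- OTUTable(tab$values, labels = tab$labels)
  halves <- split_by_phenotype(tab)
  expect_named(halves, c("Healthy", "IBD"))
  expect_equal(nrow(halves$IBD$values), 7)
  expect_equal(nrow(halves$Healthy$values), 3)
  expect_length(intersect(rownames(halves$IBD$values),
                          rownames(halves$Healthy$values)), 0)
  expect_equal(colnames(halves$IBD$values), colnames(tab$values))

  mono <- OTUTable(tab$values, labels = rep("IBD", 10))
  expect_error(split_by_phenotype(mono), "2 label values")
})

test_that("nested subsets are class-balanced, nested and seeded", {
  tab <- make_benchmark(n_taxa = 20, n_planted = 2, n_per_group = 60,
                        seed = 5)$table
  subs <- nested_subsets(tab, c(10, 25, 50), seed = 3)
  expect_equal(vapply(subs, function(s) nrow(s$values), 0L), c(20L, 50L, 100L))
  for (i in 1:2)
    expect_true(all(rownames(subs[[i]]$values) %in% rownames(subs[[i + 1]]$values)))
  for (s in subs)
    expect_true(all(table(s$labels) == nrow(s$values) / 2))
  again <- nested_subsets(tab, c(10, 25, 50), seed = 3)
  expect_identical(lapply(subs, `[[`, "values"), lapply(again, `[[`, "values"))
  expect_error(nested_subsets(tab, c(50, 25), seed = 3), "strictly increasing")
  expect_error(nested_subsets(tab, c(10, 70), seed = 3), "infeasible")
})

test_that("the optional BIOM reader matches the delimited-text reader", {
  tab <- toy_table(n_per_group = 3, n_taxa = 4)
  f <- withr::local_tempfile(fileext = ".biom")
  b <- biomformat::make_biom(t(tab$values))  # BIOM stores taxa x samples
  biomformat::write_biom(b, f)
  back <- read_otu_biom(f)
  expect_equal(back$values[rownames(tab$values), colnames(tab$values)],
               tab$values)
})
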