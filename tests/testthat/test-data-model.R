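test_that("CSV round trip is the identity on validated items", {
  items <- small_items()
  path <- withr::local_tempfile(fileext = ".csv")
  writeResponseTable(items, path)
  back <- readResponseTable(path)
  expect_equal(as.data.frame(back), as.data.frame(items), ignore_attr = TRUE)
  # bit-stable: writing the read-back file reproduces the bytes
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeResponseTable(back, path2)
  expect_identical(readLines(path), readLines(path2))
  # missing tokens survive the round trip
  expect_true(any(back$outcome == "missing"))
})

test_that("reader reconstructs the design and validates tokens row by row", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("participant,level,case,subspecialty,specimen,category,outcome",
               "P1,senior,1,breast,biopsy,1,correct",
               "P1,senior,1,breast,biopsy,3,error",
               "P2,junior,1,breast,biopsy,1,missing"), path)
  items <- readResponseTable(path)
  expect_equal(nrow(items), 3L)
  design <- attr(items, "design")
  expect_s3_class(design, "study_design")
  expect_setequal(design$participants$level, c("senior", "junior"))

  writeLines(c("participant,level,case,subspecialty,specimen,category,outcome",
               "P1,senior,1,breast,biopsy,1,correct",
               "P1,senior,1,breast,biopsy,6,correct"), path)
  expect_error(readResponseTable(path), "row 2.*category", ignore.case = TRUE)

  writeLines(c("participant,level,case,subspecialty,specimen,category,outcome",
               "P1,senior,1,breast,biopsy,1,correct",
               "P1,senior,1,breast,biopsy,1,error"), path)
  expect_error(readResponseTable(path), "duplicate")

  writeLines(c("participant,level,case,subspecialty,specimen,category,outcome",
               "P1,senior,1,breast,biopsy,1,correct",
               "P1,junior,1,breast,biopsy,3,error"), path)
  expect_error(readResponseTable(path), "inconsistent career level")
})

test_that("empty collections write a header-only file", {
  empty <- responseItems(data.frame(participant = character(0),
                                    level = character(0), case = integer(0),
                                    subspecialty = character(0),
                                    specimen = character(0),
                                    category = integer(0),
                                    outcome = character(0)))
  path <- withr::local_tempfile(fileext = ".csv")
  writeResponseTable(empty, path)
  expect_equal(readLines(path),
               "participant,level,case,subspecialty,specimen,category,outcome")
})

test_that("packaged fixture has the study's item and missingness counts", {
  items <- pkg_items()
  expect_equal(nrow(items), 1445L)
  expect_equal(sum(items$outcome == "missing"), 100L)
  expect_equal(sum(items$outcome != "missing"), 1345L)
  expect_equal(length(unique(items$participant)), 17L)
  expect_equal(length(unique(items$case)), 25L)
})

test_that("marginal validation flags exactly the perturbed groups", {
  items <- pkg_items()
  t1 <- pkg_table1()
  report <- validateAgainstMarginals(items, t1)
  expect_equal(attr(report, "n_mismatches"), 0L)

  # flip one answered outcome: one group per grouping (plus the total) moves
  flipped <- as.data.frame(items)
  i <- which(flipped$outcome == "correct")[1]
  flipped$outcome[i] <- "error"
  flipped <- responseItems(flipped)
  rep2 <- validateAgainstMarginals(flipped, t1)
  bad <- rep2[!rep2$match, ]
  expect_equal(nrow(bad), 6L)
  expect_setequal(bad$grouping, c(groupingNames(), "total"))
  expect_equal(bad$group[bad$grouping == "pathologist"],
               flipped$participant[i])
  expect_equal(bad$group[bad$grouping == "specimen"], flipped$specimen[i])

  # empty items: every reference group is a mismatch
  empty <- responseItems(items[0, ])
  rep3 <- validateAgainstMarginals(empty, t1)
  expect_true(all(!rep3$match))
})

test_that("grouping tables conserve totals across all groupings", {
  items <- small_items(seed = 7)
  tabs <- lapply(groupingNames(), function(g) errorTable(items, g))
  totals <- t(vapply(tabs, function(tab)
    unlist(tab[tab$group == "Total", c("n_tasks", "n_errors")]), numeric(2)))
  expect_true(all(totals[, 1] == totals[1, 1]))
  expect_true(all(totals[, 2] == totals[1, 2]))
})

test_that("unknown grouping labels in a reference are rejected", {
  items <- pkg_items()
  ref <- list(organ = groupErrorTable("liver", 10, 1, grouping = "organ"))
  expect_error(validateAgainstMarginals(items, ref), "unknown grouping")
})
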