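test_that("uncentred correlation distances match a double-loop oracle", {
  set.seed(5)
  m <- matrix(runif(100, 0, 20), 20,
              dimnames = list(sprintf("SYN%04d", 1:20),
                              sprintf("F%d", 1:5)))
  cl <- clusterProfiles(m, logTransform = FALSE)
  d <- cl$distanceMatrix
  rs <- rownames(cl$matrix)
  for (i in 1:20) {
    for (j in 1:20) {
      x <- m[rs[i], ]; y <- m[rs[j], ]
      want <- 1 - sum(x * y) / (sqrt(sum(x^2)) * sqrt(sum(y^2)))
      expect_lt(abs(d[i, j] - max(want, 0)), 1e-12)
    }
  }
})

test_that("identical rows merge first at height zero", {
  m <- rbind(A = c(1, 2, 3), B = c(2, 4, 6) / 2, C = c(9, 1, 4))
  cl <- clusterProfiles(m, logTransform = FALSE)
  hc <- cl$hclust
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  first <- rownames(cl$matrix)[-hc$merge[1, ]]
  expect_setequal(first, c("A", "B"))
  # merge heights are non-decreasing under average linkage
  expect_true(all(diff(hc$height) >= -1e-12))
  # two rows: a single merge
  cl2 <- clusterProfiles(m[1:2, ], logTransform = FALSE)
  expect_length(cl2$hclust$height, 1)
  expect_setequal(cl2$leafOrder, c("A", "B"))
})

test_that("clustering is invariant to row input order", {
  set.seed(6)
  m <- matrix(runif(60), 12,
              dimnames = list(sprintf("SYN%04d", 1:12),
                              sprintf("F%d", 1:5)))
  cl1 <- clusterProfiles(m)
  cl2 <- clusterProfiles(m[sample(12), ])
  expect_identical(cl1$leafOrder, cl2$leafOrder)
  expect_equal(cl1$hclust$height, cl2$hclust$height)
})

test_that("constant-zero rows get unit distance with a warning", {
  m <- rbind(A = c(0, 0, 0), B = c(1, 2, 3), C = c(3, 2, 1))
  expect_warning(cl <- clusterProfiles(m, logTransform = FALSE),
                 "zero-norm")
  expect_equal(cl$distanceMatrix["A", "B"], 1)
})

test_that("enrichment labels follow the fold rules", {
  prof <- rbind(U = c(5, 0, 0), E = c(4, 1, 0.5), S = c(3, 2, 2.5),
                D = c(1, 4, 2), Z = c(0, 0, 0))
  colnames(prof) <- c("HermesBody", "LiverGolgi", "LiverER")
  expect_message(
    calls <- classifyEnrichment(prof, "HermesBody",
                                c("LiverGolgi", "LiverER"),
                                foldThreshold = 2),
    "all-zero")
  got <- stats::setNames(calls$label, calls$group)
  expect_identical(unname(got["U"]), "unique_to_target")
  expect_identical(unname(got["E"]), "enriched_in_target")
  expect_identical(unname(got["S"]), "shared_with_reference")
  expect_identical(unname(got["D"]), "depleted_in_target")
  expect_equal(calls$fold[calls$group == "E"], 4)
  expect_identical(attr(calls, "excluded"), "Z")
  # labels partition the non-excluded groups
  expect_length(got, 4)
})

test_that("abundance ranking is descending with accession tie-break", {
  prof <- rbind(A = c(5, 0), B = c(1, 0), C = c(3, 0), E = c(2, 0),
                D = c(2, 0))
  colnames(prof) <- c("HermesBody", "X")
  expect_identical(rankByAbundance(prof, "HermesBody"),
                   c("A", "C", "D", "E", "B"))
})

test_that("category rollup conserves percentage mass and matches a brute-force oracle", {
  set.seed(8)
  prof <- matrix(runif(40, 0, 10), 10,
                 dimnames = list(sprintf("SYN%04d", 1:10),
                                 sprintf("F%d", 1:4)))
  ann <- data.frame(accession = rownames(prof)[1:7],
                    category = sample(functionalCategories()[1:4], 7,
                                      replace = TRUE))
  roll <- categoryRollup(prof, ann)
  expect_equal(colSums(roll), colSums(prof), tolerance = 1e-9)
  # brute force group-by-and-sum oracle
  cat <- ifelse(rownames(prof) %in% ann$accession,
                ann$category[match(rownames(prof), ann$accession)],
                "unknown")
  for (cc in rownames(roll)) {
    for (f in colnames(roll))
      expect_equal(roll[cc, f], sum(prof[cat == cc, f]))
  }
  expect_error(
    categoryRollup(prof, data.frame(accession = "SYN0001",
                                    category = "not a category")),
    "vocabulary")
})

test_that("annotation tables are validated against the 22-name vocabulary", {
  expect_length(functionalCategories(), 22)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeTSV(data.frame(accession = c("A", "B"),
                      category = c("traffic", "metabolism")), f)
  ann <- readCategoryTable(f)
  expect_identical(ann$category, c("traffic", "metabolism"))
  writeTSV(data.frame(accession = "A", category = "Golgi stuff"), f)
  expect_error(readCategoryTable(f), "vocabulary")
})
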