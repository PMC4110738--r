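test_that("datasets assemble requested class compositions with provenance", {
  model <- test_model()
  # a synthetic report stands in for a large ensemble: 30 networks with
  # arbitrary weights, 12 of them positive
  n <- 30L
  ids <- sprintf("net%05d", 1:n)
  set.seed(3)
  w <- matrix(sample.int(100L, n * 20L, TRUE), n, 20,
              dimnames = list(ids, sprintf("edge%02d", 1:20)))
  prof <- data.frame(network_id = ids, seed = 1:n,
                     kind = rep(c("type_a", "negative"), c(12L, 18L)),
                     x = NA_integer_, y = NA_integer_,
                     y_level = NA_integer_, monotone = TRUE, n_budget = 0L,
                     positive = rep(c(TRUE, FALSE), c(12L, 18L)))
  report <- pheronet:::new_report("exp1", prof, w,
                                  concentration_plan("exp1"), "t23",
                                  firing_policy(), 1L, model)
  ds <- make_dataset(report, n_pos = 12L, n_neg = 12L, seed = 5L)
  expect_identical(table(ds$class)[["P"]], 12L)
  expect_identical(table(ds$class)[["N"]], 12L)
  expect_identical(ncol(ds), 21L)
  # all positives are taken; only the negative sample varies with the seed
  ds2 <- make_dataset(report, n_pos = 12L, n_neg = 12L, seed = 6L)
  expect_equal(ds[ds$class == "P", ], ds2[ds2$class == "P", ],
               ignore_attr = TRUE)
  expect_identical(rownames(ds)[ds$class == "P"],
                   rownames(ds2)[ds2$class == "P"])
  expect_false(identical(rownames(ds[ds$class == "N", ]),
                         rownames(ds2[ds2$class == "N", ])))
  expect_identical(make_dataset(report, 12L, 12L, 5L), ds)
  expect_error(make_dataset(report, n_pos = 13L, n_neg = 5L, seed = 1L),
               "positives")
  expect_error(make_dataset(report, n_pos = 5L, n_neg = 30L, seed = 1L),
               "negatives")
})

test_that("a planted single-attribute signal is recovered at the root", {
  df <- planted_dataset(n = 150, cutoff = 50, seed = 11)
  tree <- induce_tree(df)
  expect_identical(tree$root$type, "node")
  expect_identical(tree$root$attribute, "s2TOt2")
  # agreement with the exhaustive single-split oracle
  oracle <- best_single_split(df)
  expect_identical(oracle$attr, "s2TOt2")
  expect_lte(abs(tree$root$threshold - oracle$cut), 2)
  expect_lte(abs(tree$root$threshold - 50), 2)
  # perfect training-set separation on the planted table
  expect_identical(predict(tree, df), df$class)
})

test_that("degenerate tables give leaves and duplication changes nothing", {
  df <- planted_dataset(n = 60, seed = 2)
  one <- df[df$class == "P", ]
  leaf <- induce_tree(one)
  expect_identical(leaf$root$type, "leaf")
  expect_identical(leaf$root$class, "P")
  # duplicating every row leaves split selection unchanged
  t1 <- induce_tree(df)
  t2 <- induce_tree(rbind(df, df))
  strip <- function(nd) {
    if (nd$type == "leaf") return(list(class = nd$class))
    list(a = nd$attribute, thr = nd$threshold,
         l = strip(nd$left), r = strip(nd$right))
  }
  expect_identical(strip(t1$root), strip(t2$root))
})

test_that("induction is deterministic and matches an independent learner", {
  skip_if_not_installed("rpart")
  df <- planted_dataset(n = 200, cutoff = 35, seed = 21, noise = 0.05)
  t1 <- induce_tree(df)
  t2 <- induce_tree(df)
  expect_identical(t1, t2)
  rp <- rpart::rpart(class ~ ., df, method = "class",
                     control = rpart::rpart.control(minsplit = 4, cp = 0.01))
  expect_identical(as.character(rp$frame$var[1]), t1$root$attribute)
})

test_that("stratified cross-validation reports per-class recall", {
  df <- planted_dataset(n = 120, seed = 31, gap = 10L)
  cv <- crossval(df, k = 10L, seed = 1L)
  expect_length(cv$fold_trees, 10L)
  expect_identical(sum(cv$confusion), 120L)
  # perfectly separable signal: both recalls at 100%
  expect_identical(unname(cv$class_accuracy["P"]), 100)
  expect_identical(unname(cv$class_accuracy["N"]), 100)
  # class-independent attributes: recalls hover around chance at n = 400
  for (s in 1:3) {
    set.seed(100 + s)
    noise <- as.data.frame(matrix(sample.int(100L, 400 * 10, TRUE), 400, 10))
    noise$class <- factor(rep(c("P", "N"), each = 200))
    cvn <- crossval(noise, k = 10L, seed = s)
    expect_true(all(cvn$class_accuracy >= 35 & cvn$class_accuracy <= 65))
  }
  expect_error(crossval(df[1:12, ], k = 10L), "at least k")
})

test_that("level summaries count attributes once per tree per level", {
  df <- planted_dataset(n = 150, cutoff = 50, seed = 41)
  tree <- induce_tree(df)
  ten <- rep(list(tree), 10L)
  sm <- summarize_levels(ten)
  expect_s3_class(sm, "tree_summary")
  expect_true(all(sm$count == 10L))
  expect_identical(sm$attribute[sm$level == 1L], "s2TOt2")
  expect_false(is.unsorted(sm$level))
  # via cross-validation: the planted attribute dominates the root level
  cv <- crossval(df, k = 10L, seed = 7L)
  sm2 <- summarize_levels(cv$fold_trees, max_level = 4L, min_count = 6L)
  root <- sm2[sm2$level == 1L, ]
  expect_identical(root$attribute, "s2TOt2")
  expect_gte(root$count, 9L)
  expect_lte(abs(root$median_threshold - 50), 2)
  # counts never exceed the number of trees
  expect_true(all(sm2$count <= 10L))
})

test_that("negative-class recall grows with the negative class prior", {
  # trend in expectation over seeded repetitions, on weak-signal data with
  # compositions shaped 1:1, 1:3, 1:4
  accs <- matrix(NA_real_, 10L, 3L)
  for (s in 1:10) {
    df <- planted_dataset(n = 400, cutoff = 50, seed = 500 + s, noise = 0.35)
    pos <- df[df$class == "P", ][1:40, ]
    neg <- df[df$class == "N", ]
    for (ci in 1:3) {
      n_neg <- c(40L, 120L, 160L)[ci]
      d <- rbind(pos, neg[seq_len(n_neg), ])
      cv <- crossval(d, k = 10L, seed = s)
      accs[s, ci] <- cv$class_accuracy[["N"]]
    }
  }
  means <- colMeans(accs)
  expect_true(all(diff(means) > -1e-9))
})

test_that("datasets export to CSV and ARFF", {
  df <- planted_dataset(n = 30, seed = 51)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_dataset(df, csv, "csv")
  back <- read.csv(csv)
  expect_identical(dim(back), dim(df))
  arff <- withr::local_tempfile(fileext = ".arff")
  write_dataset(df, arff, "arff", relation = "planted")
  lines <- readLines(arff)
  expect_identical(lines[1], "@relation planted")
  expect_identical(sum(grepl("^@attribute", lines)), ncol(df))
  expect_true("@attribute class {P,N}" %in% lines)
  expect_identical(sum(grepl("^@", lines) | lines == "@data"),
                   ncol(df) + 2L)
  expect_identical(length(lines) - ncol(df) - 2L, nrow(df))
})

test_that("three-class tables grow a single multiclass tree", {
  set.seed(61)
  n <- 90L
  df <- data.frame(edge01 = sample.int(100L, n, TRUE),
                   edge02 = sample.int(100L, n, TRUE))
  df$class <- factor(ifelse(df$edge01 <= 33, "CS",
                            ifelse(df$edge01 <= 66, "CD", "CN")),
                     levels = c("CS", "CD", "CN"))
  tree <- induce_tree(df)
  expect_identical(tree$root$attribute, "edge01")
  expect_identical(sort(unique(as.character(predict(tree, df)))),
                   sort(levels(df$class)))
  expect_identical(predict(tree, df), df$class)
  cv <- crossval(df, k = 10L, seed = 2L)
  expect_identical(sort(names(cv$class_accuracy)), sort(levels(df$class)))
})
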