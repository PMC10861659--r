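test_that("descriptor tables cover the panel with the named families", {
  desc <- buildDescriptorTable(modelPanel())
  expect_equal(nrow(desc), 17L)
  expect_gte(ncol(desc), 5L)
  expect_false(anyNA(desc))
  expect_true(all(c("logP", "TPSA", "MW", "HBD", "HBA") %in% names(desc)))
  ## empty in, empty out
  expect_equal(nrow(buildDescriptorTable(modelPanel()[0, ])), 0L)
  ## unparseable structures are flagged and excluded
  broken <- modelPanel()[1:3, ]
  broken$smiles[2] <- "not_a_structure((("
  expect_warning(d <- buildDescriptorTable(broken), "unparseable")
  expect_equal(nrow(d), 2L)
})

test_that("the variance filter removes constants and identifiers, idempotently", {
  t <- data.frame(const = rep(3.7, 17),
                  id = as.character(1:17),
                  two = rep(c(1, 2), length.out = 17),
                  cat = rep(c("a", "b"), length.out = 17),
                  stringsAsFactors = FALSE)
  f <- removeUseless(t)
  expect_setequal(names(f), c("two", "cat"))       # 17/17 distinct > 99%
  expect_identical(removeUseless(f), f)            # idempotent
  expect_identical(names(f), c("two", "cat"))      # order preserved
  expect_error(removeUseless(t[, "const", drop = FALSE]), "every feature")
  expect_error(removeUseless(t, threshold = 0), "0, 100")
})

test_that("a separable toy set trains to perfect accuracy with one tree", {
  x <- toyDescriptors(); y <- toyLabels()
  m <- trainModel(x, y, nTrees = 1, mtry = 1, seed = 1)
  expect_equal(trainingAccuracy(m), 1)
  ## AD box contains every training row by construction
  expect_true(all(inDomain(m, x)))
  expect_identical(colnames(adRanges(m)), retainedFeatures(m))
  expect_error(trainModel(x, setNames(rep("positive", 8), rownames(x))),
               "both classes")
})

test_that("range-based AD is inclusive at boundaries and order-invariant", {
  x <- toyDescriptors(); y <- toyLabels()
  m <- trainModel(x, y, nTrees = 50, seed = 2)
  atMin <- setNames(as.numeric(adRanges(m)["min", ]), retainedFeatures(m))
  expect_true(inDomain(m, atMin))
  above <- atMin; above["f1"] <- adRanges(m)["max", "f1"] + 1e-9
  expect_false(inDomain(m, above))
  ## permuting feature order does not change membership
  expect_true(inDomain(m, rev(atMin)))
  expect_error(inDomain(m, atMin[-1]), "missing feature")
})

test_that("screening scores partition and the 0.9 cut is strict", {
  x <- toyDescriptors(16); y <- toyLabels(16)
  m <- trainModel(x, y, nTrees = 200, seed = 3)
  ## screen a mix of in- and out-of-domain rows
  probe <- rbind(x, data.frame(f1 = c(100, -50), f2 = c(0, 1),
                               row.names = c("far1", "far2")))
  sc <- screenSubstances(m, probe)
  expect_equal(sc$counts$n_input,
               sc$counts$out_of_domain + sc$counts$detectable +
               sc$counts$undetectable)
  expect_true(all(is.na(sc$results$score[!sc$results$in_ad])))
  expect_true(all(sc$results$predicted[!sc$results$in_ad] ==
                  "out_of_domain"))
  ## strictness of the high-confidence threshold
  expect_true(all(sc$results$high_confidence == (
    !is.na(sc$results$score) & sc$results$score > 0.9 &
      sc$results$predicted == "detectable")))
  ## a vector deep inside the positive cloud scores 1.0
  deep <- data.frame(f1 = 8.5, f2 = 1, row.names = "deep")
  d <- screenSubstances(m, deep)
  expect_equal(d$results$score, 1.0)
  expect_true(d$results$high_confidence)
})

test_that("stratified CV is deterministic and collapses under label permutation", {
  desc <- removeUseless(buildDescriptorTable(modelPanel()))
  labels <- setNames(modelPanel()$hair_label, modelPanel()$name)
  a <- crossValidate(desc, labels, k = 10, seed = 77, nTrees = 100)
  b <- crossValidate(desc, labels, k = 10, seed = 77, nTrees = 100)
  expect_identical(a$folds, b$folds)
  expect_identical(a$accuracy, b$accuracy)
  ## every fold contains at most one negative (3 negatives, 10 folds)
  negFolds <- a$folds[labels[rownames(desc)] == "negative"]
  expect_true(all(table(negFolds) == 1))
  expect_error(crossValidate(desc, labels, k = 18), "exceed")

  ## permutation null: mean CV accuracy near the majority-class rate
  set.seed(11)
  accs <- vapply(1:30, function(i) {
    perm <- setNames(sample(labels), names(labels))
    crossValidate(desc, perm, k = 10, seed = i, nTrees = 60)$accuracy
  }, numeric(1))
  ## majority class is 14/17 ~ 0.82; permuted-label CV cannot beat it
  ## systematically (tolerance = 3 x MC standard error)
  expect_lt(abs(mean(accs) - 14 / 17), 0.12)
})
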