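## Descriptor-based hair-detectability screening: descriptor table
## construction, variance-percentage feature filtering, random-forest
## training with stratified tenfold cross-validation, range-based
## applicability domain, and scored screening of substance lists.

.descriptorSMARTS <- c(
  carboxylic_acid = "[CX3](=O)[OX2H1]",
  sulfonamide     = "[SX4](=[OX1])(=[OX1])[NX3]",
  phenol          = "[OX2H][cX3]",
  basic_amine     = "[NX3;H2,H1,H0;!$(N=*);!$(NC=O);!$(NS=O);!$(N[a])]")

#' Build a descriptor table for a substance set
#'
#' Computes the lipophilicity-, pH- and mass-related descriptor family
#' from embedded structures with Open Babel (via ChemmineR/ChemmineOB):
#' logP, topological polar surface area, H-bond donors and acceptors,
#' molecular weight, molar refractivity, plus SMARTS-counted
#' ionizable-group features (carboxylic acids, sulfonamides, phenols,
#' basic amines) and a net charge-at-pH-7.4 proxy (basic minus acidic
#' group counts). Alternatively, an externally computed descriptor CSV
#' is passed through bit-exactly.
#'
#' @param panel Substance panel with \code{name} and \code{smiles}
#'   columns; ignored when \code{descriptorCsv} is given.
#' @param descriptorCsv Optional path to an external descriptor CSV
#'   (see \code{\link{readDescriptorTable}}).
#' @return data.frame of features with substance row names; substances
#'   whose structure fails to parse are dropped with a warning. Zero
#'   rows in, zero rows out.
#' @examples
#' \donttest{head(buildDescriptorTable(modelPanel()))}
#' @export
buildDescriptorTable <- function(panel = modelPanel(),
                                 descriptorCsv = NULL) {
  if (!is.null(descriptorCsv)) return(readDescriptorTable(descriptorCsv))
  stopifnot(all(c("name", "smiles") %in% names(panel)))
  if (!nrow(panel))
    return(data.frame())
  ## per-molecule conversion: a batch call stops at the first invalid
  ## structure instead of skipping it
  sdfs <- list(); bad <- character()
  for (i in seq_len(nrow(panel))) {
    s <- tryCatch(
      suppressWarnings(ChemmineR::smiles2sdf(
        stats::setNames(panel$smiles[i], panel$name[i]))),
      error = function(e) NULL)
    if (is.null(s) || !length(s) || !ChemmineR::validSDF(s)[1])
      bad <- c(bad, panel$name[i])
    else sdfs[[panel$name[i]]] <- s
  }
  if (length(bad))
    warning("unparseable structure(s) excluded: ",
            paste(bad, collapse = ", "))
  if (!length(sdfs)) return(data.frame())
  sdf <- Reduce(c, unname(sdfs))
  props <- ChemmineR::propOB(sdf)
  tab <- data.frame(
    logP = props$logP, TPSA = props$TPSA, MW = props$MW,
    MR = props$MR, HBD = props$HBD, HBA = props$HBA2,
    row.names = names(sdfs))
  for (nm in names(.descriptorSMARTS)) {
    hits <- ChemmineR::smartsSearchOB(sdf, .descriptorSMARTS[[nm]],
                                      uniqueMatches = TRUE)
    tab[[paste0("n_", nm)]] <- as.numeric(hits)
  }
  tab$charge_ph74 <- tab$n_basic_amine -
    (tab$n_carboxylic_acid + tab$n_sulfonamide)
  stopifnot(!anyNA(tab))
  tab
}

#' Drop uninformative features (variance-percentage filter)
#'
#' Removes numeric features with (relatively) zero variance and
#' categorical features whose distinct-value count exceeds
#' \code{threshold} percent of the row count (identifier-like columns).
#' Column order of the retained features is preserved, and the filter is
#' idempotent.
#'
#' @param table Descriptor data.frame.
#' @param threshold Distinct-value percentage threshold in (0, 100]
#'   (default 99).
#' @return Filtered data.frame; error if every feature would be removed.
#' @examples
#' t <- data.frame(a = c(1, 1, 1), b = c(1, 2, 3))
#' names(removeUseless(t))  # "b"
#' @export
removeUseless <- function(table, threshold = 99) {
  if (!(threshold > 0 && threshold <= 100))
    stop("threshold must lie in (0, 100]")
  n <- nrow(table)
  keep <- vapply(table, function(col) {
    if (is.numeric(col)) {
      scale <- max(1, abs(mean(col)))
      stats::sd(col) / scale > 1e-12
    } else {
      100 * length(unique(col)) / n <= threshold
    }
  }, logical(1))
  if (!any(keep)) stop("variance filter removed every feature")
  table[, keep, drop = FALSE]
}

#' Train the random-forest hair-detectability model
#'
#' Fits a \code{randomForest} classifier under a fixed seed, re-predicts
#' the training rows for the training accuracy, and records the
#' per-feature min/max box over the training set as the range-based
#' applicability domain.
#'
#' @param table Descriptor data.frame (rows = substances).
#' @param labels Factor or character, \code{positive}/\code{negative},
#'   aligned with (or named by) the table rows.
#' @param nTrees Trees in the forest (default 500).
#' @param mtry Features tried per split (default floor(sqrt(p))).
#' @param seed Forest seed (default 20240115).
#' @return A \code{\linkS4class{QSARModel}}.
#' @export
trainModel <- function(table, labels, nTrees = 500,
                       mtry = max(1, floor(sqrt(ncol(table)))),
                       seed = 20240115) {
  if (!is.null(names(labels))) labels <- labels[rownames(table)]
  labels <- factor(labels, levels = c("negative", "positive"))
  if (anyNA(labels) || length(labels) != nrow(table))
    stop("labels must align with table rows")
  if (nlevels(droplevels(labels)) < 2L)
    stop("training requires both classes")
  x <- as.data.frame(table)
  set.seed(as.integer(seed))
  rf <- randomForest::randomForest(x = x, y = labels, ntree = nTrees,
                                   mtry = mtry)
  acc <- mean(stats::predict(rf, x) == labels)
  ranges <- vapply(x, range, numeric(2))
  rownames(ranges) <- c("min", "max")
  new("QSARModel", retainedFeatures = colnames(x), adRanges = ranges,
      forest = rf,
      forestSpec = list(nTrees = nTrees, mtry = mtry,
                        seed = as.integer(seed)),
      trainingLabels = stats::setNames(labels, rownames(x)),
      trainingAccuracy = acc)
}

#' Stratified k-fold cross-validation of the screening model
#'
#' Folds are stratified so each fold's class ratio is as close to the
#' global ratio as integer-feasible (with 3 negatives among 17 rows,
#' unstratified folds would often contain no negative). Metrics are
#' pooled over held-out predictions; fold assignment is deterministic
#' per seed.
#'
#' @param table Descriptor data.frame.
#' @param labels positive/negative labels aligned with the rows.
#' @param k Number of folds (default 10; must not exceed n).
#' @param seed Seed for fold assignment and per-fold forests.
#' @param nTrees Trees per fold forest.
#' @return list: \code{folds} (integer assignment per row),
#'   \code{accuracy}, \code{perClassRecall}.
#' @export
crossValidate <- function(table, labels, k = 10, seed = 20240115,
                          nTrees = 500) {
  n <- nrow(table)
  if (k > n) stop("k must not exceed the number of rows")
  if (!is.null(names(labels))) labels <- labels[rownames(table)]
  labels <- factor(labels, levels = c("negative", "positive"))
  if (any(table(labels) < 1L)) stop("each class needs >= 1 instance")
  set.seed(as.integer(seed))
  folds <- integer(n)
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  pred <- factor(rep(NA_character_, n), levels = levels(labels))
  for (f in seq_len(k)) {
    heldOut <- folds == f
    if (!any(heldOut)) next
    if (nlevels(droplevels(labels[!heldOut])) < 2L)
      stop("a training split lost a class; reduce k")
    set.seed(as.integer(seed) + f)
    rf <- randomForest::randomForest(
      x = table[!heldOut, , drop = FALSE], y = labels[!heldOut],
      ntree = nTrees)
    pred[heldOut] <- stats::predict(rf, table[heldOut, , drop = FALSE])
  }
  recall <- vapply(levels(labels), function(cl)
    mean(pred[labels == cl] == cl), numeric(1))
  list(folds = folds, accuracy = mean(pred == labels),
       perClassRecall = recall)
}

#' Range-based applicability-domain membership
#'
#' TRUE iff every retained feature value lies inside the training-set
#' min/max box, boundaries inclusive.
#'
#' @param model A \code{\linkS4class{QSARModel}}.
#' @param x Named numeric vector, single-row data.frame, or multi-row
#'   data.frame of feature values.
#' @return Logical (one per row of \code{x}); missing features are an
#'   error, never silently out-of-domain.
#' @export
inDomain <- function(model, x) {
  feats <- model@retainedFeatures
  if (is.numeric(x) && !is.null(names(x)))
    x <- as.data.frame(as.list(x))
  miss <- setdiff(feats, colnames(x))
  if (length(miss))
    stop("missing feature(s): ", paste(miss, collapse = ", "))
  rng <- model@adRanges
  apply(x[, feats, drop = FALSE], 1, function(v)
    all(v >= rng["min", ] & v <= rng["max", ]))
}

#' Screen a substance list for hair detectability
#'
#' Scores every in-domain substance by the fraction of trees voting
#' positive; \code{predicted} is \code{detectable} when the score is at
#' least 0.5, \code{undetectable} below, and \code{out_of_domain}
#' (score absent) outside the applicability domain — out-of-domain rows
#' are excluded from the detectable/undetectable counts. The
#' high-confidence flag requires a score strictly above 0.9.
#'
#' @param model A \code{\linkS4class{QSARModel}}.
#' @param table Descriptor data.frame with the model's retained
#'   features.
#' @param classes Optional named (or row-aligned) WADA class per
#'   substance, used for the per-class summary.
#' @return list: \code{results} (substance, in_ad, score, predicted,
#'   high_confidence) and \code{counts} (n_input, out_of_domain,
#'   detectable, undetectable, high_confidence, plus a per-class table
#'   when classes are given).
#' @export
screenSubstances <- function(model, table, classes = NULL) {
  feats <- model@retainedFeatures
  miss <- setdiff(feats, colnames(table))
  if (length(miss))
    stop("table lacks model feature(s): ", paste(miss, collapse = ", "))
  x <- table[, feats, drop = FALSE]
  inAd <- inDomain(model, x)
  votes <- stats::predict(model@forest, x, type = "vote",
                          norm.votes = TRUE)
  score <- as.numeric(votes[, "positive"])
  score[!inAd] <- NA_real_
  predicted <- ifelse(!inAd, "out_of_domain",
                      ifelse(score >= 0.5, "detectable", "undetectable"))
  hi <- !is.na(score) & score > 0.9 & predicted == "detectable"
  res <- data.frame(substance = rownames(table), in_ad = inAd,
                    score = score, predicted = predicted,
                    high_confidence = hi, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  counts <- list(n_input = nrow(res),
                 out_of_domain = sum(!inAd),
                 detectable = sum(predicted == "detectable"),
                 undetectable = sum(predicted == "undetectable"),
                 high_confidence = sum(hi))
  if (!is.null(classes)) {
    if (!is.null(names(classes))) classes <- classes[res$substance]
    counts$by_class <- table(class = classes, predicted = predicted)
  }
  list(results = res, counts = counts)
}
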