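# Confidence estimation for MCS-based imputations: reaction-complexity
# features, a boosted-tree classifier trained on resampled labeled outcomes,
# and threshold filtering.

.confidenceFeatureNames <- c("total_carbons", "total_bonds", "total_rings",
                             "fragment_count", "carbon_difference",
                             "num_boundary", "bond_change_merge",
                             "ring_change_merge")

.sideBonds <- function(mols)
  sum(vapply(mols, function(m) as.integer(igraph::ecount(m@graph)),
             integer(1)))

# cyclomatic number = independent rings
.sideRings <- function(mols)
  sum(vapply(mols, function(m) {
    as.integer(igraph::ecount(m@graph) - igraph::vcount(m@graph) +
                 igraph::components(m@graph)$no)
  }, integer(1)))

#' Extract confidence features from an MCS outcome
#'
#' Totals (carbons, bonds, rings) are computed over both sides of the
#' rebalanced reaction; `carbon_difference` is the absolute carbon imbalance
#' of the original input; `num_boundary` and `fragment_count` come from the
#' fragment set; the merge-delta features compare bond/ring totals of the
#' reaction before and after imputation. All features are computable without
#' manual input.
#'
#' @param outcome a solved [RebalanceOutcome-class] with method `"mcs"`.
#' @return named numeric vector of the eight model features.
#' @export
extractFeatures <- function(outcome) {
  if (outcome@method != "mcs")
    stop("confidence features are defined for MCS-based outcomes only")
  inp <- outcome@inputReaction
  out <- outcome@outputReaction
  allOut <- c(out@reactants, out@products)
  allIn <- c(inp@reactants, inp@products)
  bondsOut <- .sideBonds(allOut); bondsIn <- .sideBonds(allIn)
  ringsOut <- .sideRings(allOut); ringsIn <- .sideRings(allIn)
  cdiff <- abs(.sideCarbons(inp@reactants) - .sideCarbons(inp@products))
  d <- outcome@diagnostics
  stats::setNames(as.numeric(c(
    .sideCarbons(allOut), bondsOut, ringsOut,
    if (is.null(d$fragmentCount)) 0 else d$fragmentCount,
    cdiff,
    if (is.null(d$numBoundary)) 0 else d$numBoundary,
    abs(bondsOut - bondsIn), abs(ringsOut - ringsIn)
  )), .confidenceFeatureNames)
}

# ---- resampling -----------------------------------------------------------

.smote <- function(x, k = 5L, nNew) {
  n <- nrow(x)
  if (nNew <= 0L || n < 2L) return(x[0, , drop = FALSE])
  k <- min(k, n - 1L)
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k)]))
  idx <- sample.int(n, nNew, replace = TRUE)
  pick <- sample.int(k, nNew, replace = TRUE)
  gap <- stats::runif(nNew)
  base <- x[idx, , drop = FALSE]
  neigh <- x[nn[cbind(idx, pick)], , drop = FALSE]
  base + gap * (neigh - base)
}

# Remove majority-class members of Tomek links (mutual nearest neighbours of
# opposite class).
.tomekClean <- function(x, y) {
  n <- nrow(x)
  if (n < 2L) return(seq_len(n))
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  nn <- apply(d, 1, which.min)
  majority <- as.integer(names(which.max(table(y))))
  drop <- logical(n)
  for (i in seq_len(n)) {
    j <- nn[i]
    if (nn[j] == i && y[i] != y[j]) {
      if (y[i] == majority) drop[i] <- TRUE
      if (y[j] == majority) drop[j] <- TRUE
    }
  }
  which(!drop)
}

.rankAuc <- function(score, label) {
  pos <- score[label == 1]; neg <- score[label == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

.averagePrecision <- function(score, label) {
  o <- order(-score)
  lab <- label[o]
  cum <- cumsum(lab)
  prec <- cum / seq_along(lab)
  sum(prec[lab == 1]) / sum(lab)
}

#' Train the boosted-tree confidence model
#'
#' Stratified train/test split (80/20 by default), synthetic minority
#' oversampling plus Tomek-link cleaning applied to the training portion
#' only, then a gradient-boosted tree classifier. Held-out metrics
#' (F1-micro, AUC, average precision) are stored in the model metadata.
#' Fully reproducible under a fixed seed.
#'
#' @param features data.frame or matrix of feature rows (columns as in
#'   [extractFeatures()], or any numeric feature set).
#' @param labels 0/1 vector, 1 = correct imputation.
#' @param splitFraction training fraction of the stratified split.
#' @param seed integer seed controlling split, resampling and booster.
#' @param nrounds,maxDepth,eta booster hyperparameters (library defaults
#'   kept modest; all exposed).
#' @return a [ConfidenceModel-class].
#' @export
trainConfidenceModel <- function(features, labels, splitFraction = 0.8,
                                 seed = 42L, nrounds = 60L, maxDepth = 4L,
                                 eta = 0.3) {
  x <- as.matrix(features)
  y <- as.integer(labels)
  if (length(unique(y)) < 2L)
    stop("confidence training requires both outcome classes")
  set.seed(seed)
  idxTrain <- integer(0)
  for (cls in sort(unique(y))) {
    members <- which(y == cls)
    take <- max(1L, round(splitFraction * length(members)))
    idxTrain <- c(idxTrain, sort(sample(members, take)))
  }
  idxTrain <- sort(idxTrain)
  idxTest <- setdiff(seq_along(y), idxTrain)
  xtr <- x[idxTrain, , drop = FALSE]; ytr <- y[idxTrain]
  xte <- x[idxTest, , drop = FALSE]; yte <- y[idxTest]
  # SMOTE the minority class up to parity, then clean Tomek links
  tab <- table(ytr)
  minority <- as.integer(names(which.min(tab)))
  nNew <- max(tab) - min(tab)
  synth <- .smote(xtr[ytr == minority, , drop = FALSE], nNew = nNew)
  xres <- rbind(xtr, synth)
  yres <- c(ytr, rep(minority, nrow(synth)))
  keep <- .tomekClean(xres, yres)
  xres <- xres[keep, , drop = FALSE]; yres <- yres[keep]
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = maxDepth,
                  eta = eta, nthread = 1, seed = seed),
    data = xgboost::xgb.DMatrix(xres, label = yres),
    nrounds = nrounds, verbose = 0)
  scoreTest <- if (length(idxTest))
    stats::predict(booster, xgboost::xgb.DMatrix(xte)) else numeric(0)
  meta <- list(
    seed = seed, splitFraction = splitFraction,
    nTrain = length(idxTrain), nTrainResampled = length(yres),
    nTest = length(idxTest), testIndices = idxTest,
    f1Micro = if (length(idxTest)) mean((scoreTest >= 0.5) == (yte == 1))
              else NA_real_,
    auc = .rankAuc(scoreTest, yte),
    averagePrecision = if (any(yte == 1)) .averagePrecision(scoreTest, yte)
                       else NA_real_)
  methods::new("ConfidenceModel", booster = booster,
               featureNames = colnames(x), metadata = meta)
}

#' Score features with a trained confidence model
#'
#' @param model a [ConfidenceModel-class].
#' @param features named numeric vector, matrix or data.frame of feature
#'   rows.
#' @return probability (vector) in `[0, 1]`.
#' @export
scoreConfidence <- function(model, features) {
  if (is.null(dim(features))) features <- t(as.matrix(features))
  x <- as.matrix(features)[, model@featureNames, drop = FALSE]
  stats::predict(model@booster, xgboost::xgb.DMatrix(x))
}

#' Filter outcomes by a confidence threshold
#'
#' Rule-based and already-balanced outcomes always pass: the confidence
#' model applies to the MCS branch only. MCS outcomes pass when their score
#' is at least `tau`; at `tau = 0` everything passes.
#'
#' @param outcomes list of [RebalanceOutcome-class] objects.
#' @param tau threshold in `[0, 1]`.
#' @return the filtered list.
#' @export
filterByThreshold <- function(outcomes, tau) {
  if (tau <= 0) return(outcomes)
  keep <- vapply(outcomes, function(o) {
    o@method != "mcs" || (!is.na(o@confidence) && o@confidence >= tau)
  }, logical(1))
  outcomes[keep]
}

setMethod("show", "ConfidenceModel", function(object) {
  m <- object@metadata
  cat(sprintf(paste0("ConfidenceModel (gradient-boosted trees)\n",
                     "  train %d (resampled to %d), test %d\n",
                     "  held-out: F1-micro %.3f, AUC %.3f, AP %.3f\n"),
              m$nTrain, m$nTrainResampled, m$nTest,
              m$f1Micro, m$auc, m$averagePrecision))
})
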