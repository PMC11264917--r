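# Planted-rule simulation for exercising the confidence model without
# manually labeled outcomes.

#' Simulate labeled confidence-feature data under a planted rule
#'
#' Draws plausible reaction-complexity feature vectors and labels each
#' instance by the planted rule `num_boundary <= boundaryCutoff`, then flips
#' a fraction of labels as noise. Used to verify that the confidence model
#' recovers a boundary-count signal from noisy labels; the simulation does
#' not claim to reproduce the feature distribution of any real dataset.
#'
#' @param n number of instances.
#' @param seed integer seed.
#' @param noise label-flip probability.
#' @param boundaryCutoff planted decision boundary on `num_boundary`.
#' @return list with `features` (data.frame, columns as in
#'   [extractFeatures()]), `labels` (the noisy 0/1 training labels) and
#'   `plantedLabels` (the uncorrupted rule labels, the recovery target).
#' @export
simulateConfidenceData <- function(n = 1000L, seed = 42L, noise = 0.1,
                                   boundaryCutoff = 2L) {
  set.seed(seed)
  carbons <- sample(4:40, n, replace = TRUE)
  rings <- sample(0:4, n, replace = TRUE)
  bonds <- carbons + rings + sample(0:10, n, replace = TRUE)
  features <- data.frame(
    total_carbons = carbons,
    total_bonds = bonds,
    total_rings = rings,
    fragment_count = sample(1:6, n, replace = TRUE),
    carbon_difference = sample(0:8, n, replace = TRUE),
    num_boundary = sample(0:6, n, replace = TRUE),
    bond_change_merge = sample(0:5, n, replace = TRUE),
    ring_change_merge = sample(0:2, n, replace = TRUE)
  )
  planted <- as.integer(features$num_boundary <= boundaryCutoff)
  labels <- planted
  flip <- stats::runif(n) < noise
  labels[flip] <- 1L - labels[flip]
  list(features = features, labels = labels, plantedLabels = planted)
}
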