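#' Form bags from per-patient instance stacks
#'
#' In multi-instance learning each patient is one bag: the ordered stack of
#' cropped axial instances plus the patient-level label. A cancer patient is
#' a positive bag (label 1), a control a negative bag (label 0); only the bag
#' label is observed.
#'
#' @param stacks list of `instance_stack` objects ([build_instances()]).
#' @param labels named vector (names = patient ids) or vector aligned with
#'   `stacks`, values in \{0, 1\}.
#' @return list of `mil_bag` objects: `patient_id`, `instances`
#'   (`instance_stack`), `label`.
#' @export
make_bags <- function(stacks, labels) {
  stopifnot(is.list(stacks))
  out <- vector("list", length(stacks))
  for (i in seq_along(stacks)) {
    st <- stacks[[i]]
    if (!inherits(st, "instance_stack")) stop("stacks must be instance_stack objects", call. = FALSE)
    lab <- if (!is.null(names(labels))) {
      unname(labels[st$patient_id])
    } else {
      labels[i]
    }
    if (is.null(lab) || length(lab) != 1L || is.na(lab)) {
      stop(sprintf("missing label for patient %s", st$patient_id), call. = FALSE)
    }
    if (!lab %in% c(0, 1)) stop(sprintf("label for %s must be 0 or 1", st$patient_id), call. = FALSE)
    if (dim(st$instances)[3] < 1L) stop(sprintf("empty instance stack for %s", st$patient_id), call. = FALSE)
    out[[i]] <- structure(list(patient_id = st$patient_id, instances = st,
                               label = as.integer(lab)),
                          class = "mil_bag")
  }
  out
}

#' Pseudo-label the instances of a positive bag
#'
#' Implements the weak-supervision rule: the bag's instances are partitioned
#' into two clusters in feature space; the cluster whose centroid lies
#' farther (Euclidean) from the negative-instance centroid — the mean feature
#' over all instances of the training negative bags — is taken to be the
#' tumor-bearing group and labeled 1, the other 0. Under weak supervision
#' this is the only side information available for orienting the two
#' clusters. A tie in the two distances is broken deterministically (the
#' lower-indexed cluster gets label 1) with a warning.
#'
#' @param features numeric matrix of the bag's instance features (rows).
#' @param assignments integer vector in `1..2` from [kmeans_partition()].
#' @param negative_centroid numeric vector, mean feature of negative-bag
#'   instances.
#' @return integer vector of per-instance pseudo-labels in \{0, 1\}; at least
#'   one instance is labeled 1.
#' @export
assign_pseudo_labels <- function(features, assignments, negative_centroid) {
  x <- as.matrix(features)
  if (length(assignments) != nrow(x)) stop("assignments/features length mismatch", call. = FALSE)
  ks <- sort(unique(assignments))
  if (!all(ks %in% 1:2)) stop("expected 2-cluster assignments in 1..2", call. = FALSE)
  if (length(negative_centroid) != ncol(x)) {
    stop("negative_centroid length does not match feature width", call. = FALSE)
  }
  if (length(ks) == 1L) {
    # degenerate single-cluster bag: everything is the far group
    return(rep(1L, nrow(x)))
  }
  cents <- rbind(colMeans(x[assignments == 1L, , drop = FALSE]),
                 colMeans(x[assignments == 2L, , drop = FALSE]))
  d <- sqrt(rowSums(sweep(cents, 2, negative_centroid)^2))
  pos_cluster <- if (d[1] == d[2]) {
    warning("centroid distance tie; labeling cluster 1 positive", call. = FALSE)
    1L
  } else {
    which.max(d)
  }
  as.integer(assignments == pos_cluster)
}

#' Abnormality score of instances against the negative-bag reference
#'
#' Distance of each instance to its nearest negative-bag instance in
#' (standardized) feature space, expressed in units of the negative cohort's
#' own cross-patient nearest-neighbor distance and saturated at `cap`. A
#' healthy slice, which has close analogues among tumor-free patients,
#' scores around 1; a lesion-bearing slice scores high. This is the signal
#' the default pseudo-labeling clusters on, and the pipeline also feeds it to
#' the instance classifier as an extra location-agnostic input feature.
#'
#' @param features numeric matrix of instance features (rows), standardized
#'   with [standardize_features()].
#' @param negative_features list of per-bag negative feature matrices
#'   (preferred) or one stacked matrix, same standardization.
#' @param cap saturation level (default 5).
#' @return numeric vector of scores in `[0, cap]`, one per row of
#'   `features`.
#' @export
abnormality_score <- function(features, negative_features, cap = 5) {
  neg_list <- if (is.list(negative_features)) {
    lapply(negative_features, as.matrix)
  } else {
    list(as.matrix(negative_features))
  }
  negf <- do.call(rbind, neg_list)
  f <- as.matrix(features)
  if (ncol(f) != ncol(negf)) stop("feature width mismatch", call. = FALSE)
  d0 <- {
    D <- row_dist2(negf, negf)
    bag_of <- rep(seq_along(neg_list), vapply(neg_list, nrow, integer(1)))
    if (length(neg_list) > 1L) {
      for (b in unique(bag_of)) D[bag_of == b, bag_of == b] <- Inf
    } else {
      diag(D) <- Inf
    }
    med <- stats::median(sqrt(pmax(apply(D, 1, min), 0)))
    if (!is.finite(med) || med <= 0) 1 else med
  }
  nnd <- sqrt(pmax(apply(row_dist2(f, negf), 1, min), 0))
  pmin(nnd / d0, cap)
}

#' Pseudo-label every positive training bag of a cohort
#'
#' Ties [kmeans_partition()] and cluster orientation together. Negative bags
#' never enter clustering: their instances are labeled 0 directly. Positive
#' bags with a single instance skip clustering and get label 1.
#'
#' Two clustering/orientation methods are available:
#' * `"abnormality"` (default): each instance is scored by its Euclidean
#'   distance to the nearest negative-bag instance (an "abnormality" score —
#'   healthy slices have close analogues among the tumor-free negative bags,
#'   lesion-bearing slices do not). The score is expressed in units of the
#'   negative cohort's own cross-patient nearest-neighbor distance (so a
#'   healthy slice scores around 1) and saturated at `cap` (so the split
#'   K-means finds falls between the healthy range and the lesion range
#'   rather than inside the heavy lesion tail). K-means with k = 2 then
#'   partitions the scores, and the cluster with the larger median score is
#'   labeled 1. Intended to be used on features standardized with
#'   [standardize_features()].
#' * `"centroid"`: K-means on the feature vectors themselves, orientation by
#'   [assign_pseudo_labels()] (the cluster centroid farther from the
#'   negative-instance centroid is positive). Simpler, but can latch onto
#'   organ-geometry variation instead of lesion contrast.
#'
#' Clustering is per-bag by default; `pooled = TRUE` clusters all
#' positive-bag instances jointly and then guarantees at least one positive
#' instance per positive bag (the bag's most abnormal instance is promoted
#' if its cluster came up empty).
#'
#' @param bags list of `mil_bag`.
#' @param features list of feature matrices aligned with `bags` (standardized
#'   features recommended; see [feature_stats()]).
#' @param negative_features negative-bag instance features under the same
#'   standardization: either a list of per-bag matrices (preferred — lets the
#'   normal cross-patient distance scale exclude within-patient matches) or
#'   one stacked matrix. Used for the abnormality score and the negative
#'   centroid.
#' @param seed integer seed for the clustering.
#' @param method `"abnormality"` (default) or `"centroid"`.
#' @param pooled cluster positive instances across bags instead of per bag.
#' @param cap saturation level of the normalized abnormality score (default
#'   5: five times the normal cross-patient nearest-neighbor distance).
#' @return list of integer pseudo-label vectors aligned with `bags`.
#' @export
pseudo_label_bags <- function(bags, features, negative_features, seed = 1,
                              method = c("abnormality", "centroid"),
                              pooled = FALSE, cap = 5) {
  method <- match.arg(method)
  stopifnot(length(bags) == length(features))
  neg_list <- if (is.list(negative_features)) {
    lapply(negative_features, as.matrix)
  } else {
    list(as.matrix(negative_features))
  }
  negf <- do.call(rbind, neg_list)
  negative_centroid <- colMeans(negf)
  labels <- vector("list", length(bags))
  pos <- which(vapply(bags, function(b) b$label == 1L, logical(1)))
  for (i in seq_along(bags)) {
    if (!i %in% pos) labels[[i]] <- rep(0L, nrow(features[[i]]))
  }
  if (length(pos) == 0L) return(labels)

  # clustered on the log scale: compresses the heavy lesion tail so the
  # K-means split lands in the healthy/lesion gap in both low- and
  # high-contrast regimes
  ab_score <- function(f) log1p(abnormality_score(f, neg_list, cap = cap))
  # gate: a pseudo-positive must also look abnormal relative to what healthy
  # slices themselves score (leave-own-patient-out), else clustering noise in
  # ambiguous bags floods the classifier with mislabeled healthy slices
  ab_gate <- {
    neg_scores <- unlist(lapply(seq_along(neg_list), function(b) {
      if (length(neg_list) > 1L) {
        abnormality_score(neg_list[[b]], neg_list[-b], cap = cap)
      } else {
        abnormality_score(neg_list[[b]], neg_list[[b]], cap = cap)
      }
    }))
    log1p(stats::quantile(neg_scores, 0.975, names = FALSE))
  }
  gate_labels <- function(li, s) {
    li[s <= ab_gate] <- 0L
    if (!any(li == 1L)) li[which.max(s)] <- 1L
    li
  }

  label_one <- function(f, seed_i) {
    if (nrow(f) == 1L) return(1L)
    if (method == "centroid") {
      km <- kmeans_partition(f, k = 2, seed = seed_i)
      return(assign_pseudo_labels(f, km$cluster, negative_centroid))
    }
    score <- ab_score(f)
    km <- kmeans_partition(matrix(score, ncol = 1), k = 2, seed = seed_i)
    med <- c(stats::median(score[km$cluster == 1L]),
             stats::median(score[km$cluster == 2L]))
    pos_cluster <- if (med[1] >= med[2]) 1L else 2L
    gate_labels(as.integer(km$cluster == pos_cluster), score)
  }

  if (!pooled) {
    for (i in pos) labels[[i]] <- label_one(features[[i]], seed + i)
  } else {
    all_f <- do.call(rbind, features[pos])
    idx <- rep(pos, vapply(features[pos], nrow, integer(1)))
    if (method == "centroid") {
      km <- kmeans_partition(all_f, k = 2, seed = seed)
      pl <- assign_pseudo_labels(all_f, km$cluster, negative_centroid)
    } else {
      score <- ab_score(all_f)
      km <- kmeans_partition(matrix(score, ncol = 1), k = 2, seed = seed)
      med <- c(stats::median(score[km$cluster == 1L]),
               stats::median(score[km$cluster == 2L]))
      pos_cluster <- if (med[1] >= med[2]) 1L else 2L
      pl <- as.integer(km$cluster == pos_cluster)
      pl[ab_score(all_f) <= ab_gate & pl == 1L] <- 0L
    }
    for (i in pos) {
      li <- pl[idx == i]
      if (!any(li == 1L)) {
        # guarantee >= 1 positive instance per positive bag
        li[which.max(ab_score(features[[i]]))] <- 1L
      }
      labels[[i]] <- li
    }
  }
  labels
}

#' Standardize instance features by the negative-instance distribution
#'
#' Weak supervision gives one reliable reference population: the instances of
#' negative bags, all of which are tumor-free. `feature_stats()` computes
#' their per-dimension mean and standard deviation; `standardize_features()`
#' applies the affine transform `(f - mean) / sd`. In the standardized space
#' the Euclidean distance from the origin is a Mahalanobis-style (diagonal)
#' distance from the normal-tissue distribution, so directions along which
#' healthy slices naturally vary (organ cross-section area, position in the
#' organ) are down-weighted and lesion-driven contrast dominates. The
#' pipeline clusters and orients pseudo-labels in this space; without it,
#' K-means tends to split bags by organ geometry instead of tumor presence.
#'
#' @param features numeric matrix (rows = instances), typically the stacked
#'   negative-bag features for `feature_stats()`.
#' @param stats list with `mean` and `sd` vectors from `feature_stats()`.
#' @param sd_floor lower bound applied to per-dimension sd (guards noiseless
#'   degenerate dimensions).
#' @return `feature_stats()`: list with `mean`, `sd`; `standardize_features()`:
#'   matrix of the same shape as `features`.
#' @export
feature_stats <- function(features, sd_floor = 1e-8) {
  x <- as.matrix(features)
  if (nrow(x) < 2L) stop("need at least 2 instances for feature statistics", call. = FALSE)
  s <- apply(x, 2, stats::sd)
  floor_val <- max(sd_floor, 1e-6 * stats::median(s[s > 0], na.rm = TRUE))
  if (!is.finite(floor_val)) floor_val <- sd_floor
  list(mean = colMeans(x), sd = pmax(s, floor_val))
}

#' @rdname feature_stats
#' @export
standardize_features <- function(features, stats) {
  x <- as.matrix(features)
  if (ncol(x) != length(stats$mean)) stop("feature width mismatch", call. = FALSE)
  sweep(sweep(x, 2, stats$mean), 2, stats$sd, "/")
}

#' @rdname pseudo_label_bags
#' @export
negative_instance_centroid <- function(bags, features) {
  neg <- which(vapply(bags, function(b) b$label == 0L, logical(1)))
  if (length(neg) == 0L) stop("no negative bags in the training set", call. = FALSE)
  colMeans(do.call(rbind, features[neg]))
}

#' Instance classifier head configuration
#'
#' The classification head appended to the feature extractor: average pooling
#' of `pool_size` (realized inside the extractor), a dense layer of
#' `dense_units` neurons, dropout between it and the output, and a dense
#' 2-unit softmax output.
#'
#' @param pool_size length-2 average-pool block preceding the dense layers
#'   (default 4x4; forwarded to [extractor_cnn()] by the pipeline).
#' @param dense_units hidden width (default 256).
#' @param dropout_rate dropout probability in `[0, 1)` (default 0.3).
#' @return an object of class `head_config`.
#' @export
head_config <- function(pool_size = c(4, 4), dense_units = 256, dropout_rate = 0.3) {
  pool_size <- as.integer(rep(pool_size, length.out = 2))
  if (any(pool_size < 1L)) stop_config("pool_size", "must be >= 1")
  if (!is.numeric(dense_units) || dense_units < 1) stop_config("dense_units", "must be >= 1")
  if (!is.numeric(dropout_rate) || dropout_rate < 0 || dropout_rate >= 1) {
    stop_config("dropout_rate", "must be in [0, 1)")
  }
  structure(list(pool_size = pool_size, dense_units = as.integer(dense_units),
                 dropout_rate = dropout_rate, output_units = 2L),
            class = "head_config")
}

#' Train the instance classifier
#'
#' Fits the softmax head ([head_config()]) on pseudo-labeled instance
#' features with full-batch Adam and inverted dropout. Both classes must be
#' present. Training is seeded and reproducible.
#'
#' @param features numeric matrix, one row per training instance.
#' @param labels integer pseudo-labels in \{0, 1\}, one per row.
#' @param head a [head_config()].
#' @param epochs,lr optimizer settings.
#' @param seed integer seed.
#' @return object of class `instance_classifier`.
#' @export
train_instance_classifier <- function(features, labels, head = head_config(),
                                      epochs = 300, lr = 5e-3, seed = 1) {
  x <- as.matrix(features)
  labels <- as.integer(labels)
  if (length(labels) != nrow(x)) stop("features/labels length mismatch", call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("training set contains a single pseudo-label class", call. = FALSE)
  }
  Y <- cbind(1 - labels, labels)  # one-hot, column 2 = class 1
  net <- mlp_train(x, Y, hidden = head$dense_units, output = "softmax",
                   dropout = head$dropout_rate, epochs = epochs, lr = lr,
                   seed = seed)
  structure(list(net = net, head = head), class = "instance_classifier")
}

#' Predict per-instance cancer probabilities
#'
#' Returns the softmax component for class 1 (tumor), one probability per
#' instance, applied instance-wise (hence invariant to instance order).
#'
#' @param classifier an `instance_classifier`.
#' @param features feature matrix (rows = instances), or an `mil_bag` plus an
#'   `extractor` to featurize on the fly.
#' @param extractor optional `milct_extractor` when `features` is a bag.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_instance_probs <- function(classifier, features, extractor = NULL) {
  stopifnot(inherits(classifier, "instance_classifier"))
  if (inherits(features, "mil_bag")) {
    if (is.null(extractor)) stop("supply `extractor` to featurize a bag", call. = FALSE)
    features <- extract_features(features$instances, extractor)
  }
  P <- mlp_predict(classifier$net, features)
  as.numeric(P[, 2])
}
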