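#' Configuration for an end-to-end phantom run
#'
#' Bundles every stage's parameters: phantom cohort, preprocessing targets,
#' cropping, classifier head, aggregator, decision threshold, patient-level
#' split fractions, and one global seed from which all per-stage seeds are
#' derived.
#'
#' @param phantom a [phantom_config()].
#' @param target_spacing homogeneous voxel spacing after resampling (mm);
#'   the default is the phantom cohort's native (median) spacing, mirroring
#'   the common practice of resampling a dataset to its median spacing.
#' @param margin_mm in-plane crop margin around the organ box (mm).
#' @param instance_size length-2 instance shape after cropping.
#' @param head a [head_config()].
#' @param aggregator an [aggregator_config()].
#' @param threshold decision threshold tau.
#' @param split named fractions `train`/`validation`/`test` summing to 1.
#' @param seed global integer seed.
#' @param extractor `"cnn"` (default, seeded random-feature CNN) or `"pool"`.
#' @param pseudo_label_method `"abnormality"` (default) or `"centroid"`; see
#'   [pseudo_label_bags()].
#' @param pooled_clustering cluster positive instances across bags instead of
#'   per bag.
#' @param augment augment training instances with the 8 dihedral transforms
#'   before classifier training (default `TRUE`); see [dihedral_transform()].
#' @param classifier_epochs,classifier_lr,aggregator_epochs,aggregator_lr
#'   optimizer settings for the two trainable stages.
#' @return an object of class `run_config`.
#' @export
run_config <- function(phantom = phantom_config(),
                       target_spacing = c(1, 1, 2.5),
                       margin_mm = 5,
                       instance_size = c(64, 64),
                       head = head_config(),
                       aggregator = aggregator_config(),
                       threshold = 0.5,
                       split = c(train = 0.5, validation = 0.25, test = 0.25),
                       seed = 1,
                       extractor = c("cnn", "pool"),
                       pseudo_label_method = c("abnormality", "centroid"),
                       pooled_clustering = FALSE,
                       augment = TRUE,
                       classifier_epochs = 300, classifier_lr = 5e-3,
                       aggregator_epochs = 400, aggregator_lr = 1e-2) {
  extractor <- match.arg(extractor)
  pseudo_label_method <- match.arg(pseudo_label_method)
  if (!inherits(phantom, "phantom_config")) phantom <- do.call(phantom_config, phantom)
  if (abs(sum(split) - 1) > 1e-8) stop_config("split", "fractions must sum to 1")
  if (length(split) != 3L) stop_config("split", "needs train/validation/test fractions")
  if (is.null(names(split))) names(split) <- c("train", "validation", "test")
  check_scalar_number(seed, "seed")
  structure(list(phantom = phantom, target_spacing = as.numeric(target_spacing),
                 margin_mm = margin_mm, instance_size = as.integer(instance_size),
                 head = head, aggregator = aggregator, threshold = threshold,
                 split = split, seed = as.integer(seed), extractor = extractor,
                 pseudo_label_method = pseudo_label_method,
                 pooled_clustering = isTRUE(pooled_clustering),
                 augment = isTRUE(augment),
                 classifier_epochs = classifier_epochs, classifier_lr = classifier_lr,
                 aggregator_epochs = aggregator_epochs, aggregator_lr = aggregator_lr),
            class = "run_config")
}

# Stratified, seeded patient-level split. Every patient lands in exactly one
# split; train and test are guaranteed at least one patient per label class
# (validation may be empty for tiny cohorts).
split_patients <- function(patient_ids, labels, fractions, seed) {
  stopifnot(length(patient_ids) == length(labels))
  if (length(unique(labels)) < 2L) {
    stop("split requires both classes (cases and controls) in the cohort", call. = FALSE)
  }
  assignment <- stats::setNames(rep(NA_character_, length(patient_ids)), patient_ids)
  with_seed(seed, {
    for (lab in c(0, 1)) {
      ids <- patient_ids[labels == lab]
      ids <- sample(ids)
      k <- length(ids)
      n_tr <- round(fractions[["train"]] * k)
      n_va <- round(fractions[["validation"]] * k)
      n_te <- k - n_tr - n_va
      if (n_te < 1L) { if (n_va > 0) { n_va <- n_va - 1 } else { n_tr <- n_tr - 1 }; n_te <- n_te + 1 }
      if (n_tr < 1L) { if (n_va > 0) { n_va <- n_va - 1 } else { n_te <- n_te - 1 }; n_tr <- n_tr + 1 }
      assignment[ids] <- rep(c("train", "validation", "test"), c(n_tr, n_va, n_te))
    }
  })
  assignment
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full two-stage pipeline on a phantom cohort
#'
#' Executes simulate -> resample/normalize -> crop -> pseudo-label -> train
#' instance classifier -> aggregate -> evaluate, with a patient-level
#' stratified split (no patient's instances straddle splits), normalization
#' statistics frozen on the training organ voxels, and aggregator model
#' selection frozen on the validation split. Re-running with an identical
#' config reproduces the report exactly.
#'
#' @param config a [run_config()].
#' @param verbose log per-stage counts with `message()`.
#' @return object of class `mil_report`; see [report_json()] for
#'   serialization.
#' @export
run_end_to_end <- function(config = run_config(), verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  cohort <- stage("simulate", generate_cohort(config$phantom))
  ids <- vapply(cohort, `[[`, character(1), "patient_id")
  labels <- stats::setNames(vapply(cohort, `[[`, integer(1), "label"), ids)
  say("simulate: %d patients (%d cases / %d controls)",
      length(cohort), sum(labels == 1), sum(labels == 0))

  resampled <- stage("preprocess", lapply(cohort, function(v) {
    img <- resample_image(v$image, v$spacing, config$target_spacing)
    org <- resample_mask(v$organ_mask, v$spacing, config$target_spacing)
    tum <- resample_mask(v$tumor_mask, v$spacing, config$target_spacing)
    list(image = img$data, organ = org$data, tumor = tum$data,
         spacing = img$spacing, patient_id = v$patient_id, label = v$label)
  }))

  split <- stage("split", split_patients(ids, labels, config$split, config$seed + 11L))
  say("split: %s", paste(names(table(split)), table(split), sep = "=", collapse = " "))

  norm <- stage("normalize", {
    train_vox <- unlist(lapply(resampled[split[ids] == "train"],
                               function(v) v$image[v$organ > 0]))
    normalization_stats(train_vox)
  })

  stacks <- stage("crop", lapply(resampled, function(v) {
    img <- normalize_global(v$image, norm)
    st <- build_instances(img, v$organ, config$margin_mm, config$instance_size,
                          v$spacing, v$patient_id)
    # ground-truth slice indicators (phantom only; used for diagnostics/tests)
    st$tumor_slices <- as.integer(st$slice_indices %in% slices_with_organ(v$tumor))
    st
  }))
  bags <- stage("bags", make_bags(stacks, labels))
  n_inst <- vapply(bags, function(b) dim(b$instances$instances)[3], integer(1))
  say("crop: %d bags, %d instances (median %g per bag)",
      length(bags), sum(n_inst), stats::median(n_inst))

  ext <- if (config$extractor == "cnn") {
    extractor_cnn(seed = config$seed + 101L, pool_size = config$head$pool_size)
  } else {
    extractor_pool()
  }
  feat_stage <- stage("features", {
    raw <- lapply(bags, function(b) extract_features(b$instances, ext))
    # standardize by the training negative-instance distribution so that
    # clustering and cluster orientation respond to lesion contrast rather
    # than organ geometry (see feature_stats())
    tr_neg <- which(split[ids] == "train" & labels == 0)
    fs <- feature_stats(do.call(rbind, raw[tr_neg]))
    list(features = lapply(raw, standardize_features, stats = fs), stats = fs)
  })
  features <- feat_stage$features
  feat_stats <- feat_stage$stats

  is_train <- split[ids] == "train"
  train_idx <- which(is_train)
  pseudo <- stage("pseudo_label", {
    neg_train <- features[split[ids] == "train" & labels == 0]
    pl <- vector("list", length(bags))
    pl[train_idx] <- pseudo_label_bags(bags[train_idx], features[train_idx],
                                       neg_train, seed = config$seed + 211L,
                                       method = config$pseudo_label_method,
                                       pooled = config$pooled_clustering)
    pl
  })

  # classifier input = standardized features + the location-agnostic
  # abnormality score as an extra column (computable at test time from the
  # frozen training negatives)
  # two views of the score: the capped value separates healthy from lesion
  # robustly; the uncapped log view keeps gradation among clear lesions so
  # the head is not left with a degenerate single training value
  neg_train_list <- features[split[ids] == "train" & labels == 0]
  with_ab <- function(f) {
    ab <- abnormality_score(f, neg_train_list, cap = Inf)
    cbind(f, pmin(ab, 5), log1p(ab))
  }

  clf <- stage("train_classifier", {
    if (config$augment) {
      # dihedral-8 augmentation of the training instances: teaches the
      # location-coded features that lesions occur anywhere in the crop
      Xtr <- do.call(rbind, unlist(lapply(train_idx, function(i) {
        arr <- bags[[i]]$instances$instances
        lapply(1:8, function(k) {
          aug <- array(0, dim(arr))
          for (j in seq_len(dim(arr)[3])) aug[, , j] <- dihedral_transform(arr[, , j], k)
          with_ab(standardize_features(extract_features(aug, ext), feat_stats))
        })
      }), recursive = FALSE))
      ytr <- unlist(rep(pseudo[train_idx], each = 8))
    } else {
      Xtr <- do.call(rbind, lapply(features[train_idx], with_ab))
      ytr <- unlist(pseudo[train_idx])
    }
    train_instance_classifier(Xtr, ytr, config$head,
                              epochs = config$classifier_epochs,
                              lr = config$classifier_lr,
                              seed = config$seed + 307L)
  })

  probs <- stage("predict_instances",
                 lapply(features, function(f) predict_instance_probs(clf, with_ab(f))))
  summaries <- do.call(rbind, lapply(probs, bag_summary, config = config$aggregator))

  is_val <- split[ids] == "validation"
  agg <- stage("train_aggregator", {
    validation <- if (any(is_val)) {
      list(summaries = summaries[is_val, , drop = FALSE], labels = labels[is_val])
    }
    train_aggregator(summaries[is_train, , drop = FALSE], labels[is_train],
                     config$aggregator, seed = config$seed + 401L,
                     epochs = config$aggregator_epochs, lr = config$aggregator_lr,
                     validation = validation)
  })

  is_test <- split[ids] == "test"
  test_pred <- stage("predict_patients", {
    idx <- which(is_test)
    data.frame(patient_id = ids[idx],
               label = as.integer(labels[idx]),
               probability = vapply(idx, function(i) {
                 predict_patient(agg, summaries[i, ], config$threshold,
                                 ids[i], summarized = TRUE)$probability
               }, numeric(1)),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  test_pred$decision <- as.integer(test_pred$probability >= config$threshold)

  metrics <- stage("evaluate", {
    cm <- confusion_at_threshold(test_pred$probability, test_pred$label, config$threshold)
    sm <- summary_metrics(cm)
    auc <- roc_auc(test_pred$probability, test_pred$label)
    de <- if (sum(test_pred$label == 1) >= 2 && sum(test_pred$label == 0) >= 2) {
      delong_ci(test_pred$probability, test_pred$label)
    }
    c(list(confusion = cm[c("TP", "FP", "TN", "FN")]), sm, list(auc = auc),
      if (!is.null(de)) list(auc_variance = de$variance,
                             auc_ci = c(de$ci_low, de$ci_high)))
  })
  say("evaluate: acc %.3f sens %.3f spec %.3f auc %.3f",
      metrics$accuracy, metrics$sensitivity, metrics$specificity, metrics$auc)

  structure(list(
    seed = config$seed,
    counts = list(patients = length(bags),
                  cases = as.integer(sum(labels == 1)),
                  controls = as.integer(sum(labels == 0)),
                  instances = as.integer(sum(n_inst)),
                  split = as.list(table(split))),
    normalization = norm[c("mean", "sd")],
    metrics = metrics,
    test_predictions = test_pred,
    pseudo_labels = stats::setNames(pseudo, ids),
    tumor_slices = stats::setNames(lapply(stacks, `[[`, "tumor_slices"), ids),
    split = as.list(split)
  ), class = "mil_report")
}

#' Serialize / print a pipeline report
#'
#' `report_json()` renders the deterministic part of an [run_end_to_end()]
#' report (counts, normalization statistics, metrics, per-patient test
#' predictions) as a JSON string; identical configs yield byte-identical
#' strings.
#'
#' @param report an `mil_report`.
#' @param path optional file to write the JSON to.
#' @return the JSON string, invisibly when `path` is given.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "mil_report"))
  x <- list(seed = report$seed, counts = report$counts,
            normalization = report$normalization, metrics = report$metrics,
            test_predictions = report$test_predictions)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @export
print.mil_report <- function(x, ...) {
  cat(sprintf("<mil_report> %d patients (%d cases / %d controls), %d instances\n",
              x$counts$patients, x$counts$cases, x$counts$controls, x$counts$instances))
  cat(sprintf("  test: n=%d  accuracy %.3f  sensitivity %.3f  specificity %.3f  AUC %.3f\n",
              nrow(x$test_predictions), x$metrics$accuracy, x$metrics$sensitivity,
              x$metrics$specificity, x$metrics$auc))
  if (!is.null(x$metrics$auc_ci)) {
    cat(sprintf("  DeLong 95%% CI: %.3f-%.3f\n", x$metrics$auc_ci[1], x$metrics$auc_ci[2]))
  }
  invisible(x)
}
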