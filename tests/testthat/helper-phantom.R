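# Small, fast phantom worlds shared across tests. Native spacing is kept as
# the resampling target so the MIL fixtures exercise the pipeline's default
# median-spacing convention.

ph_small <- function(n_cases = 4, n_controls = 4, noise_sd = 0,
                     tumor_intensity = -100, seed = 7, ...) {
  phantom_config(grid_shape = c(32, 32, 16), spacing = c(1.5, 1.5, 2.5),
                 organ_radius = 12, tumor_radius = 4.5,
                 noise_sd = noise_sd, tumor_intensity = tumor_intensity,
                 n_cases = n_cases, n_controls = n_controls, seed = seed, ...)
}

# Run the pre-MIL stages (resample to native spacing, normalize, crop,
# featurize, standardize) and attach ground-truth tumor-slice indicators.
mil_fixture <- function(cfg, extractor_seed = 101, instance_size = c(48, 48)) {
  cohort <- generate_cohort(cfg)
  target <- cfg$spacing
  prep <- lapply(cohort, function(v) {
    list(image = resample_image(v$image, v$spacing, target)$data,
         organ = resample_mask(v$organ_mask, v$spacing, target)$data,
         tumor = resample_mask(v$tumor_mask, v$spacing, target)$data,
         label = v$label, patient_id = v$patient_id)
  })
  labs <- vapply(prep, `[[`, integer(1), "label")
  norm <- normalization_stats(unlist(lapply(prep, function(p) p$image[p$organ > 0])))
  stacks <- lapply(prep, function(p) {
    st <- build_instances(normalize_global(p$image, norm), p$organ,
                          margin_mm = 5, target_size = instance_size,
                          spacing = target, patient_id = p$patient_id)
    st$gt <- as.integer(st$slice_indices %in% slices_with_organ(p$tumor))
    st
  })
  ext <- extractor_cnn(seed = extractor_seed)
  feats <- lapply(stacks, function(s) extract_features(s, ext))
  fs <- feature_stats(do.call(rbind, feats[labs == 0]))
  featz <- lapply(feats, standardize_features, stats = fs)
  list(cohort = cohort, stacks = stacks, labels = labs, features = featz,
       negative_features = featz[labs == 0],
       bags = make_bags(stacks, labs), extractor = ext)
}
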