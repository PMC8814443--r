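# Heavier shared fixtures for the property and acceptance tests. All are
# lazy and cached, so the cost is paid once per test run, and every AUC is
# produced by the full pipeline (crop -> resample -> normalize ->
# [attention] -> nine views -> backbone features -> fused-kernel LOOCV)
# with the random-initialization extractor.

cohort_auc <- function(cohort, attention, modalities = NULL) {
  fc <- extract_cohort_features(cohort, full_net(), attention = attention)
  feats <- if (is.null(modalities)) fc$features else fc$features[modalities]
  if (length(feats) == 1L) feats <- feats[[1]]
  loocv(feats, fc$labels)$auc
}

# per-method AUCs for one cohort; the no-attention arm is optional because
# only the attention-contrast property needs it
cohort_panel <- function(cohort, with_plain = TRUE) {
  fc_mask <- extract_cohort_features(cohort, full_net(), attention = TRUE)
  single_mask <- vapply(names(fc_mask$features), function(m)
    loocv(fc_mask$features[[m]], fc_mask$labels)$auc, numeric(1))
  fused_plain <- if (with_plain) {
    fc_plain <- extract_cohort_features(cohort, full_net(), attention = FALSE)
    loocv(fc_plain$features, fc_plain$labels)$auc
  } else NA_real_
  list(fused_mask = loocv(fc_mask$features, fc_mask$labels)$auc,
       fused_plain = fused_plain,
       single_mask = single_mask)
}

# twenty independent large-effect cohorts (n = 12 each) for the fusion
# property; the first ten also carry the no-attention arm for the paired
# attention contrast
multi_cohort_panels <- function() cached("multi_cohort_panels", function() {
  lapply(1:20, function(k) {
    co <- generate_cohort(test_cohort_config(6L, 6L, effect = 2.0,
                                             seed = 100L + k))
    cohort_panel(co, with_plain = k <= 10)
  })
})

# LOOCV AUC of the fused pipeline at n = 60 for the null and the
# large-effect condition
null_cohort_auc <- function() cached("null_cohort_auc", function() {
  co <- generate_cohort(test_cohort_config(30L, 30L, effect = 0, seed = 501L))
  cohort_auc(co, attention = TRUE)
})

effect_cohort_auc <- function() cached("effect_cohort_auc", function() {
  co <- generate_cohort(test_cohort_config(30L, 30L, effect = 2.0, seed = 502L))
  cohort_auc(co, attention = TRUE)
})
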