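# Shared small synthetic cohort + features, computed once per test run.
# 6 s at 500 Hz is the shortest regime at which every channel reliably
# yields the 6 modes feature extraction needs.
.test_cache <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.test_cache$cohort)) {
    cfg <- synthetic_config(n_bad = 2L, n_good = 3L,
                            rest_duration = 6, task_duration = 6, fs = 500,
                            effect_bad = 2, effect_good = 0.02, seed = 77L)
    .test_cache$cohort <- generate_cohort(cfg)
    .test_cache$cfg <- cfg
  }
  c(.test_cache$cohort, list(cfg = .test_cache$cfg))
}

small_cohort_features <- function() {
  if (is.null(.test_cache$features)) {
    .test_cache$features <- extract_cohort_features(small_cohort()$recordings)
  }
  .test_cache$features
}

# Synthetic feature table built directly (no EMD): one rest and one task
# row per subject, the two classes separated by a large margin on a few
# feature columns plus small subject-specific noise.
toy_feature_table <- function(n_subjects = 8L, margin = 4, seed = 1L,
                              n_informative = 60L) {
  set.seed(seed)
  layout <- feature_layout()
  ids <- sprintf("T%02d", seq_len(n_subjects))
  rows <- lapply(ids, function(sid) {
    base <- stats::rnorm(length(layout), sd = 0.1)
    rest <- base + stats::rnorm(length(layout), sd = 0.15)
    task <- base + stats::rnorm(length(layout), sd = 0.15)
    task[seq_len(n_informative)] <- task[seq_len(n_informative)] + margin
    out <- rbind(rest, task)
    colnames(out) <- layout
    cbind(data.frame(subject_id = sid, condition = c("rest", "task"),
                     stringsAsFactors = FALSE),
          as.data.frame(out, check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

toy_manifest <- function(n_subjects = 8L, n_bad = 3L) {
  data.frame(subject_id = sprintf("T%02d", seq_len(n_subjects)),
             X = c(seq_len(n_bad), 10 + 2 * seq_len(n_subjects - n_bad)),
             group = rep(c("BAD", "GOOD"), c(n_bad, n_subjects - n_bad)),
             stringsAsFactors = FALSE)
}
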