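# Independent brute-force oracles and small fixture builders shared by the
# unit and acceptance tests. The oracles deliberately use naive enumeration,
# not the package's rank/sweep implementations.

# AUROC by exhaustive positive-negative pair counting (ties count one half).
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Youden point by explicit confusion-matrix sweep over unique thresholds
# (call positive when score >= threshold); ties broken to the lowest
# qualifying threshold.
oracle_youden <- function(scores, labels) {
  best <- NULL
  for (t in sort(unique(scores))) {
    tp <- sum(scores >= t & labels == 1)
    fn <- sum(scores < t & labels == 1)
    tn <- sum(scores < t & labels == 0)
    fp <- sum(scores >= t & labels == 0)
    sens <- tp / (tp + fn)
    spec <- tn / (tn + fp)
    j <- sens + spec - 1
    if (is.null(best) || j > best$youden + 1e-12) {
      best <- list(threshold = t, sensitivity = sens, specificity = spec,
                   youden = j)
    }
  }
  best
}

# Small synthetic federated cohort for training/federation tests.
make_small_cohort <- function(n_sites = 3L, n = 150L, seed = 1L,
                              d_binary = 6L, d_continuous = 2L,
                              incidence = NULL) {
  incidence <- incidence %||% seq(0.25, 0.5, length.out = n_sites)
  specs <- lapply(seq_len(n_sites), function(i) {
    site_spec(sprintf("S%02d", i), n, incidence[i],
              site_shift = (i - (n_sites + 1) / 2) * 0.2)
  })
  cfg <- generator_config(specs = specs, d_binary = d_binary,
                          d_continuous = d_continuous,
                          effect_sizes = default_effect_sizes(d_binary, d_continuous),
                          seed = seed)
  generate_federated_cohort(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Test double: a "model" that predicts a constant probability, for closed-
# form aggregation checks.
constant_model <- function(site_id, p) {
  structure(list(site_id = site_id, p = p), class = c("constant_model"))
}
predict_probability.constant_model <- function(model, features) {
  rep(model$p, nrow(as.data.frame(features)))
}
# register the S3 method for the test session
registerS3method("predict_probability", "constant_model",
                 predict_probability.constant_model,
                 envir = asNamespace("fedforest"))
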