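# Shared fixtures: everything is built in code at test time.

published_mean_profile <- function(condition = "CHD", dataset = "AGES-I") {
  vector_to_profile(reference_params(condition, dataset = dataset)$mean)
}

# A small cohort with a strong, well-separated synthetic signal is not
# wanted everywhere; this is the plain generator at modest size.
small_cohort <- function(n = 120, seed = 42, ...) {
  simulate_cohort(n, seed = seed, exact_counts = TRUE,
                  prevalence = c(CHD = 0.2, CVD = 0.25, CHF = 0.15), ...)
}

# Two linearly separable Gaussian clusters in d dimensions, pooled-SD
# separation `sep`.
separable_clusters <- function(n_per = 100, d = 4, sep = 10, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * d), n_per),
             matrix(rnorm(n_per * d, mean = sep), n_per))
  colnames(X) <- c("fat_N", "fat_mu", "fat_sigma", "fat_alpha")[seq_len(d)]
  list(X = X, y = rep(c(FALSE, TRUE), each = n_per))
}

# Independent all-pairs AUC oracle with half-credit for ties.
brute_force_auc <- function(y, s) {
  pos <- s[as.logical(y)]
  neg <- s[!as.logical(y)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
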