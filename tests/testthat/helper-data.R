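# Small fixture builders used across test files.

left_index <- function(v) data.frame(hemisphere = "left", vertex = seq_len(v))

# Evaluate an expression right after seeding (argument is lazy).
with_seed_helper <- function(seed, expr) {
  set.seed(seed)
  expr
}

random_responses <- function(n, v, hemisphere = "left") {
  neural_responses(matrix(rnorm(n * v), n, v),
                   data.frame(hemisphere = hemisphere, vertex = seq_len(v)))
}

# Standardized train/test blocks from a synthetic dataset, following the
# pipeline convention (train and test z-scored independently).
standardized_split <- function(ds, n_train) {
  spec <- first_last_split(nrow(ds$X), n_train)
  Xs <- split_concepts(ds$X, spec)
  Ys <- split_concepts(ds$Y, spec)
  list(spec = spec,
       Xtr = zscore_columns(Xs$train)$values,
       Xte = zscore_columns(Xs$test)$values,
       Ytr_z = zscore_columns(Ys$train),
       Ytr = zscore_columns(Ys$train)$values,
       Yte = zscore_columns(Ys$test)$values)
}
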