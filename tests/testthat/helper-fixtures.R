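# Shared fixtures: datasets are expensive, so they are built once per test
# run and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

# Full default-scale dataset (the study conditions).
default_dataset <- function() {
  if (is.null(.fixtures$default))
    .fixtures$default <- simulate_dataset(seed = 101)
  .fixtures$default
}

# Small dataset for structural tests that do not need the default scale.
small_dataset <- function() {
  if (is.null(.fixtures$small))
    .fixtures$small <- simulate_dataset(
      list(chrom_length = 100000L, n_genes = 20L, n_dmrs = 8L, n_de = 10L),
      seed = 202)
  .fixtures$small
}

sample_ids <- function(ds, breed, stage) {
  ds$samples$sample_id[ds$samples$breed == breed & ds$samples$stage == stage]
}

# Independent binomial upper-tail oracle: explicit summation of point masses
# on the log scale (never calls pbinom).
binom_tail_oracle <- function(m, n, p) {
  if (m <= 0) return(1)
  if (m > n) return(0)
  js <- m:n
  sum(exp(lchoose(n, js) + js * log(p) + (n - js) * log1p(-p)))
}

# Interval overlap helper for truth-table recovery checks.
overlaps_any <- function(chrom, start, end, tab) {
  any(tab$chrom == chrom & tab$start < end & tab$end > start)
}
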