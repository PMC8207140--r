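# Cached small synthetic datasets so several test files can share one
# generation run.
.fixtures <- new.env(parent = emptyenv())

small_dataset <- function(seed = 11, n_genes = 120, noise_sd = 0.5,
                          plan = default_motif_plan()) {
  key <- paste(seed, n_genes, noise_sd, nrow(plan), sep = "_")
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- generate_dataset(synth_config(
      n_genes = n_genes, genes_per_contig = 30, noise_sd = noise_sd,
      motif_plan = plan, seed = seed))
  }
  .fixtures[[key]]
}

empty_plan <- function() default_motif_plan()[0, ]

# brute-force TOM oracle: explicit triple loop
tom_oracle <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  out <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      s <- 0
      for (u in seq_len(n)) s <- s + a[i, u] * a[u, j]
      out[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  out
}

# exact binomial upper-tail oracle by term summation
binom_tail_oracle <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(i) stats::dbinom(i, n, p), numeric(1)))
}
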