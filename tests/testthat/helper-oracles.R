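# Independent brute-force evaluation of the TMM scaling-factor formula,
# written as plain loops so it shares no code with tmm_factors().
tmm_oracle <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  lib <- colSums(counts)
  props <- sweep(counts, 2, lib, "/")
  uq <- apply(props, 2, function(p) unname(quantile(p, 0.75)))
  ref <- which.min(abs(uq - mean(uq)))
  factors <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    ms <- as <- ws <- c()
    for (g in seq_len(nrow(counts))) {
      yo <- counts[g, j]; yr <- counts[g, ref]
      if (yo > 0 && yr > 0) {
        po <- yo / lib[j]; pr <- yr / lib[ref]
        ms <- c(ms, log2(po / pr))
        as <- c(as, (log2(po) + log2(pr)) / 2)
        ws <- c(ws, (lib[j] - yo) / (lib[j] * yo) +
                     (lib[ref] - yr) / (lib[ref] * yr))
      }
    }
    if (length(ms) == 0 || max(abs(ms)) < 1e-6) {
      factors[j] <- 1
      next
    }
    n <- length(ms)
    lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
    rk_m <- rank(ms); rk_a <- rank(as)
    keep <- which(rk_m >= lo_m & rk_m <= hi_m & rk_a >= lo_a & rk_a <= hi_a)
    if (length(keep) == 0) {
      factors[j] <- 1
      next
    }
    num <- den <- 0
    for (i in keep) {
      num <- num + ms[i] / ws[i]
      den <- den + 1 / ws[i]
    }
    factors[j] <- 2^(num / den)
  }
  geo <- exp(mean(log(factors)))
  factors / geo
}

# Small labelled count matrix for toy tests.
toy_counts <- function(values, n_genes, n_samples) {
  matrix(values, nrow = n_genes, ncol = n_samples,
         dimnames = list(paste0("g", seq_len(n_genes)),
                         paste0("s", seq_len(n_samples))))
}

# Default-like config scaled down for speed.
small_config <- function(...) {
  sim_config(n_per_group = c(normo = 15, micro = 8, macro = 10),
             n_genes = 400, n_kidney_enriched = 40, ...)
}
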