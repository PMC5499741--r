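# bootstrap standard error of a statistic of one sample
boot_se <- function(x, stat, B = 200, seed = 99) {
  set.seed(seed)
  n <- length(x)
  sd(vapply(seq_len(B), function(b) stat(x[sample.int(n, n, replace = TRUE)]),
            numeric(1)))
}

# standard error of a sample mean
se_mean <- function(x) sd(x) / sqrt(length(x))

# delta-method-free plug-in SEs for the dual-reporter squared-noise
# estimators (treating the channel means as known, adequate at large n)
se_eta_int2 <- function(g, r) {
  sd((g - r)^2) / (2 * mean(g) * mean(r) * sqrt(length(g)))
}
se_eta_ext2 <- function(g, r) {
  sd((g - mean(g)) * (r - mean(r))) / (mean(g) * mean(r) * sqrt(length(g)))
}
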