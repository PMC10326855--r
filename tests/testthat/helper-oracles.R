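# Closed-form and brute-force oracles, independent of the fitting paths
# they check (the package fits via lm / nlsLM; these use the textbook sums).

ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  c(intercept = intercept, slope = slope)
}

through_origin_oracle <- function(x, y) sum(x * y) / sum(x^2)

# volume-weighted 90th percentile straight from a particle list
d90_bruteforce <- function(sizes) {
  sizes <- sort(sizes)
  cum <- cumsum(sizes^3) / sum(sizes^3)
  sizes[which(cum >= 0.9)[1L]]
}

# histogram an explicit particle list into the detector bins
histogram_particles <- function(sizes) {
  edges <- psd_bin_edges()
  keep <- sizes >= edges[1L] & sizes <= edges[100L]
  tabulate(findInterval(sizes[keep], edges, rightmost.closed = TRUE),
           nbins = 99L)
}
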