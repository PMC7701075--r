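# Shared fixtures built in code; everything is seeded.

afm_mass_dist <- function(seed = 42, n = 2000) {
  x <- generate_afm_fixture(n = n, seed = seed)
  d <- suppressMessages(ingest_length_table(x$length_nm))
  convert_weighting(d, "mass")
}

# trapezoid integral of a weighted distribution, written independently of
# the package's node-weight helper
trap_integral <- function(dist) {
  g <- dist$grid
  p <- dist$density
  sum(diff(g) * (p[-length(p)] + p[-1]) / 2)
}

# sup distance between the CDFs of two distributions on a common grid
cdf_sup_distance <- function(d1, d2) {
  grid <- sort(unique(c(d1$grid, d2$grid)))
  c1 <- stats::approx(d1$grid, cumulative_weight(d1), grid, rule = 2)$y
  c2 <- stats::approx(d2$grid, cumulative_weight(d2), grid, rule = 2)$y
  max(abs(c1 - c2))
}
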