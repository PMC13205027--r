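# Shared fixtures: everything is generated in code at test time.

# small reduced-geometry cohort spec; defaults give one field per arm
small_spec <- function(arms, seed = 42, fields = 1, replicates = 1,
                       grid_dim = 5) {
  geom <- reduced_field_spec()
  cohort_spec("TEST", arms,
              fields_per_replicate = fields, replicates = replicates,
              field_size_px = geom$field_size_px, pixel_size = geom$pixel_size,
              grid_dim = grid_dim, seed = seed)
}

# channel parameters without any noise, for exact round-trip checks
noise_free <- function() {
  channel_params(bf_noise_sd = 0, fluor_noise_sd = 0, poisson = FALSE)
}

# digital disk mask: pixels whose centres lie within radius r of (cx, cy)
disk_mask <- function(n, cx, cy, r) {
  d2 <- outer((seq_len(n) - cx)^2, (seq_len(n) - cy)^2, "+")
  d2 <= r^2
}

# independent brute-force Feret oracle: max pairwise distance over every
# mask pixel (no convex hull), + 1 px pixel-extent correction
feret_bruteforce_px <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) == 1) return(1)
  max(stats::dist(pts)) + 1
}

# independent RECIST rule oracle, written as a direct transcription of the
# SLD rules (CR; then 30% decrease; then 20% + 5 mm increase; else SD)
recist_oracle <- function(pre, post) {
  if (post == 0) return("CR")
  change <- (post - pre) / pre
  if (change <= -0.3) return("PR")
  if (change >= 0.2 && (post - pre) >= 5) return("PD")
  "SD"
}

# Jaccard index of two masks
jaccard <- function(a, b) sum(a & b) / sum(a | b)
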