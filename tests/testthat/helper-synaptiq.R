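# Shared fixtures, all generated in code.

# Noiseless two-channel scene with 5 synaptic + 5 extrasynaptic puncta on a
# 20 x 20 um field; fixed geometry so segmentation tests are deterministic.
demo_scene <- function(seed = 11, noiseless = TRUE) {
  tr <- scene_truth(random_puncta(5, 5, seed = seed), background = 10,
                    gaussian_sd = if (noiseless) 0 else 2, seed = seed)
  make_dendrite_scene(tr)
}

# Segment both channels of a scene with one fixed threshold and label
# synaptic receptor clusters by marker overlap.
segment_scene <- function(scene, threshold = NULL) {
  tr <- scene$truth
  if (is.null(threshold)) threshold <- tr$background + min(tr$puncta$peak) / 2
  rimg <- scene$images$receptor
  mimg <- scene$images$marker
  rcl <- detect_clusters(threshold_mask(rimg, "fixed", fixed_value = threshold),
                         rimg)
  mcl <- detect_clusters(threshold_mask(mimg, "fixed", fixed_value = threshold),
                         mimg)
  label_synaptic(rcl, mcl)
}

# Hand-built 20-synapse FRET cell: 14 clean synapses plus designed violators
# of criteria 2 (2 synapses), 3 (3 synapses) and 4 (1 synapse).
designed_fret_cell <- function() {
  clean <- data.frame(synapse_id = 1:14, donor_sum = 10000,
                      donor_mean = 1000, fret_sum = 400, fret_mean = 40,
                      total_acceptor_sum = 1000)
  bad_ratio <- data.frame(synapse_id = 15:16, donor_sum = 10000,
                          donor_mean = 1000, fret_sum = c(1200, 1000),
                          fret_mean = 100, total_acceptor_sum = 1000)
  dim_donor <- data.frame(synapse_id = 17:19, donor_sum = 6000,
                          donor_mean = c(499, 300, 100), fret_sum = 400,
                          fret_mean = 40, total_acceptor_sum = 1000)
  huge_donor <- data.frame(synapse_id = 20, donor_sum = 100000,
                           donor_mean = 1000, fret_sum = 400, fret_mean = 40,
                           total_acceptor_sum = 1000)
  rbind(clean, bad_ratio, dim_donor, huge_donor)
}

# Simulated FRAP cohort for one condition.
frap_cohort <- function(k, n = 60, noise_sd = 5, seed0 = 1000) {
  kin <- kinetic_truth(k_exchange = k, mobile_fraction = 0.8,
                       bleach_depth = 0.2)
  lapply(seq_len(n), function(i)
    simulate_frap(kin, seq(0, 30, 2), pre_bleach = 100, noise_sd = noise_sd,
                  seed = seed0 + i, synapse_id = paste0("s", seed0 + i)))
}

# Brute-force two-sided Fisher p by hypergeometric tail enumeration:
# sum of all table probabilities not exceeding the observed one.
fisher_p_enum <- function(x, r, cc, N) {
  lo <- max(0, r + cc - N); hi <- min(r, cc)
  probs <- stats::dhyper(lo:hi, cc, N - cc, r)
  sum(probs[probs <= probs[x - lo + 1] * (1 + 1e-7)])
}

# Brute-force Otsu: direct between-class variance at every candidate split.
otsu_brute <- function(x) {
  v <- sort(unique(as.numeric(x)))
  best <- -Inf; thr <- NA
  for (t in v[-1]) {
    lo <- x[x < t]; hi <- x[x >= t]
    w0 <- length(lo) / length(x); w1 <- 1 - w0
    sb <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (sb > best) { best <- sb; thr <- t }
  }
  thr
}

# Brute-force balanced two-way ANOVA decomposition (treatment x time).
anova_brute <- function(y, a, b) {
  gm <- mean(y)
  ssa <- sum(tapply(y, a, function(v) length(v) * (mean(v) - gm)^2))
  ssb <- sum(tapply(y, b, function(v) length(v) * (mean(v) - gm)^2))
  cell <- tapply(y, list(a, b), mean)
  na <- nlevels(factor(a)); nb <- nlevels(factor(b))
  ncell <- length(y) / (na * nb)
  ssab <- ncell * sum((cell - outer(rowMeans(cell), colMeans(cell), "+") +
                         gm)^2)
  sse <- sum((y - ave(y, a, b))^2)
  dfa <- na - 1; dfb <- nb - 1; dfab <- dfa * dfb
  dfe <- length(y) - na * nb
  c(F_a = (ssa / dfa) / (sse / dfe), F_b = (ssb / dfb) / (sse / dfe),
    F_ab = (ssab / dfab) / (sse / dfe))
}
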