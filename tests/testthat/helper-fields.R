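# Shared fixtures: compact synthetic fields and a greedy center matcher.

# Single-nucleus field with a fixed focus complement on a compact canvas.
one_nucleus_field <- function(diameters, seed = 3, noise_sd = 0.01,
                              snr = 8, radius = 5) {
  spec <- field_spec(field_shape = c(160L, 160L), n_nuclei = 1, seed = seed,
                     noise_sd = noise_sd, focus_peak_snr = snr,
                     nucleus_radius = c(mean = radius, sd = 0.1),
                     markers = list(RAD51 = marker_model(
                       count = length(diameters), diameters = diameters)))
  synthesize_field(spec)
}

# Greedy one-to-one matching of detections to ground-truth foci within
# `radius` pixels; returns c(tp, fn, fp).
match_foci <- function(truth, detected, radius = 2) {
  if (is.null(detected) || !nrow(detected))
    return(c(tp = 0, fn = nrow(truth), fp = 0))
  used <- rep(FALSE, nrow(detected))
  tp <- 0
  for (i in seq_len(nrow(truth))) {
    d2 <- (detected$row - truth$row[i])^2 + (detected$col - truth$col[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (d2[j] <= radius^2) { used[j] <- TRUE; tp <- tp + 1 }
  }
  c(tp = tp, fn = nrow(truth) - tp, fp = nrow(detected) - tp)
}

# Nucleus records built directly (no imaging), for scoring-logic tests.
make_records <- function(n_gem_pos, n_gem_neg = 0, rad51_pos = 0,
                         sample_id = "S1", area_ids = "A1",
                         gh2ax_pos_frac = 1) {
  n <- n_gem_pos + n_gem_neg
  gem <- rep(c(TRUE, FALSE), c(n_gem_pos, n_gem_neg))
  pos <- rep(FALSE, n)
  pos[seq_len(rad51_pos)] <- TRUE
  data.frame(sample_id = sample_id,
             field_id = "F1",
             area_id = rep_len(area_ids, n),
             nucleus_id = seq_len(n),
             area_um2 = 30,
             geminin = gem,
             RAD51_foci = ifelse(pos, 8L, 1L),
             RAD51_pos = pos,
             gH2AX_foci = 10L,
             gH2AX_pos = runif(n) < gh2ax_pos_frac,
             stringsAsFactors = FALSE)
}
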