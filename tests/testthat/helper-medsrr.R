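# Shared test fixtures.

# The template bank is immutable and costs ~10 ms; build it once per run.
test_bank <- build_template_bank()

# Tiny network fixture for finite-difference gradient checks. The biases are
# lifted to 0.5 so no ReLU pre-activation sits near its kink: central
# differences across a kink do not measure the one-sided analytic gradient
# and would report spurious errors unrelated to backpropagation.
tiny_check_net <- function(seed = 2L) {
  net <- hybrid_network(f2 = 3, n2 = 2, n3 = 2, f3 = 3, init = "gaussian",
                        sd = 0.1, seed = seed, bank = test_bank)
  net$b2 <- rep(0.5, length(net$b2))
  net$b3 <- rep(0.5, length(net$b3))
  net
}

# A few small random (LR, HR) pairs in [0, 1].
tiny_pairs <- function(n = 3, hr_size = 16, seed = 1L) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    hr <- matrix(stats::runif(hr_size * hr_size), hr_size, hr_size)
    list(lr = scale_down(hr, 4L), hr = hr)
  }))
}

# SIFT parameters used throughout the tests: one octave at sigma0 = 1.2 so
# that 64..96-pixel synthetic images yield features without octave warnings.
test_sift <- function(image, id = NA_character_) {
  sift_features(image, id, octaves = 1, sigma0 = 1.2,
                contrast_threshold = 0.02)
}
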