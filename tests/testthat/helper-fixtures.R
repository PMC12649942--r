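# shared in-code fixtures for the test suite

tiny_samples <- function() {
  data.frame(
    sample_id = sprintf("s%02d", 1:6),
    group = c("A", "A", "A", "B", "B", "B"),
    d13C = c(-20, -22, -21, -18, -17.5, -18.5),
    d15N = c(10, 11, 10.5, 8, 8.5, 7.5),
    pctC = c(40, 40, NA, 42, 41, 40),
    pctN = c(12, 10, NA, 12, 11.5, 12),
    stringsAsFactors = FALSE)
}

# three well-separated sources spanning a wide mixing triangle
toy_sources <- function() {
  data.frame(
    name = c("algae", "plankton", "detritus"),
    n = c(10, 10, 10),
    mean_d13C = c(-24, -16, -20),
    sd_d13C = c(0.5, 0.5, 0.5),
    mean_d15N = c(4, 6, 14),
    sd_d15N = c(0.5, 0.5, 0.5),
    stringsAsFactors = FALSE)
}

table7_sources <- function() nys_sources()

anemone_consumers <- function(seed = 101)
  gen_source_samples(nys_anemone_summary(), 10, seed = seed)
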