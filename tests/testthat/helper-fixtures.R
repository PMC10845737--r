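# Shared fixture builders; everything is generated in code, no stored data.

# A normalized histogram with random bin masses.
random_histogram <- function() {
  m <- matrix(runif(768), 256, 3, dimnames = list(NULL, c("R", "G", "B")))
  m <- sweep(m, 2, colSums(m), "/")
  structure(list(bins = m, source_count = 1L), class = "rgb_histogram")
}

# A delta histogram: all mass at pixel value v in every channel.
delta_histogram <- function(v) {
  m <- matrix(0, 256, 3, dimnames = list(NULL, c("R", "G", "B")))
  m[v + 1L, ] <- 1
  structure(list(bins = m, source_count = 1L), class = "rgb_histogram")
}

# The uniform histogram over all 256 values.
uniform_histogram <- function() {
  m <- matrix(1 / 256, 256, 3, dimnames = list(NULL, c("R", "G", "B")))
  structure(list(bins = m, source_count = 1L), class = "rgb_histogram")
}

# A random 8-bit RGB array.
random_rgb_array <- function(h = 16, w = 16) {
  array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
}

# Minimal score/case tables for a single case.
one_case_tables <- function(dsa, ps, ground_truth = "ganglion_present",
                            expert_call = NA_character_, id = "c1") {
  list(
    cases = data.frame(case_id = id, ground_truth = ground_truth,
                       expert_call = expert_call, cohort = "X",
                       scanner = "S"),
    sets = data.frame(case_id = id, cohort = "X", scanner = "S",
                      set_index = seq_along(dsa), dsa_score = dsa,
                      pathologist_score = ps)
  )
}

# Literal evaluation of the three published decision criteria, kept
# separate from the implementation as the reference oracle.
literal_decision <- function(dsa, ps) {
  if (sum(ps == 5) >= 2) {
    "positive"
  } else if (mean(dsa) < 0.6) {
    "negative"
  } else {
    "in_doubt"
  }
}
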