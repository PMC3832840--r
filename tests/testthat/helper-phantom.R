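# Shared fixture builders; everything is generated in code at test time.

# Small, quiet phantom configuration for fast unit tests.
test_config <- function(...) {
  phantom_config(fast_n_voxels = 40000L, ...)
}

# Noise-free, partial-volume-free configuration: the analyzer should then
# recover the label-field composition almost exactly.
clean_config <- function(...) {
  phantom_config(noise_sigma = 0, partial_volume_shell = 0,
                 fast_n_voxels = 40000L, ...)
}

test_subject <- function(fraction = 70, seed = 99L, global_scale = 1,
                         age = 50, sex = "female", id = "T0001") {
  tibble::tibble(subject_id = id, age = age, sex = sex,
                 true_brain_fraction = fraction,
                 global_scale = global_scale, seed = as.integer(seed))
}

# An adc_map built directly from values (bypassing volumes), for histogram
# unit tests.
adc_map_from_values <- function(values, b_value = 1000) {
  structure(list(values = values, b_value = b_value,
                 n_voxels = length(values)),
            class = "adc_map")
}

# Build an adc_histogram with prescribed per-bin percentages.
histogram_from_percent <- function(percent, edges = adc_bin_edges(),
                                   overflow = 0, total = 1e6) {
  stopifnot(length(percent) == length(edges) - 1L)
  structure(
    list(bin_edges = edges, mids = (edges[-1] + edges[-length(edges)]) / 2,
         percent = percent, overflow_percent = overflow, total_count = total),
    class = "adc_histogram"
  )
}
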