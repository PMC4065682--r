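# Shared fixtures: noise-free curves and small random-profile generators.

truth_noise_free <- function() rabbit_cipro_truth(0, 0)

noise_free_profile <- function(times = rabbit_sampling_times(),
                               truth = truth_noise_free()) {
  list(
    times = times,
    conc = conc_two_compartment_oral(
      times, truth$ka, truth$v1_f, truth$k10, truth$k12, truth$k21,
      truth$dose
    ),
    dose = truth$dose,
    truth = truth
  )
}

# A random dissolution profile pair on a shared 3-10 point grid.
random_profile_pair <- function() {
  n <- sample(3:10, 1)
  times <- sort(sample(5:120, n))
  ref <- sort(runif(n, 10, 100))
  test <- pmin(pmax(ref + rnorm(n, 0, 8), 0), 110)
  list(times = times, ref = ref, test = test)
}

# Long-format dissolution tibble from per-product value vectors.
dissolution_tbl <- function(times, ...) {
  vals <- list(...)
  purrr::map_dfr(names(vals), function(id) {
    tibble::tibble(product_id = id, time_min = times, pct_dissolved = vals[[id]])
  })
}

# Unique scratch path for file-format tests.
temp_path <- function(name) tempfile(pattern = "pkbioeq-", fileext = paste0("-", name))
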