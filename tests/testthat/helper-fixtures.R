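# Shared fixtures, built in code. Kept tiny: most tests generate their
# own data at the scale they need.

two_class_specs <- function() default_fatigue_classes()[c(1, 5)]

# Small two-class cohort (class 0 vs class 4) at a reduced sampling
# rate; used wherever full 5-s physical windows would be overkill.
small_cohort <- function(n = 20, seed = 42, fs = 128, window_s = 0.5) {
  generate_cohort(cohort_spec(classes = two_class_specs(),
                              n_windows_per_class = n, fs = fs,
                              window_s = window_s, seed = seed))
}

random_symmetric_adjacency <- function(n, seed = 1) {
  set.seed(seed)
  A <- matrix(runif(n * n), n)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  A
}
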