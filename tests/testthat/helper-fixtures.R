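# Shared fixtures, built once per test run and cached across files.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# one noise-free Set-A trial under the default protocol
clean_trial <- function() fixture("clean_trial", function()
  generate_trial(sim_config(seed = 7, noise_sd = 0)))

# one noisy Set-A trial at study conditions
noisy_trial <- function() fixture("noisy_trial", function()
  generate_trial(sim_config(seed = 8)))

# a small two-subject cohort for unit tests of cross-validated evaluation
small_cohort <- function() fixture("small_cohort", function()
  generate_cohort(2, 3, sim_config(seed = 5)))

# the full-size evaluation cohort at study conditions (7 subjects x 6
# pairs, noise_sd = 0.05, mode_separation = 1)
study_cohort <- function() fixture("study_cohort", function()
  generate_cohort(7, 6, sim_config(seed = 20260925)))

study_loocv <- function() fixture("study_loocv", function()
  loocv_evaluate(study_cohort()))

# a hand-buildable protocol: stand, one walking bout, stand
walk_only_protocol <- function(steps = 8L) {
  out <- data.frame(mode = c("S", "W", "S"),
                    kind = c("stand", "gait", "stand"),
                    steps = c(NA_integer_, as.integer(steps), NA_integer_),
                    duration = c(2, NA, 2), stringsAsFactors = FALSE)
  attr(out, "set_variant") <- "A"
  out
}
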