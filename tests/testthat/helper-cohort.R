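# Shared fixtures, built in code.

ref_times <- c(-60, -15, 15, 30, 45, 60, 90, 120, 150, 180, 210)

# A hand-written, physiologically shaped NGT-like series (no model behind it).
make_series <- function(glucose = c(5.0, 5.0, 6.2, 7.8, 8.6, 8.2, 7.1, 6.2,
                                    5.6, 5.2, 5.0),
                        insulin = c(50, 50, 180, 320, 400, 380, 290, 180, 120,
                                    80, 60),
                        cpeptide = c(450, 450, 700, 1100, 1450, 1550, 1500,
                                     1250, 1000, 800, 650),
                        times = ref_times) {
  ogtt_series(times, glucose, insulin, cpeptide)
}

make_subject <- function(id = "S001", family = "F001", class = "NGT",
                         weight = 78, height = 1.72) {
  subject_record(subject_id = id, family_id = family, ethnicity = "synthetic",
                 sex = "male", age = 45, weight = weight, height = height,
                 serum_creatinine = 0.9, tolerance_class = class)
}

test_kinetics <- function() {
  biexponential_to_compartments(0.76, 4.95, 29.2, v_c = 4.3)
}

# Noise-free single-subject cohort config (fast paths in tests).
quiet_config <- function(...) {
  cohort_config(noise_cv = list(glucose = 0, insulin = 0, cpeptide = 0), ...)
}
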