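# Shared fixtures built in code: cohort-mean and patient-specific IF
# models, and noise-free synthetic tissue curves.

pc18f <- physical_constants()

mean_if <- function() if_model(16.00, 0.1574, 0.0145)
p9_if <- function() if_model(53.45, 0.2245, 0.0193)
mean_3p <- list(Ki = 0.0414, k_b = 0.0009, V_b = 0.16)

# noise-free decay-uncorrected tissue TAC from the 3P model
make_tissue_3p <- function(Ki, k_b, V_b, model,
                           scheme = default_frame_scheme()) {
  tac(scheme$mid,
      tissue_model_3p(scheme$mid, Ki, k_b, V_b, model, pc18f),
      decay_corrected = FALSE)
}

# draws a valid random 3P parameter set + IF within cohort-like ranges
draw_case_3p <- function() {
  list(model = if_model(runif(1, 8, 54), runif(1, 0.11, 0.26),
                        runif(1, 0.010, 0.019)),
       Ki = runif(1, 0.03, 0.15), k_b = runif(1, 0, 0.006),
       V_b = runif(1, 0.02, 0.12))
}
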