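# Shared fixtures: a shrunk session design (two control + six treatment
# epochs of 300 s) and a low-rate generator so unit tests stay fast; the
# acceptance suite uses the full-scale design.

small_design <- function() {
  session_design(control_start_s = -600, injection_s = 0,
                 antagonist_injection_s = -300, treatment_end_s = 1800,
                 epoch_length_s = 300)
}

small_session <- function(seed = 1L, preset = NULL, fs = 128, ...) {
  assemble_session(preset = preset, design = small_design(), fs = fs,
                   seed = seed, ...)
}

# ground-truth events as a plain swd event frame
gt_swds <- function(session) {
  session$ground_truth[session$ground_truth$label == "swd", , drop = FALSE]
}
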