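# shared fixtures, all generated in code

default_params <- function() {
  peirs_params(alpha_q = 0.3, alpha_s = 0.3, beta = 0.15,
               gamma0 = 0.1, gamma1 = 0.03)
}

# a small completed session on the set-1 stimuli, for hand-checkable cases
toy_session <- function() {
  tibble::tibble(
    trial = 1:6,
    block = 1L,
    set = 1L,
    trial_type = c("forced", "high", "low", "mixed", "high", "low"),
    option_left = c("D", "C", "A", "C", "D", "B"),
    option_right = c(NA, "D", "B", "B", "C", "A"),
    chosen = c("D", "D", "A", "C", "C", "B"),
    reward = c(80, 70, 30, 60, 55, 20)
  )
}

quick_sim <- function(params = default_params(), seed = 42, sched_seed = 7,
                      model = "peirs", ...) {
  sched <- experience_schedule(seed = sched_seed, ...)
  simulate_subject(params, sched, seed = seed, model = model)
}
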