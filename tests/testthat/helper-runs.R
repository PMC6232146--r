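# One small end-to-end pipeline run shared by several test files (built on
# first use).  10 conditions, 1 repetition, 2 subjects keeps it light while
# still exercising every stage including the full 806-cell searchlight.
demo_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- grasp_config(n_subjects = 2, n_conditions = 10,
                          n_repetitions = 1, seed = 99, windows = 3,
                          n_boot = 25)
      cache <<- run_pipeline(cfg)
    }
    cache
  }
})

# reduced-scale planted-effect profile used by the recovery checks:
# 14 conditions x 1 repetition x 5 subjects, window 1 only
recovery_config <- function(seed, effect_size = 1) {
  grasp_config(n_subjects = 5, n_conditions = 14, n_repetitions = 1,
               seed = seed, windows = 1, n_boot = 0,
               effect_size = effect_size)
}
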