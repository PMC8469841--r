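# Desk-scale training runs shared by the end-to-end acceptance tests.
# Five paired seeds, dueling and plain heads under the identical protocol;
# each run trains on the 24-phantom split and localizes the 8 held-out
# phantoms. Computed once per test session and cached.

desk_seeds <- 1:5

desk_cache <- new.env(parent = emptyenv())

desk_runs <- function(head_mode) {
  key <- paste0("runs_", head_mode)
  if (!is.null(desk_cache[[key]])) return(desk_cache[[key]])
  runs <- lapply(desk_seeds, function(s) {
    ex <- run_desk_experiment(seed = s, head_mode = head_mode)
    list(seed = s,
         median_error_vox = ex$median_error_vox,
         errors_vox = ex$errors_vox,
         ma_first = ex$reward_ma_first_quartile,
         ma_last = ex$reward_ma_last_quartile,
         rewards = ex$run$log$total_reward,
         causes = ex$run$log$cause)
  })
  desk_cache[[key]] <- runs
  runs
}
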