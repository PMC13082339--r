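# Full scenario runs are expensive (tens of seconds each); they are run
# once per test session and shared across test blocks.
.run_cache <- new.env(parent = emptyenv())

scenario_run <- function(scenario) {
  if (is.null(.run_cache[[scenario]]))
    .run_cache[[scenario]] <- simulate_phyllid(scenario)
  .run_cache[[scenario]]
}

# Division events cumulated over the 2-to-4.5-day imaging window,
# excluding the oblique apical divisions, split by wall orientation.
window_division_counts <- function(traj, from = 2, to = 4.5) {
  ev <- events_table(traj)
  ev <- ev[ev$kind == "division" & ev$time >= from & ev$time <= to, ]
  c(longitudinal = sum(ev$orientation == "longitudinal"),
    mediolateral = sum(ev$orientation == "mediolateral"))
}

# elementwise equality treating NA == NA as TRUE
identical_na <- function(a, b) (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
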