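## Shared expensive fixture: the tuned reference simulation and the
## aortic-stenosis rerun. Computed once per test session on first use.
.scenario_cache <- new.env(parent = emptyenv())

get_scenario_pair <- function() {
  if (is.null(.scenario_cache$pair)) {
    cfg <- default_config()
    .scenario_cache$pair <- run_scenario_pair(cfg, quiet = TRUE)
  }
  .scenario_cache$pair
}
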