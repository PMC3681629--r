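# One full-scale simulated study (default generator settings) shared
# by the acceptance blocks that need it; built on first use.
.fullrun_cache <- new.env(parent = emptyenv())

full_study <- function() {
  if (!exists("res", envir = .fullrun_cache)) {
    ds <- simulate_dataset(simulation_config(rng_seed = 42L))
    res <- run_pipeline(ds, outdir = NULL)
    assign("ds", ds, envir = .fullrun_cache)
    assign("res", res, envir = .fullrun_cache)
    assign("eval", evaluate_run(ds, res), envir = .fullrun_cache)
  }
  list(ds = get("ds", envir = .fullrun_cache),
       res = get("res", envir = .fullrun_cache),
       eval = get("eval", envir = .fullrun_cache))
}
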