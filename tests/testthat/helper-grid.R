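# Simulation-study runner shared by the acceptance tests: mean
# reconstruction rate and genotype-repair rate over replicate datasets of
# one (g_e, n, c) configuration.
run_sim_config <- function(g_e, n, c, reps = 100L, seed0 = 20000L) {
  r <- g <- rep(NA_real_, reps)
  for (i in seq_len(reps)) {
    sim <- generate_dataset(sim_config(n = n, c = c, g_e = g_e,
                                       seed = seed0 + i))
    asm <- assemble_haplotypes(sim$matrix)
    ev <- evaluate_assembly(asm, sim$truth)
    r[i] <- ev$recon_rate
    g[i] <- ev$imp_ge_ac
  }
  c(recon = mean(r, na.rm = TRUE), imp = mean(g, na.rm = TRUE))
}

# Cached full-grid results so the two simulation-study acceptance blocks
# share one computation.
sim_grid_results <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      grid <- expand.grid(g_e = c(0.04, 0.08), n = c(100L, 200L, 300L),
                          c = c(4L, 6L, 8L, 10L))
      res <- t(mapply(function(g_e, n, c) {
        run_sim_config(g_e, n, c, reps = 100L,
                       seed0 = 20000L + round(1e4 * g_e) * 100L + n + c)
      }, grid$g_e, grid$n, grid$c))
      cache <<- cbind(grid, res)
    }
    cache
  }
})
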