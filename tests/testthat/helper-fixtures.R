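# shared fixtures, built once per test run ------------------------------------

fx <- local({
  spec <- synthetic_lake_spec()
  hyp <- gen_hypsograph(spec)
  met <- gen_meteorology(spec, years = 3)
  inf <- gen_inflow(spec, years = 3)
  forcing <- prepare_forcing(met, inf, n_days = 1095)
  closed <- forcing
  closed$q_in <- 0
  list(spec = spec, hyp = hyp, meteo = met, inflow = inf,
       forcing = forcing, closed_forcing = closed,
       grid4 = build_grid(hyp, 4, 0.03),
       grid16 = build_grid(hyp, 16, 0.03),
       grid0d = build_grid(hypsograph_box(spec$surface_area_m2,
                                          spec$mean_depth_m), 1, 0),
       params = default_parameters())
})

# hand-made minimal run object for testing extraction logic in isolation
fake_run <- function(daily, cover_layers = NULL, grid = fx$grid4) {
  layers <- list()
  if (!is.null(cover_layers)) layers$cover <- cover_layers
  structure(list(daily = daily, layers = layers, grid = grid),
            class = "lake_run")
}
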