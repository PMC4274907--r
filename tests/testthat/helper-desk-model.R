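# The desk-scale study model, trained once per test run and shared by
# the tuning / reverse-correlation / connectivity acceptance tests.
.desk_cache <- new.env(parent = emptyenv())

desk_model <- function() {
  if (is.null(.desk_cache$model)) {
    grid <- default_grid("desk")
    syn <- make_synthetic_targets(6, seed = 1)
    init <- init_nguyen_widrow(grid$n_units, 60L, 6L, seed = 2)
    tr <- train_rmm(init, syn$target_set, grid,
                    training_config(n_epochs = 2e5, learning_rate = 0.01,
                                    momentum = 0.9, seed = 3))
    .desk_cache$model <- list(params = tr$params, syn = syn, grid = grid,
                              loss = tr$loss, loss_epoch = tr$loss_epoch)
  }
  .desk_cache$model
}

desk_banks <- function() {
  if (is.null(.desk_cache$banks)) {
    m <- desk_model()
    .desk_cache$banks <- revcorr_units(m$params, m$grid, 1:6, "output",
                                       n_frames = 2e5,
                                       bar_width_units = 2L,
                                       n_filters = 13L, seed = 21)
  }
  .desk_cache$banks
}
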