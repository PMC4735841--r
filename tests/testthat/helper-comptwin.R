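# shared simulation fixtures, generated once per test session
.comptwin_cache <- new.env(parent = emptyenv())

# moderate 1275-line run used by several statistical checks
sim_midrun <- function() {
  if (is.null(.comptwin_cache$mid)) {
    src <- na22_source(annihilation = FALSE)
    .comptwin_cache$mid <- run_experiment(default_prototype(), src,
                                          n_decays = 2e8, seed = 404)
  }
  .comptwin_cache$mid
}

# drop reader/selection attributes before frame comparisons
strip_attrs <- function(df) {
  df <- as.data.frame(df)
  attributes(df) <- attributes(df)[c("names", "row.names", "class")]
  df
}
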