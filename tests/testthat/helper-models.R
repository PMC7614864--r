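# Shared fixtures: small models and parameter sets built in code.
# Heavy simulations keep short settles on passive fixtures; the full 5 s
# settle is exercised in the acceptance suite.

quiet_params <- function() {
  p <- default_parameters()
  p[c("g_na", "g_kdr", "g_ka", "g_km", "g_h", "g_cal", "g_cat",
      "g_can", "g_sk", "g_bk")] <- 0
  p
}

tiny_stick <- function(trunk = 200) {
  build_synthetic_morphology(trunk_length = max(trunk, 300),
                             n_oblique = 0, n_basal = 1,
                             basal_length = 100, basal_diam = 4)
}

study_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- discretize(build_synthetic_morphology())
    cache
  }
})

swc_fixture_text <- function() {
  c("# three-point soma with apical and basal stick",
    "1 1 0 0 0 5 -1",
    "2 1 0 5 0 5 1",
    "3 1 0 -5 0 5 1",
    "4 4 0 55 0 1.5 2",
    "5 4 0 105 0 1.5 4",
    "6 3 0 -55 0 2 3")
}
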