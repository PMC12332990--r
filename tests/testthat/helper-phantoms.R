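# Shared small-phantom fixtures, built in code at test time.  Heavy
# objects are memoised per session in an environment so independent test
# files can reuse them without regenerating.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

TEST_DIMS <- c(48L, 48L, 24L)
TEST_SPACING <- c(1, 1, 3)

# one preprocessed phantom pair with a jittered geometry; prev controls
# whether the left side carries a supra-centimetre nodule
make_phantom_record <- function(seed, nodule_left = NULL, nodule_right = NULL,
                                noise_sigma = 5,
                                pre = preprocess_config(patch_size = c(24, 24, 24))) {
  set.seed(seed)
  geom <- default_gland_geometry(TEST_DIMS, TEST_SPACING)
  for (side in c("left", "right")) {
    geom[[side]]$center <- geom[[side]]$center + stats::runif(3, -2, 2)
    geom[[side]]$semi_axes <- geom[[side]]$semi_axes * stats::runif(3, 0.9, 1.1)
  }
  ph <- generate_phantom(phantom_spec(
    dims = TEST_DIMS, spacing = TEST_SPACING, gland_geometry = geom,
    nodule_left = nodule_left, nodule_right = nodule_right,
    noise_sigma = noise_sigma, seed = seed))
  pp <- preprocess_volume(ph$volume, ph$mask, pre)
  list(volume = pp$volume, mask = pp$mask,
       left_label = ph$left_label, right_label = ph$right_label)
}

# note: `pre` is an exact formal here, so it cannot partially match
# `prevalence`
make_phantom_set <- function(seeds, prevalence = 0.5,
                             pre = preprocess_config(patch_size = c(24, 24, 24)),
                             noise_sigma = 5) {
  lapply(seeds, function(s) {
    set.seed(s + 5000)
    nod <- if (stats::runif(1) < prevalence)
      list(diameter = stats::runif(1, 12, 16),
           contrast = stats::runif(1, 20, 60)) else NULL
    make_phantom_record(s, nodule_left = nod, noise_sigma = noise_sigma,
                        pre = pre)
  })
}
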