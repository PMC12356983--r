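# shared fixtures: tiny scenes and maps built in code

grid5 <- seq(400, 700, 5)

# constant-spectrum radiance scene
flat_scene <- function(h = 4, w = 4, value = 1, ppd = 10,
                       quantity = "radiance", env = "natural",
                       id = "flat") {
  cube <- array(value, dim = c(h, w, length(grid5)))
  hyperspectralScene(cube, grid5, quantity = quantity, environment = env,
                     pixelsPerDegree = ppd, sceneId = id)
}

# radiance scene with arbitrary per-pixel spectra from a generator function
random_scene <- function(h = 3, w = 3, ppd = 10, seed = 1, id = "rand") {
  withr::with_seed(seed, {
    cube <- array(runif(h * w * length(grid5)), dim = c(h, w, length(grid5)))
  })
  hyperspectralScene(cube, grid5, quantity = "radiance",
                     pixelsPerDegree = ppd, sceneId = id)
}

random_map <- function(h, w, seed = 1, channel = "Mel", ppd = 10) {
  withr::with_seed(seed, m <- matrix(runif(h * w), h, w))
  new("ChannelMap", values = m, channel = channel, sceneId = "m",
      pixelsPerDegree = ppd)
}

patch_records <- function(values, channel = "Mel", field = 1.37) {
  data.frame(scene_id = "s", channel = channel, field_deg = field,
             patch_index = seq_along(values), x0 = 0, y0 = 0,
             local_value = values, contrast = NA_real_)
}
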