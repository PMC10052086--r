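# Small, fast scene configurations for unit tests; acceptance tests build
# their own larger ones.

quiet_cfg <- function(...) {
  args <- list(...)
  defaults <- list(seed = 1L, days = 20, image_size = c(64L, 64L), gsd = 3,
                   plane_tilt = 0, depth_noise_sd = 0,
                   growth = list(cv = 0))
  for (nm in names(args)) defaults[[nm]] <- args[[nm]]
  do.call(sim_config, defaults)
}

# a single plant row in the state format the generator uses
plant_row <- function(x = 0, y = 0, radius = 50, height = 40, id = 1L) {
  data.frame(id = id, x = x, y = y, radius = radius, height = height,
             radius_max = 200, height_max = 200, weight_err = 0, hue = 0)
}

# brute-force per-class IoU by pixel enumeration (independent of miou())
enum_miou <- function(pred, gt) {
  score <- function(cls) {
    inter <- 0; uni <- 0
    for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
      p <- pred[i, j] == cls; g <- gt[i, j] == cls
      inter <- inter + (p && g)
      uni <- uni + (p || g)
    }
    if (uni == 0) 1 else inter / uni
  }
  (score(TRUE) + score(FALSE)) / 2
}
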