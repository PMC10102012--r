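test_that("channel statistics use the population convention, per channel", {
  cs <- channel_stats(array(c(1, 2, 3), dim = c(3, 1, 1)))
  expect_equal(cs$mean, 2)
  expect_equal(cs$sd, sqrt(2 / 3), tolerance = 1e-12)

  const <- channel_stats(array(5, dim = c(4, 4, 1)))
  expect_equal(const$sd, 0)

  two <- array(c(rep(1, 4), 1:4), dim = c(2, 2, 2))
  cs2 <- channel_stats(two)
  expect_equal(cs2$mean, c(1, 2.5))
  expect_equal(cs2$sd[1], 0)
  expect_equal(cs2$sd[2], sqrt(mean((1:4 - 2.5)^2)))

  expect_error(channel_stats(matrix(1, 2, 2)), "H, W, C")
})

test_that("adain aligns statistics exactly and blends by alpha", {
  cont <- array(c(1, 2, 3), dim = c(3, 1, 1))
  sty <- array(c(8, 10, 12), dim = c(3, 1, 1))
  expect_equal(as.vector(adain(cont, sty, alpha = 1)), c(8, 10, 12),
               tolerance = 1e-12)
  # style == content leaves the map unchanged
  expect_equal(adain(cont, cont, alpha = 1), cont, tolerance = 1e-12)
  # alpha = 0 is the identity regardless of style
  expect_identical(adain(cont, sty, alpha = 0), cont)

  expect_error(adain(cont, array(1:4, dim = c(2, 1, 2)), 1), "channel count")
  expect_warning(adain(array(1, dim = c(2, 2, 1)), sty[, , 1, drop = FALSE], 1),
                 "constant content")

  # exact algebra on random maps; idempotence of the aligned statistics
  set.seed(10)
  for (r in 1:100) {
    ch <- sample(1:4, 1)
    cmap <- array(rnorm(6 * 5 * ch, sd = runif(1, 0.5, 2)), dim = c(6, 5, ch))
    smap <- array(rnorm(4 * 7 * ch, mean = runif(1, -2, 2)), dim = c(4, 7, ch))
    out <- adain(cmap, smap, alpha = 1)
    os <- channel_stats(out); ss <- channel_stats(smap)
    expect_lt(max(abs(os$mean - ss$mean)), 1e-6)
    expect_lt(max(abs(os$sd - ss$sd)), 1e-6)
    again <- adain(out, smap, alpha = 1)
    expect_lt(max(abs(again - out)), 1e-6)
  }
})

test_that("coder training converges, is seeded, and guards preconditions", {
  coder <- fixture_coder()
  expect_lt(coder$holdout_error, coder$config$recon_ceiling)
  expect_true(all(diff(coder$loss_trace[c(1, length(coder$loss_trace))]) < 0))

  expect_error(train_coder(lapply(1:10, function(i) array(0.5, c(32, 32, 3)))),
               "at least 64")

  # determinism: a short run repeated under one seed gives identical weights
  imgs <- c(lapply(fixture_dataset()$path[1:40], read_image),
            fixture_style_bank(),
            generate_style_bank(16, 32, seed = 79))
  cfg <- desk_coder_config(content_size = 32L, style_size = 32L, epochs = 2L,
                           recon_ceiling = 1)
  c1 <- train_coder(imgs, cfg, seed = 5)
  c2 <- train_coder(imgs, cfg, seed = 5)
  expect_identical(retinaCL:::net_params(c1$encoder),
                   retinaCL:::net_params(c2$encoder))
  expect_identical(retinaCL:::net_params(c1$decoder),
                   retinaCL:::net_params(c2$decoder))
})

test_that("stylize blends at the feature level and decodes deterministically", {
  coder <- fixture_coder()
  cont <- generate_fundus(desk_params(), 2, seed = 1)$image
  sty <- generate_style(style_params(32, "stripes"), seed = 3)

  # at alpha = 1 the pre-decode features carry the style statistics exactly
  out <- quiet_adain(stylize(cont, sty, alpha = 1, coder, return_features = TRUE))
  fs <- channel_stats(out$features)
  ss <- channel_stats(out$style_features)
  live <- channel_stats(out$content_features)$sd > 0
  expect_lt(max(abs(fs$mean - ss$mean)[live]), 1e-5)
  expect_lt(max(abs(fs$sd - ss$sd)[live]), 1e-5)

  # alpha = 0 propagates to the plain reconstruction of the content
  rec <- retinaCL:::decode_features(coder, retinaCL:::encode_image(coder, cont))
  a0 <- quiet_adain(stylize(cont, sty, alpha = 0, coder))
  expect_equal(a0, retinaCL:::quantize8(rec), tolerance = 1e-12)

  # deterministic bytes under fixed inputs
  o1 <- quiet_adain(stylize(cont, sty, alpha = 1, coder))
  o2 <- quiet_adain(stylize(cont, sty, alpha = 1, coder))
  expect_identical(o1, o2)

  expect_error(stylize(cont, sty, alpha = 1, coder = list()), "trained coder")
})

test_that("stylization changes texture but preserves lesion polarity", {
  coder <- fixture_coder()
  ok <- 0L; total <- 0L
  for (fam in c("swirl", "stripes", "noise-field", "color-patches")) {
    sty <- generate_style(style_params(32, fam), seed = 21)
    for (seed in 1:6) {
      rec <- generate_fundus(desk_params(), 4, seed = seed)
      out <- quiet_adain(stylize(rec$image, sty, alpha = 1, coder))
      expect_gt(mean(abs(out - rec$image)), 0)   # texture actually changed
      l1 <- retinaCL:::luminance(rec$image)
      l2 <- retinaCL:::luminance(out)
      s <- dim(l1)[1]
      for (k in seq_len(nrow(rec$objects))) {
        o <- rec$objects[k, ]
        cx <- round(o$x); cy <- round(o$y); r <- max(1L, ceiling(o$radius))
        if (cx - 3 * r < 1 || cx + 3 * r > s ||
            cy - 3 * r < 1 || cy + 3 * r > s) next
        ii <- (cx - r):(cx + r); jj <- (cy - r):(cy + r)
        si <- (cx - 3 * r):(cx + 3 * r); sj <- (cy - 3 * r):(cy + 3 * r)
        d_orig <- mean(l1[ii, jj]) - mean(l1[si, sj])
        d_sty <- mean(l2[ii, jj]) - mean(l2[si, sj])
        total <- total + 1L
        if (sign(d_orig) == sign(d_sty)) ok <- ok + 1L
      }
    }
  }
  expect_gt(total, 80)
  expect_gte(ok / total, 0.9)
})

test_that("precompute_stylized writes a seeded, complete variant cache", {
  man <- fixture_dataset()
  sub <- man[1:10, , drop = FALSE]
  class(sub) <- class(man)
  dir1 <- file.path(tempdir(), "sty-a")
  cache <- precompute_stylized(sub, fixture_style_bank(), 2L, 1.0,
                               fixture_coder(), dir1, seed = 5)
  expect_equal(nrow(cache$index), 20)
  expect_true(all(file.exists(cache$index$variant_path)))
  expect_equal(sort(unique(cache$index$image_id)), sort(sub$image_id))

  # same seed reproduces the style assignments
  dir2 <- file.path(tempdir(), "sty-b")
  cache2 <- precompute_stylized(sub, fixture_style_bank(), 2L, 1.0,
                                fixture_coder(), dir2, seed = 5)
  expect_identical(cache$index$style_id, cache2$index$style_id)

  # variants genuinely differ from their sources at alpha = 1
  src <- read_image(sub$path[1])
  var1 <- read_image(cache$index$variant_path[1])
  expect_gt(mean(abs(var1 - src)), 0)

  expect_error(precompute_stylized(sub, list(), 2L, 1.0, fixture_coder(),
                                   tempdir(), 1), "empty")
  # index round-trips through the loader
  reloaded <- load_stylized_cache(dir1)
  expect_equal(reloaded$index$variant_path, cache$index$variant_path)
})
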