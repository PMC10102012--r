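test_that("regular augmentation is seeded and respects the identity policy", {
  img <- generate_fundus(desk_params(), 1, seed = 2)$image
  pol0 <- identity_policy()
  out <- regular_augment(img, pol0, seed = 1)
  expect_equal(out, retinaCL:::resize_image(img, 32), ignore_attr = TRUE)

  pol <- augmentation_policy(output_size = 32)
  a <- regular_augment(img, pol, seed = 9)
  b <- regular_augment(img, pol, seed = 9)
  expect_identical(a, b)
  expect_equal(dim(a), c(32, 32, 3))

  # rotation draws stay inside +/- 30 degrees (read from the draw log)
  angles <- vapply(1:200, function(s) {
    attr(regular_augment(img, pol, seed = s), "draws")$rotation_deg
  }, numeric(1))
  expect_true(all(abs(angles) <= 30))
  expect_gt(max(abs(angles)), 15)   # the range is actually exercised
})

test_that("view pairs draw NST substitution as configured", {
  man <- fixture_dataset()
  cache <- fixture_stylized_cache()
  rec <- man[1, , drop = FALSE]

  vp0 <- make_view_pair(rec, identity_policy(nst_probability = 0),
                        cache = NULL, seed = 4)
  src <- retinaCL:::resize_image(read_image(rec$path), 32)
  expect_equal(vp0$view_i, src, ignore_attr = TRUE)
  expect_equal(vp0$view_j, src, ignore_attr = TRUE)
  expect_false(any(vp0$used_nst))

  vp1 <- quiet_adain(make_view_pair(rec, identity_policy(nst_probability = 1),
                                    cache = cache, seed = 4))
  expect_true(all(vp1$used_nst))
  variants <- lapply(retinaCL:::cache_variant_paths(cache, rec$image_id),
                     read_image)
  match_i <- any(vapply(variants, function(v) {
    isTRUE(all.equal(vp1$view_i, retinaCL:::resize_image(v, 32),
                     check.attributes = FALSE))
  }, logical(1)))
  expect_true(match_i)

  ghost <- as_manifest(data.frame(image_id = "ghost", path = rec$path,
                                  dr_grade = 0L, referable = FALSE,
                                  split = NA_character_))
  expect_error(make_view_pair(ghost[1, , drop = FALSE],
                              identity_policy(nst_probability = 1),
                              cache = cache, seed = 1),
               "ghost")
})

test_that("NT-Xent matches its closed forms and validates inputs", {
  # N = 2, positives identical unit vectors, the two pairs orthogonal
  z <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  pidx <- c(2L, 1L, 4L, 3L)
  expect_equal(nt_xent_loss(z, pidx, tau = 0.5),
               -log(exp(2) / (exp(2) + 2)), tolerance = 1e-9)

  # a single pair has no negatives: the loss is exactly 0
  expect_equal(nt_xent_loss(rbind(c(1, 2), c(-3, 1)), c(2L, 1L), 0.5), 0)

  expect_error(nt_xent_loss(z, c(1L, 2L, 3L, 4L), 0.5), "involution")
  expect_error(nt_xent_loss(z, pidx, tau = 0), "tau")
  z_bad <- z; z_bad[2, ] <- 0
  expect_error(nt_xent_loss(z_bad, pidx, 0.5), "zero-norm.*2")
})

test_that("NT-Xent is alignment-sensitive and scale-invariant", {
  set.seed(31)
  base <- matrix(rnorm(8 * 16), 8, 16)
  pidx <- as.integer(seq_len(8) + c(1, -1))

  # pulling one positive pair together strictly decreases the loss
  losses <- vapply(c(0, 0.5, 0.9), function(w) {
    z <- base
    z[2, ] <- (1 - w) * base[2, ] + w * base[1, ]
    nt_xent_loss(z, pidx, 0.5)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))

  # cosine similarity: per-row positive rescaling changes nothing
  z_scaled <- base
  z_scaled[5, ] <- 13.7 * z_scaled[5, ]
  z_scaled[1, ] <- 0.01 * z_scaled[1, ]
  expect_equal(nt_xent_loss(base, pidx, 0.5),
               nt_xent_loss(z_scaled, pidx, 0.5), tolerance = 1e-12)
})

test_that("the NT-Xent analytic gradient matches finite differences", {
  ns <- asNamespace("retinaCL")
  set.seed(8)
  z <- matrix(rnorm(12 * 6), 12, 6)
  pidx <- as.integer(seq_len(12) + c(1, -1))
  g <- ns$nt_xent(z, pidx, 0.5, want_grad = TRUE)$grad
  for (i in sample(length(z), 6)) {
    eps <- 1e-6
    z1 <- z; z1[i] <- z1[i] + eps
    z0 <- z; z0[i] <- z0[i] - eps
    num <- (nt_xent_loss(z1, pidx, 0.5) - nt_xent_loss(z0, pidx, 0.5)) / (2 * eps)
    expect_lt(abs(num - g[i]), 1e-6 * max(1, abs(num)))
  }
})

test_that("LARS applies the trust ratio and momentum as specified", {
  w <- list(layer.W = matrix(c(0.6, 0.8), 1))     # ||w|| = 1
  g <- list(layer.W = matrix(c(1, 0), 1))          # ||g|| = 1
  up <- lars_step(w, g, base_lr = 0.25, weight_decay = 0,
                  trust_coefficient = 1)
  # local_lr = 1, fresh momentum: step = base_lr * g
  expect_equal(up$weights$layer.W, w$layer.W - 0.25 * g$layer.W)

  # zero gradient, zero decay: nothing moves
  z <- lars_step(w, list(layer.W = matrix(0, 1, 2)), 0.3, 0, 1e-3)
  expect_equal(z$weights$layer.W, w$layer.W)

  # identical state twice gives identical updates
  u1 <- lars_step(w, g, 0.1, 1e-4, 1e-3)
  u2 <- lars_step(w, g, 0.1, 1e-4, 1e-3)
  expect_identical(u1, u2)

  # biases and normalization gains skip trust scaling (local_lr = 1)
  wb <- list(layer.b = c(1, 1), projbn.W = c(1, 1))
  gb <- list(layer.b = c(0.1, 0), projbn.W = c(0, 0.1))
  ub <- lars_step(wb, gb, base_lr = 1, weight_decay = 0.5,
                  trust_coefficient = 1e-9)
  expect_equal(ub$weights$layer.b, c(0.9, 1))
  expect_equal(ub$weights$projbn.W, c(1, 0.9))

  expect_error(lars_step(w, list(layer.W = matrix(c(NaN, 0), 1)), 0.1, 0),
               "non-finite")
})

test_that("embed produces paired 128-dim projections", {
  enc <- make_encoder("tiny", seed = 2)
  head <- retinaCL:::make_projection_head(32L, 64L, 128L, seed = 3)
  set.seed(1)
  views <- array(runif(16 * 16 * 3 * 8), dim = c(16, 16, 3, 8))
  views[, , , 4] <- views[, , , 3]   # duplicated view
  eb <- embed(views, enc, head)
  expect_equal(dim(eb$z), c(8, 128))
  expect_equal(dim(eb$h), c(8, 32))
  expect_equal(eb$h[3, ], eb$h[4, ])
  expect_equal(eb$pair_index[eb$pair_index], seq_len(8))
  expect_false(any(eb$pair_index == seq_len(8)))
})

test_that("pretraining is seeded end to end and respects epoch bounds", {
  man <- fixture_dataset()
  cfg0 <- desk_pretrain_config(batch_size = 8L, epochs = 0L,
                               augmentation = identity_policy())
  ck0 <- pretrain(man, NULL, cfg0, seed = 5)
  init <- retinaCL:::make_encoder("tiny", retinaCL:::derive_seed(5, "enc-init"))
  expect_identical(ck0$encoder, retinaCL:::net_params(init$net))
  expect_equal(ck0$epoch, 0L)
  expect_length(ck0$loss_trace, 0)

  cfg <- desk_pretrain_config(
    batch_size = 8L, epochs = 2L,
    augmentation = augmentation_policy(nst_probability = 0, output_size = 32L))
  ck1 <- pretrain(man, NULL, cfg, seed = 5)
  ck2 <- pretrain(man, NULL, cfg, seed = 5)
  expect_identical(ck1$loss_trace, ck2$loss_trace)
  expect_identical(ck1$encoder, ck2$encoder)
  expect_identical(ck1$projection, ck2$projection)

  expect_error(pretrain(man, NULL, desk_pretrain_config(batch_size = 64L),
                        seed = 1), "exceeds dataset")
})

test_that("checkpoints round-trip bit-exactly through JSON", {
  man <- fixture_dataset()
  cfg <- desk_pretrain_config(batch_size = 8L, epochs = 1L,
                              augmentation = identity_policy())
  ck <- pretrain(man, NULL, cfg, seed = 9)
  path <- tempfile(fileext = ".json")
  save_checkpoint(ck, path)
  back <- load_checkpoint(path)
  expect_identical(ck$encoder, back$encoder)
  expect_identical(ck$projection, back$projection)
  expect_equal(ck$loss_trace, back$loss_trace)

  # identical forward pass from the reloaded weights
  enc1 <- make_encoder("tiny", 1)
  enc1$net <- retinaCL:::net_set_params(enc1$net, ck$encoder)
  enc2 <- make_encoder("tiny", 2)
  enc2$net <- retinaCL:::net_set_params(enc2$net, back$encoder)
  set.seed(3)
  x <- array(runif(16 * 16 * 3 * 2), dim = c(16, 16, 3, 2))
  expect_identical(retinaCL:::net_forward(enc1$net, x)$out,
                   retinaCL:::net_forward(enc2$net, x)$out)
})
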