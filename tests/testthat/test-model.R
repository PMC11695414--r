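test_that("encode_eeg identity configuration reproduces the input", {
  cfg <- model_config(d = 3, d_h = 3, conv_kernel = 1, activation = "linear",
                      use_positional_encoding = FALSE, dropout_p = 0,
                      n_classes = 2, max_T = 8)
  m <- build_model(cfg, seed = 1)
  m$params$Wc <- diag(3)
  m$params$bc <- rep(0, 3)
  set.seed(2)
  X <- matrix(rnorm(15), 5, 3)
  enc <- encode_eeg(eeg_sequence(X), cfg, m$params)
  expect_equal(enc$h, X)
})

test_that("encode_eeg on time-constant input gives equal context rows", {
  # kernel 1: zero padding would otherwise perturb the boundary rows
  cfg <- model_config(d = 2, d_h = 4, conv_kernel = 1,
                      use_positional_encoding = FALSE,
                      dropout_p = 0, n_classes = 2, max_T = 8)
  m <- build_model(cfg, seed = 3)
  X <- matrix(rep(c(0.5, -1), each = 6), 6, 2)
  enc <- encode_eeg(eeg_sequence(X), cfg, m$params)
  expect_equal(enc$attn, matrix(1 / 6, 6, 6), tolerance = 1e-12)
  for (t in 2:6) expect_equal(enc$ctx[t, ], enc$ctx[1, ], tolerance = 1e-12)
  expect_equal(enc$ctx[1, ], enc$h[1, ], tolerance = 1e-12)
})

test_that("encode_eeg matches the double-loop oracle on random instances", {
  for (seed in 1:25) {
    set.seed(seed)
    cfg <- model_config(d = 3, d_h = sample(2:4, 1),
                        conv_kernel = sample(c(1, 3), 1),
                        use_positional_encoding = sample(c(TRUE, FALSE), 1),
                        dropout_p = 0, n_classes = 2, max_T = 8)
    m <- build_model(cfg, seed = seed + 100)
    X <- matrix(rnorm(4 * 3), 4, 3)
    got <- encode_eeg(eeg_sequence(X), cfg, m$params)
    want <- oracle_encode_eeg(X, cfg, m$params)
    expect_equal(got$h, want$h, tolerance = 1e-10)
    expect_equal(got$ctx, want$ctx, tolerance = 1e-10)
    expect_equal(got$attn, want$attn, tolerance = 1e-10)
  }
})

test_that("encode_video spatial stage honours its degenerate cases", {
  # 1x1 grid: pooled vector is that pixel's embedding unchanged
  cfg <- model_config(d = 2, h = 1, w = 1, c = 2, h_v = 3,
                      use_positional_encoding = FALSE,
                      use_spatial_positions = FALSE, dropout_p = 0,
                      n_classes = 2, max_T = 8)
  m <- build_model(cfg, seed = 5)
  fr <- array(rnorm(3 * 1 * 1 * 2), c(3, 1, 1, 2))
  enc <- encode_video(video_sequence(frames = fr), cfg, m$params)
  for (t in 1:3) {
    ev <- drop(fr[t, 1, 1, ] %*% m$params$Wemb) + m$params$bemb
    expect_equal(enc$h[t, ], ev, tolerance = 1e-12)
  }

  # spatially constant frame: uniform spatial weights; pooled vector
  # equals any single pixel's embedding (spatial positions off)
  cfg2 <- model_config(d = 2, h = 3, w = 4, c = 1, h_v = 3,
                       use_positional_encoding = FALSE,
                       use_spatial_positions = FALSE, dropout_p = 0,
                       n_classes = 2, max_T = 8)
  m2 <- build_model(cfg2, seed = 6)
  fr2 <- array(0.7, c(2, 3, 4, 1))
  enc2 <- encode_video(video_sequence(frames = fr2), cfg2, m2$params)
  ev <- drop(0.7 * m2$params$Wemb[1, ]) + m2$params$bemb
  expect_equal(enc2$h[1, ], ev, tolerance = 1e-12)
})

test_that("encode_video matches the per-pixel double-loop oracle", {
  for (seed in 1:25) {
    set.seed(seed)
    cfg <- model_config(d = 2, h = 2, w = 2, c = sample(1:2, 1),
                        h_v = sample(2:4, 1),
                        use_positional_encoding = sample(c(TRUE, FALSE), 1),
                        use_spatial_positions = sample(c(TRUE, FALSE), 1),
                        dropout_p = 0, n_classes = 2, max_T = 8)
    m <- build_model(cfg, seed = seed + 200)
    fr <- array(rnorm(3 * 2 * 2 * cfg$c), c(3, 2, 2, cfg$c))
    got <- encode_video(video_sequence(frames = fr), cfg, m$params)
    want <- oracle_encode_video(fr, cfg, m$params)
    expect_equal(got$h, want$h, tolerance = 1e-10)
    expect_equal(got$ctx, want$ctx, tolerance = 1e-10)
    expect_equal(got$attn, want$attn, tolerance = 1e-10)
  }
})

test_that("encode_video rejects mixed input and validates widths", {
  expect_error(video_sequence(frames = array(0, c(2, 2, 2, 1)),
                              features = matrix(0, 2, 3)),
               class = "eegfuse_validation_error")
  cfg <- tiny_cfg(use_positional_encoding = FALSE)
  m <- build_model(cfg, seed = 1)
  expect_error(encode_video(video_sequence(features = matrix(0, 4, 7)),
                            cfg, m$params),
               class = "eegfuse_validation_error")
  # pre-featurized input skips the spatial stage
  feats <- matrix(rnorm(12), 4, 3)
  enc <- encode_video(video_sequence(features = feats), cfg, m$params)
  expect_equal(enc$h, feats)
})

test_that("cross_modal_fuse matches examples and oracle", {
  # T = 1: attn = 1, cross = sum of the two context rows
  e <- matrix(c(1, 2), 1); v <- matrix(c(-1, 0.5), 1)
  fz <- cross_modal_fuse(e, v)
  expect_equal(fz$attn, matrix(1, 1, 1))
  expect_equal(fz$cross, e + v)

  # identical video rows: uniform attention, cross = mean_j (e_j + v_j)
  set.seed(4)
  E <- matrix(rnorm(8), 4, 2)
  V <- matrix(rep(c(0.2, -0.7), each = 4), 4, 2)
  fz <- cross_modal_fuse(E, V)
  expect_equal(fz$attn, matrix(0.25, 4, 4))
  expect_equal(fz$cross, matrix(colMeans(E + V), 4, 2, byrow = TRUE))

  # random instances against the double-loop oracle
  for (seed in 1:50) {
    set.seed(seed)
    Tn <- sample(1:6, 1); df <- sample(1:4, 1)
    E <- matrix(rnorm(Tn * df), Tn, df); V <- matrix(rnorm(Tn * df), Tn, df)
    got <- cross_modal_fuse(E, V)
    want <- oracle_fuse(E, V)
    expect_equal(got$cross, want$cross, tolerance = 1e-12)
    expect_equal(got$attn, want$attn, tolerance = 1e-12)
  }
  expect_error(cross_modal_fuse(matrix(0, 2, 2), matrix(0, 2, 3)),
               class = "eegfuse_validation_error")
})

test_that("predict_probs follows the softmax head contract", {
  head <- list(weight = matrix(0, 2, 4), bias = rep(0, 4))
  p <- predict_probs(matrix(rnorm(6), 3, 2), head)
  expect_equal(p, matrix(0.25, 3, 4))

  head$bias <- c(1e4, 0, 0, 0)
  p <- predict_probs(matrix(rnorm(2), 1, 2), head)
  expect_equal(drop(p), c(1, 0, 0, 0))

  head2 <- list(weight = matrix(0, 2, 2), bias = c(log(3), 0))
  p <- predict_probs(matrix(0, 1, 2), head2)
  expect_equal(drop(p), c(0.75, 0.25))
  expect_error(predict_probs(matrix(0, 1, 3), head2),
               class = "eegfuse_validation_error")
})

test_that("sequence_cross_entropy limits and monotonicity", {
  # perfect one-hot predictions: exactly zero
  P <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  expect_identical(sequence_cross_entropy(P, c(0, 1)), 0)
  # uniform, |C| = 4, T = 2: 2 ln 4
  expect_equal(sequence_cross_entropy(matrix(0.25, 2, 4), c(1, 3)), 2 * log(4),
               tolerance = 1e-12)
  # T = 1, true-class prob 0.5
  expect_equal(sequence_cross_entropy(matrix(c(0.5, 0.5), 1), 0), log(2),
               tolerance = 1e-12)
  # nonnegative, and strictly decreasing as mass moves to the true class
  ps <- seq(0.05, 0.95, by = 0.05)
  losses <- vapply(ps, function(p)
    sequence_cross_entropy(matrix(c(p, 1 - p), 1), 0), numeric(1))
  expect_true(all(losses >= 0))
  expect_true(all(diff(losses) < 0))
  # zero probability at the true label: clamped, large and finite
  l0 <- sequence_cross_entropy(matrix(c(0, 1), 1), 0)
  expect_true(is.finite(l0) && l0 >= -log(1e-12) - 1e-9)
  expect_error(sequence_cross_entropy(matrix(c(0.6, 0.6), 1), 0),
               class = "eegfuse_validation_error")
})

test_that("count_parameters matches an independent container walk", {
  # head-only: d_f * |C| + |C|
  cfg <- model_config(d = 2, d_f = 2, n_classes = 3, max_T = 8)
  expect_identical(count_parameters(cfg, "head_only"), 2 * 3 + 3)
  # doubling |C| adds exactly d_f*|C| + |C| scalars
  cfg6 <- model_config(d = 2, d_f = 2, n_classes = 6, max_T = 8)
  expect_identical(count_parameters(cfg6, "head_only") -
                     count_parameters(cfg, "head_only"), 2 * 3 + 3)
  # 20 random configs x all variants against the walked containers
  for (seed in 1:20) {
    set.seed(seed)
    cfg <- model_config(d = sample(1:4, 1), h = sample(2:4, 1),
                        w = sample(2:4, 1), c = sample(1:2, 1),
                        h_v = sample(2:5, 1), d_h = sample(2:5, 1),
                        d_f = sample(2:5, 1), n_classes = sample(2:4, 1),
                        conv_kernel = sample(c(1, 3, 5), 1),
                        use_positional_encoding = sample(c(TRUE, FALSE), 1),
                        use_spatial_positions = sample(c(TRUE, FALSE), 1),
                        max_T = 8)
    for (v in c("full", "no_cross_modal", "no_adaptive_attention",
                "no_eeg_stream")) {
      m <- build_model(cfg, v, seed = seed)
      walked <- sum(vapply(m$params, length, integer(1)))
      expect_identical(count_parameters(cfg, v), as.numeric(walked) + 0,
                       info = sprintf("seed %d variant %s", seed, v))
    }
  }
})

test_that("estimate_flops follows the documented per-layer formulas", {
  cfg <- model_config(d = 2, d_f = 2, n_classes = 3, max_T = 8)
  expect_identical(estimate_flops(cfg, 1, "head_only"), 6)
  # doubling T quadruples attention terms and doubles conv/head terms
  cfg2 <- model_config(d = 3, h = 4, w = 4, c = 1, h_v = 4, d_h = 4,
                       d_f = 4, n_classes = 2, max_T = 16)
  f1 <- estimate_flops(cfg2, 8)
  f2 <- estimate_flops(cfg2, 16)
  Tm <- 8
  attn1 <- 2 * Tm^2 * cfg2$d_h + 2 * Tm^2 * cfg2$h_v + 2 * Tm^2 * cfg2$d_f
  lin1 <- f1 - attn1
  expect_identical(f2, 4 * attn1 + 2 * lin1)
  # hand sum for a fixed tiny config (spreadsheet oracle)
  cfg3 <- model_config(d = 2, h = 2, w = 2, c = 1, h_v = 3, d_h = 2,
                       d_f = 2, n_classes = 2, conv_kernel = 3, max_T = 8)
  Tn <- 4
  hand <- Tn * 2 * 2 * 3 +                      # conv
    (2 * Tn * 4 + 2 * Tn^2 * 2) +               # eeg attention
    Tn * 2 * 2 +                                # eeg projection
    Tn * 4 * (1 * 3 + 2 * 3) +                  # spatial pooling
    (2 * Tn * 9 + 2 * Tn^2 * 3) +               # video attention
    Tn * 3 * 2 +                                # video projection
    2 * Tn^2 * 2 +                              # fusion
    Tn * 2 * 2                                  # head
  expect_identical(estimate_flops(cfg3, Tn), hand)
})

test_that("analytic gradients match central differences (all variants)", {
  cfg <- tiny_cfg()
  ins <- rand_model_inputs(4, cfg, seed = 11)
  for (variant in c("full", "no_cross_modal", "no_adaptive_attention",
                    "no_eeg_stream")) {
    m <- build_model(cfg, variant, seed = 13)
    fwd <- eegfuse:::forward_seq(m, ins$eeg, ins$video, ins$labels)
    g <- eegfuse:::grads_as_vector(eegfuse:::backward_seq(m, fwd), m$params)
    th <- eegfuse:::flatten_params(m$params)
    eps <- 1e-6
    ng <- vapply(seq_along(th), function(i) {
      tp <- th; tp[i] <- tp[i] + eps
      tm <- th; tm[i] <- tm[i] - eps
      mp <- m; mp$params <- eegfuse:::unflatten_params(tp, m$params)
      mm <- m; mm$params <- eegfuse:::unflatten_params(tm, m$params)
      (eegfuse:::forward_seq(mp, ins$eeg, ins$video, ins$labels)$loss -
         eegfuse:::forward_seq(mm, ins$eeg, ins$video, ins$labels)$loss) /
        (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(g - ng)) / max(1, max(abs(ng))), 1e-6)
  }
})

test_that("checkpoint round trip is bit-exact", {
  cfg <- tiny_cfg()
  m <- build_model(cfg, "full", seed = 21)
  path <- tempfile(fileext = ".json")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m2$params, m$params)
  expect_identical(m2$variant, m$variant)
  expect_identical(unclass(m2$config), unclass(m$config))
  unlink(path)
})
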