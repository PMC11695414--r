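test_that("cyclic_lr follows the cosine schedule with warm restarts", {
  cfg <- train_config(eta_min = 1e-4, eta_max = 1e-2, T_max = 20L)
  expect_identical(cyclic_lr(0, cfg), cfg$eta_max)
  expect_equal(cyclic_lr(10, cfg), (cfg$eta_min + cfg$eta_max) / 2,
               tolerance = 1e-15)
  # approaches eta_min at the end of the cycle, restarts at eta_max
  expect_equal(cyclic_lr(19, cfg),
               cfg$eta_min + 0.5 * (cfg$eta_max - cfg$eta_min) *
                 (1 + cos(pi * 19 / 20)), tolerance = 1e-15)
  expect_identical(cyclic_lr(20, cfg), cfg$eta_max)
  # bounded, monotone non-increasing within a cycle, periodic
  etas <- vapply(0:19, cyclic_lr, numeric(1), cfg = cfg)
  expect_true(all(etas >= cfg$eta_min & etas <= cfg$eta_max))
  expect_true(all(diff(etas) <= 0))
  expect_equal(vapply(0:19 + 20L, cyclic_lr, numeric(1), cfg = cfg), etas)
  cfg$T_max <- 0L
  expect_error(cyclic_lr(1, cfg), class = "eegfuse_validation_error")
})

test_that("clip_gradient enforces the norm contract", {
  expect_identical(clip_gradient(c(0.3, -0.4), 1), c(0.3, -0.4))
  expect_equal(clip_gradient(c(3, 4), 1), c(0.6, 0.8), tolerance = 1e-15)
  expect_identical(clip_gradient(numeric(3), 1), numeric(3))
  expect_error(clip_gradient(c(1, 2), 0), class = "eegfuse_validation_error")
  expect_error(clip_gradient(c(1, Inf), 1), class = "eegfuse_validation_error")
  set.seed(99)
  for (i in 1:200) {
    g <- rnorm(sample(1:20, 1), sd = runif(1, 0.1, 10))
    tau <- runif(1, 0.1, 5)
    gc <- clip_gradient(g, tau)
    expect_lte(sqrt(sum(gc^2)), tau * (1 + 1e-12))
    expect_lte(sqrt(sum(gc^2)), sqrt(sum(g^2)) * (1 + 1e-12))
    if (sqrt(sum(g^2)) > 1e-8)
      expect_equal(sum(g * gc) / (sqrt(sum(g^2)) * sqrt(sum(gc^2))), 1,
                   tolerance = 1e-12)
  }
})

test_that("early_stop_check walks the definition", {
  expect_identical(early_stop_check(numeric(0), 3),
                   list(stop = FALSE, best_epoch = NA_integer_))
  # strictly decreasing: never stops
  expect_false(early_stop_check(seq(5, 1), 2)$stop)
  # losses 1.0, 0.5, 0.6, 0.6 with patience 2: stops after the 4th
  expect_false(early_stop_check(c(1.0, 0.5, 0.6), 2)$stop)
  es <- early_stop_check(c(1.0, 0.5, 0.6, 0.6), 2)
  expect_true(es$stop)
  expect_identical(es$best_epoch, 2L)   # 0-based epoch 1
  # eleven identical losses, patience 10: stops with best at the first
  es <- early_stop_check(rep(1, 11), 10)
  expect_true(es$stop)
  expect_identical(es$best_epoch, 1L)   # tie resolved to the earliest
  expect_false(early_stop_check(rep(1, 10), 10)$stop)
})

test_that("build_ablation degenerate equivalences hold", {
  # kernel 1 keeps conv outputs exactly time-constant on constant input
  # (zero padding would perturb the boundary rows)
  cfg <- tiny_cfg(use_positional_encoding = FALSE, conv_kernel = 1)
  ins <- rand_model_inputs(5, cfg, seed = 31)
  full <- build_ablation(cfg, ablation_spec("full"), seed = 41)

  # identity build: full spec equals the unablated assembly
  expect_identical(full$params, build_model(cfg, "full", seed = 41)$params)

  # constant-in-time input: uniform-attention ablation == full model
  Xc <- matrix(rep(c(1, -0.5), each = 4), 4, 2)
  frc <- array(rep(array(rnorm(3 * 2 * 1), c(3, 2, 1)),
                   each = 4), c(4, 3, 2, 1))
  ec <- eeg_sequence(Xc); vc <- video_sequence(frames = frc)
  noad <- build_ablation(cfg, "no_adaptive_attention", seed = 41)
  # share the overlapping parameters so the comparison is meaningful
  for (nm in names(noad$params)) noad$params[[nm]] <- full$params[[nm]]
  pf <- eegfuse:::forward_seq(full, ec, vc)$probs
  pa <- eegfuse:::forward_seq(noad, ec, vc)$probs
  expect_equal(pa, pf, tolerance = 1e-12)

  # T = 1: no_cross_modal equals the full model (fusion degenerates)
  ins1 <- rand_model_inputs(1, cfg, seed = 32)
  ncm <- build_ablation(cfg, "no_cross_modal", seed = 41)
  p1f <- eegfuse:::forward_seq(full, ins1$eeg, ins1$video)$probs
  p1n <- eegfuse:::forward_seq(ncm, ins1$eeg, ins1$video)$probs
  expect_equal(p1n, p1f, tolerance = 1e-12)

  expect_error(build_ablation(cfg, "bogus"), class = "eegfuse_validation_error")
})

test_that("train_model honours max_epochs = 0 and determinism", {
  cfg <- tiny_cfg(dropout_p = 0.2)
  set.seed(55)
  data <- lapply(1:12, function(i) rand_model_inputs(3, cfg, seed = 500 + i))
  class(data) <- "eegfuse_dataset"
  split <- list(train = 1:8, val = 9:12)
  m <- build_model(cfg, "full", seed = 5)

  tc0 <- train_config(max_epochs = 0L, batch_size = 4L, seed = 9)
  fit0 <- train_model(m, data, split, tc0)
  expect_identical(fit0$model$params, m$params)
  expect_length(fit0$record$train_loss, 0)

  tc <- train_config(eta_max = 0.01, batch_size = 4L, max_epochs = 4L,
                     patience = 10L, seed = 9)
  fit1 <- train_model(m, data, split, tc)
  fit2 <- train_model(m, data, split, tc)
  expect_identical(fit1$record$train_loss, fit2$record$train_loss)
  expect_identical(fit1$record$val_loss, fit2$record$val_loss)
  expect_identical(fit1$model$params, fit2$model$params)
  expect_identical(fit1$record$lr, fit2$record$lr)
  expect_error(train_model(m, data, list(train = 1:8, val = 8:12), tc),
               class = "eegfuse_validation_error")
})

test_that("a convex head-only model descends monotonically on a separable task", {
  # T = 1 sequences, two classes, features linearly separable
  cfg <- model_config(d = 2, d_f = 2, n_classes = 2, dropout_p = 0, max_T = 4)
  set.seed(77)
  data <- lapply(1:40, function(i) {
    y <- i %% 2L
    x <- rnorm(2, mean = c(2, -2) * (if (y == 1) 1 else -1), sd = 0.3)
    list(eeg = eeg_sequence(matrix(x, 1, 2)), video = NULL,
         labels = label_sequence(y, 2))
  })
  class(data) <- "eegfuse_dataset"
  split <- list(train = 1:32, val = 33:40)
  m <- build_model(cfg, "head_only", seed = 3)
  tc <- train_config(eta_max = 0.01, batch_size = 32L, max_epochs = 10L,
                     patience = 10L, seed = 3)
  fit <- train_model(m, data, split, tc)
  expect_true(all(diff(fit$record$train_loss) < 0))
})

test_that("training record serializes to CSV", {
  rec <- structure(list(train_loss = c(1, 0.5), val_loss = c(1.1, 0.7),
                        lr_first_step = c(0.001, 0.0009),
                        lr = c(0.001, 0.00095, 0.0009),
                        best_epoch = 2L, stop_epoch = 2L, aborted = FALSE),
                   class = "train_record")
  path <- tempfile(fileext = ".csv")
  write_train_record(rec, path)
  df <- utils::read.csv(path)
  expect_identical(names(df), c("epoch", "train_loss", "val_loss",
                                "lr_first_step"))
  expect_equal(df$train_loss, c(1, 0.5))
  unlink(path)
})
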