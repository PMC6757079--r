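test_that("training loss decreases from the start on separable data", {
  seqs <- small_sequences("alpha", "alpha", tS = 0.25)
  ds <- small_effect_set("alpha")
  cfg <- model_config(batch_size = Inf, learning_rate = 5e-3,
                      max_epochs = 10, val_fraction = 0, seed = 3)
  fit <- train(seqs, ds$labels, "valence", cfg)
  expect_true(all(diff(fit$loss_history[1:5]) < 0))
  expect_equal(fit$input_dim, 4 * 32)
  expect_equal(fit$band, "alpha")
})

test_that("training is deterministic under a fixed seed", {
  seqs <- small_sequences("alpha", "alpha", tS = 0.25)
  ds <- small_effect_set("alpha")
  cfg <- model_config(seed = 3, max_epochs = 8)
  f1 <- train(seqs, ds$labels, "valence", cfg)
  f2 <- train(seqs, ds$labels, "valence", cfg)
  expect_identical(f1$final_loss, f2$final_loss)
  p1 <- predict(f1, seqs[1:6])
  p2 <- predict(f2, seqs[1:6])
  expect_identical(p1$score, p2$score)
  expect_true(all(p1$score >= 0 & p1$score <= 1))
  expect_equal(p1$class, as.integer(p1$score >= 0.5))
})

test_that("full-batch training is invariant to trial order", {
  seqs <- small_sequences("alpha", "alpha", tS = 0.25)
  ds <- small_effect_set("alpha")
  cfg <- model_config(batch_size = Inf, learning_rate = 5e-3,
                      max_epochs = 10, val_fraction = 0, seed = 3)
  fit <- train(seqs, ds$labels, "valence", cfg)
  set.seed(31)
  perm <- sample(length(seqs))
  fit_p <- train(seqs[perm], ds$labels[perm, ], "valence", cfg)
  expect_equal(predict(fit, seqs[1:8])$score,
               predict(fit_p, seqs[1:8])$score, tolerance = 1e-8)
})

test_that("retraining on globally rescaled inputs gives the same model", {
  # per-feature z-scoring with training-set statistics absorbs any c > 0
  seqs <- small_sequences("alpha", "alpha", tS = 0.25)
  ds <- small_effect_set("alpha")
  cfg <- model_config(batch_size = Inf, learning_rate = 5e-3,
                      max_epochs = 10, val_fraction = 0, seed = 3)
  fit <- train(seqs, ds$labels, "valence", cfg)
  scaled <- lapply(seqs, function(s) { s$vectors <- 7 * s$vectors; s })
  fit_s <- train(scaled, ds$labels, "valence", cfg)
  expect_equal(predict(fit, seqs[1:8])$score,
               predict(fit_s, scaled[1:8])$score, tolerance = 1e-9)
})

test_that("held-out accuracy sits at chance when labels are coin flips", {
  seqs <- small_sequences("alpha", "alpha", tS = 0.25)
  set.seed(77)
  y_flip <- rep(c(0, 1), each = 20)[sample(40)]
  cv <- crossval(seqs, y_flip, "valence", model_config(seed = 2), k = 5,
                 seed = 13)
  expect_gt(cv$mean["acc"], 40)
  expect_lt(cv$mean["acc"], 60)
})

test_that("the effect band is recovered: its accuracy beats off-band by >= 15 points", {
  ds <- small_effect_set("alpha")
  cv_alpha <- crossval(small_sequences("alpha", "alpha", 0.25), ds$labels,
                       "valence", model_config(seed = 2), k = 5, seed = 9)
  cv_theta <- crossval(small_sequences("alpha", "theta", 0.25), ds$labels,
                       "valence", model_config(seed = 2), k = 5, seed = 9)
  expect_gte(cv_alpha$mean["acc"] - cv_theta$mean["acc"], 15)
})

test_that("degenerate training sets and dimension mismatches are rejected", {
  seqs <- small_sequences("alpha", "alpha", tS = 0.25)
  ds <- small_effect_set("alpha")
  expect_error(train(seqs[1:20], rep(1L, 20), "valence"), "single class")
  expect_error(train(seqs, rep(NA, 40) * 1L, "valence"), "0/1|excluded")

  mixed <- seqs
  mixed[[2]]$vectors <- mixed[[2]]$vectors[, 1:64]
  expect_error(train(mixed, ds$labels, "valence"), "E")

  fit <- train(seqs, ds$labels, "valence", model_config(seed = 1,
                                                        max_epochs = 2))
  short <- seqs[[1]]
  short$vectors <- short$vectors[, 1:64]
  expect_error(predict(fit, short), "input_dim")
})

test_that("a stacked two-layer model trains and predicts", {
  seqs <- small_sequences("alpha", "alpha", tS = 0.25)
  ds <- small_effect_set("alpha")
  cfg <- model_config(seed = 4, n_layers = 2, hidden_units = 8,
                      max_epochs = 6)
  fit <- train(seqs, ds$labels, "valence", cfg)
  p <- predict(fit, seqs)
  expect_true(all(is.finite(p$score)))
  expect_true(all(p$score >= 0 & p$score <= 1))
})
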