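test_that("subject-level splits honour the 6:2:2 ratio without leakage", {
  subs <- sprintf("P%03d", 1:100)
  sp <- split_dataset(subs, seed = 1)
  expect_length(sp$train, 60L)
  expect_length(sp$validation, 20L)
  expect_length(sp$test, 20L)
  expect_length(intersect(sp$train, sp$validation), 0L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_length(intersect(sp$validation, sp$test), 0L)
  expect_setequal(c(sp$train, sp$validation, sp$test), subs)

  sp10 <- split_dataset(sprintf("P%d", 1:10), seed = 3)
  expect_equal(lengths(sp10), c(train = 6L, validation = 2L, test = 2L))

  expect_identical(split_dataset(subs, seed = 7), split_dataset(subs, seed = 7))
  expect_false(identical(split_dataset(subs, seed = 7), split_dataset(subs, seed = 8)))

  expect_error(split_dataset(c("a", "b"), seed = 1), "at least")
  expect_error(split_dataset(subs, ratio = c(5, 2, 2), seed = 1), "summing to 10")

  # uneven counts stay within one subject of the exact proportion
  for (n in c(11, 17, 23)) {
    spn <- split_dataset(sprintf("Q%d", 1:n), seed = 2)
    expect_true(all(abs(lengths(spn) - n * c(6, 2, 2) / 10) < 1))
    expect_equal(sum(lengths(spn)), n)
  }
})

test_that("class balancing equalizes counts by seeded downsampling", {
  set.seed(1)
  bs <- structure(list(
    X = matrix(rnorm(1400 * 120), 1400),
    meta = data.frame(record_id = "r", subject_id = "s",
                      label = rep(c("hyper", "normo"), c(1000, 400)),
                      potassium = 5),
    records = data.frame()), class = "beat_set")
  bal <- balance_classes(bs, seed = 2)
  expect_equal(as.vector(table(bal$meta$label)[c("hyper", "normo")]), c(400L, 400L))
  expect_identical(balance_classes(bs, seed = 2)$X, bal$X)

  even <- beat_subset(bs, 601:1400)  # 400 + 400
  expect_identical(balance_classes(even, seed = 5), even)

  onecls <- beat_subset(bs, 1:1000)
  expect_error(balance_classes(onecls, seed = 1), "both classes")
})

test_that("plateau schedule halves after 3 flat epochs and resets on improvement", {
  cfg <- train_config()
  # strictly decreasing: never reduced
  expect_equal(lr_schedule(c(1, 0.9, 0.8, 0.7), cfg), rep(5e-5, 5))
  # three non-improving epochs then reduction
  expect_equal(lr_schedule(c(1.0, 1.1, 1.1, 1.1), cfg)[5], 2.5e-5)
  expect_equal(lr_schedule(c(1.0, 1.1, 1.1, 1.1), cfg)[1:4], rep(5e-5, 4))
  # improvement at epoch 3 resets the counter; first reduction after epoch 6
  l <- c(1.0, 1.1, 1.0 - 1e-9, 1.1, 1.1, 1.1)
  s <- lr_schedule(l, cfg)
  expect_equal(s[6], 5e-5)
  expect_equal(s[7], 2.5e-5)
  # counter also resets after each reduction
  expect_equal(lr_schedule(rep(1, 13), train_config())[c(1, 5, 8, 11)],
               c(5e-5, 2.5e-5, 1.25e-5, 6.25e-6))
})

test_that("train_config validates its invariants", {
  expect_error(train_config(ratio = c(1, 1, 1)), "summing to 10")
  expect_error(train_config(patience = 0), "patience")
  expect_equal(train_config()$lr, 5e-5)
  expect_equal(train_config()$batch_size, 1024L)
  expect_equal(train_config()$max_epochs, 50L)
})

test_that("generic training tracks the best validation epoch and serializes it", {
  # tiny separable problem: class 1 has a bump at the fiducial
  sp <- tiny_spec("basic", input_length = 24L)
  set.seed(4)
  n <- 120
  y <- rep(c("normo", "hyper"), each = n / 2)
  X <- matrix(rnorm(n * 24, sd = 0.1), n)
  X[y == "hyper", 8:12] <- X[y == "hyper", 8:12] + 2
  mk <- function(idx) structure(list(
    X = X[idx, , drop = FALSE],
    meta = data.frame(record_id = "r", subject_id = sprintf("s%d", idx),
                      label = y[idx], potassium = 5),
    records = data.frame()), class = "beat_set")
  idx <- sample(n)
  ck <- train_generic(mk(idx[1:80]), mk(idx[81:120]), sp,
                      train_config(lr = 3e-3, batch_size = 16, max_epochs = 6,
                                   balance = FALSE, seed = 2))
  expect_s3_class(ck, "ecg_checkpoint")
  # best-checkpoint property: recorded loss is the minimum of the log
  expect_equal(ck$meta$val_loss, min(ck$log$val_loss))
  expect_equal(ck$log$val_loss[ck$meta$epoch], ck$meta$val_loss)
  # learnable problem: the best epoch beats chance clearly
  expect_gt(ck$log$val_accuracy[ck$meta$epoch], 0.9)
  # checkpoint round-trips bitwise and reproduces its validation loss
  dir <- withr::local_tempdir()
  save_checkpoint(ck, dir)
  ck2 <- load_checkpoint(dir)
  expect_identical(ck2$params, ck$params)
  expect_identical(ck2$buffers, ck$buffers)
  m <- checkpoint_model(ck2)
  ev <- eval_beats(m, X[idx[81:120], ], as.integer(y[idx[81:120]] == "hyper"))
  expect_equal(ev$loss, ck$meta$val_loss, tolerance = 1e-6)
})
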