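test_that("gan_losses reproduces closed-form values", {
  expect_equal(gan_losses(c(1, 1), c(1, 1))$loss_x, 0)
  expect_equal(gan_losses(c(0.5, 0.5), c(0.5, 0.5))$loss_x, 2 * log(0.5),
               tolerance = 1e-12)
  # direct evaluation: mean(ln .8, ln .6) + mean(ln .7, ln .9)
  expect_equal(gan_losses(c(0.8, 0.6), c(0.7, 0.9))$loss_x,
               -0.5980023, tolerance = 1e-6)
  expect_error(gan_losses(numeric(0), c(0.5)), "empty batch")
})

test_that("gan_losses matches an independent log-sum oracle on random batches", {
  set.seed(21)
  for (rep in 1:20) {
    nr <- sample(1:8, 1); nf <- sample(1:8, 1); K <- sample(2:4, 1)
    pr <- runif(nr); pf <- runif(nf)
    Pr <- matrix(runif(nr * K), nr); Pr <- Pr / rowSums(Pr)
    Pf <- matrix(runif(nf * K), nf); Pf <- Pf / rowSums(Pf)
    cls <- paste0("c", 1:K)
    colnames(Pr) <- cls; colnames(Pf) <- cls
    tr <- sample(cls, nr, TRUE); tf <- sample(cls, nf, TRUE)
    got <- gan_losses(pr, pf, list(probs = Pr, classes = tr),
                      list(probs = Pf, classes = tf))
    # oracle: explicit sums of logs
    ox <- sum(log(pr)) / nr + sum(log(pf)) / nf
    oc <- sum(log(Pr[cbind(1:nr, match(tr, cls))])) / nr +
      sum(log(Pf[cbind(1:nf, match(tf, cls))])) / nf
    expect_equal(got$loss_x, ox, tolerance = 1e-10)
    expect_equal(got$loss_c, oc, tolerance = 1e-10)
  }
})

test_that("both losses are log-probabilities: never positive", {
  set.seed(3)
  for (rep in 1:10) {
    l <- gan_losses(runif(5), runif(5))
    expect_lte(l$loss_x, 0)
  }
})

test_that("training smoke contract: one epoch, recorded history, class coverage", {
  ds <- simulate_expression(sim_config(p = 4, n_per_class = 4,
                                       n_informative = 0, seed = 1))
  m <- train_gan(ds$matrix, ds$labels, gan_config(epochs = 1, seed = 1))
  expect_s3_class(m, "gan_model")
  expect_identical(nrow(m$loss_history), 1L)
  expect_true(all(is.finite(unlist(m$loss_history))))
  expect_error(generate_samples(m, "NOPE", 3), "not seen")
  # a class with a single member cannot anchor class-conditional synthesis
  idx <- c(1, 2, 5)
  expect_error(train_gan(ds$matrix[, idx], ds$labels[idx],
                         gan_config(epochs = 1)), ">= 2 samples")
})

test_that("generation respects shape, origin flags, scale and determinism", {
  ds <- simulate_expression(sim_config(p = 10, n_per_class = 10,
                                       n_informative = 5, effect = 2, seed = 6))
  m <- train_gan(ds$matrix, ds$labels, gan_config(epochs = 300, seed = 6))
  g0 <- generate_samples(m, "OVT", 0)
  expect_identical(nrow(g0), 0L)
  g <- generate_samples(m, "OVT", 50, seed = 2)
  expect_identical(dim(g), c(50L, 10L))
  expect_identical(attr(g, "origin"), "synthetic")
  expect_identical(colnames(g), rownames(ds$matrix))
  expect_identical(generate_samples(m, "OVT", 50, seed = 2), g)
  expect_false(identical(generate_samples(m, "OVT", 50, seed = 3), g))
})

test_that("two training seeds give different parameters that both fit a single-class fixture", {
  set.seed(9)
  X <- matrix(rnorm(2 * 200, mean = c(3, -1), sd = 1), 2, 200,
              dimnames = list(c("gA", "gB"), paste0("s", 1:200)))
  y <- factor(rep("only", 200)); names(y) <- colnames(X)
  errs <- sapply(1:3, function(s) {
    m <- train_gan(X, y, gan_config(seed = s, epochs = 2000))
    g <- generate_samples(m, "only", 400, seed = 1)
    max(abs(colMeans(g) - rowMeans(X)) / apply(X, 1, sd))
  })
  expect_lte(stats::median(errs), 0.25)
  m1 <- train_gan(X, y, gan_config(seed = 1, epochs = 50))
  m2 <- train_gan(X, y, gan_config(seed = 2, epochs = 50))
  expect_false(identical(m1$generator, m2$generator))
})

test_that("discriminator-confidence filtering with an uninformative class head comes up short", {
  ds <- simulate_expression(sim_config(p = 3, n_per_class = 5,
                                       n_informative = 0, seed = 2))
  m <- train_gan(ds$matrix, ds$labels,
                 gan_config(epochs = 1, filter_threshold = 0.9, seed = 2))
  # force a uniform class head: acceptance probability per draw ~ 0 at 0.9
  m$discriminator$cls$W[] <- 0
  m$discriminator$cls$b[] <- 0
  expect_warning(g <- generate_samples(m, "OVT", 25, seed = 1), "filter kept")
  expect_lt(nrow(g), 25)
})

test_that("a lone discriminator drives loss_x up on separable sources", {
  set.seed(4)
  X_real <- matrix(rnorm(40 * 3, mean = 2), 40, 3)
  X_fake <- matrix(rnorm(40 * 3, mean = -2), 40, 3)
  y <- factor(rep(c("a", "b"), 20))
  hist <- ovaboost:::train_discriminator_only(
    X_real, X_fake, y, y, gan_config(epochs = 60, instance_noise = 0, seed = 1)
  )$loss_x_history
  win <- sapply(seq(5, 60, by = 5), function(e) mean(hist[(e - 4):e]))
  expect_true(all(diff(win) > -1e-6))
  expect_gt(hist[60], hist[1])
})
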