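ns <- asNamespace("nirscgan")

# An untrained model with seeded random weights, for forward-pass contracts.
make_untrained_cgan <- function(seed = 1, cfg = cgan_config(latent_dim = 16,
                                                            gen_filters = c(8, 6),
                                                            disc_filters = c(6, 8))) {
  mdl <- withr::with_seed(seed, ns$cgan_init_params(cfg))
  structure(list(generator = mdl$g, discriminator = mdl$d,
                 g_state = mdl$g_state, geom = mdl$geom, config = cfg,
                 latent_dim = cfg$latent_dim, n_classes = 3L,
                 history = tibble::tibble()),
            class = "cgan_model")
}

test_that("generator inference is deterministic, bounded and correctly shaped", {
  m <- make_untrained_cgan()
  z <- withr::with_seed(2, rnorm(16))
  for (lab in c("RHT", "LHT", "FT")) {
    out1 <- generator_forward(m, z, lab)
    out2 <- generator_forward(m, z, lab)
    expect_identical(out1, out2)
    expect_equal(dim(out1), c(28, 28))
    expect_gt(min(out1), -1)
    expect_lt(max(out1), 1)
  }
  # conditioning enters the forward pass: labels change the output
  expect_false(identical(generator_forward(m, z, "RHT"),
                         generator_forward(m, z, "FT")))
  expect_error(generator_forward(m, rnorm(5), "RHT"), "length")
})

test_that("discriminator outputs calibrated probabilities", {
  m <- make_untrained_cgan()
  img <- matrix(runif(784), 28, 28)
  p1 <- discriminator_forward(m, img, "RHT")
  expect_identical(p1, discriminator_forward(m, img, "RHT"))
  expect_gt(p1, 0); expect_lt(p1, 1)
  # all-zero weights -> logit 0 -> exactly 1/2
  m0 <- m
  m0$discriminator <- lapply(m0$discriminator, function(p) p * 0)
  expect_equal(discriminator_forward(m0, img, "LHT"), 0.5)
  expect_error(discriminator_forward(m, matrix(0, 10, 10), "RHT"), "28 x 28")
})

test_that("synthesis allocates class-balanced counts by the declared rule", {
  m <- make_untrained_cgan()
  g1 <- synthesize(m, 90, 1.1, seed = 7)
  expect_length(g1, 99)
  expect_equal(as.vector(table(dataset_labels(g1))), rep(33L, 3))
  g2 <- synthesize(m, 90, 0.1, seed = 7)
  expect_length(g2, 9)
  expect_equal(as.vector(table(dataset_labels(g2))), rep(3L, 3))
  # remainder round-robin by class code: 10 -> 4 RHT, 3 LHT, 3 FT
  g3 <- synthesize(m, 10, 1, seed = 7)
  expect_equal(as.vector(table(dataset_labels(g3))), c(4L, 3L, 3L))
  expect_length(synthesize(m, 90, 0, seed = 7), 0)
  expect_error(synthesize(m, 90, -0.1), ">= 0")

  expect_true(all(dataset_provenance(g1) == "generated"))
  px <- g1$images[[1]]$pixels
  expect_true(all(px >= 0 & px <= 1))

  # identical seeds give bit-identical images; different seeds differ
  g4 <- synthesize(m, 90, 0.1, seed = 7)
  expect_identical(lapply(g2$images, `[[`, "pixels"),
                   lapply(g4$images, `[[`, "pixels"))
  g5 <- synthesize(m, 90, 0.1, seed = 8)
  expect_false(identical(lapply(g2$images, `[[`, "pixels"),
                         lapply(g5$images, `[[`, "pixels")))
})

test_that("short adversarial training is finite, seeded, and keeps honest books", {
  ds <- toy_images(10, seed = 3)
  cfg <- cgan_config(latent_dim = 16, gen_filters = c(8, 6),
                     disc_filters = c(6, 8), batch_size = 16, steps = 25,
                     seed = 5)
  m1 <- suppressWarnings(train_cgan(ds, cfg))
  h <- tidy(m1)
  expect_equal(nrow(h), 25)
  expect_true(all(is.finite(as.matrix(h[, -1]))))
  # the two discriminator batch losses sum to the negated empirical value
  # function of the minimax objective
  expect_equal(h$d_loss_real + h$d_loss_fake, -h$value_fn, tolerance = 1e-12)
  expect_equal(h$d_loss, h$d_loss_real + h$d_loss_fake, tolerance = 1e-12)

  # seeded end-to-end reproducibility, through to generated image hashes
  m2 <- suppressWarnings(train_cgan(ds, cfg))
  expect_identical(m1$generator, m2$generator)
  s1 <- synthesize(m1, 30, 0.5, seed = 11)
  s2 <- synthesize(m2, 30, 0.5, seed = 11)
  expect_identical(lapply(s1$images, `[[`, "pixels"),
                   lapply(s2$images, `[[`, "pixels"))

  two_class <- gasf_dataset(ds$images[dataset_labels(ds) != "FT"], "train")
  expect_error(train_cgan(two_class, cfg), "three classes")
})

test_that("a trained generator produces class-faithful, diverse images", {
  ds <- toy_images(12, seed = 6, noise = 0.08)
  cfg <- cgan_config(steps = 250, batch_size = 32, seed = 9)
  m <- train_cgan(ds, cfg)
  # near convergence the discriminator hovers around 1/2 on balanced batches
  expect_gte(mean(tail(tidy(m)$d_accuracy, 50)), 0.25)
  expect_lte(mean(tail(tidy(m)$d_accuracy, 50)), 0.75)

  oracle <- nearest_centroid_fit(ds)
  gen <- synthesize(m, length(ds), 3, seed = 10)  # 108 samples
  expect_gte(length(gen), 100)
  fidelity <- mean(oracle(gen$images) == dataset_labels(gen))
  expect_gt(fidelity, 1 / 3)

  div <- diversity_report(gen, seed = 1)
  expect_true(all(div$mean_ms_ssim < 0.98))
})

test_that("a small discriminator recovers the known density ratio on a 1-D toy problem", {
  # equal-variance Gaussians: the optimal discriminator
  # p_r / (p_r + p_g) is known in closed form
  mu_r <- -1; mu_g <- 1; s <- 1
  withr::with_seed(12, {
    xr <- rnorm(3000, mu_r, s)
    xg <- rnorm(3000, mu_g, s)
  })
  dfun <- toy_discriminator(xr, xg, hidden = 16, steps = 1500, seed = 13)
  grid <- seq(-3, 3, by = 0.05)
  truth <- stats::dnorm(grid, mu_r, s) /
    (stats::dnorm(grid, mu_r, s) + stats::dnorm(grid, mu_g, s))
  expect_lt(mean(abs(dfun(grid) - truth)), 0.05)
})
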