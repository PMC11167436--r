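# Unit tests use a throwaway micro-configuration (16x16 inputs, 2
# epochs); cohort-level behavior is covered by the acceptance suite.

tiny_patches <- function(n_subj_per_class = 2, per_subject = 4, P = 16,
                         seed = 1) {
  set.seed(seed)
  out <- list()
  for (cl in c("disease", "control")) for (s in seq_len(n_subj_per_class)) {
    base <- if (cl == "disease") 0.7 else 0.3
    for (k in seq_len(per_subject)) {
      px <- array(pmin(1, pmax(0, rnorm(P * P * 3, base, 0.1))), c(P, P, 3))
      out[[length(out) + 1L]] <- list(pixels = px, origin = c(row = 0, col = 0),
                                      tissue_fraction = 1,
                                      parent = sprintf("%s%d", cl, s), label = cl)
    }
  }
  out
}

tiny_config <- function(seed = 1, epochs = 2)
  cnn_config(input_size = 16, channels = c(2, 3), feature_width = 4,
             epochs = epochs, batch_size = 4, seed = seed)

test_that("softmax probabilities are a proper distribution", {
  m <- train_classifier(tiny_patches(), tiny_config())
  px <- tiny_patches()[[1]]$pixels
  pr <- predict_patch(m, px)
  expect_equal(sum(pr$probs), 1, tolerance = 1e-6)
  expect_true(pr$disease_probability >= 0 && pr$disease_probability <= 1)
  expect_identical(predict_patch(m, px), predict_patch(m, px))
})

test_that("pre-final features are nonnegative and reproduce the logits", {
  m <- train_classifier(tiny_patches(), tiny_config())
  f <- extract_features(m, tiny_patches()[[3]]$pixels)
  expect_length(f$vector, 4)
  expect_true(all(f$vector >= 0))
  relogit <- as.numeric(crossprod(m$par$Wd, f$vector)) + m$par$bd
  expect_equal(relogit, f$logits, tolerance = 1e-10)
})

test_that("the split manifest is subject-level and seed-deterministic", {
  p <- tiny_patches(n_subj_per_class = 5)
  m1 <- train_classifier(p, tiny_config(seed = 11, epochs = 1))
  m2 <- train_classifier(p, tiny_config(seed = 11, epochs = 1))
  m3 <- train_classifier(p, tiny_config(seed = 12, epochs = 1))
  expect_identical(m1$split, m2$split)
  expect_false(identical(m1$split, m3$split))
  tab <- table(m1$split$label, m1$split$role)
  expect_true(all(tab[, "validation"] >= 1))
  expect_true(all(tab[, "train"] >= 1))
})

test_that("single-class input and too-few subjects are rejected", {
  p <- tiny_patches()
  only_d <- Filter(function(x) x$label == "disease", p)
  expect_error(train_classifier(only_d, tiny_config()), "both classes")
  few <- Filter(function(x) x$parent %in% c("disease1", "control1", "control2"), p)
  expect_error(train_classifier(few, tiny_config()), "2 subjects")
})

test_that("analytic gradients match finite differences", {
  set.seed(21)
  cfg <- cnn_config(input_size = 8, channels = c(2, 2), feature_width = 3,
                    epochs = 1, seed = 21)
  par <- eedomics:::init_cnn(cfg)
  idx <- eedomics:::make_idx(cfg)
  x <- array(rnorm(8 * 8 * 3, 0, 0.5), c(8, 8, 3))
  loss_at <- function(par) {
    fwd <- eedomics:::cnn_forward(par, x, idx)
    -log(fwd$probs[1])
  }
  fwd <- eedomics:::cnn_forward(par, x, idx, keep_cache = TRUE)
  g <- eedomics:::cnn_backward(par, fwd, 1L, idx)
  h <- 1e-5
  for (nm in c("W1", "W3", "Wd", "b2", "bd")) {
    for (probe in seq_len(min(4, length(par[[nm]])))) {
      i <- if (probe == 1) 1 else sample(length(par[[nm]]), 1)
      pp <- par; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- par; pm[[nm]][i] <- pm[[nm]][i] - h
      num <- (loss_at(pp) - loss_at(pm)) / (2 * h)
      expect_equal(g[[nm]][i], num, tolerance = 1e-3)
    }
  }
})

test_that("saliency maps are normalized, class-sensitive and patch-sized", {
  m <- get_test_model()
  patches <- get_test_patches()
  dis <- Filter(function(p) p$label == "disease", patches)[[1]]
  g <- gradcam(m, dis$pixels, "disease")
  expect_equal(dim(g$heat), c(64, 64))
  expect_gte(min(g$heat), 0)
  expect_lte(max(g$heat), 1)
  g2 <- gradcam(m, dis$pixels, "control")
  expect_false(identical(g$heat, g2$heat))
  expect_error(gradcam(m, dis$pixels, "lesional"), "unknown class")
})

test_that("model checkpoints round-trip with a JSON sidecar", {
  m <- train_classifier(tiny_patches(), tiny_config())
  f <- withr::local_tempfile(fileext = ".rds")
  save_histo_model(m, f)
  back <- load_histo_model(f)
  px <- tiny_patches()[[2]]$pixels
  expect_identical(predict_patch(back, px), predict_patch(m, px))
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$config$input_size, 16)
  expect_length(side$split, nrow(m$split))
  saveRDS(1:3, f)
  expect_error(load_histo_model(f), "not a histo_model")
})

test_that("evaluation produces a coherent confusion matrix", {
  m <- train_classifier(tiny_patches(), tiny_config())
  p <- tiny_patches()
  ev <- evaluate(m, p)
  expect_equal(dim(ev$confusion), c(2, 2))
  expect_equal(sum(ev$confusion), length(p))
  expect_equal(ev$accuracy,
               sum(diag(ev$confusion)) / sum(ev$confusion))
  expect_error(evaluate(m, list()), "no patches")
})
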