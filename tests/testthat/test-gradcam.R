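test_that("channel weights are length-averaged gradients", {
  # y = sum of all activations: every partial is 1, so every weight is 1
  A <- matrix(stats::runif(12), 4, 3)
  rec <- list(A = A, grad = matrix(1, 4, 3))
  expect_equal(channel_weights(rec), rep(1, 3))
  # score independent of a channel: zero weight for it
  g <- matrix(1, 4, 3)
  g[, 2] <- 0
  expect_equal(channel_weights(list(A = A, grad = g)), c(1, 0, 1))
  expect_error(channel_weights(list(A = A, grad = matrix(1, 2, 3))),
               "shape")
  expect_error(channel_weights(list(grad = matrix(0, 0, 3))), "zero-length")
})

test_that("the localization map is the ReLU of the weighted map sum", {
  expect_equal(compute_cam(1, matrix(c(-1, 2, 0), 3, 1)), c(0, 2, 0))
  expect_equal(compute_cam(c(0, 0), matrix(stats::runif(10), 5, 2)),
               rep(0, 5))
  A <- cbind(c(3, 0), c(1, 2))
  expect_equal(compute_cam(c(1, -1), A), c(2, 0))
  expect_error(compute_cam(c(1, 2, 3), A), "mismatch")
})

test_that("backprop channel weights match finite differences", {
  # toy 2-channel encoder: perturb the last-conv activations directly and
  # difference the class logit
  model <- make_tiny_model(seed = 31L)
  model$params$protein <- ns$protein_init(
    protein_cnn_config(32L, embed_dim = 8L, kernel = 2L, channels = 2L,
                       fc_dim = 10L, output_dim = 12L, dropout = 0))
  model$config$protein <- protein_cnn_config(
    32L, embed_dim = 8L, kernel = 2L, channels = 2L, fc_dim = 10L,
    output_dim = 12L, dropout = 0)
  set.seed(32)
  pcfg <- model$config$protein
  # full-length sequence: no zero-pad plateau, so activations are generic
  # and finite differences are valid (no max-pool ties)
  full_seq <- paste(sample(c("A", "R", "N", "D", "K", "W", "H", "E"),
                           30L, replace = TRUE), collapse = "")
  tok <- tokenize(full_seq, model$token_vocab, 32L)
  # a positive last-conv bias keeps activations off the ReLU clip plateau,
  # where tied zeros would invalidate the finite-difference comparison
  model$params$protein$conv3$b <- model$params$protein$conv3$b + 1
  h <- decompose("Cc1ccccc1")
  cls <- 1L

  cb <- ns$hgcn_batch(list(h), model$atom_vocab)
  comp <- ns$hgcn_forward(model$params$compound, model$buffers$compound,
                          cb, model$config$hgcn, training = FALSE)
  prot <- ns$protein_forward(model$params$protein,
                             matrix(tok$ids, nrow = 1), pcfg,
                             training = FALSE)
  # logit as a function of the last-conv activation map
  logit_from_A <- function(A) {
    p2 <- ns$maxpool_forward(A, prot$cache$im$p2)
    L5 <- pcfg$lengths[5]
    arr <- array(t(p2$out), dim = c(pcfg$channels, L5, 1))
    flat <- t(matrix(arr, pcfg$channels * L5, 1))
    f1 <- ns$linear_forward(flat, model$params$protein$fc1$W,
                            model$params$protein$fc1$b)
    rf1 <- ns$relu_forward(f1$out)
    f2 <- ns$linear_forward(rf1$out, model$params$protein$fc2$W,
                            model$params$protein$fc2$b)
    hf <- ns$head_forward(model$params$head, cbind(comp$out, f2$out))
    hf$out[1, cls + 1L]
  }
  A <- prot$cache$A
  # analytic channel weights via the package backprop
  hf <- ns$head_forward(model$params$head, cbind(comp$out, prot$out))
  dlogits <- matrix(0, 1, 2)
  dlogits[1, cls + 1L] <- 1
  hb <- ns$head_backward(dlogits, hf, model$params$head)
  dprot <- hb$dX[, 12L + seq_len(12L), drop = FALSE]
  dA <- ns$protein_backward(dprot, prot, model$params$protein, pcfg,
                            to_conv3_only = TRUE)$dA
  alpha <- channel_weights(list(A = A, grad = dA))
  # central finite differences over every map element, channel-averaged
  eps <- 1e-5
  num_grad <- matrix(0, nrow(A), ncol(A))
  for (i in seq_len(nrow(A))) {
    for (k in seq_len(ncol(A))) {
      Ap <- A; Ap[i, k] <- A[i, k] + eps
      Am <- A; Am[i, k] <- A[i, k] - eps
      num_grad[i, k] <- (logit_from_A(Ap) - logit_from_A(Am)) / (2 * eps)
    }
  }
  expect_equal(alpha, colMeans(num_grad), tolerance = 1e-4)
})

test_that("explain returns masked, normalized per-residue saliency", {
  model <- make_tiny_model(seed = 33L)
  seqs <- c("MKWVHEHAHAKLMWQ", strrep("ARNDKW", 8)) # second one truncates
  for (s in seqs) {
    sal <- explain(model, "Cc1ccccc1", s, class = 1L)
    expect_s3_class(sal, "saliency_map")
    expect_true(all(sal$raw >= 0))
    n_res <- min(nchar(s), model$max_len - 2L)
    expect_length(sal$projected, n_res)
    expect_true(all(sal$projected >= 0 & sal$projected <= 1))
    expect_setequal(sal$highlighted,
                    which(sal$projected >= sal$threshold))
  }
  # threshold semantics on a known map
  expect_equal(which(c(0.1, 0.5, 0.9) >= 0.2), c(2L, 3L))
})

test_that("all-zero maps are flagged flat instead of divided", {
  model <- make_tiny_model(seed = 34L)
  # zero out the head so every logit gradient path vanishes
  model$params$head <- lapply(model$params$head, function(l) {
    list(W = l$W * 0, b = l$b * 0)
  })
  sal <- explain(model, "CCO", "MKWVHEHAHAKLMWQ")
  expect_true(sal$flat)
  expect_true(all(sal$projected == 0))
  expect_length(sal$highlighted, 0)
})

test_that("smaller kernels give finer-grained localization maps", {
  cfg6 <- protein_cnn_config(max_len = 300L, kernel = 6L)
  cfg12 <- protein_cnn_config(max_len = 300L, kernel = 12L)
  # map positions at the last convolutional layer
  expect_gt(cfg6$lengths[4], cfg12$lengths[4])
})

test_that("saliency tables and intervals export coherently", {
  model <- make_tiny_model(seed = 35L)
  sal <- explain(model, "Cc1ccccc1", "MKWVHEHAHAKLMWQ")
  tab <- saliency_table(sal)
  expect_equal(nrow(tab), length(sal$projected))
  expect_equal(tab$position, seq_along(sal$projected))
  expect_equal(which(tab$highlighted), sal$highlighted)
  iv <- saliency_intervals(sal)
  if (nrow(iv)) {
    covered <- unlist(Map(seq, iv$start, iv$end))
    expect_setequal(covered, sal$highlighted)
    expect_true(all(iv$start <= iv$end))
  }
})

test_that("saliency maps plot without error", {
  model <- make_tiny_model(seed = 36L)
  sal <- explain(model, "Cc1ccccc1", "MKWVHEHAHAKLMWQ")
  png_path <- tempfile(fileext = ".png")
  grDevices::png(png_path)
  expect_silent(plot(sal))
  grDevices::dev.off()
  expect_true(file.exists(png_path))
})
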