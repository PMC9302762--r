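test_that("conv_step matches hand-evaluated message passing", {
  d <- 3L
  ident_layer <- list(W = rbind(diag(d), diag(d)), b = rep(0, d))
  # isolated node: zero message, identity weights leave a one-hot unchanged
  h <- matrix(c(1, 0, 0), 1, 3)
  out <- conv_step(h, NULL, ident_layer)
  expect_equal(out, h)
  # two-node path: both nodes end at e1 + e2
  H <- rbind(c(1, 0, 0), c(0, 1, 0))
  edges <- rbind(c(1L, 2L), c(2L, 1L))
  out <- conv_step(H, edges, ident_layer)
  expect_equal(out, rbind(c(1, 1, 0), c(1, 1, 0)))
  # negative pre-activations are clipped to zero
  neg_layer <- list(W = rbind(diag(d), diag(d)), b = c(-2, 0, 0))
  out <- conv_step(h, NULL, neg_layer)
  expect_equal(out[1, 1], 0)
  # width mismatch is a shape error
  expect_error(conv_step(matrix(0, 1, 2), NULL, ident_layer),
               "incompatible")
})

test_that("max_pool_readout is the coordinate-wise maximum", {
  expect_equal(max_pool_readout(rbind(c(1, 0), c(0, 2))), c(1, 2))
  expect_equal(max_pool_readout(c(3, 1, 2)), c(3, 1, 2))
  v <- c(0.5, -1, 2)
  expect_equal(max_pool_readout(rbind(v, v, v)), v)
  expect_error(max_pool_readout(matrix(0, 0, 3)), "empty")
})

test_that("batched encoder matches the naive per-node loop oracle", {
  set.seed(42)
  cfg <- hgcn_config(initial_dim = 6L, output_dim = 9L)
  vocab <- c("C", "N", "O", "<unk>")
  params <- ns$hgcn_init(cfg, 4L)
  buffers <- ns$hgcn_buffers(cfg)
  graphs <- list()
  for (n in 2:4) {
    for (e in enumerate_connected_graphs(n)) {
      m <- nrow(e)
      graphs[[length(graphs) + 1L]] <- make_molgraph(
        n, e, aromatic = sample(c(TRUE, FALSE), m, replace = TRUE),
        elements = sample(c("C", "N", "O"), n, replace = TRUE))
    }
  }
  expect_gte(length(graphs), 40)
  for (g in graphs) {
    h <- decompose_molgraph(g)
    batch <- ns$hgcn_batch(list(h), vocab)
    got <- drop(ns$hgcn_forward(params, buffers, batch, cfg,
                                training = TRUE)$out)
    want <- naive_encode_compound(h, params, cfg, vocab)
    expect_equal(got, want, tolerance = 1e-5)
  }
})

test_that("compound embeddings are invariant to atom relabeling", {
  set.seed(3)
  cfg <- hgcn_config(initial_dim = 6L, output_dim = 9L)
  vocab <- c("C", "N", "O", "<unk>")
  params <- ns$hgcn_init(cfg, 4L)
  buffers <- ns$hgcn_buffers(cfg)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    es <- enumerate_connected_graphs(n)
    e <- es[[sample(length(es), 1)]]
    arom <- sample(c(TRUE, FALSE), nrow(e), replace = TRUE)
    elem <- sample(c("C", "N", "O"), n, replace = TRUE)
    g <- make_molgraph(n, e, arom, elem)
    perm <- sample(n)
    g_perm <- make_molgraph(n, cbind(perm[e[, 1]], perm[e[, 2]]), arom,
                            elem[order(perm)])
    b1 <- ns$hgcn_batch(list(decompose_molgraph(g)), vocab)
    b2 <- ns$hgcn_batch(list(decompose_molgraph(g_perm)), vocab)
    v1 <- drop(ns$hgcn_forward(params, buffers, b1, cfg, TRUE)$out)
    v2 <- drop(ns$hgcn_forward(params, buffers, b2, cfg, TRUE)$out)
    expect_equal(v1, v2, tolerance = 1e-5)
  }
})

test_that("atom-level message passing stays within substructures", {
  # biphenyl: the two rings share no atom; perturbing a ring-1 atom must not
  # move ring-2 pre-readout states (evaluation mode, fixed buffers)
  set.seed(5)
  cfg <- hgcn_config(initial_dim = 6L, output_dim = 9L)
  vocab <- c("C", "N", "O", "<unk>")
  params <- ns$hgcn_init(cfg, 4L)
  buffers <- ns$hgcn_buffers(cfg)
  h <- decompose("c1ccccc1-c1ccccc1")
  sizes <- vapply(h$substructures, function(s) nrow(s$atoms), 0L)
  rings <- which(sizes == 6L)
  h2 <- h
  h2$substructures[[rings[1]]]$atoms$element[2] <- "N"
  states <- function(hh) {
    b <- ns$hgcn_batch(list(hh), vocab)
    f <- ns$hgcn_forward(params, buffers, b, cfg, training = FALSE)
    f$cache$atom_caches[[cfg$atom_steps]]$out[b$sub_atom_rows[[rings[2]]], ]
  }
  expect_equal(states(h), states(h2))
})

test_that("duplicated atom copies diverge when their neighborhoods differ", {
  set.seed(6)
  cfg <- hgcn_config(initial_dim = 6L, output_dim = 9L)
  vocab <- c("C", "N", "O", "<unk>")
  params <- ns$hgcn_init(cfg, 4L)
  buffers <- ns$hgcn_buffers(cfg)
  h <- decompose("Cc1ccccc1")
  shared <- intersect(h$substructures[[1]]$atoms$orig,
                      h$substructures[[2]]$atoms$orig)
  b <- ns$hgcn_batch(list(h), vocab)
  f <- ns$hgcn_forward(params, buffers, b, cfg, training = FALSE)
  H1 <- f$cache$atom_caches[[1]]$out
  rows <- vapply(1:2, function(si) {
    b$sub_atom_rows[[si]][match(shared,
                                h$substructures[[si]]$atoms$orig)]
  }, 0L)
  expect_gt(max(abs(H1[rows[1], ] - H1[rows[2], ])), 1e-8)
})

test_that("embedding width equals output_dim and nosplit degenerates", {
  set.seed(7)
  cfg <- hgcn_config()
  vocab <- c("C", "N", "O", "Cl", "<unk>")
  params <- ns$hgcn_init(cfg, 5L)
  buffers <- ns$hgcn_buffers(cfg)
  for (smi in c("CCO", "Cc1ccccc1", "[Na+].CCO")) {
    v <- encode_compound(decompose(smi), params, cfg, vocab, buffers)
    expect_length(v, 128L)
  }
  # benzene is a single aromatic substructure: split and nosplit agree
  h <- decompose("c1ccccc1")
  v_split <- encode_compound(h, params, cfg, vocab, buffers)
  cfg_ns <- hgcn_config(nosplit = TRUE)
  v_nosplit <- encode_compound(h, params, cfg_ns, vocab, buffers)
  expect_equal(v_split, v_nosplit, tolerance = 1e-10)
})

test_that("encoder backprop matches numerical gradients", {
  set.seed(21)
  cfg <- hgcn_config(initial_dim = 4L, output_dim = 5L)
  vocab <- c("C", "N", "O", "<unk>")
  params <- ns$hgcn_init(cfg, 4L)
  buffers <- ns$hgcn_buffers(cfg)
  batch <- ns$hgcn_batch(list(decompose("Cc1ccccc1"), decompose("CCO")),
                         vocab)
  w <- stats::rnorm(2L * cfg$output_dim)
  loss <- function(p) {
    sum(ns$hgcn_forward(p, buffers, batch, cfg, training = TRUE)$out * w)
  }
  fwd <- ns$hgcn_forward(params, buffers, batch, cfg, training = TRUE)
  grads <- ns$hgcn_backward(matrix(w, 2, cfg$output_dim), fwd, cfg)
  eps <- 1e-6
  check <- function(get, set, g) {
    arr <- get(params)
    for (k in sample(length(arr), min(4, length(arr)))) {
      pp <- params; arr2 <- arr; arr2[k] <- arr[k] + eps; pp <- set(pp, arr2)
      pm <- params; arr2 <- arr; arr2[k] <- arr[k] - eps; pm <- set(pm, arr2)
      num <- (loss(pp) - loss(pm)) / (2 * eps)
      expect_equal(num, g[k], tolerance = 1e-5)
    }
  }
  check(function(p) p$embed,
        function(p, a) {p$embed <- a; p}, grads$embed)
  check(function(p) p$atom_layers[[1]]$W,
        function(p, a) {p$atom_layers[[1]]$W <- a; p},
        grads$atom_layers[[1]]$W)
  check(function(p) p$atom_layers[[2]]$gamma,
        function(p, a) {p$atom_layers[[2]]$gamma <- a; p},
        grads$atom_layers[[2]]$gamma)
  check(function(p) p$sub_layers[[1]]$W,
        function(p, a) {p$sub_layers[[1]]$W <- a; p},
        grads$sub_layers[[1]]$W)
})
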