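test_that("leaky ReLU follows the two-branch definition", {
  expect_equal(leaky_relu(2), 2)
  expect_equal(leaky_relu(0), 0)
  expect_equal(leaky_relu(-1), -0.01)
  x <- matrix(c(-2, -0.5, 0, 0.5, 2, -10), 2, 3)
  expect_equal(leaky_relu(x), ifelse(x > 0, x, 0.01 * x))
})

test_that("commutative reduction concatenates max, sum and average", {
  v <- c(1.5, -2, 0)
  expect_equal(commutative_reduce(list(v)), c(v, v, v))
  expect_equal(commutative_reduce(list(c(1, 2), c(3, 0))),
               c(3, 2, 4, 2, 2, 1))
  expect_equal(commutative_reduce(list(), width = 4), numeric(12))
  expect_error(commutative_reduce(list(c(1, 2), c(1, 2, 3))))
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(3); y <- rnorm(3)
    expect_equal(commutative_reduce(list(x, y)),
                 commutative_reduce(list(y, x)))
  }
})

test_that("conv_transform equals the explicit affine-plus-activation map", {
  # zero weights: output is f(b)
  W0 <- matrix(0, 3, 7)
  expect_equal(conv_transform(c(1, -1), c(0, 1, 0, 2, 0), W0, c(0.1, 0, -5)),
               c(0.1, 0, -0.05))
  # identity weights, nonnegative input: concat passes through
  x <- c(0.5, 0.2); p <- c(1, 0, 0, 1.54, 1)
  expect_equal(conv_transform(x, p, diag(7), numeric(7)), c(x, p))
  # random case against scalar-loop oracle
  set.seed(21)
  W <- matrix(rnorm(21), 3, 7); b <- c(0.1, 0, -5)
  got <- conv_transform(c(1, -1), c(0, 1, 0, 2, 0), W, b)
  want <- naive_leaky(naive_affine(W, c(1, -1, 0, 1, 0, 2, 0), b))
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(conv_transform(c(1, 2, 3), p, W, b), "width")
})

test_that("conv_layer concatenates the reduction and respects the width rule", {
  g <- build_graph(mol_ethane())
  states <- matrix(rnorm(2 * 4, 0.5), 2, 4)
  set.seed(3)
  W <- matrix(rnorm(3 * 9, sd = 0.3), 3, 9); b <- rnorm(3)
  out <- conv_layer(states, g, W, b)$states
  expect_equal(dim(out), c(2, 4 + 3 * 3))

  # isolated atom: reduction block is zero (before normalization identity)
  he <- build_graph(mol_helium())
  s1 <- matrix(c(1, 2, 3, 4), 1, 4)
  o1 <- conv_layer(s1, he, W, b, bn_eps = 0)$states
  expect_equal(o1[1, 5:13], numeric(9))

  # two-atom molecule against the composed naive oracle
  d_t <- nrow(W)
  want <- t(vapply(1:2, function(a) {
    other <- 3 - a
    tr <- naive_leaky(naive_affine(W, c(states[other, ],
                                        g$edges$pair[g$edges$center == a, ]),
                                   b))
    c(states[a, ], naive_reduce(list(tr), d_t))
  }, numeric(13)))
  got <- conv_layer(states, g, W, b, bn_eps = 0)$states
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("atom-state widths follow d[k+1] = d[k] + 3 * d_transform", {
  for (tw in list(c(8L), c(8L, 16L), c(4L, 4L, 4L), c(32L, 8L, 2L, 64L))) {
    cfg <- network_config(n_conv_layers = length(tw), transform_widths = tw,
                          head_widths = 8L)
    w <- molgcn:::conv_widths(cfg)
    expect_equal(w[1], 33L)
    for (k in seq_along(tw)) expect_equal(w[k + 1], w[k] + 3L * tw[k])
    model <- gcn_init(cfg)
    g <- build_graph(mol_propane())
    fwd <- gcn_forward(model, pack_graphs(list(g)))
    expect_equal(ncol(fwd$emb), 3L * w[length(w)])
  }
})

test_that("pooling is the commutative reduction over atom rows", {
  expect_equal(pool_atoms(rbind(c(1, 2), c(3, 0))), c(3, 2, 4, 2, 2, 1))
  v <- c(0.3, -1, 2)
  expect_equal(pool_atoms(rbind(v)), c(v, v, v))
  set.seed(8)
  S <- matrix(rnorm(15), 5, 3)
  expect_equal(pool_atoms(S), pool_atoms(S[sample(5), ]))
  expect_error(pool_atoms(matrix(0, 0, 3)))
})

test_that("dense head is an affine stack with one output per task", {
  cfg <- network_config(n_conv_layers = 1, transform_widths = 2,
                        head_widths = 4, n_tasks = 3, seed = 11)
  model <- gcn_init(cfg)
  # zero weights everywhere: prediction equals the final bias
  for (nm in grep("^head", names(model$params), value = TRUE))
    model$params[[nm]][] <- 0
  model$params[["head2.b"]] <- c(1.5, -2, 0.25)
  emb <- rnorm(3 * molgcn:::conv_widths(cfg)[2])
  expect_equal(dense_head(emb, model), c(1.5, -2, 0.25))
  expect_length(dense_head(emb, model), 3L)
  expect_error(dense_head(emb[-1], model), "width")

  # single linear layer against a hand dot product
  cfg1 <- network_config(n_conv_layers = 0, transform_widths = integer(),
                         head_widths = integer(), n_tasks = 1)
  m1 <- gcn_init(cfg1)
  x <- rnorm(99)
  expect_equal(dense_head(x, m1),
               sum(m1$params[["head1.W"]] * x) + m1$params[["head1.b"]],
               ignore_attr = TRUE)
})

test_that("full forward matches the naive loop oracle on tiny molecules", {
  for (mol in list(mol_helium(), mol_ethane(), mol_propane(),
                   mol_cyclopropane())) {
    g <- build_graph(mol)
    cfg <- network_config(n_conv_layers = 2, transform_widths = c(3, 2),
                          head_widths = 5, n_tasks = 2, seed = 4)
    model <- randomize_model(gcn_init(cfg), seed = 17)
    got <- gcn_forward(model, pack_graphs(list(g)), mode = "eval")$pred
    want <- naive_forward(model, g)
    expect_equal(unname(got[1, ]), want, tolerance = 1e-6)
  }
})

test_that("eval-mode predictions are deterministic and permutation invariant", {
  mols <- fixture_mols(4, seed = 13, size_range = c(6L, 12L))
  cfg <- network_config(n_conv_layers = 2, transform_widths = 8,
                        head_widths = 16, seed = 2)
  model <- gcn_init(cfg)
  graphs <- lapply(mols, build_graph)
  p1 <- gcn_forward(model, pack_graphs(graphs))$pred
  p2 <- gcn_forward(model, pack_graphs(graphs))$pred
  expect_identical(p1, p2)
  set.seed(123)
  for (rep in 1:25) {
    i <- sample(length(mols), 1)
    perm <- sample(length(mols[[i]]$elements))
    gp <- build_graph(permute_molecule(mols[[i]], perm))
    pp <- gcn_forward(model, pack_graphs(list(gp)))$pred
    expect_lt(abs(pp[1, 1] - p1[i, 1]), 1e-4)
  }
})

test_that("eval predictions are independent of batch packing", {
  mols <- fixture_mols(6, seed = 19)
  model <- gcn_init(network_config(n_conv_layers = 2, transform_widths = 6,
                                   head_widths = 8, seed = 7))
  graphs <- lapply(mols, build_graph)
  packed <- gcn_forward(model, pack_graphs(graphs))$pred
  solo <- vapply(graphs, function(g)
    gcn_forward(model, pack_graphs(list(g)))$pred[1, 1], numeric(1))
  expect_equal(unname(packed[, 1]), solo, tolerance = 1e-5)
})

test_that("train-mode gradients agree with finite differences", {
  mols <- fixture_mols(3, seed = 23, size_range = c(4L, 6L))
  ex <- make_examples(mols, rnorm(3))
  b <- molgcn:::examples_batch(ex)
  model <- gcn_init(network_config(n_conv_layers = 2, transform_widths = 3,
                                   head_widths = 4, seed = 31))
  fwd <- gcn_forward(model, b, mode = "train", keep_cache = TRUE)
  dPred <- molgcn:::.mt_loss_grad(fwd$pred, b$labels, b$mask, 1)
  grads <- molgcn:::gcn_backward(model, fwd$cache, dPred)
  loss_at <- function(m) {
    f <- gcn_forward(m, b, mode = "train")
    as.numeric(mt_loss(f$pred, b$labels, b$mask))
  }
  set.seed(5)
  for (nm in names(model$params)) {
    ix <- sample(length(model$params[[nm]]), 1)
    eps <- 1e-5
    up <- model; up$params[[nm]][ix] <- up$params[[nm]][ix] + eps
    dn <- model; dn$params[[nm]][ix] <- dn$params[[nm]][ix] - eps
    num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
    expect_equal(grads[[nm]][ix], num, tolerance = 1e-4,
                 label = sprintf("gradient of %s[%d]", nm, ix))
  }
})

test_that("checkpoint round trip reproduces eval outputs bit for bit", {
  mols <- fixture_mols(3, seed = 37, size_range = c(5L, 8L))
  graphs <- lapply(mols, build_graph)
  model <- randomize_model(gcn_init(network_config(
    n_conv_layers = 2, transform_widths = 5, head_widths = 7,
    n_tasks = 2)), seed = 3)
  tmp <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(model, tmp)
  back <- load_checkpoint(tmp)
  expect_identical(gcn_forward(model, pack_graphs(graphs))$pred,
                   gcn_forward(back, pack_graphs(graphs))$pred)
})
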