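test_that("node grid has the triangular layout and exact parameter count", {
  set.seed(20)
  net4 <- build_network(network_spec(levels = 4, base_channels = 4))
  expect_length(net4$params$nodes, 10)  # 4 + 3 + 2 + 1
  expect_length(net4$params$heads, 4)

  # hand enumeration for the minimal 3-node grid (L = 2, 1 channel,
  # growth 1, attention off):
  #   X(0,0): conv 9+1, bn 2, conv 9+1, bn 2             = 24
  #   X(1,0): same                                        = 24
  #   X(0,1): up 1x1 1->1 (1+1), conv 9*2+1, bn 2,
  #           conv 9+1, bn 2                              = 35
  #   heads:  two 1x1 heads, (1+1) each                   =  4
  net2 <- build_network(network_spec(levels = 2, base_channels = 1,
                                     channel_growth = 1, attention = FALSE))
  expect_equal(parameter_count(net2), 87)

  # attention adds parameters; width increases them monotonically
  set.seed(20)
  n_att <- parameter_count(build_network(network_spec(levels = 3,
                                                      base_channels = 8)))
  set.seed(20)
  n_plain <- parameter_count(build_network(
    network_spec(levels = 3, base_channels = 8, attention = FALSE)))
  expect_gt(n_att, n_plain)
  set.seed(20)
  n_wide <- parameter_count(build_network(
    network_spec(levels = 3, base_channels = 16, attention = FALSE)))
  expect_gt(n_wide, n_plain)

  expect_error(network_spec(levels = 1), "levels")
  expect_error(network_spec(base_channels = 0), "base_channels")
})

test_that("probability pyramids obey the shape and range contract", {
  set.seed(21)
  net <- build_network(network_spec(levels = 4, base_channels = 2))
  x <- matrix(rnorm(64 * 64), 64, 64)
  pyr <- net_forward(net, x)[[1]]
  expect_equal(vapply(pyr, nrow, numeric(1)), c(64, 32, 16, 8))
  expect_equal(vapply(pyr, ncol, numeric(1)), c(64, 32, 16, 8))
  for (m in pyr) expect_true(all(m >= 0 & m <= 1 & is.finite(m)))

  # property: random valid sizes and depths
  for (rep in 1:4) {
    L <- sample(2:4, 1)
    f <- 2^(L - 1)
    H <- f * sample(2:4, 1); W <- f * sample(2:4, 1)
    netr <- build_network(network_spec(levels = L, base_channels = 2,
                                       attention = sample(c(TRUE, FALSE), 1)))
    pr <- net_forward(netr, matrix(rnorm(H * W), H, W))[[1]]
    expect_equal(vapply(pr, nrow, numeric(1)), H / 2^(0:(L - 1)))
    expect_equal(vapply(pr, ncol, numeric(1)), W / 2^(0:(L - 1)))
  }
  expect_error(net_forward(net, matrix(0, 60, 64)), "divisible")
})

test_that("inference is deterministic and attention preserves shapes", {
  set.seed(22)
  x <- matrix(rnorm(16 * 16), 16, 16)
  net <- build_network(network_spec(levels = 3, base_channels = 2))
  out <- net_forward(net, list(x, x))
  expect_identical(out[[1]], out[[2]])
  set.seed(22)
  net_a <- build_network(network_spec(levels = 3, base_channels = 2,
                                      attention = TRUE))
  set.seed(22)
  net_b <- build_network(network_spec(levels = 3, base_channels = 2,
                                      attention = FALSE))
  pa <- net_forward(net_a, x)[[1]]
  pb <- net_forward(net_b, x)[[1]]
  for (s in 1:3) expect_identical(dim(pa[[s]]), dim(pb[[s]]))
})

test_that("analytic gradients match finite differences everywhere", {
  set.seed(23)
  spec <- network_spec(levels = 2, base_channels = 2, attention = TRUE)
  net <- build_network(spec)
  H <- 8; W <- 8; N <- 2
  x <- matrix(rnorm(H * W * N), ncol = 1)
  y <- lapply(1:2, function(s) {
    hw <- (H / 2^(s - 1)) * (W / 2^(s - 1)) * N
    as.numeric(runif(hw) < 0.3)
  })
  lossfun <- function(nn) {
    fw <- perivox:::net_forward_full(nn, x, H, W, N, training = TRUE,
                                     keep_cache = TRUE)
    mean(vapply(1:2, function(s) {
      mean(perivox:::batch_dice_terms(as.vector(fw$probs[[s]]),
                                      y[[s]], N, 1)$loss)
    }, numeric(1)))
  }
  fw <- perivox:::net_forward_full(net, x, H, W, N, training = TRUE,
                                   keep_cache = TRUE)
  dl <- lapply(1:2, function(s) {
    p <- fw$probs[[s]]
    t <- perivox:::batch_dice_terms(as.vector(p), y[[s]], N, 1)
    matrix((1 / (2 * N)) * t$dldp * p * (1 - p), ncol = 1)
  })
  gr <- perivox:::net_backward_full(net, fw, dl)
  eps <- 1e-6
  paths <- list(c("nodes", "0_0", "W1"), c("nodes", "0_0", "g1"),
                c("nodes", "1_0", "W2"), c("nodes", "0_1", "W1"),
                c("nodes", "0_1", "A1"), c("nodes", "0_1", "A2"),
                c("ups", "0_1", "U"), c("heads", "0", "W"),
                c("heads", "1", "W"), c("nodes", "1_0", "be2"))
  for (pth in paths) {
    v <- net$params[[pth[1]]][[pth[2]]][[pth[3]]]
    i <- sample(length(v), 1)
    tmp <- net
    tmp$params[[pth[1]]][[pth[2]]][[pth[3]]][i] <- v[i] + eps
    up <- lossfun(tmp)
    tmp$params[[pth[1]]][[pth[2]]][[pth[3]]][i] <- v[i] - eps
    dn <- lossfun(tmp)
    expect_equal(gr[[pth[1]]][[pth[2]]][[pth[3]]][i], (up - dn) / (2 * eps),
                 tolerance = 1e-5,
                 label = paste(pth, collapse = "/"))
  }
})

test_that("every parameter receives gradient through some head", {
  set.seed(24)
  spec <- network_spec(levels = 3, base_channels = 2, attention = TRUE)
  net <- build_network(spec)
  H <- 16; W <- 16; N <- 2
  x <- matrix(rnorm(H * W * N), ncol = 1)
  fw <- perivox:::net_forward_full(net, x, H, W, N, training = TRUE,
                                   keep_cache = TRUE)
  dl <- lapply(1:3, function(s) {
    p <- fw$probs[[s]]
    hw <- length(p) / N
    y <- as.numeric(runif(length(p)) < 0.3)
    t <- perivox:::batch_dice_terms(as.vector(p), y, N, 1)
    matrix(t$dldp * p * (1 - p), ncol = 1)
  })
  gr <- perivox:::net_backward_full(net, fw, dl)
  walk <- function(g, path) {
    if (is.list(g)) {
      for (nm in names(g)) walk(g[[nm]], c(path, nm))
    } else {
      expect_true(any(g != 0), label = paste(path, collapse = "/"))
    }
  }
  walk(gr, "grads")
})

test_that("the network can overfit a single slice (capacity check)", {
  set.seed(25)
  img <- matrix(rnorm(16 * 16, sd = 0.3), 16, 16)
  lab <- matrix(0, 16, 16)
  lab[5:7, 4:11] <- 1
  lab[12, 13] <- 1
  img[lab == 1] <- img[lab == 1] + 3
  train <- rep(list(list(image = img, label = lab)), 4)
  cfg <- train_config(batch_size = 4, max_epochs = 200, select_epoch = 200,
                      seed = 1, checkpoint_every = 200)
  fit <- train_model(train, spec = network_spec(levels = 3,
                                                base_channels = 4),
                     config = cfg)
  expect_lt(min(fit$history$train_loss), 0.05)
})
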