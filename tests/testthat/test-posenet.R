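test_that("joint sets round-trip between polar and Cartesian", {
  set.seed(2)
  r <- runif(6, 0.8, 1.6); phi <- runif(6, -1, 1); th <- runif(6, -1, 1)
  js <- joint_set(r, phi, th)
  back <- joint_set_from_xyz(as.matrix(js[, c("x", "y", "z")]))
  expect_lt(max(abs(back$r - r)), 1e-9)
  expect_lt(max(abs(back$phi - phi)), 1e-9)
  expect_lt(max(abs(back$theta - th)), 1e-9)
})

test_that("the angular loss measures the mean direction error", {
  js <- joint_set(rep(1.2, 6), seq(-0.3, 0.2, by = 0.1),
                  seq(0.2, -0.3, by = -0.1))
  expect_equal(angular_loss(js, js), 0)

  # rotate one joint by 2 degrees about the origin (within the plane
  # spanned by the joint direction and an orthogonal axis, so the
  # direction change is exactly 2 degrees): loss = 2/6 degrees
  a <- 2 * pi / 180
  xyz <- as.matrix(js[, c("x", "y", "z")])
  v <- xyz[3, ]
  w <- c(-v[2], v[1], 0); w <- w / sqrt(sum(w^2)) * sqrt(sum(v^2))
  xyz[3, ] <- cos(a) * v + sin(a) * w
  rot <- joint_set_from_xyz(xyz)
  expect_equal(angular_loss(js, rot), 2 / 6, tolerance = 1e-9)
  expect_equal(angular_loss(rot, js), angular_loss(js, rot))

  # x-z plane MAE: constant 5 cm offset in x gives 5 cm for every joint
  off <- js; off$x <- off$x + 0.05
  expect_equal(unname(xz_mae(list(js), list(off))), rep(5, 6),
               tolerance = 1e-9)
  expect_equal(unname(xz_mae(list(js), list(js))), rep(0, 6))
})

test_that("target encoding round-trips exactly", {
  set.seed(4)
  jl <- lapply(1:5, function(i)
    joint_set(runif(6, 0.9, 1.5), runif(6, -0.5, 0.5),
              runif(6, -0.4, 0.4)))
  enc <- encode_joint_targets(jl)
  # invert the squashing map so decode reproduces the encoded joints
  cc <- sqrt(0.995)
  den <- sqrt(1 - (enc$u^2 + enc$v^2) / cc^2)
  out <- matrix(0, 18, 5)
  iu <- seq(1, 16, by = 3)
  out[iu, ] <- enc$u / cc / den
  out[iu + 1, ] <- enc$v / cc / den
  out[iu + 2, ] <- enc$rn
  dec <- decode_joint_outputs(out, enc$r_mean, enc$r_sd)
  for (i in 1:5) {
    expect_lt(max(abs(dec[[i]]$r - jl[[i]]$r)), 1e-9)
    expect_lt(angular_loss(jl[[i]], dec[[i]]), 1e-6)
  }
})

test_that("network analytic gradients match finite differences", {
  shapes <- list(c(3, 10, 12), c(3, 12, 14))
  set.seed(5)
  bs <- 3
  x1 <- matrix(rnorm(prod(shapes[[1]]) * bs), ncol = bs)
  x2 <- matrix(rnorm(prod(shapes[[2]]) * bs), ncol = bs)
  eps <- 1e-6

  for (head in c("classification", "regression")) {
    cfg <- forked_net_config(shapes, conv_filters = c(4, 5, 6),
                             mlp = c(16, 12, 8, 6), dropout = c(0, 0),
                             head = head)
    net <- build_forked_net(cfg, seed = 4)
    if (head == "classification") {
      y <- c(1L, 3L, 2L)
      lossfun <- function(nn) {
        fw <- net_forward(nn, list(x1 = x1, x2 = x2))
        radarvitals:::loss_classification(fw$out, y)$loss
      }
      lgrad <- function(out) radarvitals:::loss_classification(out, y)
    } else {
      set.seed(6)
      y <- list(u = matrix(runif(18, -0.5, 0.5), 6, bs),
                v = matrix(runif(18, -0.5, 0.5), 6, bs),
                rn = matrix(rnorm(18), 6, bs))
      lossfun <- function(nn) {
        fw <- net_forward(nn, list(x1 = x1, x2 = x2))
        radarvitals:::loss_regression(fw$out, y)$loss
      }
      lgrad <- function(out) radarvitals:::loss_regression(out, y)
    }
    fw <- net_forward(net, list(x1 = x1, x2 = x2))
    gr <- radarvitals:::net_backward(net, fw$cache, lgrad(fw$out)$grad)
    slots <- list(
      c("dense", 1), c("dense", 5),
      c("fork", 1, 1), c("fork", 2, 3))
    set.seed(9)
    for (sl in slots) {
      if (sl[[1]] == "dense") {
        W <- net$dense[[as.integer(sl[2])]]$W
        G <- gr$dense[[as.integer(sl[2])]]$W
      } else {
        W <- net$forks[[as.integer(sl[2])]]$layers[[as.integer(sl[3])]]$W
        G <- gr$forks[[as.integer(sl[2])]][[as.integer(sl[3])]]$W
      }
      for (k in sample(length(W), 4)) {
        pert <- function(d) {
          nn <- net
          if (sl[[1]] == "dense") nn$dense[[as.integer(sl[2])]]$W[k] <-
              W[k] + d
          else nn$forks[[as.integer(sl[2])]]$layers[[
            as.integer(sl[3])]]$W[k] <- W[k] + d
          nn
        }
        num <- (lossfun(pert(eps)) - lossfun(pert(-eps))) / (2 * eps)
        expect_lt(abs(num - G[k]) / max(1e-7, abs(num) + abs(G[k])), 1e-5)
      }
    }
  }
})

test_that("network structure behaves: softmax, capacity, determinism", {
  shapes <- list(c(3, 10, 12), c(3, 12, 14))
  cfg <- forked_net_config(shapes, conv_filters = c(4, 5, 6),
                           mlp = c(16, 12, 8, 6), head = "classification")
  net <- build_forked_net(cfg, seed = 1)
  # parameter count is a pure function of the configuration
  expect_equal(n_parameters(net),
               n_parameters(build_forked_net(cfg, seed = 99)))
  set.seed(1)
  bs <- 4
  x1 <- matrix(rnorm(prod(shapes[[1]]) * bs), ncol = bs)
  x2 <- matrix(rnorm(prod(shapes[[2]]) * bs), ncol = bs)
  pr <- net_forward(net, list(x1 = x1, x2 = x2))$out
  expect_equal(colSums(pr), rep(1, bs), tolerance = 1e-12)

  # zero-weight regression model: constant output for any input
  cfgr <- forked_net_config(shapes, conv_filters = c(4, 5, 6),
                            mlp = c(16, 12, 8, 6), head = "regression")
  netr <- build_forked_net(cfgr, seed = 2)
  for (i in seq_along(netr$dense)) netr$dense[[i]]$W[] <- 0
  o <- net_forward(netr, list(x1 = x1, x2 = x2))$out
  expect_equal(max(apply(o, 1, function(z) diff(range(z)))), 0)

  # a small net (without dropout noise) overfits a couple of samples
  cfg0 <- forked_net_config(shapes, conv_filters = c(4, 5, 6),
                            mlp = c(16, 12, 8, 6), dropout = c(0, 0),
                            head = "classification")
  y <- c(1L, 2L, 3L, 1L)
  tr <- train_forked_net(build_forked_net(cfg0, seed = 1), x1, x2, y,
                         train_idx = 1:3, val_idx = 4,
                         epochs = 200, batch_size = 3, lr = 3e-3,
                         patience = 300, seed = 3)
  expect_lt(tail(tr$history$train_loss, 1), 0.05)

  # identical seeds give identical training trajectories
  tr2 <- train_forked_net(build_forked_net(cfg, seed = 1), x1, x2, y,
                          train_idx = 1:3, val_idx = 4, epochs = 5,
                          batch_size = 3, lr = 3e-3, seed = 3)
  tr3 <- train_forked_net(build_forked_net(cfg, seed = 1), x1, x2, y,
                          train_idx = 1:3, val_idx = 4, epochs = 5,
                          batch_size = 3, lr = 3e-3, seed = 3)
  expect_identical(tr2$history, tr3$history)
})

test_that("person-level splits refuse leakage", {
  person <- rep(1:4, each = 3)
  sp <- make_person_split(person, test_persons = 4, val_persons = 3)
  expect_equal(sort(c(sp$train, sp$val, sp$test)), 1:12)
  expect_error(make_person_split(person, test_persons = 4,
                                 val_persons = 4), "both")
  expect_error(train_forked_net(
    build_forked_net(forked_net_config(
      list(c(1, 8, 8), c(1, 8, 8)), conv_filters = c(2, 2, 2),
      mlp = c(4, 4, 4, 4), head = "classification"), seed = 1),
    matrix(0, 64, 4), matrix(0, 64, 4), c(1L, 1L, 2L, 2L),
    train_idx = 1:3, val_idx = 3:4), "overlap")
})
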