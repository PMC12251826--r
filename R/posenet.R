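#' Forked CNN configuration
#'
#' The network has two independent convolutional forks, one per heatmap
#' arrangement (azimuth-elevation and elevation-distance). Each fork is
#' three `kernel x kernel` valid convolutions with ReLU, followed by one
#' 2 x 2 max-pooling layer and a dropout layer. The fork outputs are
#' flattened, concatenated and passed through an MLP of four dense layers
#' (ReLU) with dropout after the first two, and a final dense head: 18
#' linear outputs for joint regression (six joints times the encoding
#' `(u, v, r_norm)`), or a 3-way softmax for pose classification.
#'
#' @param input_shapes List of two integer vectors `c(channels, height,
#'   width)`.
#' @param conv_filters Filter counts of the three conv layers per fork.
#' @param kernel Square kernel size.
#' @param dropout Length-2: dropout rate after each fork's pooling, and
#'   after the first two MLP layers.
#' @param mlp Widths of the four dense layers.
#' @param head `"regression"` (18 outputs) or `"classification"`.
#' @param n_classes Number of classes for the classification head.
#' @return A `forked_net_config` list.
#' @export
forked_net_config <- function(input_shapes,
                              conv_filters = c(8, 12, 16), kernel = 3,
                              dropout = c(0.25, 0.4),
                              mlp = c(96, 64, 32, 16),
                              head = c("regression", "classification"),
                              n_classes = 3) {
  head <- match.arg(head)
  stopifnot(length(input_shapes) == 2, length(conv_filters) == 3,
            length(mlp) == 4, length(dropout) == 2)
  cfg <- list(input_shapes = input_shapes, conv_filters = conv_filters,
              kernel = kernel, dropout = dropout, mlp = mlp, head = head,
              n_out = if (head == "regression") 18L else as.integer(n_classes))
  class(cfg) <- "forked_net_config"
  cfg
}

# im2col index matrix for a valid k x k convolution on an (h, w, c) map
# stored as a column-major vector of length h*w*c.
im2col_idx <- function(h, w, c, k) {
  oh <- h - k + 1; ow <- w - k + 1
  oi <- rep(seq_len(oh), ow)           # output row index
  oj <- rep(seq_len(ow), each = oh)    # output col index
  cols <- matrix(0L, oh * ow, k * k * c)
  col <- 0L
  for (ch in seq_len(c)) for (dj in 0:(k - 1)) for (di in 0:(k - 1)) {
    col <- col + 1L
    cols[, col] <- (ch - 1L) * h * w + (oj + dj - 1L) * h + (oi + di)
  }
  cols
}

# 2x2/stride-2 max-pool index vectors on an (h, w) map (per channel).
pool_idx <- function(h, w) {
  ph <- h %/% 2; pw <- w %/% 2
  pi <- rep(seq_len(ph), pw); pj <- rep(seq_len(pw), each = ph)
  base <- function(di, dj) (2 * pj - 2 + dj) * h + (2 * pi - 1 + di)
  list(ph = ph, pw = pw,
       idx = list(base(0, 0), base(1, 0), base(0, 1), base(1, 1)))
}

#' Build a forked CNN with freshly initialized weights
#'
#' He-normal initialization, deterministic given the seed. The parameter
#' count is a pure function of the configuration.
#'
#' @param config A [forked_net_config()].
#' @param seed Integer seed for the initialization.
#' @return A `forked_net` object (weights, layer plumbing, config).
#' @export
build_forked_net <- function(config, seed = 1) {
  stopifnot(inherits(config, "forked_net_config"))
  set.seed(seed)
  k <- config$kernel
  he <- function(nin, nout) matrix(rnorm(nin * nout, 0, sqrt(2 / nin)),
                                   nin, nout)
  forks <- lapply(config$input_shapes, function(sh) {
    c0 <- sh[1]; h <- sh[2]; w <- sh[3]
    chans <- c(c0, config$conv_filters)
    layers <- list()
    for (i in 1:3) {
      if (h < k || w < k) stop("input too small for the conv stack")
      layers[[i]] <- list(idx = im2col_idx(h, w, chans[i], k),
                          W = he(k * k * chans[i], chans[i + 1]),
                          b = rep(0, chans[i + 1]),
                          h = h, w = w, cin = chans[i],
                          oh = h - k + 1, ow = w - k + 1)
      h <- h - k + 1; w <- w - k + 1
    }
    pool <- pool_idx(h, w)
    if (pool$ph < 1 || pool$pw < 1)
      stop("input too small: fork output collapses to zero after pooling")
    list(layers = layers, pool = pool,
         flat = pool$ph * pool$pw * chans[4])
  })
  d_in <- sum(vapply(forks, `[[`, numeric(1), "flat"))
  widths <- c(d_in, config$mlp, config$n_out)
  dense <- lapply(seq_len(length(widths) - 1), function(i) {
    list(W = he(widths[i], widths[i + 1]), b = rep(0, widths[i + 1]))
  })
  net <- list(config = config, forks = forks, dense = dense,
              seed = seed, norm = NULL, scratch = new.env(parent = emptyenv()))
  class(net) <- "forked_net"
  net
}

#' Number of trainable parameters
#' @param net A `forked_net`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(net) {
  np <- 0
  for (f in net$forks) for (l in f$layers) np <- np + length(l$W) + length(l$b)
  for (d in net$dense) np <- np + length(d$W) + length(d$b)
  np
}

# leaky ReLU: the small negative slope prevents units from dying, which
# otherwise traps a fraction of training runs at the predict-the-mean
# plateau
relu <- function(x) x * (x > 0) + 0.01 * x * (x <= 0)
relu_mask <- function(pre) (pre > 0) + 0.01 * (pre <= 0)

#' Forward pass through a forked CNN
#'
#' @param net A `forked_net`.
#' @param batch List with `x1`, `x2`: `d_i x batch` matrices of flattened
#'   heatmaps (column-major vectorization of the `(channels, h, w)`
#'   arrays from [to_heatmaps()]).
#' @param train Apply dropout (training mode) and cache activations.
#' @return List with `out` (`n_out x batch`; class probabilities for the
#'   classification head) and the activation `cache`.
#' @export
net_forward <- function(net, batch, train = FALSE) {
  bs <- ncol(batch$x1)
  cache <- list(fork = vector("list", 2))
  flat <- vector("list", 2)
  for (fi in 1:2) {
    f <- net$forks[[fi]]
    # convolutions run as one im2col matrix product per layer over the
    # whole batch: sample s occupies rows (s-1)*npix+1 .. s*npix of the
    # stacked column matrix
    xv <- as.vector(batch[[fi]])
    sc <- list(layers = vector("list", 3))
    for (li in 1:3) {
      L <- f$layers[[li]]
      key <- paste0("ib", fi, "_", li, "_", bs)
      ib <- net$scratch[[key]]
      if (is.null(ib)) {
        d <- L$h * L$w * L$cin
        npix <- nrow(L$idx)
        ib <- L$idx[rep(seq_len(npix), bs), , drop = FALSE] +
          rep((0:(bs - 1)) * d, each = npix)
        net$scratch[[key]] <- ib
      }
      cols <- xv[ib]
      dim(cols) <- dim(ib)
      pre <- cols %*% L$W
      pre <- pre + rep(L$b, each = nrow(pre))
      a <- relu(pre)
      sc$layers[[li]] <- list(cols = cols, a = a)
      xv <- as.vector(aperm(array(a, c(nrow(L$idx), bs, ncol(L$W))),
                            c(1, 3, 2)))
    }
    L3 <- f$layers[[3]]
    A <- sc$layers[[3]]$a                  # stacked (npix*bs, cout)
    p <- f$pool
    npix <- L3$oh * L3$ow
    keyp <- paste0("pb", fi, "_", bs)
    pb <- net$scratch[[keyp]]
    if (is.null(pb)) {
      pb <- lapply(p$idx, function(ix)
        rep(ix, bs) + rep((0:(bs - 1)) * npix, each = length(ix)))
      net$scratch[[keyp]] <- pb
    }
    c1 <- A[pb[[1]], , drop = FALSE]; c2 <- A[pb[[2]], , drop = FALSE]
    c3 <- A[pb[[3]], , drop = FALSE]; c4 <- A[pb[[4]], , drop = FALSE]
    Y <- pmax(c1, c2, c3, c4)
    amax <- matrix(1L, nrow(Y), ncol(Y))
    amax[c2 == Y] <- 2L; amax[c3 == Y] <- 3L; amax[c4 == Y] <- 4L
    sc$pool <- list(Y = Y, amax = amax, pb = pb)
    fl <- matrix(aperm(array(Y, c(p$ph * p$pw, bs, ncol(Y))), c(1, 3, 2)),
                 f$flat, bs)
    if (train && net$config$dropout[1] > 0) {
      pd <- net$config$dropout[1]
      mask <- matrix(runif(length(fl)) >= pd, nrow(fl), ncol(fl)) / (1 - pd)
      fl <- fl * mask
      sc$dropmask <- mask
    }
    cache$fork[[fi]] <- sc
    flat[[fi]] <- fl
  }
  x <- rbind(flat[[1]], flat[[2]])
  cache$concat_in <- x
  nd <- length(net$dense)
  dact <- vector("list", nd)
  p2 <- net$config$dropout[2]
  for (i in seq_len(nd)) {
    W <- net$dense[[i]]$W; b <- net$dense[[i]]$b
    pre <- crossprod(W, x) + b
    a <- if (i < nd) relu(pre) else pre
    dmask <- NULL
    if (train && i <= 2 && p2 > 0) {
      dmask <- matrix(runif(length(a)) >= p2, nrow(a), ncol(a)) / (1 - p2)
      a <- a * dmask
    }
    dact[[i]] <- list(x_in = x, pre = pre, a = a, dmask = dmask)
    x <- a
  }
  cache$dense <- dact
  out <- x
  if (net$config$head == "classification") {
    e <- exp(sweep(out, 2, apply(out, 2, max)))
    out <- sweep(e, 2, colSums(e), `/`)
  }
  list(out = out, cache = cache)
}

# Backward pass from d(out_pre_head) (n_out x bs); returns gradient list
# mirroring the weight structure.
net_backward <- function(net, cache, dout) {
  nd <- length(net$dense)
  gd <- vector("list", nd)
  g <- dout
  for (i in nd:1) {
    li <- cache$dense[[i]]
    if (!is.null(li$dmask)) g <- g * li$dmask
    if (i < nd) g <- g * relu_mask(li$pre)
    gd[[i]] <- list(W = tcrossprod(li$x_in, g), b = rowSums(g))
    g <- net$dense[[i]]$W %*% g
  }
  gf <- vector("list", 2)
  off <- 0
  for (fi in 1:2) {
    f <- net$forks[[fi]]
    sc <- cache$fork[[fi]]
    gfl <- g[off + seq_len(f$flat), , drop = FALSE]
    off <- off + f$flat
    if (!is.null(sc$dropmask)) gfl <- gfl * sc$dropmask
    bs <- ncol(gfl)
    p <- f$pool
    L3 <- f$layers[[3]]
    npix3 <- L3$oh * L3$ow
    # per-sample flat gradient back to the stacked pooled layout
    dY <- matrix(aperm(array(gfl, c(p$ph * p$pw, ncol(sc$pool$Y), bs)),
                       c(1, 3, 2)), nrow(sc$pool$Y), ncol(sc$pool$Y))
    dA <- matrix(0, npix3 * bs, ncol(sc$pool$Y))
    for (q in 1:4) {
      sel <- which(sc$pool$amax == q, arr.ind = TRUE)
      if (nrow(sel) == 0) next
      rows <- sc$pool$pb[[q]][sel[, 1]]
      dA[cbind(rows, sel[, 2])] <- dA[cbind(rows, sel[, 2])] + dY[sel]
    }
    gl <- vector("list", 3)
    gcur <- dA
    for (li in 3:1) {
      L <- f$layers[[li]]
      lc <- sc$layers[[li]]
      gcur <- gcur * relu_mask(lc$a)
      gl[[li]] <- list(W = t(lc$cols) %*% gcur, b = colSums(gcur))
      if (li > 1) {
        dcols <- gcur %*% t(L$W)
        d <- L$h * L$w * L$cin
        npix <- nrow(L$idx)
        dx <- col2im_acc_cpp(dcols, L$idx, d, bs)
        # stacked per-sample (h*w*cin) vectors back to (npix_prev*bs, cin)
        Lp <- f$layers[[li - 1]]
        npp <- Lp$oh * Lp$ow
        gcur <- matrix(aperm(array(dx, c(npp, ncol(Lp$W), bs)),
                             c(1, 3, 2)), npp * bs, ncol(Lp$W))
      }
    }
    gf[[fi]] <- gl
  }
  list(dense = gd, forks = gf)
}

# --- losses ------------------------------------------------------------

# Classification: y integer vector (1..K). Returns loss and gradient wrt
# pre-softmax activations (computed via softmax output).
loss_classification <- function(probs, y) {
  bs <- length(y)
  idx <- cbind(y, seq_len(bs))
  eps <- 1e-12
  loss <- -mean(log(pmax(probs[idx], eps)))
  g <- probs
  g[idx] <- g[idx] - 1
  list(loss = loss, grad = g / bs)
}

# Smooth squashing of raw head outputs (a, b) into the direction-cosine
# disc: (u, v) = sqrt(0.995) (a, b) / sqrt(1 + a^2 + b^2). Keeps
# u^2 + v^2 < 0.995 so the forward direction component stays real, with
# well-behaved gradients everywhere (no hard clipping).
squash_uv <- function(a, b) {
  w <- sqrt(1 + a^2 + b^2)
  cc <- sqrt(0.995)
  list(u = cc * a / w, v = cc * b / w, w = w, cc = cc)
}

# Regression: out (18 x bs) rows are raw (a, b, rn) per joint; targets a
# list with u, v, rn matrices (6 x bs). Loss = mean angular error in
# degrees plus lambda_r * mean |drn|. The predicted direction is the unit
# vector (u, sqrt(1 - u^2 - v^2), v), on the sphere by construction.
loss_regression <- function(out, targets, lambda_r = 10) {
  bs <- ncol(out)
  iu <- seq(1, 16, by = 3); iv <- iu + 1; ir <- iu + 2
  a <- out[iu, , drop = FALSE]; b <- out[iv, , drop = FALSE]
  rn <- out[ir, , drop = FALSE]
  sq <- squash_uv(a, b)
  u <- sq$u; v <- sq$v
  yy <- sqrt(1 - u^2 - v^2)
  tu <- targets$u; tv <- targets$v; trn <- targets$rn
  ty <- sqrt(pmax(1 - tu^2 - tv^2, 0))
  d <- tu * u + ty * yy + tv * v
  d <- pmin(pmax(d, -1), 1)
  ang <- acos(d)
  deg <- 180 / pi
  loss_ang <- mean(ang) * deg
  dr <- rn - trn
  loss_r <- mean(abs(dr))
  # gradient of the angle: d(acos)/dd = -1/sin(theta); the numerator
  # t . dp/d(u,v) vanishes proportionally, so the product stays bounded
  s <- pmax(sqrt(pmax(1 - d^2, 0)), 1e-9)
  dtheta_dd <- -1 / s
  scale <- deg / (6 * bs)
  gu <- scale * dtheta_dd * (tu - ty * u / yy)
  gv <- scale * dtheta_dd * (tv - ty * v / yy)
  # chain through the squashing map
  w3 <- sq$w^3; cc <- sq$cc
  ga <- gu * cc * (1 + b^2) / w3 + gv * cc * (-a * b) / w3
  gb <- gu * cc * (-a * b) / w3 + gv * cc * (1 + a^2) / w3
  gr <- lambda_r * sign(dr) / (6 * bs)
  g <- matrix(0, 18, bs)
  g[iu, ] <- ga; g[iv, ] <- gb; g[ir, ] <- gr
  list(loss = loss_ang + lambda_r * loss_r, grad = g,
       angular_deg = loss_ang, r_mae = loss_r)
}

# --- training ----------------------------------------------------------

adam_init <- function(net) {
  zero_like <- function(x) if (is.matrix(x)) 0 * x else rep(0, length(x))
  st <- list(m = list(), v = list(), t = 0)
  st
}

# Flatten/apply updates generically over the nested gradient structure.
adam_step <- function(net, grads, state, lr = 1e-3, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  t <- state$t
  upd <- function(w, g, key) {
    if (is.null(state$m[[key]])) {
      state$m[[key]] <<- 0 * g; state$v[[key]] <<- 0 * g
    }
    state$m[[key]] <<- b1 * state$m[[key]] + (1 - b1) * g
    state$v[[key]] <<- b2 * state$v[[key]] + (1 - b2) * g^2
    mh <- state$m[[key]] / (1 - b1^t)
    vh <- state$v[[key]] / (1 - b2^t)
    w - lr * mh / (sqrt(vh) + eps)
  }
  for (i in seq_along(net$dense)) {
    net$dense[[i]]$W <- upd(net$dense[[i]]$W, grads$dense[[i]]$W,
                            paste0("dW", i))
    net$dense[[i]]$b <- upd(net$dense[[i]]$b, grads$dense[[i]]$b,
                            paste0("db", i))
  }
  for (fi in 1:2) for (li in 1:3) {
    net$forks[[fi]]$layers[[li]]$W <-
      upd(net$forks[[fi]]$layers[[li]]$W, grads$forks[[fi]][[li]]$W,
          paste0("fW", fi, li))
    net$forks[[fi]]$layers[[li]]$b <-
      upd(net$forks[[fi]]$layers[[li]]$b, grads$forks[[fi]][[li]]$b,
          paste0("fb", fi, li))
  }
  list(net = net, state = state)
}

#' Train a forked CNN
#'
#' Minibatch Adam with early stopping on the validation loss. Training is
#' deterministic given the seed (shuffling, dropout and initialization all
#' draw from the seeded R stream).
#'
#' @param net A freshly built (or resumed) `forked_net`.
#' @param x1,x2 Flattened heatmap matrices (`d x n`), one column per
#'   window.
#' @param y Targets: integer class vector (classification) or list with
#'   `u`, `v`, `rn` matrices (`6 x n`, regression).
#' @param train_idx,val_idx Column indices of the training and validation
#'   split (person-disjoint splits are the caller's responsibility; see
#'   [make_person_split()]).
#' @param epochs,batch_size,lr,patience Optimization hyperparameters.
#' @param lambda_r Weight of the distance term in the regression loss
#'   (degrees of angular error per unit of normalized distance error; the
#'   angular loss alone does not constrain the radial coordinate).
#' @param init_output_bias Optional numeric vector (length `n_out`) used
#'   to initialize the bias of the output layer, e.g. the mean encoded
#'   target so training starts from the mean-predictor baseline.
#' @param seed Integer seed.
#' @param verbose Print per-epoch losses.
#' @return List with `net` (best-validation weights) and `history` data
#'   frame.
#' @export
train_forked_net <- function(net, x1, x2, y, train_idx, val_idx,
                             epochs = 60, batch_size = 32, lr = 1e-3,
                             patience = 12, lambda_r = 10,
                             init_output_bias = NULL, seed = 1,
                             verbose = FALSE) {
  if (length(train_idx) == 0 || length(val_idx) == 0)
    stop("empty training or validation split")
  if (length(intersect(train_idx, val_idx)) > 0)
    stop("training and validation splits overlap")
  if (!is.null(init_output_bias)) {
    stopifnot(length(init_output_bias) == net$config$n_out)
    net$dense[[length(net$dense)]]$b <- init_output_bias
  }
  set.seed(seed)
  cls <- net$config$head == "classification"
  state <- adam_init(net)
  best <- list(loss = Inf, net = net, epoch = 0)
  hist <- data.frame()
  eval_loss <- function(nn, idx) {
    fw <- net_forward(nn, list(x1 = x1[, idx, drop = FALSE],
                               x2 = x2[, idx, drop = FALSE]), train = FALSE)
    if (cls) loss_classification(fw$out, y[idx])$loss
    else loss_regression(fw$out, lapply(y, function(m)
      m[, idx, drop = FALSE]), lambda_r)$loss
  }
  for (ep in seq_len(epochs)) {
    ord <- sample(train_idx)
    nb <- ceiling(length(ord) / batch_size)
    tr_loss <- 0
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1) * batch_size + 1):min(b * batch_size, length(ord))]
      fw <- net_forward(net, list(x1 = x1[, idx, drop = FALSE],
                                  x2 = x2[, idx, drop = FALSE]),
                        train = TRUE)
      ls <- if (cls) loss_classification(fw$out, y[idx])
      else loss_regression(fw$out, lapply(y, function(m)
        m[, idx, drop = FALSE]), lambda_r)
      tr_loss <- tr_loss + ls$loss * length(idx)
      gr <- net_backward(net, fw$cache, ls$grad)
      st <- adam_step(net, gr, state, lr = lr)
      net <- st$net; state <- st$state
    }
    tr_loss <- tr_loss / length(train_idx)
    vl <- eval_loss(net, val_idx)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = tr_loss,
                                   val_loss = vl))
    if (verbose) message(sprintf("epoch %3d  train %.4f  val %.4f",
                                 ep, tr_loss, vl))
    if (vl < best$loss) best <- list(loss = vl, net = net, epoch = ep)
    if (ep - best$epoch >= patience) break
  }
  list(net = best$net, history = hist, best_epoch = best$epoch)
}

#' Encode joint targets for the regression head
#'
#' Each joint is encoded as `(u, v, r_norm)` with `u = x / r`,
#' `v = z / r` (direction cosines, free of angle wrap-around) and the
#' z-scored distance. The normalization constants are estimated from the
#' training set and must be stored with the model for decoding.
#'
#' @param joint_list List of [joint_set()] objects.
#' @param r_mean,r_sd Normalization constants; estimated from the data
#'   when `NULL`.
#' @return List with matrices `u`, `v`, `rn` (`6 x n`) and the constants.
#' @export
encode_joint_targets <- function(joint_list, r_mean = NULL, r_sd = NULL) {
  u <- sapply(joint_list, function(j) j$x / j$r)
  v <- sapply(joint_list, function(j) j$z / j$r)
  r <- sapply(joint_list, function(j) j$r)
  if (is.null(r_mean)) r_mean <- mean(r)
  if (is.null(r_sd)) r_sd <- max(sd(r), 1e-6)
  list(u = u, v = v, rn = (r - r_mean) / r_sd, r_mean = r_mean, r_sd = r_sd)
}

#' Decode regression outputs into joint sets
#'
#' Inverse of [encode_joint_targets()]: round-trips exactly for encoded
#' ground truth.
#'
#' @param out `18 x n` output matrix (rows `(u, v, rn)` per joint).
#' @param r_mean,r_sd Normalization constants stored with the model.
#' @return List of [joint_set()] objects.
#' @export
decode_joint_outputs <- function(out, r_mean, r_sd) {
  iu <- seq(1, 16, by = 3)
  lapply(seq_len(ncol(out)), function(s) {
    sq <- squash_uv(out[iu, s], out[iu + 1, s])
    u <- sq$u; v <- sq$v
    rn <- out[iu + 2, s]
    r <- pmax(rn * r_sd + r_mean, 1e-3)
    theta <- asin(pmin(pmax(v, -1), 1))
    phi <- asin(pmin(pmax(u / cos(theta), -1), 1))
    joint_set(r, phi, theta)
  })
}

#' Person-disjoint train/validation/test split
#'
#' Assigns whole persons to splits so that no person's windows appear in
#' more than one of them.
#'
#' @param person Integer or character vector, one person id per window.
#' @param test_persons Person ids held out for testing.
#' @param val_persons Person ids (from the remainder) used for validation.
#' @return List of index vectors `train`, `val`, `test`.
#' @export
make_person_split <- function(person, test_persons, val_persons) {
  if (length(intersect(test_persons, val_persons)) > 0)
    stop("a person cannot be in both the validation and the test split")
  test <- which(person %in% test_persons)
  val <- which(person %in% val_persons)
  train <- which(!person %in% c(test_persons, val_persons))
  stopifnot(length(intersect(train, c(val, test))) == 0)
  list(train = train, val = val, test = test)
}
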