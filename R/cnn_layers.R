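# Layer framework for the convolutional phase classifier.
#
# A network is a list of layer objects, each a list with $type and its
# parameters. Activations are numeric arrays [H, W, C, N]; dense layers see
# a features x N matrix. Heavy kernels (conv, pooling, warps) live in
# src/kernels.cpp; batch norm, ReLU and dense algebra are vectorized R.

# ---- layer specs (shape-free; parameters are allocated by init_layers) ----

conv_spec <- function(kh, kw, out_c, stride = 1L, pad = "valid",
                      bn = TRUE, act = "relu")
  list(type = "conv", kh = as.integer(kh), kw = as.integer(kw),
       out_c = out_c, stride = as.integer(stride), pad = pad,
       bn = bn, act = act)

maxpool_spec <- function(kh = 3L, kw = 3L, stride = 2L, pad = "valid")
  list(type = "maxpool", kh = kh, kw = kw, stride = as.integer(stride),
       pad = pad)

avgpool_spec <- function(kh = 3L, kw = 3L, stride = 1L, pad = "same")
  list(type = "avgpool", kh = kh, kw = kw, stride = as.integer(stride),
       pad = pad)

gap_spec <- function() list(type = "gap")

dense_spec <- function(out, act = "relu")
  list(type = "dense", out = as.integer(out), act = act)

inception_spec <- function(branches) list(type = "inception",
                                          branches = branches)

pad_amount <- function(pad, kh, kw) {
  if (is.character(pad)) {
    if (pad == "valid") return(c(0L, 0L))
    if (pad == "same") return(as.integer(c((kh - 1) %/% 2, (kw - 1) %/% 2)))
    stop("unknown padding '", pad, "'", call. = FALSE)
  }
  as.integer(pad)
}

conv_out_hw <- function(h, w, kh, kw, stride, ph, pw) {
  oh <- (h + 2L * ph - kh) %/% stride + 1L
  ow <- (w + 2L * pw - kw) %/% stride + 1L
  if (oh < 1L || ow < 1L)
    stop("construction error: input_shape incompatible with the ",
         "stride/pool schedule (", h, "x", w, " grid collapsed under ",
         kh, "x", kw, "/", stride, ")", call. = FALSE)
  c(oh, ow)
}

# Allocate parameters for a spec list given the input shape c(H, W, C) (or a
# feature count for dense stacks). Returns list(layers, out_shape).
init_layers <- function(specs, in_shape) {
  layers <- vector("list", length(specs))
  shape <- in_shape
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    l <- s
    if (s$type == "conv") {
      p <- pad_amount(s$pad, s$kh, s$kw)
      hw <- conv_out_hw(shape[1], shape[2], s$kh, s$kw, s$stride, p[1], p[2])
      fan_in <- s$kh * s$kw * shape[3]
      l$w <- array(stats::rnorm(fan_in * s$out_c, 0, sqrt(2 / fan_in)),
                   dim = c(s$kh, s$kw, shape[3], s$out_c))
      l$b <- numeric(s$out_c)
      l$ph <- p[1]; l$pw <- p[2]
      if (s$bn) {
        l$gamma <- rep(1, s$out_c); l$beta <- numeric(s$out_c)
        l$r_mean <- numeric(s$out_c); l$r_var <- rep(1, s$out_c)
      }
      shape <- c(hw, s$out_c)
    } else if (s$type %in% c("maxpool", "avgpool")) {
      p <- pad_amount(s$pad, s$kh, s$kw)
      hw <- conv_out_hw(shape[1], shape[2], s$kh, s$kw, s$stride, p[1], p[2])
      l$ph <- p[1]; l$pw <- p[2]
      shape <- c(hw, shape[3])
    } else if (s$type == "gap") {
      shape <- shape[3]
    } else if (s$type == "dense") {
      fan_in <- prod(shape)
      l$w <- matrix(stats::rnorm(s$out * fan_in, 0, sqrt(2 / fan_in)),
                    s$out, fan_in)
      l$b <- numeric(s$out)
      shape <- s$out
    } else if (s$type == "inception") {
      outs <- integer(length(s$branches))
      br <- vector("list", length(s$branches))
      for (k in seq_along(s$branches)) {
        ib <- init_layers(s$branches[[k]], shape)
        br[[k]] <- ib$layers
        if (length(ib$out_shape) != 3L)
          stop("inception branches must keep spatial shape", call. = FALSE)
        outs[k] <- ib$out_shape[3]
        if (k == 1L) hw <- ib$out_shape[1:2]
        else if (!all(ib$out_shape[1:2] == hw))
          stop("construction error: inception branch grids disagree",
               call. = FALSE)
      }
      l$branches <- br
      l$branch_channels <- outs
      shape <- c(hw, sum(outs))
    } else stop("unknown layer type ", s$type, call. = FALSE)
    l$out_shape <- shape
    layers[[i]] <- l
  }
  list(layers = layers, out_shape = shape)
}

# ---- batch norm over (H, W, N) per channel ----

bn_forward <- function(l, z, training) {
  d <- dim(z); hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  zm <- z; dim(zm) <- c(hw, C, N)
  if (training) {
    sums <- colSums(zm)                   # C x N (sums over hw)
    mu <- rowSums(matrix(sums, C, N)) / (hw * N)
    sq <- colSums(zm^2)
    v <- rowSums(matrix(sq, C, N)) / (hw * N) - mu^2
    v[v < 0] <- 0
    l$r_mean <- 0.9 * l$r_mean + 0.1 * mu
    l$r_var <- 0.9 * l$r_var + 0.1 * v
  } else {
    mu <- l$r_mean; v <- l$r_var
  }
  inv_sd <- 1 / sqrt(v + 1e-3)
  xhat <- (zm - rep(mu, each = hw)) * rep(inv_sd, each = hw)
  y <- xhat * rep(l$gamma, each = hw) + rep(l$beta, each = hw)
  dim(xhat) <- d; dim(y) <- d
  list(layer = l, y = y, xhat = xhat, inv_sd = inv_sd)
}

bn_backward <- function(l, cache, dy) {
  d <- dim(dy); hw <- d[1] * d[2]; C <- d[3]; N <- d[4]; M <- hw * N
  dym <- dy; dim(dym) <- c(hw, C, N)
  xh <- cache$xhat; dim(xh) <- c(hw, C, N)
  dbeta <- rowSums(matrix(colSums(dym), C, N))
  dgamma <- rowSums(matrix(colSums(dym * xh), C, N))
  scale <- l$gamma * cache$inv_sd
  dz <- rep(scale, each = hw) *
    (dym - rep(dbeta / M, each = hw) - xh * rep(dgamma / M, each = hw))
  dim(dz) <- d
  list(dz = dz, dgamma = dgamma, dbeta = dbeta)
}

# ---- forward / backward over a layer list ----

net_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      z <- conv2d_forward_cpp(x, l$w, l$b, l$stride, l$ph, l$pw)
      cache <- list(x = x)
      if (isTRUE(l$bn)) {
        bnf <- bn_forward(l, z, training)
        l <- bnf$layer
        cache$xhat <- bnf$xhat; cache$inv_sd <- bnf$inv_sd
        a <- bnf$y
      } else a <- z
      if (l$act == "relu") {
        cache$mask <- a > 0
        a[!cache$mask] <- 0
      }
      x <- a
    } else if (l$type == "maxpool") {
      mp <- maxpool_forward_cpp(x, l$kh, l$kw, l$stride, l$ph, l$pw)
      cache <- list(idx = mp$idx, xdim = dim(x))
      x <- mp$y
    } else if (l$type == "avgpool") {
      cache <- list(xdim = dim(x))
      x <- avgpool_forward_cpp(x, l$kh, l$kw, l$stride, l$ph, l$pw)
    } else if (l$type == "gap") {
      d <- dim(x)
      cache <- list(xdim = d)
      xm <- x; dim(xm) <- c(d[1] * d[2], d[3], d[4])
      x <- colSums(xm) / (d[1] * d[2])          # C x N
      dim(x) <- c(d[3], d[4])
    } else if (l$type == "dense") {
      if (!is.matrix(x)) {
        d <- dim(x)
        dim(x) <- c(prod(d[-length(d)]), d[length(d)])
      }
      cache <- list(x = x)
      x <- l$w %*% x + l$b
    } else if (l$type == "inception") {
      ys <- vector("list", length(l$branches))
      bcaches <- vector("list", length(l$branches))
      for (k in seq_along(l$branches)) {
        bf <- net_forward(l$branches[[k]], x, training)
        l$branches[[k]] <- bf$layers
        ys[[k]] <- bf$out
        bcaches[[k]] <- bf$caches
      }
      cache <- list(bcaches = bcaches, xdim = dim(x))
      x <- concat_channels(ys)
    }
    caches[[i]] <- cache
    layers[[i]] <- l
  }
  list(out = x, caches = caches, layers = layers)
}

concat_channels <- function(ys) {
  d1 <- dim(ys[[1]])
  cs <- vapply(ys, function(y) dim(y)[3], integer(1))
  out <- array(0, dim = c(d1[1], d1[2], sum(cs), d1[4]))
  at <- 0L
  for (k in seq_along(ys)) {
    out[, , at + seq_len(cs[k]), ] <- ys[[k]]
    at <- at + cs[k]
  }
  out
}

net_backward <- function(layers, caches, dy) {
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    cache <- caches[[i]]
    if (l$type == "conv") {
      if (l$act == "relu") dy <- dy * cache$mask
      if (isTRUE(l$bn)) {
        bnb <- bn_backward(l, cache, dy)
        l$g_gamma <- (l$g_gamma %||% 0) + bnb$dgamma
        l$g_beta <- (l$g_beta %||% 0) + bnb$dbeta
        dy <- bnb$dz
      }
      cb <- conv2d_backward_cpp(cache$x, l$w, dy, l$stride, l$ph, l$pw)
      l$g_w <- (l$g_w %||% 0) + cb$dw
      l$g_b <- (l$g_b %||% 0) + cb$db
      dy <- cb$dx
    } else if (l$type == "maxpool") {
      dy <- maxpool_backward_cpp(dy, cache$idx, cache$xdim)
    } else if (l$type == "avgpool") {
      dy <- avgpool_backward_cpp(dy, cache$xdim, l$kh, l$kw, l$stride,
                                 l$ph, l$pw)
    } else if (l$type == "gap") {
      d <- cache$xdim
      hw <- d[1] * d[2]
      dx <- array(rep(dy / hw, each = hw), dim = c(hw, d[3], d[4]))
      dim(dx) <- d
      dy <- dx
    } else if (l$type == "dense") {
      l$g_w <- (l$g_w %||% 0) + dy %*% t(cache$x)
      l$g_b <- (l$g_b %||% 0) + rowSums(dy)
      dy <- t(l$w) %*% dy
    } else if (l$type == "inception") {
      at <- 0L
      dx <- NULL
      for (k in seq_along(l$branches)) {
        ck <- l$branch_channels[k]
        dyk <- dy[, , at + seq_len(ck), , drop = FALSE]
        at <- at + ck
        bb <- net_backward(l$branches[[k]], cache$bcaches[[k]], dyk)
        l$branches[[k]] <- bb$layers
        dx <- if (is.null(dx)) bb$dx else dx + bb$dx
      }
      dy <- dx
    }
    layers[[i]] <- l
  }
  list(dx = dy, layers = layers)
}

# momentum SGD step over all parameters; clears gradients
net_update <- function(layers, lr, momentum) {
  upd <- function(l, pname, gname, vname) {
    if (is.null(l[[gname]])) return(l)
    v <- l[[vname]] %||% 0
    v <- momentum * v - lr * l[[gname]]
    l[[pname]] <- l[[pname]] + v
    l[[vname]] <- v
    l[[gname]] <- NULL
    l
  }
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv") {
      l <- upd(l, "w", "g_w", "v_w")
      l <- upd(l, "b", "g_b", "v_b")
      if (isTRUE(l$bn)) {
        l <- upd(l, "gamma", "g_gamma", "v_gamma")
        l <- upd(l, "beta", "g_beta", "v_beta")
      }
    } else if (l$type == "dense") {
      l <- upd(l, "w", "g_w", "v_w")
      l <- upd(l, "b", "g_b", "v_b")
    } else if (l$type == "inception") {
      for (k in seq_along(l$branches))
        l$branches[[k]] <- net_update(l$branches[[k]], lr, momentum)
    }
    layers[[i]] <- l
  }
  layers
}
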