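# Minimal trainable CNN engine: conv / ReLU / average-pool / flatten / dense
# / dropout layers with analytic backward passes (verified against finite
# differences in the test suite), softmax cross-entropy loss, and He-style
# initialization. Images are H x W x C arrays; samples are processed one at a
# time with gradients accumulated over the minibatch.

# ---- layer constructors (specs; weights are materialized by init_network) ----

nn_conv <- function(in_ch, out_ch, k = 3, padding = c("same", "valid")) {
  list(type = "conv", in_ch = in_ch, out_ch = out_ch, k = k,
       padding = match.arg(padding))
}
nn_relu <- function() list(type = "relu")
# k may be a scalar or c(rows, cols): pooling can be anisotropic
nn_avgpool <- function(k) list(type = "avgpool", k = rep(as.integer(k), length.out = 2))
nn_flatten <- function() list(type = "flatten")
nn_dense <- function(in_dim, out_dim, l2 = 0) {
  list(type = "dense", in_dim = in_dim, out_dim = out_dim, l2 = l2)
}
nn_dropout <- function(rate) list(type = "dropout", rate = rate)

init_network <- function(layers, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  layers <- lapply(layers, function(ly) {
    if (ly$type == "conv") {
      fan_in <- ly$k * ly$k * ly$in_ch
      ly$W <- array(rnorm(fan_in * ly$out_ch, sd = sqrt(2 / fan_in)),
                    c(ly$k, ly$k, ly$in_ch, ly$out_ch))
      ly$b <- numeric(ly$out_ch)
    } else if (ly$type == "dense") {
      ly$W <- matrix(rnorm(ly$in_dim * ly$out_dim, sd = sqrt(2 / ly$in_dim)),
                     ly$in_dim, ly$out_dim)
      ly$b <- numeric(ly$out_dim)
    }
    ly
  })
  structure(list(layers = layers), class = "kg_network")
}

# ---- forward / backward ----

layer_forward <- function(ly, x, training = FALSE) {
  switch(ly$type,
    conv = {
      pad <- if (ly$padding == "same") (ly$k - 1L) %/% 2L else 0L
      d <- dim(x)
      xcol <- im2col_cpp(x, d, ly$k, pad)
      y <- xcol %*% matrix(ly$W, ncol = ly$out_ch)
      y <- y + rep(ly$b, each = nrow(y))
      ho <- d[1] + 2 * pad - ly$k + 1
      wo <- d[2] + 2 * pad - ly$k + 1
      list(out = array(y, c(ho, wo, ly$out_ch)),
           cache = list(xcol = xcol, in_dim = d, pad = pad))
    },
    relu = {
      m <- x > 0
      list(out = x * m, cache = m)
    },
    avgpool = {
      kr <- ly$k[1]; kc <- ly$k[2]
      d <- dim(x)
      out <- 0
      for (dr in seq_len(kr)) {
        for (dc in seq_len(kc)) {
          out <- out + x[seq(dr, d[1], kr), seq(dc, d[2], kc), , drop = FALSE]
        }
      }
      list(out = out / (kr * kc), cache = d)
    },
    flatten = list(out = as.numeric(x), cache = dim(x)),
    dense = {
      y <- drop(matrix(x, 1) %*% ly$W) + ly$b
      list(out = y, cache = x)
    },
    dropout = {
      if (training && ly$rate > 0) {
        m <- (runif(length(x)) >= ly$rate) / (1 - ly$rate)
        list(out = x * m, cache = m)
      } else {
        list(out = x, cache = NULL)
      }
    },
    abort(paste("unknown layer type", ly$type))
  )
}

layer_backward <- function(ly, dout, cache) {
  switch(ly$type,
    conv = {
      dycol <- matrix(dout, ncol = ly$out_ch)
      wcol <- matrix(ly$W, ncol = ly$out_ch)
      dW <- crossprod(cache$xcol, dycol)
      db <- colSums(dycol)
      dx <- col2im_cpp(tcrossprod(dycol, wcol), cache$in_dim, ly$k, cache$pad)
      list(dx = dx, grads = list(W = array(dW, dim(ly$W)), b = db))
    },
    relu = list(dx = dout * cache, grads = NULL),
    avgpool = {
      kr <- ly$k[1]; kc <- ly$k[2]
      d <- cache
      dx <- array(0, d)
      dsub <- dout / (kr * kc)
      for (dr in seq_len(kr)) {
        for (dc in seq_len(kc)) {
          dx[seq(dr, d[1], kr), seq(dc, d[2], kc), ] <- dsub
        }
      }
      list(dx = dx, grads = NULL)
    },
    flatten = list(dx = array(dout, cache), grads = NULL),
    dense = {
      dW <- outer(as.numeric(cache), dout)
      if (ly$l2 > 0) dW <- dW + 2 * ly$l2 * ly$W
      list(dx = drop(ly$W %*% dout), grads = list(W = dW, b = dout))
    },
    dropout = {
      if (is.null(cache)) list(dx = dout, grads = NULL)
      else list(dx = dout * cache, grads = NULL)
    }
  )
}

net_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    fw <- layer_forward(net$layers[[i]], x, training)
    x <- fw$out
    caches[[i]] <- fw$cache
  }
  list(out = x, caches = caches)
}

net_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    bw <- layer_backward(net$layers[[i]], dout, caches[[i]])
    dout <- bw$dx
    grads[i] <- list(bw$grads) # plain assignment would drop NULL entries
  }
  grads
}

# softmax + categorical cross-entropy head; returns loss, probabilities and
# the gradient w.r.t. the logits.
softmax_cce <- function(logits, y_class) {
  z <- logits - max(logits)
  p <- exp(z) / sum(exp(z))
  loss <- -log(max(p[y_class + 1], 1e-12))
  d <- p
  d[y_class + 1] <- d[y_class + 1] - 1
  list(loss = loss, probs = p, dlogits = d)
}

# L2 penalty of all dense layers (added to the reported training loss).
net_l2_penalty <- function(net) {
  sum(vapply(net$layers, function(ly) {
    if (ly$type == "dense" && ly$l2 > 0) ly$l2 * sum(ly$W^2) else 0
  }, numeric(1)))
}

# predict class probabilities for a list of H x W (or H x W x 1) matrices
net_predict_probs <- function(net, pixel_list) {
  t(vapply(pixel_list, function(px) {
    if (is.matrix(px)) dim(px) <- c(dim(px), 1)
    logits <- net_forward(net, px, training = FALSE)$out
    z <- logits - max(logits)
    exp(z) / sum(exp(z))
  }, numeric(output_dim(net))))
}

output_dim <- function(net) {
  last_dense <- Filter(function(ly) ly$type == "dense", net$layers)
  last_dense[[length(last_dense)]]$out_dim
}

# ---- Adam ----
# Updates run in place through C++ for speed; fit_knee_classifier duplicates
# the network's parameter arrays up front so the caller's model is never
# mutated, and snapshots (net_get_params) copy.

adam_init <- function(net) {
  lapply(net$layers, function(ly) {
    if (!is.null(ly$W)) list(mW = ly$W * 0, vW = ly$W * 0,
                             mb = ly$b * 0, vb = ly$b * 0)
    else NULL
  })
}

adam_step <- function(net, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    s <- state[[i]]
    adam_update_inplace_cpp(net$layers[[i]]$W, s$mW, s$vW, g$W,
                            lr, beta1, beta2, eps, t)
    adam_update_inplace_cpp(net$layers[[i]]$b, s$mb, s$vb, g$b,
                            lr, beta1, beta2, eps, t)
  }
  list(net = net, state = state)
}

# copy, so snapshots survive later in-place updates
net_get_params <- function(net) {
  lapply(net$layers, function(ly) {
    if (!is.null(ly$W)) list(W = ly$W + 0, b = ly$b + 0)
  })
}

# duplicate every parameter array so in-place optimization cannot touch the
# arrays the caller handed in
net_duplicate_params <- function(net) {
  net$layers <- lapply(net$layers, function(ly) {
    if (!is.null(ly$W)) { ly$W <- ly$W + 0; ly$b <- ly$b + 0 }
    ly
  })
  net
}

net_set_params <- function(net, params) {
  for (i in seq_along(params)) {
    if (!is.null(params[[i]])) {
      net$layers[[i]]$W <- params[[i]]$W
      net$layers[[i]]$b <- params[[i]]$b
    }
  }
  net
}

# ---- exported elementary ops ----

#' 2-D convolution forward pass
#'
#' Evaluates the convolutional forward map
#' `y[i, j] = sum_{m, n} X[i + m, j + n] * W[m, n] + b`
#' (cross-correlation convention, as in deep-learning frameworks) at every
#' valid position. `"same"` padding zero-pads symmetrically so the output
#' keeps the input size.
#'
#' @param X Input matrix.
#' @param W Kernel matrix (M x N).
#' @param b Scalar bias.
#' @param padding `"valid"` or `"same"`.
#' @return The output feature map matrix.
#' @export
#' @examples
#' conv2d_forward(diag(3), matrix(1, 3, 3)) # sums all entries -> 3
conv2d_forward <- function(X, W, b = 0, padding = c("valid", "same")) {
  padding <- match.arg(padding)
  stopifnot(is.matrix(X), is.matrix(W), length(b) == 1)
  m <- nrow(W); n <- ncol(W)
  if (padding == "same") {
    pt <- (m - 1L) %/% 2L; pl <- (n - 1L) %/% 2L
    Xp <- matrix(0, nrow(X) + m - 1L, ncol(X) + n - 1L)
    Xp[pt + seq_len(nrow(X)), pl + seq_len(ncol(X))] <- X
  } else {
    Xp <- X
  }
  ho <- nrow(Xp) - m + 1L; wo <- ncol(Xp) - n + 1L
  if (ho < 1 || wo < 1) abort("kernel is larger than the (padded) input.")
  out <- matrix(b, ho, wo)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      out <- out + W[i, j] * Xp[(i - 1L) + seq_len(ho), (j - 1L) + seq_len(wo)]
    }
  }
  out
}

#' Fully connected layer forward pass
#'
#' `y = f(W x + b)` with `W` an `out x in` matrix.
#'
#' @param x Input vector.
#' @param W Weight matrix (`out x in`).
#' @param b Bias vector of length `out`.
#' @param activation `"identity"`, `"relu"` or `"softmax"`.
#' @return Output vector of length `out`.
#' @export
fc_forward <- function(x, W, b, activation = c("identity", "relu", "softmax")) {
  activation <- match.arg(activation)
  if (ncol(W) != length(x) || nrow(W) != length(b)) {
    abort(sprintf("shape mismatch: W is %dx%d, x has %d, b has %d.",
                  nrow(W), ncol(W), length(x), length(b)))
  }
  y <- drop(W %*% x) + b
  switch(activation,
         identity = y,
         relu = pmax(y, 0),
         softmax = { z <- y - max(y); exp(z) / sum(exp(z)) })
}
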