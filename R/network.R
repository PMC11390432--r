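#' Network specification
#'
#' Describes the densely nested encoder-decoder: a triangular grid of
#' convolutional nodes `X(i, j)` (`i` = resolution row, 0 finest; `j` =
#' position along the skip pathway, `j <= L - 1 - i`). Encoder nodes
#' `X(i, 0)` consume the 2x2 max-pooled output of the row above; every
#' nested node `X(i, j > 0)` consumes the concatenation of all same-row
#' predecessors plus the bilinearly upsampled (and 1x1-projected) output
#' of `X(i + 1, j - 1)`. Each node is two 3x3 conv + norm + ReLU blocks
#' with an optional squeeze-and-excite channel-attention gate, and each
#' decoder row ends in a 1x1 sigmoid head emitting a probability map at
#' its native scale, so a forward pass yields an L-level probability
#' pyramid.
#'
#' @param levels Number of resolution rows L (>= 2, default 4). Deeper
#'   rows have larger receptive fields, matching larger targets.
#' @param base_channels Channels of the finest row (default 32).
#' @param channel_growth Per-row channel multiplier (default 2).
#' @param attention Enable the per-node channel-attention gate.
#' @param in_channels Input channels (1: T2-weighted only).
#' @param norm `"batch"` (default; batch statistics at the training batch
#'   size) or `"none"`.
#' @return Object of class `network_spec`.
#' @export
network_spec <- function(levels = 4L, base_channels = 32L,
                         channel_growth = 2, attention = TRUE,
                         in_channels = 1L, norm = c("batch", "none")) {
  norm <- match.arg(norm)
  if (levels < 2L) stop("levels must be >= 2")
  if (base_channels < 1L) stop("base_channels must be >= 1")
  if (channel_growth < 1) stop("channel_growth must be >= 1")
  structure(list(levels = as.integer(levels),
                 base_channels = as.integer(base_channels),
                 channel_growth = channel_growth,
                 attention = isTRUE(attention),
                 in_channels = as.integer(in_channels),
                 norm = norm),
            class = "network_spec")
}

row_channels <- function(spec) {
  as.integer(round(spec$base_channels *
                     spec$channel_growth^(seq_len(spec$levels) - 1L)))
}

node_key <- function(i, j) paste0(i, "_", j)

# He-normal initialised conv / linear weight
he_init <- function(fan_in, n_out) {
  matrix(stats::rnorm(fan_in * n_out, sd = sqrt(2 / fan_in)), fan_in, n_out)
}

init_node <- function(c_in, c_out, attention) {
  node <- list(
    W1 = he_init(9L * c_in, c_out), b1 = numeric(c_out),
    g1 = rep(1, c_out), be1 = numeric(c_out),
    W2 = he_init(9L * c_out, c_out), b2 = numeric(c_out),
    g2 = rep(1, c_out), be2 = numeric(c_out)
  )
  if (attention) {
    hidden <- max(1L, c_out %/% 4L)
    node$A1 <- he_init(c_out, hidden)
    node$a1 <- numeric(hidden)
    node$A2 <- matrix(stats::rnorm(hidden * c_out, sd = sqrt(1 / hidden)),
                      hidden, c_out)
    node$a2 <- numeric(c_out)
  }
  node
}

#' Build the dense nested segmentation network
#'
#' Instantiates all node, projection and head parameters (He-normal
#' initialisation from the current RNG stream; seed the RNG beforehand
#' for reproducible weights).
#'
#' @param spec A [network_spec()].
#' @return Object of class `pvs_net`.
#' @export
build_network <- function(spec) {
  if (!inherits(spec, "network_spec")) stop("spec must be a network_spec")
  L <- spec$levels
  ch <- row_channels(spec)
  params <- list(nodes = list(), ups = list(), heads = list())
  bn <- list()
  for (j in 0:(L - 1L)) {
    for (i in 0:(L - 1L - j)) {
      c_out <- ch[i + 1L]
      c_in <- if (j == 0L) {
        if (i == 0L) spec$in_channels else ch[i]
      } else {
        (j + 1L) * c_out
      }
      key <- node_key(i, j)
      params$nodes[[key]] <- init_node(c_in, c_out, spec$attention)
      bn[[key]] <- list(m1 = numeric(c_out), v1 = rep(1, c_out),
                        m2 = numeric(c_out), v2 = rep(1, c_out))
      if (j > 0L) {
        params$ups[[key]] <- list(U = he_init(ch[i + 2L], c_out),
                                  ub = numeric(c_out))
      }
    }
  }
  for (i in 0:(L - 1L)) {
    params$heads[[as.character(i)]] <- list(
      W = matrix(stats::rnorm(ch[i + 1L], sd = sqrt(1 / ch[i + 1L])),
                 ch[i + 1L], 1L),
      b = 0)
  }
  structure(list(spec = spec, params = params, bn = bn), class = "pvs_net")
}

#' @export
print.pvs_net <- function(x, ...) {
  L <- x$spec$levels
  cat(sprintf(
    "<pvs_net> %d levels, %d nodes, %d heads, channels %s, attention %s\n  %s trainable parameters\n",
    L, L * (L + 1L) / 2L, L,
    paste(row_channels(x$spec), collapse = "/"),
    if (x$spec$attention) "on" else "off",
    format(parameter_count(x), big.mark = ",")))
  invisible(x)
}

#' Total trainable parameter count
#'
#' @param net A [build_network()] model.
#' @return Integer count of trainable parameters (batch-norm running
#'   statistics excluded).
#' @export
parameter_count <- function(net) {
  n <- 0L
  walk <- function(x) {
    if (is.list(x)) for (el in x) walk(el) else n <<- n + length(x)
  }
  walk(net$params)
  n
}

sigmoid <- function(z) 1 / (1 + exp(-z))

bn_eps <- 1e-5
bn_momentum <- 0.1

bn_forward <- function(A, gamma, beta, run_m, run_v, training) {
  if (training) {
    m <- colMeans(A)
    v <- colMeans(A^2) - m^2
    v[v < 0] <- 0
  } else {
    m <- run_m
    v <- run_v
  }
  invstd <- 1 / sqrt(v + bn_eps)
  xhat <- colop(A, invstd, -m * invstd)
  out <- colop(xhat, gamma, beta)
  list(out = out, xhat = xhat, invstd = invstd, m = m, v = v)
}

bn_backward <- function(dout, cache, gamma) {
  n <- nrow(dout)
  C <- ncol(dout)
  zero <- numeric(C)
  one <- rep(1, C)
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- colop(dout, gamma, zero)
  t1 <- colop(dxhat, one, -colSums(dxhat) / n)
  t2 <- colop(cache$xhat, colSums(dxhat * cache$xhat) / n, zero)
  dA <- colop(t1 - t2, cache$invstd, zero)
  list(dA = dA, dgamma = dgamma, dbeta = dbeta)
}

# One node: conv3x3 + norm + ReLU, twice, then optional channel attention.
node_forward <- function(Z, p, bnst, H, W, N, training, use_bn, attention,
                         keep_cache) {
  cache <- list(H = H, W = W, N = N)
  one <- rep(1, ncol(p$W1))
  P1 <- im2col3(Z, H, W, N)
  A <- colop(P1 %*% p$W1, one, p$b1)
  if (use_bn) {
    bn1 <- bn_forward(A, p$g1, p$be1, bnst$m1, bnst$v1, training)
    A <- bn1$out
  } else bn1 <- NULL
  r1 <- A > 0
  A <- A * r1
  P2 <- im2col3(A, H, W, N)
  B <- colop(P2 %*% p$W2, one, p$b2)
  if (use_bn) {
    bn2 <- bn_forward(B, p$g2, p$be2, bnst$m2, bnst$v2, training)
    B <- bn2$out
  } else bn2 <- NULL
  r2 <- B > 0
  B <- B * r2
  se <- NULL
  if (attention) {
    HW <- H * W
    grp <- rep(seq_len(N), each = HW)
    s <- rowsum(B, grp) / HW
    hpre <- sweep(s %*% p$A1, 2L, p$a1, `+`)
    # leaky activation: at the small gate widths used here a hard ReLU
    # leaves whole gates dead, starving their parameters of gradient
    h <- hpre * ifelse(hpre > 0, 1, 0.1)
    g <- sigmoid(sweep(h %*% p$A2, 2L, p$a2, `+`))
    gexp <- g[grp, , drop = FALSE]
    se <- list(s = s, hpre = hpre, h = h, g = g, Bpre = B, grp = grp)
    B <- B * gexp
  }
  if (keep_cache) {
    cache$P1 <- P1; cache$bn1 <- bn1; cache$r1 <- r1
    cache$P2 <- P2; cache$bn2 <- bn2; cache$r2 <- r2
    cache$se <- se
  }
  list(out = B, cache = cache)
}

node_backward <- function(dB, p, cache, use_bn, attention) {
  H <- cache$H; W <- cache$W; N <- cache$N
  g <- list()
  if (attention) {
    se <- cache$se
    HW <- H * W
    gexp <- se$g[se$grp, , drop = FALSE]
    dBpre <- dB * gexp
    dg <- rowsum(dB * se$Bpre, se$grp)
    dz2 <- dg * se$g * (1 - se$g)
    g$A2 <- crossprod(se$h, dz2)
    g$a2 <- colSums(dz2)
    dh <- tcrossprod(dz2, p$A2)
    dh <- dh * ifelse(se$hpre > 0, 1, 0.1)
    g$A1 <- crossprod(se$s, dh)
    g$a1 <- colSums(dh)
    ds <- tcrossprod(dh, p$A1)
    dB <- dBpre + ds[se$grp, , drop = FALSE] / HW
  }
  dB <- dB * cache$r2
  if (use_bn) {
    bb <- bn_backward(dB, cache$bn2, p$g2)
    g$g2 <- bb$dgamma; g$be2 <- bb$dbeta
    dB <- bb$dA
  }
  g$W2 <- crossprod(cache$P2, dB)
  g$b2 <- colSums(dB)
  dP2 <- tcrossprod(dB, p$W2)
  dA <- col2im3(dP2, H, W, N, ncol(p$W1))
  dA <- dA * cache$r1
  if (use_bn) {
    bb <- bn_backward(dA, cache$bn1, p$g1)
    g$g1 <- bb$dgamma; g$be1 <- bb$dbeta
    dA <- bb$dA
  }
  g$W1 <- crossprod(cache$P1, dA)
  g$b1 <- colSums(dA)
  dP1 <- tcrossprod(dA, p$W1)
  dZ <- col2im3(dP1, H, W, N, nrow(p$W1) %/% 9L)
  list(grads = g, dZ = dZ)
}

# Full forward pass over the node grid. x: (H*W*N) x in_channels matrix.
# Returns per-row head logits/probabilities and (optionally) all caches.
net_forward_full <- function(net, x, H, W, N, training = FALSE,
                             keep_cache = FALSE) {
  spec <- net$spec
  L <- spec$levels
  use_bn <- spec$norm == "batch"
  if (training) keep_cache <- TRUE  # running-stat update reads the caches
  if (H %% 2L^(L - 1L) != 0L || W %% 2L^(L - 1L) != 0L) {
    stop("input sides (", H, "x", W, ") must be divisible by 2^(levels-1)",
         " = ", 2L^(L - 1L), "; pad the input (see to_slices)")
  }
  out <- list(); caches <- list(); pools <- list(); upc <- list()
  new_bn <- net$bn
  for (j in 0:(L - 1L)) {
    for (i in 0:(L - 1L - j)) {
      key <- node_key(i, j)
      Hi <- H %/% 2L^i; Wi <- W %/% 2L^i
      if (j == 0L) {
        if (i == 0L) {
          Z <- x
        } else {
          below <- out[[node_key(i - 1L, 0L)]]
          mp <- maxpool2(below, Hi * 2L, Wi * 2L, N)
          pools[[key]] <- mp$idx
          Z <- mp$out
        }
      } else {
        same_row <- lapply(0:(j - 1L), function(jj) out[[node_key(i, jj)]])
        up_src <- out[[node_key(i + 1L, j - 1L)]]
        U <- upsample2(up_src, Hi %/% 2L, Wi %/% 2L, N)
        pu <- net$params$ups[[key]]
        Uproj <- colop(U %*% pu$U, rep(1, length(pu$ub)), pu$ub)
        if (keep_cache) upc[[key]] <- U
        Z <- do.call(cbind, c(same_row, list(Uproj)))
      }
      nf <- node_forward(Z, net$params$nodes[[key]], net$bn[[key]],
                         Hi, Wi, N, training, use_bn, spec$attention,
                         keep_cache)
      out[[key]] <- nf$out
      if (keep_cache) {
        nf$cache$Z <- Z
        caches[[key]] <- nf$cache
      }
      if (training && use_bn) {
        new_bn[[key]]$m1 <- (1 - bn_momentum) * net$bn[[key]]$m1 +
          bn_momentum * nf$cache$bn1$m
        new_bn[[key]]$v1 <- (1 - bn_momentum) * net$bn[[key]]$v1 +
          bn_momentum * nf$cache$bn1$v
        new_bn[[key]]$m2 <- (1 - bn_momentum) * net$bn[[key]]$m2 +
          bn_momentum * nf$cache$bn2$m
        new_bn[[key]]$v2 <- (1 - bn_momentum) * net$bn[[key]]$v2 +
          bn_momentum * nf$cache$bn2$v
      }
    }
  }
  logits <- list(); probs <- list()
  for (i in 0:(L - 1L)) {
    hp <- net$params$heads[[as.character(i)]]
    feat <- out[[node_key(i, L - 1L - i)]]
    z <- feat %*% hp$W + hp$b
    logits[[i + 1L]] <- z
    probs[[i + 1L]] <- sigmoid(z)
  }
  list(probs = probs, logits = logits, out = out, caches = caches,
       pools = pools, upc = upc, new_bn = new_bn, H = H, W = W, N = N)
}

# Backward pass. dlogits: per-row gradients of the loss wrt head logits.
net_backward_full <- function(net, fw, dlogits) {
  spec <- net$spec
  L <- spec$levels
  use_bn <- spec$norm == "batch"
  grads <- list(nodes = list(), ups = list(), heads = list())
  douts <- list()
  add_d <- function(key, d) {
    douts[[key]] <<- if (is.null(douts[[key]])) d else douts[[key]] + d
  }
  for (i in 0:(L - 1L)) {
    hp <- net$params$heads[[as.character(i)]]
    key <- node_key(i, L - 1L - i)
    feat <- fw$out[[key]]
    dz <- dlogits[[i + 1L]]
    grads$heads[[as.character(i)]] <- list(W = crossprod(feat, dz),
                                           b = sum(dz))
    add_d(key, tcrossprod(dz, hp$W))
  }
  for (j in (L - 1L):0) {
    for (i in (L - 1L - j):0) {
      key <- node_key(i, j)
      dB <- douts[[key]]
      if (is.null(dB)) next
      Hi <- fw$H %/% 2L^i; Wi <- fw$W %/% 2L^i
      nb <- node_backward(dB, net$params$nodes[[key]], fw$caches[[key]],
                          use_bn, spec$attention)
      grads$nodes[[key]] <- nb$grads
      dZ <- nb$dZ
      if (j == 0L) {
        if (i > 0L) {
          below_key <- node_key(i - 1L, 0L)
          nrow_in <- (Hi * 2L) * (Wi * 2L) * fw$N
          add_d(below_key, maxpool2_bw(dZ, fw$pools[[key]], nrow_in))
        }
      } else {
        ci <- ncol(fw$out[[key]])
        offsets <- 0L
        for (jj in 0:(j - 1L)) {
          cols <- offsets + seq_len(ci)
          add_d(node_key(i, jj), dZ[, cols, drop = FALSE])
          offsets <- offsets + ci
        }
        dUproj <- dZ[, offsets + seq_len(ci), drop = FALSE]
        pu <- net$params$ups[[key]]
        U <- fw$upc[[key]]
        grads$ups[[key]] <- list(U = crossprod(U, dUproj),
                                 ub = colSums(dUproj))
        dU <- tcrossprod(dUproj, pu$U)
        add_d(node_key(i + 1L, j - 1L),
              upsample2_bw(dU, Hi %/% 2L, Wi %/% 2L, fw$N))
      }
    }
  }
  grads
}

#' Forward pass: multi-scale probability pyramids
#'
#' Runs a batch of slice images through the network in inference mode and
#' returns, per image, the L-level probability pyramid (finest scale
#' first; map `s` has sides `input / 2^(s-1)`, all values in `[0, 1]`).
#'
#' @param net A [build_network()] model.
#' @param images A single 2D matrix or a list of equally sized matrices
#'   (sides divisible by `2^(levels - 1)`).
#' @return A list of pyramids (one per image), each a list of L matrices.
#' @export
net_forward <- function(net, images) {
  if (is.matrix(images)) images <- list(images)
  H <- nrow(images[[1L]]); W <- ncol(images[[1L]])
  N <- length(images)
  x <- matrix(unlist(lapply(images, as.vector), use.names = FALSE),
              ncol = net$spec$in_channels)
  fw <- net_forward_full(net, x, H, W, N, training = FALSE,
                         keep_cache = FALSE)
  L <- net$spec$levels
  lapply(seq_len(N), function(n) {
    lapply(seq_len(L), function(s) {
      Hs <- H %/% 2L^(s - 1L); Ws <- W %/% 2L^(s - 1L)
      rows <- (n - 1L) * Hs * Ws + seq_len(Hs * Ws)
      matrix(fw$probs[[s]][rows, 1L], Hs, Ws)
    })
  })
}

#' Segment a volume with a trained network
#'
#' Slices the volume axially, z-score normalises it, pads to the network's
#' required side multiple, runs every slice through the finest-scale head
#' (or the average of all heads upsampled is deliberately not used:
#' inference reads the finest head unless `fuse_heads = TRUE`, which
#' averages all heads after bilinear upsampling to full resolution), and
#' reassembles a binary mask at the given threshold.
#'
#' @param object A `pvs_net`.
#' @param volume A [pvs_volume()].
#' @param threshold Foreground threshold (strict `>`), default 0.5.
#' @param fuse_heads Average all heads (upsampled) instead of using the
#'   finest head only.
#' @param normalize Apply [normalize_volume()] first (default `TRUE`).
#' @param batch_size Slices per forward batch.
#' @param ... Unused.
#' @return Binary mask as a [pvs_volume()].
#' @export
predict.pvs_net <- function(object, volume, threshold = 0.5,
                            fuse_heads = FALSE, normalize = TRUE,
                            batch_size = 8L, ...) {
  if (normalize) volume <- normalize_volume(volume)
  L <- object$spec$levels
  ss <- to_slices(volume, pad_to = 2L^(L - 1L))
  nz <- length(ss$images)
  maps <- vector("list", nz)
  for (start in seq(1L, nz, by = batch_size)) {
    idx <- start:min(nz, start + batch_size - 1L)
    pyrs <- net_forward(object, ss$images[idx])
    for (q in seq_along(idx)) {
      pyr <- pyrs[[q]]
      if (fuse_heads) {
        Hf <- nrow(pyr[[1L]]); Wf <- ncol(pyr[[1L]])
        acc <- pyr[[1L]]
        for (s in 2:L) {
          m <- pyr[[s]]
          for (r in seq_len(s - 1L)) {
            m <- matrix(upsample2(matrix(as.vector(m), ncol = 1L),
                                  nrow(m), ncol(m), 1L),
                        nrow(m) * 2L, ncol(m) * 2L)
          }
          acc <- acc + m
        }
        maps[[idx[q]]] <- acc / L
      } else {
        maps[[idx[q]]] <- pyr[[1L]]
      }
    }
  }
  reassemble(maps, ss, threshold = threshold)
}
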