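# Internal convolutional-network engine for the denoiser.
#
# Feature maps are stored as dense matrices of shape (batch * H * W) x C,
# pixels in R's native column-major order within each sample, samples
# stacked in contiguous blocks. 3x3 convolutions with zero padding are
# computed as nine gather-then-matmul steps, so all heavy arithmetic runs
# through BLAS. The adjoint of a zero-padded convolution is the correlation
# with mirrored offsets, which reuses the same gather maps.

conv_offsets <- matrix(c(-1, -1, -1, 0, 0, 0, 1, 1, 1,
                         -1, 0, 1, -1, 0, 1, -1, 0, 1), 9, 2)

# Gather map for one offset on an H x W grid: out pixel p reads in pixel
# map[p], with out-of-bounds pixels pointing at a shared zero row.
offset_map <- function(h, w, dr, dc, zero_row) {
  r <- rep.int(seq_len(h), w) + dr
  c <- rep(seq_len(w), each = h) + dc
  ok <- r >= 1 & r <= h & c >= 1 & c <= w
  m <- ifelse(ok, (c - 1) * h + r, zero_row)
  as.integer(m)
}

# Build (and memoize per geometry) all index maps needed at one spatial size
# for a given batch size: the nine conv gathers and their mirrors, 2x2 mean
# pooling children, and nearest-neighbor upsampling parents.
make_maps <- function(h, w, batch, cache) {
  key <- paste(h, w, batch, sep = "x")
  if (!is.null(cache[[key]])) return(cache[[key]])
  npix <- h * w
  zero_row <- batch * npix + 1L
  rep_batch <- function(m) {
    # replicate a per-sample map across the batch, shifting interior indices
    out <- integer(batch * npix)
    interior <- m != zero_row
    for (b in seq_len(batch)) {
      idx <- (b - 1L) * npix + seq_len(npix)
      out[idx] <- ifelse(interior, m + (b - 1L) * npix, zero_row)
    }
    out
  }
  g <- vector("list", 9); gt <- vector("list", 9)
  for (k in 1:9) {
    g[[k]] <- rep_batch(offset_map(h, w, conv_offsets[k, 1], conv_offsets[k, 2], zero_row))
    gt[[k]] <- rep_batch(offset_map(h, w, -conv_offsets[k, 1], -conv_offsets[k, 2], zero_row))
  }
  # concatenated gather vectors: one indexing operation builds the full
  # im2col matrix (columns ordered offset-fastest, matching the row layout
  # of matrix(W, 9 * cin, cout))
  maps <- list(g = g, gt = gt, idx9 = unlist(g), idx9t = unlist(gt),
               npix = npix, zero_row = zero_row)
  if (h %% 2 == 0 && w %% 2 == 0) {
    h2 <- h %/% 2; w2 <- w %/% 2
    base <- function(dr, dc) {
      r <- rep.int(seq_len(h2) * 2L - 1L + dr, w2)
      c <- rep(seq_len(w2) * 2L - 1L + dc, each = h2)
      (c - 1L) * h + r
    }
    child <- lapply(list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)),
                    function(d) {
                      m <- base(d[1], d[2])
                      as.integer(outer(m, (seq_len(batch) - 1L) * npix, "+"))
                    })
    # upsample parent map: each fine pixel reads its coarse parent
    rpar <- (rep.int(seq_len(h), w) + 1L) %/% 2L
    cpar <- (rep(seq_len(w), each = h) + 1L) %/% 2L
    par <- (cpar - 1L) * h2 + rpar
    npix2 <- h2 * w2
    maps$pool_child <- child
    maps$up_parent <- as.integer(outer(par, (seq_len(batch) - 1L) * npix2, "+"))
  }
  cache[[key]] <- maps
  maps
}

# im2col: gather the nine shifted copies into (npix*batch) x (9*cin),
# columns ordered offset-fastest (compiled; the hot path of every conv).
im2col <- function(x, idx9) .im2col_gather(x, idx9)

conv_fwd <- function(x, W, b, maps, return_cols = FALSE) {
  cin <- dim(W)[2]; cout <- dim(W)[3]
  cols <- im2col(x, maps$idx9)
  y <- cols %*% matrix(W, 9L * cin, cout)
  y <- sweep_bias(y, b)
  if (return_cols) list(y = y, cols = cols) else y
}

sweep_bias <- function(y, b) {
  y + rep(b, each = nrow(y))
}

# Backward through a zero-padded 3x3 conv. `cols` is the cached im2col of
# the input; dx uses the mirrored gather (the adjoint of zero-padded
# convolution is correlation with flipped offsets).
conv_bwd <- function(cols, dy, W, maps) {
  cin <- dim(W)[2]; cout <- dim(W)[3]
  dWm <- crossprod(cols, dy)
  dcols <- im2col(dy, maps$idx9t)
  Wt <- matrix(aperm(W, c(1, 3, 2)), 9L * cout, cin)
  dx <- dcols %*% Wt
  list(dW = array(dWm, dim = c(9, cin, cout)), db = colSums(dy), dx = dx)
}

lrelu <- function(x) pmax(x, 0) + 0.1 * pmin(x, 0)
lrelu_grad <- function(x) 0.1 + 0.9 * (x > 0)

pool_fwd <- function(x, maps) {
  ch <- maps$pool_child
  (x[ch[[1]], , drop = FALSE] + x[ch[[2]], , drop = FALSE] +
     x[ch[[3]], , drop = FALSE] + x[ch[[4]], , drop = FALSE]) / 4
}

pool_bwd <- function(dy, maps, n_in) {
  dx <- matrix(0, n_in, ncol(dy))
  for (ch in maps$pool_child) dx[ch, ] <- dy / 4
  dx
}

up_fwd <- function(x, maps_fine) x[maps_fine$up_parent, , drop = FALSE]

up_bwd <- function(dy, maps_fine, n_coarse) {
  # adjoint of nearest upsampling = 2x2 sum over children
  ch <- maps_fine$pool_child
  dy[ch[[1]], , drop = FALSE] + dy[ch[[2]], , drop = FALSE] +
    dy[ch[[3]], , drop = FALSE] + dy[ch[[4]], , drop = FALSE]
}

# He-style seeded initialization of one conv layer.
init_conv <- function(cin, cout) {
  sd <- sqrt(2 / (9 * cin))
  list(W = array(stats::rnorm(9 * cin * cout, 0, sd), dim = c(9, cin, cout)),
       b = numeric(cout))
}

# Build the U-Net parameter list: `depth` poolings, channel widths doubling
# from base_channels, two 3x3 convs per scale, skip connections by
# concatenation, linear 3x3 output head.
unet_init <- function(depth, base_channels, seed) {
  with_seed(seed, {
    ch <- base_channels * 2^(0:depth)
    enc <- vector("list", depth + 1)
    cin <- 1
    for (l in seq_len(depth + 1)) {
      enc[[l]] <- list(a = init_conv(cin, ch[l]), b = init_conv(ch[l], ch[l]))
      cin <- ch[l]
    }
    dec <- vector("list", depth)
    for (l in seq_len(depth)) {
      # decoder level l works at encoder scale l; input = upsampled ch[l+1]
      # concatenated with the skip ch[l]
      dec[[l]] <- list(a = init_conv(ch[l + 1] + ch[l], ch[l]),
                       b = init_conv(ch[l], ch[l]))
    }
    head <- init_conv(ch[1], 1)
    list(enc = enc, dec = dec, head = head, depth = depth, ch = ch)
  })
}

# Forward pass. x: (batch*H*W) x 1 in [0,1]. Returns prediction and, when
# `keep = TRUE`, every intermediate needed by unet_backward.
unet_forward <- function(net, x, h, w, batch, cache, keep = FALSE) {
  depth <- net$depth
  maps <- vector("list", depth + 1)
  hs <- h; ws <- w
  for (l in seq_len(depth + 1)) {
    maps[[l]] <- make_maps(hs, ws, batch, cache)
    hs <- hs %/% 2; ws <- ws %/% 2
  }
  conv_block <- function(cur, layer_a, layer_b, m) {
    fa <- conv_fwd(cur, layer_a$W, layer_a$b, m, return_cols = keep)
    za <- if (keep) fa$y else fa
    aa <- lrelu(za)
    fb <- conv_fwd(aa, layer_b$W, layer_b$b, m, return_cols = keep)
    zb <- if (keep) fb$y else fb
    list(za = za, aa = aa, zb = zb, ab = lrelu(zb),
         cols_a = if (keep) fa$cols, cols_b = if (keep) fb$cols)
  }
  enc_pre <- vector("list", depth + 1)
  enc_out <- vector("list", depth + 1)
  cur <- x
  for (l in seq_len(depth + 1)) {
    blk <- conv_block(cur, net$enc[[l]]$a, net$enc[[l]]$b, maps[[l]])
    enc_pre[[l]] <- blk
    enc_out[[l]] <- blk$ab
    if (l <= depth) cur <- pool_fwd(blk$ab, maps[[l]])
  }
  dec_pre <- vector("list", depth)
  cur <- enc_out[[depth + 1]]
  for (l in rev(seq_len(depth))) {
    up <- up_fwd(cur, maps[[l]])
    cat_in <- cbind(up, enc_out[[l]])
    blk <- conv_block(cat_in, net$dec[[l]]$a, net$dec[[l]]$b, maps[[l]])
    dec_pre[[l]] <- blk
    cur <- blk$ab
  }
  fh <- conv_fwd(cur, net$head$W, net$head$b, maps[[1]], return_cols = keep)
  pred <- if (keep) fh$y else fh
  if (!keep) return(list(pred = pred))
  list(pred = pred, maps = maps, enc_pre = enc_pre, enc_out = enc_out,
       dec_pre = dec_pre, head_cols = fh$cols)
}

# Backward pass; returns gradients in the same structure as the net.
unet_backward <- function(net, fw, dpred) {
  depth <- net$depth
  maps <- fw$maps
  grads <- list(enc = vector("list", depth + 1), dec = vector("list", depth))
  gb <- conv_bwd(fw$head_cols, dpred, net$head$W, maps[[1]])
  grads$head <- list(W = gb$dW, b = gb$db)
  dcur <- gb$dx
  dskip <- vector("list", depth + 1)   # gradient flowing into enc_out[[l]]
  for (l in seq_len(depth)) {
    pre <- fw$dec_pre[[l]]
    dzb <- dcur * lrelu_grad(pre$zb)
    g2 <- conv_bwd(pre$cols_b, dzb, net$dec[[l]]$b$W, maps[[l]])
    dza <- g2$dx * lrelu_grad(pre$za)
    g1 <- conv_bwd(pre$cols_a, dza, net$dec[[l]]$a$W, maps[[l]])
    grads$dec[[l]] <- list(a = list(W = g1$dW, b = g1$db),
                           b = list(W = g2$dW, b = g2$db))
    c_up <- net$ch[l + 1]
    dup <- g1$dx[, seq_len(c_up), drop = FALSE]
    dskip[[l]] <- g1$dx[, c_up + seq_len(net$ch[l]), drop = FALSE]
    # through the upsample into the coarser decoder output (or bottleneck)
    dcoarse <- up_bwd(dup, maps[[l]], NULL)
    if (l < depth) {
      dcur <- dcoarse   # gradient w.r.t. dec_pre[[l+1]]$ab
    } else {
      dskip[[depth + 1]] <- dcoarse  # gradient w.r.t. bottleneck output
    }
  }
  if (depth == 0) dskip[[1]] <- dcur
  dpool_from_above <- NULL
  for (l in rev(seq_len(depth + 1))) {
    dab <- dskip[[l]]
    if (is.null(dab)) dab <- 0
    if (!is.null(dpool_from_above)) {
      dab <- dab + pool_bwd(dpool_from_above, maps[[l]], nrow(fw$enc_out[[l]]))
    }
    pre <- fw$enc_pre[[l]]
    dzb <- dab * lrelu_grad(pre$zb)
    g2 <- conv_bwd(pre$cols_b, dzb, net$enc[[l]]$b$W, maps[[l]])
    dza <- g2$dx * lrelu_grad(pre$za)
    g1 <- conv_bwd(pre$cols_a, dza, net$enc[[l]]$a$W, maps[[l]])
    grads$enc[[l]] <- list(a = list(W = g1$dW, b = g1$db),
                           b = list(W = g2$dW, b = g2$db))
    dpool_from_above <- if (l > 1) g1$dx else NULL
  }
  grads
}

# Flatten the parameter tree into a named list of arrays for the optimizer.
net_params <- function(net) {
  out <- list()
  for (l in seq_along(net$enc)) {
    out[[paste0("enc", l, "aW")]] <- net$enc[[l]]$a$W
    out[[paste0("enc", l, "ab")]] <- net$enc[[l]]$a$b
    out[[paste0("enc", l, "bW")]] <- net$enc[[l]]$b$W
    out[[paste0("enc", l, "bb")]] <- net$enc[[l]]$b$b
  }
  for (l in seq_along(net$dec)) {
    out[[paste0("dec", l, "aW")]] <- net$dec[[l]]$a$W
    out[[paste0("dec", l, "ab")]] <- net$dec[[l]]$a$b
    out[[paste0("dec", l, "bW")]] <- net$dec[[l]]$b$W
    out[[paste0("dec", l, "bb")]] <- net$dec[[l]]$b$b
  }
  out[["headW"]] <- net$head$W
  out[["headb"]] <- net$head$b
  out
}

grad_params <- function(grads, net) {
  out <- list()
  for (l in seq_along(net$enc)) {
    out[[paste0("enc", l, "aW")]] <- grads$enc[[l]]$a$W
    out[[paste0("enc", l, "ab")]] <- grads$enc[[l]]$a$b
    out[[paste0("enc", l, "bW")]] <- grads$enc[[l]]$b$W
    out[[paste0("enc", l, "bb")]] <- grads$enc[[l]]$b$b
  }
  for (l in seq_along(net$dec)) {
    out[[paste0("dec", l, "aW")]] <- grads$dec[[l]]$a$W
    out[[paste0("dec", l, "ab")]] <- grads$dec[[l]]$a$b
    out[[paste0("dec", l, "bW")]] <- grads$dec[[l]]$b$W
    out[[paste0("dec", l, "bb")]] <- grads$dec[[l]]$b$b
  }
  out[["headW"]] <- grads$head$W
  out[["headb"]] <- grads$head$b
  out
}

set_net_params <- function(net, params) {
  for (l in seq_along(net$enc)) {
    net$enc[[l]]$a$W <- params[[paste0("enc", l, "aW")]]
    net$enc[[l]]$a$b <- params[[paste0("enc", l, "ab")]]
    net$enc[[l]]$b$W <- params[[paste0("enc", l, "bW")]]
    net$enc[[l]]$b$b <- params[[paste0("enc", l, "bb")]]
  }
  for (l in seq_along(net$dec)) {
    net$dec[[l]]$a$W <- params[[paste0("dec", l, "aW")]]
    net$dec[[l]]$a$b <- params[[paste0("dec", l, "ab")]]
    net$dec[[l]]$b$W <- params[[paste0("dec", l, "bW")]]
    net$dec[[l]]$b$b <- params[[paste0("dec", l, "bb")]]
  }
  net$head$W <- params[["headW"]]
  net$head$b <- params[["headb"]]
  net
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
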