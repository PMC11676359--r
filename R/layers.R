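# Residual encoder internals: architecture construction, forward pass with
# activation caching, and manual backpropagation. Convolutions run through
# the GEMM kernels in src/. Activation layout [H, W, C, N].

conv_init <- function(kh, kw, c_in, c_out) {
  fan_in <- kh * kw * c_in
  list(w = array(rnorm(kh * kw * c_in * c_out, sd = sqrt(2 / fan_in)),
                 dim = c(kh, kw, c_in, c_out)),
       b = rep(0, c_out))
}

# one residual block: out = relu(conv_b(relu(conv_a(x, stride))) + shortcut)
# shortcut = x, or a 1x1 stride-s projection when shape changes.
# conv_b starts at zero so every block is an identity at initialization —
# the usual residual stabilization when no batch norm is present.
block_init <- function(c_in, c_out, stride) {
  b <- conv_init(3, 3, c_out, c_out)
  b$w[] <- 0
  list(a = conv_init(3, 3, c_in, c_out),
       b = b,
       proj = if (stride != 1L || c_in != c_out) conv_init(1, 1, c_in, c_out) else NULL,
       stride = stride)
}

# encoder architecture per scale; returns list(stem=, blocks=list(...), out_channels=)
encoder_init <- function(scale, in_channels = 1L) {
  if (scale == "tiny") {
    widths <- c(16L, 32L); depths <- c(1L, 1L); stem_w <- 16L; stem_stride <- 2L
  } else if (scale == "resnet18") {
    widths <- c(64L, 128L, 256L, 512L); depths <- c(2L, 2L, 2L, 2L)
    stem_w <- 64L; stem_stride <- 1L
  } else stopf("unknown encoder scale '%s'", scale)
  blocks <- list()
  c_in <- stem_w
  for (s in seq_along(widths)) {
    for (d in seq_len(depths[s])) {
      stride <- if (d == 1L && s > 1L) 2L else 1L
      blocks[[length(blocks) + 1L]] <- block_init(c_in, widths[s], stride)
      c_in <- widths[s]
    }
  }
  list(stem = c(conv_init(3, 3, in_channels, stem_w), list(stride = stem_stride)),
       blocks = blocks, out_channels = c_in)
}

conv_fwd <- function(x, p, stride) {
  conv2d_forward_cpp(x, p$w, p$b, as.integer(stride),
                     as.integer((dim(p$w)[1L] - 1L) %/% 2L))
}

conv_bwd <- function(x, p, dy, stride, need_dx = TRUE) {
  conv2d_backward_cpp(x, p$w, dy, as.integer(stride),
                      as.integer((dim(p$w)[1L] - 1L) %/% 2L), need_dx)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

encoder_forward <- function(enc, x, keep_cache = FALSE) {
  cache <- if (keep_cache) list(x = x) else NULL
  h0 <- conv_fwd(x, enc$stem, enc$stem$stride)
  h <- relu(h0)
  if (keep_cache) cache$stem_pre <- h0
  bc <- list()
  for (i in seq_along(enc$blocks)) {
    bl <- enc$blocks[[i]]
    a_pre <- conv_fwd(h, bl$a, bl$stride)
    a <- relu(a_pre)
    b_pre <- conv_fwd(a, bl$b, 1L)
    sc <- if (is.null(bl$proj)) h else conv_fwd(h, bl$proj, bl$stride)
    out_pre <- b_pre + sc
    out <- relu(out_pre)
    if (keep_cache) bc[[i]] <- list(x_in = h, a_pre = a_pre, a = a, out_pre = out_pre)
    h <- out
  }
  if (keep_cache) cache$blocks <- bc
  list(out = h, cache = cache)
}

# dh: gradient wrt encoder output feature map
encoder_backward <- function(enc, cache, dh, need_dx = FALSE) {
  gblocks <- vector("list", length(enc$blocks))
  for (i in rev(seq_along(enc$blocks))) {
    bl <- enc$blocks[[i]]
    cc <- cache$blocks[[i]]
    d_out_pre <- dh * (cc$out_pre > 0)
    # branch b
    gb <- conv_bwd(cc$a, bl$b, d_out_pre, 1L, TRUE)
    d_a <- gb$dx
    d_a_pre <- d_a * (cc$a_pre > 0)
    ga <- conv_bwd(cc$x_in, bl$a, d_a_pre, bl$stride, TRUE)
    d_in <- ga$dx
    if (is.null(bl$proj)) {
      d_in <- d_in + d_out_pre
      gp <- NULL
    } else {
      gpj <- conv_bwd(cc$x_in, bl$proj, d_out_pre, bl$stride, TRUE)
      d_in <- d_in + gpj$dx
      gp <- list(w = gpj$dw, b = gpj$db)
    }
    gblocks[[i]] <- list(a = list(w = ga$dw, b = ga$db),
                         b = list(w = gb$dw, b = gb$db),
                         proj = gp, stride = NULL)
    dh <- d_in
  }
  d_stem_pre <- dh * (cache$stem_pre > 0)
  gs <- conv_bwd(cache$x, enc$stem, d_stem_pre, enc$stem$stride, need_dx)
  list(grads = list(stem = list(w = gs$dw, b = gs$db, stride = NULL),
                    blocks = gblocks, out_channels = NULL),
       dx = if (need_dx) gs$dx else NULL)
}

# global average pool: [H,W,C,N] -> N x C
gap_forward <- function(h) {
  d <- dim(h)
  m <- matrix(h, nrow = d[1L] * d[2L])        # HW x (C*N)
  t(matrix(colMeans(m), nrow = d[3L]))        # N x C
}

gap_backward <- function(dG, hdim) {
  # dG: N x C -> [H,W,C,N]
  scale <- 1 / (hdim[1L] * hdim[2L])
  array(rep(t(dG), each = hdim[1L] * hdim[2L]) * scale, dim = hdim)
}
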