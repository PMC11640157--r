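# Low-level dense tensor operations used by every network in the package.
#
# Internal tensor layout is a 4-D array dim = c(C, H, W, N): channels first
# (matching the public FeatureMap convention), batch last.  All convolutions
# are expressed as a gather (im2col) followed by one BLAS matrix product,
# and their backward passes as the transposed product plus a scatter-add.

.sonnseg_cache <- new.env(parent = emptyenv())

as_nchw <- function(x) {
  # promote (C,H,W) to (C,H,W,1)
  d <- dim(x)
  if (is.null(d)) stop("expected an array, got a vector", call. = FALSE)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  if (length(dim(x)) != 4L) stop("expected a 3-D or 4-D array", call. = FALSE)
  x
}

conv_out_size <- function(n, k, stride, pad) {
  o <- (n + 2L * pad - k) %/% stride + 1L
  if (o < 1L) stop("spatial size ", n, " too small for kernel ", k, call. = FALSE)
  o
}

# Gather index matrix for im2col over a zero-padded (C,Hp,Wp) block.
# Rows are patch elements ordered (channel fastest, then ky, then kx);
# columns are output positions ordered (oy fastest, then ox).  The same
# index set is kept as a sparse scatter matrix S (padded-plane x patch
# elements) so that gather is t(S) %*% x and scatter-add is S %*% g,
# each one sparse product per batch.
conv_gather_idx <- function(C, H, W, k, stride, pad) {
  key <- paste("cv", C, H, W, k, stride, pad, sep = "_")
  hit <- .sonnseg_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- conv_out_size(H, k, stride, pad)
  Wo <- conv_out_size(W, k, stride, pad)
  kx <- rep(seq_len(k) - 1L, each = C * k)
  ky <- rep(rep(seq_len(k) - 1L, each = C), times = k)
  ch <- rep(seq_len(C), times = k * k)
  offsets <- ch + C * (ky + Hp * kx)                      # length C*k*k
  oy <- rep(seq_len(Ho) - 1L, times = Wo) * stride
  ox <- rep(seq_len(Wo) - 1L, each = Ho) * stride
  bases <- C * (oy + Hp * ox)                             # length Ho*Wo
  idx <- outer(offsets, bases, "+")
  plane <- C * Hp * Wp
  S <- Matrix::sparseMatrix(i = as.vector(idx), j = seq_along(idx), x = 1,
                            dims = c(plane, length(idx)))
  out <- list(idx = idx, S = S, St = Matrix::t(S), plane = plane,
              Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp)
  .sonnseg_cache[[key]] <- out
  out
}

pad_nchw <- function(x, pad, value = 0) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(value, dim = c(d[1L], d[2L] + 2L * pad, d[3L] + 2L * pad, d[4L]))
  out[, pad + seq_len(d[2L]), pad + seq_len(d[3L]), ] <- x
  out
}

# im2col: returns matrix (C*k*k, Ho*Wo*N) plus geometry.
im2col <- function(x, k, stride, pad) {
  x <- as_nchw(x)
  d <- dim(x)
  g <- conv_gather_idx(d[1L], d[2L], d[3L], k, stride, pad)
  xp <- pad_nchw(x, pad)
  dim(xp) <- c(g$plane, d[4L])
  P <- as.matrix(g$St %*% xp)       # (C*k*k*Ho*Wo, N)
  dim(P) <- c(nrow(g$idx), g$Ho * g$Wo * d[4L])
  list(P = P, Ho = g$Ho, Wo = g$Wo, C = d[1L], H = d[2L], W = d[3L], N = d[4L],
       k = k, stride = stride, pad = pad, S = g$S, plane = g$plane,
       Hp = g$Hp, Wp = g$Wp)
}

# col2im: scatter-add of dP (same shape as P) back to input gradient.
col2im <- function(dP, geom) {
  dim(dP) <- c(length(dP) %/% geom$N, geom$N)
  gpad <- as.matrix(geom$S %*% dP)
  dim(gpad) <- c(geom$C, geom$Hp, geom$Wp, geom$N)
  if (geom$pad > 0L) {
    gpad <- gpad[, geom$pad + seq_len(geom$H), geom$pad + seq_len(geom$W), ,
                 drop = FALSE]
  }
  gpad
}

# Plain cross-correlation.  Wm is (Cin*k*k, Cout) with rows ordered like
# im2col patch elements; b is length Cout or NULL.
conv2d_forward <- function(x, Wm, b, k, stride = 1L, pad = 0L) {
  ic <- im2col(x, k, stride, pad)
  Y <- crossprod(Wm, ic$P)                                # (Cout, Ho*Wo*N)
  if (!is.null(b)) Y <- Y + b
  dim(Y) <- c(ncol(Wm), ic$Ho, ic$Wo, ic$N)
  list(out = Y, cache = ic)
}

conv2d_backward <- function(dY, Wm, cache, has_bias = TRUE) {
  Cout <- ncol(Wm)
  dYm <- matrix(dY, nrow = Cout)
  dW <- cache$P %*% t(dYm)
  db <- if (has_bias) rowSums(dYm) else NULL
  dP <- Wm %*% dYm
  dx <- col2im(dP, cache)
  list(dx = dx, dW = dW, db = db)
}

# Max pooling, kernel k, stride s, padding p (padded with -Inf).
maxpool_gather_idx <- function(C, H, W, k, stride, pad) {
  key <- paste("mp", C, H, W, k, stride, pad, sep = "_")
  hit <- .sonnseg_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- conv_out_size(H, k, stride, pad)
  Wo <- conv_out_size(W, k, stride, pad)
  kx <- rep(seq_len(k) - 1L, each = k)
  ky <- rep(seq_len(k) - 1L, times = k)
  offsets <- C * (ky + Hp * kx)                           # length k*k
  ch <- rep(seq_len(C), times = Ho * Wo)
  oy <- rep(rep(seq_len(Ho) - 1L, times = Wo), each = C) * stride
  ox <- rep(seq_len(Wo) - 1L, each = C * Ho) * stride
  bases <- ch + C * (oy + Hp * ox)                        # length C*Ho*Wo
  idx <- outer(offsets, bases, "+")
  out <- list(idx = idx, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp)
  .sonnseg_cache[[key]] <- out
  out
}

maxpool_forward <- function(x, k = 2L, stride = k, pad = 0L) {
  x <- as_nchw(x)
  d <- dim(x)
  g <- maxpool_gather_idx(d[1L], d[2L], d[3L], k, stride, pad)
  xp <- pad_nchw(x, pad, value = -Inf)
  plane <- d[1L] * g$Hp * g$Wp
  ncols <- ncol(g$idx)
  out <- array(0, dim = c(d[1L], g$Ho, g$Wo, d[4L]))
  amax <- matrix(0L, nrow = ncols, ncol = d[4L])
  xv <- as.vector(xp)
  for (n in seq_len(d[4L])) {
    Pm <- matrix(xv[g$idx + (n - 1L) * plane], nrow = k * k)
    a <- max.col(t(Pm), ties.method = "first")
    amax[, n] <- a
    out[, , , n] <- Pm[cbind(a, seq_len(ncols))]
  }
  list(out = out,
       cache = list(idx = g$idx, amax = amax, C = d[1L], H = d[2L], W = d[3L],
                    N = d[4L], Hp = g$Hp, Wp = g$Wp, pad = pad))
}

maxpool_backward <- function(dY, cache) {
  plane <- cache$C * cache$Hp * cache$Wp
  gpad <- numeric(plane * cache$N)
  dYm <- matrix(dY, ncol = cache$N)
  ncols <- nrow(dYm)
  for (n in seq_len(cache$N)) {
    sel <- cache$idx[cbind(cache$amax[, n], seq_len(ncols))] + (n - 1L) * plane
    rs <- rowsum(dYm[, n], group = sel)
    at <- as.integer(rownames(rs))
    gpad[at] <- gpad[at] + rs[, 1L]
  }
  dim(gpad) <- c(cache$C, cache$Hp, cache$Wp, cache$N)
  if (cache$pad > 0L) {
    gpad <- gpad[, cache$pad + seq_len(cache$H), cache$pad + seq_len(cache$W), ,
                 drop = FALSE]
  }
  gpad
}

avgpool2_forward <- function(x) {
  x <- as_nchw(x)
  d <- dim(x)
  Ho <- d[2L] %/% 2L; Wo <- d[3L] %/% 2L
  x <- x[, seq_len(2L * Ho), seq_len(2L * Wo), , drop = FALSE]
  out <- (x[, seq(1L, 2L * Ho, 2L), seq(1L, 2L * Wo, 2L), , drop = FALSE] +
          x[, seq(2L, 2L * Ho, 2L), seq(1L, 2L * Wo, 2L), , drop = FALSE] +
          x[, seq(1L, 2L * Ho, 2L), seq(2L, 2L * Wo, 2L), , drop = FALSE] +
          x[, seq(2L, 2L * Ho, 2L), seq(2L, 2L * Wo, 2L), , drop = FALSE]) / 4
  list(out = out, cache = list(H = d[2L], W = d[3L]))
}

avgpool2_backward <- function(dY, cache) {
  d <- dim(dY)
  dx <- array(0, dim = c(d[1L], cache$H, cache$W, d[4L]))
  sp <- dY / 4
  dx[, seq(1L, 2L * d[2L], 2L), seq(1L, 2L * d[3L], 2L), ] <- sp
  dx[, seq(2L, 2L * d[2L], 2L), seq(1L, 2L * d[3L], 2L), ] <- sp
  dx[, seq(1L, 2L * d[2L], 2L), seq(2L, 2L * d[3L], 2L), ] <- sp
  dx[, seq(2L, 2L * d[2L], 2L), seq(2L, 2L * d[3L], 2L), ] <- sp
  dx
}

# Bilinear interpolation matrix mapping length-n to length-(f*n),
# half-pixel-centre convention (matches common DL framework default).
bilinear_matrix <- function(n, f) {
  key <- paste("bl", n, f, sep = "_")
  hit <- .sonnseg_cache[[key]]
  if (!is.null(hit)) return(hit)
  m <- f * n
  U <- matrix(0, nrow = m, ncol = n)
  for (i in seq_len(m)) {
    src <- (i - 0.5) / f - 0.5          # 0-based source coordinate
    src <- min(max(src, 0), n - 1)
    lo <- floor(src)
    fr <- src - lo
    U[i, lo + 1L] <- U[i, lo + 1L] + (1 - fr)
    if (fr > 0) U[i, lo + 2L] <- U[i, lo + 2L] + fr
  }
  .sonnseg_cache[[key]] <- U
  U
}

# Apply row matrix over the H axis and col matrix over the W axis.
resize_apply <- function(x, Uh, Uw) {
  x <- as_nchw(x)
  d <- dim(x)
  # H axis: bring H first
  xh <- aperm(x, c(2L, 1L, 3L, 4L))
  dim(xh) <- c(d[2L], d[1L] * d[3L] * d[4L])
  xh <- Uh %*% xh
  dim(xh) <- c(nrow(Uh), d[1L], d[3L], d[4L])
  xh <- aperm(xh, c(2L, 1L, 3L, 4L))
  d2 <- dim(xh)
  # W axis
  xw <- aperm(xh, c(3L, 1L, 2L, 4L))
  dim(xw) <- c(d2[3L], d2[1L] * d2[2L] * d2[4L])
  xw <- Uw %*% xw
  dim(xw) <- c(nrow(Uw), d2[1L], d2[2L], d2[4L])
  aperm(xw, c(2L, 3L, 1L, 4L))
}

upsample_forward <- function(x, factor = 2L) {
  x <- as_nchw(x)
  d <- dim(x)
  Uh <- bilinear_matrix(d[2L], factor)
  Uw <- bilinear_matrix(d[3L], factor)
  list(out = resize_apply(x, Uh, Uw), cache = list(Uh = Uh, Uw = Uw))
}

upsample_backward <- function(dY, cache) {
  resize_apply(dY, t(cache$Uh), t(cache$Uw))
}

# Batch normalisation over (H,W,N) per channel.
batchnorm_forward <- function(x, gamma, beta, running, training, eps = 1e-5,
                              momentum = 0.1) {
  x <- as_nchw(x)
  d <- dim(x)
  xm <- matrix(x, nrow = d[1L])   # C x (H*W*N); C is the fastest axis
  if (training) {
    mu <- rowMeans(xm)
    va <- rowMeans((xm - mu)^2)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    nelem <- ncol(xm)
    unb <- if (nelem > 1L) va * nelem / (nelem - 1L) else va
    running$var <- (1 - momentum) * running$var + momentum * unb
  } else {
    mu <- running$mean
    va <- running$var
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- (xm - mu) * invstd
  y <- gamma * xhat + beta
  dim(y) <- d
  list(out = y, running = running,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma, d = d,
                    training = training))
}

batchnorm_backward <- function(dY, cache) {
  d <- cache$d
  dYm <- matrix(dY, nrow = d[1L])
  dgamma <- rowSums(dYm * cache$xhat)
  dbeta <- rowSums(dYm)
  m <- ncol(dYm)
  if (cache$training) {
    dxhat <- dYm * cache$gamma
    dxm <- (dxhat - rowMeans(dxhat) -
            cache$xhat * rowMeans(dxhat * cache$xhat)) * cache$invstd
  } else {
    dxm <- dYm * cache$gamma * cache$invstd
  }
  dim(dxm) <- d
  list(dx = dxm, dgamma = dgamma, dbeta = dbeta)
}

softmax2_forward <- function(x) {
  # channelwise softmax for a 2-channel map, numerically stabilised
  x <- as_nchw(x)
  m <- pmax(x[1L, , , , drop = FALSE], x[2L, , , , drop = FALSE])
  e1 <- exp(x[1L, , , , drop = FALSE] - m)
  e2 <- exp(x[2L, , , , drop = FALSE] - m)
  s <- e1 + e2
  p <- x
  p[1L, , , ] <- e1 / s
  p[2L, , , ] <- e2 / s
  list(out = p, cache = list(p = p))
}

softmax2_backward <- function(dY, cache) {
  p <- cache$p
  # dx_c = p_c * (dY_c - sum_k p_k dY_k)
  dot <- p[1L, , , , drop = FALSE] * dY[1L, , , , drop = FALSE] +
         p[2L, , , , drop = FALSE] * dY[2L, , , , drop = FALSE]
  dx <- p
  dx[1L, , , ] <- p[1L, , , ] * (dY[1L, , , ] - dot[1L, , , ])
  dx[2L, , , ] <- p[2L, , , ] * (dY[2L, , , ] - dot[1L, , , ])
  dx
}
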