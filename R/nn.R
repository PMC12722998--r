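## Minimal convolutional-network engine.
##
## Forward/backward passes are written as im2col gathers followed by BLAS
## matrix products; the backward-data pass of a stride-1 convolution is itself
## a convolution with spatially rotated, channel-transposed kernels, so one
## forward primitive serves both directions. Arrays are H x W x C x N.

.idxCache <- new.env(parent = emptyenv())

## Gather indices turning a padded batch into im2col columns.
.convIdx <- function(H, W, C, k, pad, N) {
  key <- paste(H, W, C, k, pad, N, sep = "_")
  hit <- .idxCache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- Hp - k + 1L; Wo <- Wp - k + 1L
  off <- as.vector(outer(as.vector(outer(0:(k - 1L), (0:(k - 1L)) * Hp, "+")),
                         (0:(C - 1L)) * Hp * Wp, "+"))
  pos <- as.vector(outer(0:(Ho - 1L), (0:(Wo - 1L)) * Hp, "+"))
  idx1 <- as.vector(outer(off, pos, "+")) + 1L
  idx <- as.integer(rep(idx1, N) +
                    rep((0:(N - 1L)) * Hp * Wp * C, each = length(idx1)))
  out <- list(idx = idx, Ho = Ho, Wo = Wo)
  .idxCache[[key]] <- out
  out
}

## x: H x W x C x N; w: k x k x C x F; b: length F. Stride 1.
.convFwd <- function(x, w, b, pad, keepCol = FALSE) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  k <- dim(w)[1]; nF <- dim(w)[4]
  if (pad > 0L) {
    xp <- array(0, c(H + 2L * pad, W + 2L * pad, C, N))
    xp[pad + seq_len(H), pad + seq_len(W), , ] <- x
  } else xp <- x
  ci <- .convIdx(H, W, C, k, as.integer(pad), N)
  xcol <- matrix(xp[ci$idx], nrow = k * k * C)
  out <- crossprod(matrix(w, k * k * C, nF), xcol) + b
  list(out = aperm(array(out, c(nF, ci$Ho, ci$Wo, N)), c(2, 3, 1, 4)),
       xcol = if (keepCol) xcol else NULL)
}

.convBwdW <- function(xcol, dout, k, C) {
  nF <- dim(dout)[3]
  dm <- matrix(aperm(dout, c(3, 1, 2, 4)), nrow = nF)
  list(dW = array(tcrossprod(xcol, dm), c(k, k, C, nF)), db = rowSums(dm))
}

.convBwdX <- function(dout, w, pad) {
  k <- dim(w)[1]; C <- dim(w)[3]
  wrot <- aperm(w[k:1, k:1, , , drop = FALSE], c(1, 2, 4, 3))
  .convFwd(dout, wrot, numeric(C), k - 1L - pad)$out
}

.relu <- function(x) { x[x < 0] <- 0; x }

.pool2 <- function(x) {
  d <- dim(x)
  ro <- seq.int(1L, d[1], 2L); re <- ro + 1L
  co <- seq.int(1L, d[2], 2L); ce <- co + 1L
  (x[ro, co, , , drop = FALSE] + x[re, co, , , drop = FALSE] +
   x[ro, ce, , , drop = FALSE] + x[re, ce, , , drop = FALSE]) / 4
}

.pool2Bwd <- function(dy, H, W) {
  d <- dim(dy)
  dx <- array(0, c(H, W, d[3], d[4]))
  q <- dy / 4
  ro <- seq.int(1L, H, 2L); re <- ro + 1L
  co <- seq.int(1L, W, 2L); ce <- co + 1L
  dx[ro, co, , ] <- q; dx[re, co, , ] <- q
  dx[ro, ce, , ] <- q; dx[re, ce, , ] <- q
  dx
}

.gapFwd <- function(x) {
  d <- dim(x)
  matrix(colMeans(matrix(x, d[1] * d[2])), d[3], d[4])
}

.gapBwd <- function(dfeat, H, W) {
  d <- dim(dfeat)
  array(rep(as.vector(dfeat), each = H * W) / (H * W), c(H, W, d[1], d[2]))
}

## Kaiming (He) normal initialization: sd = sqrt(2 / fan_in); biases zero.
.kaimingConv <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

.tinyCnnFilters <- c(8L, 16L, 32L)

.initTinyCnn <- function(inChannels) {
  f <- .tinyCnnFilters
  list(w1 = .kaimingConv(3L, inChannels, f[1]), b1 = numeric(f[1]),
       w2 = .kaimingConv(3L, f[1], f[2]), b2 = numeric(f[2]),
       w3 = .kaimingConv(3L, f[2], f[3]), b3 = numeric(f[3]),
       wf = matrix(stats::rnorm(f[3] * 2L, 0, sqrt(2 / f[3])), f[3], 2L),
       bf = numeric(2L))
}

.forwardTiny <- function(params, x, keepCache = FALSE) {
  x <- 2 * x - 1  # center unit-interval intensities to [-1, 1]
  c1 <- .convFwd(x, params$w1, params$b1, 1L, keepCache)
  a1 <- .relu(c1$out); p1 <- .pool2(a1)
  c2 <- .convFwd(p1, params$w2, params$b2, 1L, keepCache)
  a2 <- .relu(c2$out); p2 <- .pool2(a2)
  c3 <- .convFwd(p2, params$w3, params$b3, 1L, keepCache)
  a3 <- .relu(c3$out)
  feat <- .gapFwd(a3)
  logits <- crossprod(params$wf, feat) + params$bf
  cache <- if (keepCache)
    list(xcol1 = c1$xcol, xcol2 = c2$xcol, xcol3 = c3$xcol,
         a1 = a1, a2 = a2, a3 = a3, feat = feat,
         d1 = dim(a1), d2 = dim(a2), d3 = dim(a3))
  list(logits = logits, cache = cache)
}

.backwardTiny <- function(params, cache, dlogits) {
  inC <- dim(params$w1)[3]
  dwf <- tcrossprod(cache$feat, dlogits)
  dbf <- rowSums(dlogits)
  dfeat <- params$wf %*% dlogits
  da3 <- .gapBwd(dfeat, cache$d3[1], cache$d3[2])
  da3[cache$a3 <= 0] <- 0
  g3 <- .convBwdW(cache$xcol3, da3, 3L, dim(params$w3)[3])
  dp2 <- .convBwdX(da3, params$w3, 1L)
  da2 <- .pool2Bwd(dp2, cache$d2[1], cache$d2[2])
  da2[cache$a2 <= 0] <- 0
  g2 <- .convBwdW(cache$xcol2, da2, 3L, dim(params$w2)[3])
  dp1 <- .convBwdX(da2, params$w2, 1L)
  da1 <- .pool2Bwd(dp1, cache$d1[1], cache$d1[2])
  da1[cache$a1 <= 0] <- 0
  g1 <- .convBwdW(cache$xcol1, da1, 3L, inC)
  list(w1 = g1$dW, b1 = g1$db, w2 = g2$dW, b2 = g2$db,
       w3 = g3$dW, b3 = g3$db, wf = dwf, bf = dbf)
}

.softmaxProbs <- function(logits) {
  m <- pmax(logits[1L, ], logits[2L, ])
  e1 <- exp(logits[1L, ] - m); e2 <- exp(logits[2L, ] - m)
  rbind(e1, e2, deparse.level = 0) / rep(e1 + e2, each = 2L)
}

## y: class indices (1 = negative, 2 = positive)
.xentLoss <- function(probs, y) {
  -mean(log(pmax(probs[cbind(y, seq_along(y))], 1e-12)))
}

.xentGrad <- function(probs, y) {
  n <- length(y)
  d <- probs
  d[cbind(y, seq_len(n))] <- d[cbind(y, seq_len(n))] - 1
  d / n
}

.adamInit <- function(params) {
  zero <- lapply(params, function(p) p * 0)
  list(m = zero, v = zero, t = 0L)
}

.adamStep <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t; b2t <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + eps)
  }
  list(params = params, state = state)
}

## Early stopping on validation loss: stop once `patience` epochs have passed
## without improving on the best epoch so far.
.stopAfterPatience <- function(valLosses, patience) {
  (length(valLosses) - which.min(valLosses)) >= patience
}

## Resample an H x W x C stack to S x S (bilinear); identity when already S.
.resizeStack <- function(stack, S) {
  d <- dim(stack)
  if (d[1] == S && d[2] == S) return(stack)
  EBImage::resize(stack, w = S, h = S)
}

.stacksToBatch <- function(stacks) {
  d <- dim(stacks[[1]])
  array(vapply(stacks, identity, numeric(prod(d))), c(d, length(stacks)))
}
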