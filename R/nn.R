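# Dilated residual convolutional classifier over binned spectra.
#
# The network and its training loop are implemented on base-R matrices
# (BLAS-backed); the dilated convolutions, the only compute-heavy primitive,
# run through compiled kernels in src/conv1d.cpp. Activations for a batch of N
# spectra are stored as C x (L*N) matrices, column-major by sample.

#' Model architecture configuration
#'
#' The spectral trunk is a 1-D convolution plus leaky ReLU, six residual
#' dilated convolutions (dilations 1, 2, 4, 8, 16, 32), max-pooling with kernel
#' size 20 and a fully connected layer to 1024 features. Precursor m/z and
#' normalized retention time each pass a linear layer, layer normalization and
#' leaky ReLU into 24 dimensions; the five categorical metadata codes are
#' embedded into 24 dimensions each. The concatenation feeds two blocks of
#' (linear, layer norm, leaky ReLU, dropout 0.2) and a final linear layer to
#' the class scores. Channel counts, kernel size and hidden width are package
#' defaults, exposed here.
#'
#' @param n_classes Number of library classes (>= 2).
#' @param n_bins Input length (2048).
#' @param dilations Dilation factors of the residual blocks.
#' @param pool_kernel Max-pooling kernel/stride.
#' @param trunk_dim Output width of the post-pooling linear layer.
#' @param embed_dim Embedding width per categorical / scalar input.
#' @param dropout Dropout rate in the head.
#' @param conv_channels,conv_kernel Convolution width and kernel size.
#' @param hidden_dim Width of the two head blocks.
#' @return List of class \code{"ModelConfig"}.
#' @export
modelConfig <- function(n_classes, n_bins = 2048L,
                        dilations = c(1L, 2L, 4L, 8L, 16L, 32L),
                        pool_kernel = 20L, trunk_dim = 1024L,
                        embed_dim = 24L, dropout = 0.2,
                        conv_channels = 8L, conv_kernel = 5L,
                        hidden_dim = 256L) {
  stopifnot(n_classes >= 2L, n_bins >= pool_kernel, conv_kernel %% 2L == 1L)
  structure(list(n_classes = as.integer(n_classes), n_bins = as.integer(n_bins),
                 dilations = as.integer(dilations),
                 pool_kernel = as.integer(pool_kernel),
                 trunk_dim = as.integer(trunk_dim),
                 embed_dim = as.integer(embed_dim), dropout = dropout,
                 conv_channels = as.integer(conv_channels),
                 conv_kernel = as.integer(conv_kernel),
                 hidden_dim = as.integer(hidden_dim),
                 n_meta = 5L,
                 meta_levels = vapply(.META_CODEBOOKS, function(cb)
                   max(cb) + 1L, integer(1))),
            class = "ModelConfig")
}

.he <- function(nout, nin, fan) matrix(stats::rnorm(nout * nin, 0, sqrt(2 / fan)),
                                       nout, nin)

#' Build an untrained model
#'
#' He-initialized weights for the architecture described in
#' \code{\link{modelConfig}}.
#'
#' @param cfg A \code{\link{modelConfig}}.
#' @param seed Integer seed for the initialization.
#' @return List of class \code{"nnModel"} with \code{cfg} and \code{params}.
#' @export
buildModel <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "ModelConfig"))
  C <- cfg$conv_channels; k <- cfg$conv_kernel
  Lp <- cfg$n_bins %/% cfg$pool_kernel
  E <- cfg$embed_dim; H <- cfg$hidden_dim
  concat <- cfg$trunk_dim + 2L * E + cfg$n_meta * E
  .withSeed(seed, {
    p <- list()
    for (j in seq_len(k)) p[[paste0("conv0.W", j)]] <- .he(C, 2L, 2L * k)
    p[["conv0.b"]] <- numeric(C)
    for (bl in seq_along(cfg$dilations)) {
      for (j in seq_len(k)) {
        p[[paste0("block", bl, ".W", j)]] <- .he(C, C, C * k)
      }
      p[[paste0("block", bl, ".b")]] <- numeric(C)
    }
    p[["fcpool.W"]] <- .he(cfg$trunk_dim, C * Lp, C * Lp)
    p[["fcpool.b"]] <- numeric(cfg$trunk_dim)
    for (sc in 1:2) {
      p[[paste0("scal", sc, ".W")]] <- .he(E, 1L, 1L)
      p[[paste0("scal", sc, ".b")]] <- numeric(E)
      p[[paste0("scal", sc, ".g")]] <- rep(1, E)
      p[[paste0("scal", sc, ".s")]] <- numeric(E)
    }
    for (m in seq_len(cfg$n_meta)) {
      p[[paste0("emb", m)]] <- matrix(stats::rnorm(E * cfg$meta_levels[m],
                                                   0, 0.1),
                                      E, cfg$meta_levels[m])
    }
    dims <- c(concat, H, H)
    for (t in 1:2) {
      p[[paste0("head", t, ".W")]] <- .he(H, dims[t], dims[t])
      p[[paste0("head", t, ".b")]] <- numeric(H)
      p[[paste0("head", t, ".g")]] <- rep(1, H)
      p[[paste0("head", t, ".s")]] <- numeric(H)
    }
    p[["out.W"]] <- .he(cfg$n_classes, H, H)
    p[["out.b"]] <- numeric(cfg$n_classes)
    structure(list(cfg = cfg, params = p), class = "nnModel")
  })
}

# --- tensor helpers ----------------------------------------------------------

# Assemble the per-offset weight matrices of one layer into a cube for the
# compiled kernels.
.weightCube <- function(params, prefix, k) {
  W1 <- params[[paste0(prefix, ".W1")]]
  cube <- array(0, dim = c(nrow(W1), ncol(W1), k))
  for (j in seq_len(k)) cube[, , j] <- params[[paste0(prefix, ".W", j)]]
  cube
}

.convForward <- function(params, prefix, x, k, dil, L, N) {
  .conv1dFwd(.weightCube(params, prefix, k),
             params[[paste0(prefix, ".b")]], x, dil, L, N)
}

.convBackward <- function(params, grads, prefix, x, dout, k, dil, L, N) {
  res <- .conv1dBwd(.weightCube(params, prefix, k), x, dout, dil, L, N)
  for (j in seq_len(k)) grads[[paste0(prefix, ".W", j)]] <- res$dW[, , j]
  grads[[paste0(prefix, ".b")]] <- as.numeric(res$db)
  list(dx = res$dx, grads = grads)
}

.lrelu <- function(x) if (is.matrix(x)) .lreluCpp(x) else pmax(x, 0.01 * x)

# Layer norm over the feature dimension (rows) per column.
.lnForward <- function(x, g, s) {
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  v <- colMeans(xc^2)
  inv <- 1 / sqrt(v + 1e-5)
  xhat <- sweep(xc, 2L, inv, `*`)
  list(y = xhat * g + s, xhat = xhat, inv = inv)
}

.lnBackward <- function(cache, g, dy) {
  D <- nrow(dy)
  dxhat <- dy * g
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * cache$xhat)
  dx <- sweep(dxhat, 2L, m1) - cache$xhat * rep(m2, each = D)
  dx <- sweep(dx, 2L, cache$inv, `*`)
  list(dx = dx, dg = rowSums(dy * cache$xhat), ds = rowSums(dy))
}

# Max pool (kernel = stride = P) along L with argmax for the backward pass
# (compiled; see src/conv1d.cpp).
.poolForward <- function(x, P, L, N) .poolFwdCpp(x, P, L, N)

.poolBackward <- function(pool, dy, P, L, N) .poolBwdCpp(pool$arg, dy, P, L, N)

# Assemble model inputs from a list of BinnedSpectrum objects.
.buildInputs <- function(binned) {
  N <- length(binned)
  L <- length(binned[[1L]]@intensities)
  x <- matrix(0, 2L, L * N)
  scal <- matrix(0, 2L, N)
  metaM <- matrix(0L, 5L, N)
  w <- binWidth()
  for (n in seq_len(N)) {
    b <- binned[[n]]
    cols <- seq.int((n - 1L) * L + 1L, n * L)
    x[1L, cols] <- b@intensities
    x[2L, cols] <- b@remainders / w
    scal[1L, n] <- b@precursorMz / 3000
    scal[2L, n] <- b@rtNorm
    metaM[, n] <- b@meta
  }
  list(x = x, scal = scal, meta = metaM, L = L, N = N)
}

# Forward pass; returns logits (K x N) and, when keep_cache (default), the
# cache needed for the backward pass (dropout masks drawn from the current
# RNG). Inference passes use keep_cache = FALSE to avoid retaining the large
# convolution activations.
.nnForward <- function(model, inputs, train = FALSE, keep_cache = train) {
  cfg <- model$cfg; p <- model$params
  k <- cfg$conv_kernel; L <- inputs$L; N <- inputs$N
  cache <- list(inputs = inputs)

  h <- .convForward(p, "conv0", inputs$x, k, 1L, L, N)
  if (keep_cache) cache$conv0_pre <- h
  h <- .lrelu(h)
  for (bl in seq_along(cfg$dilations)) {
    pre <- .convForward(p, paste0("block", bl), h, k, cfg$dilations[bl], L, N)
    if (keep_cache) {
      cache[[paste0("block", bl, "_in")]] <- h
      cache[[paste0("block", bl, "_pre")]] <- pre
    }
    h <- h + .lrelu(pre)
  }
  pool <- .poolForward(h, cfg$pool_kernel, L, N)
  if (keep_cache) cache$pool <- pool
  flat <- matrix(pool$y, cfg$conv_channels * pool$Lp, N)
  cache$flat <- flat
  specPre <- p[["fcpool.W"]] %*% flat + p[["fcpool.b"]]
  cache$spec_pre <- specPre
  spec <- .lrelu(specPre)

  scalOut <- vector("list", 2L)
  for (sc in 1:2) {
    z <- p[[paste0("scal", sc, ".W")]] %*% inputs$scal[sc, , drop = FALSE] +
      p[[paste0("scal", sc, ".b")]]
    ln <- .lnForward(z, p[[paste0("scal", sc, ".g")]],
                     p[[paste0("scal", sc, ".s")]])
    cache[[paste0("scal", sc, "_z")]] <- z
    cache[[paste0("scal", sc, "_ln")]] <- ln
    scalOut[[sc]] <- .lrelu(ln$y)
  }
  embOut <- vector("list", cfg$n_meta)
  for (m in seq_len(cfg$n_meta)) {
    idx <- pmin(inputs$meta[m, ] + 1L, ncol(p[[paste0("emb", m)]]))
    cache[[paste0("emb", m, "_idx")]] <- idx
    embOut[[m]] <- p[[paste0("emb", m)]][, idx, drop = FALSE]
  }
  h <- rbind(spec, scalOut[[1L]], scalOut[[2L]], do.call(rbind, embOut))
  cache$concat <- h
  for (t in 1:2) {
    z <- p[[paste0("head", t, ".W")]] %*% h + p[[paste0("head", t, ".b")]]
    ln <- .lnForward(z, p[[paste0("head", t, ".g")]],
                     p[[paste0("head", t, ".s")]])
    a <- .lrelu(ln$y)
    if (train && cfg$dropout > 0) {
      mask <- matrix(stats::rbinom(length(a), 1L, 1 - cfg$dropout) /
                       (1 - cfg$dropout), nrow(a), ncol(a))
      a <- a * mask
      cache[[paste0("head", t, "_mask")]] <- mask
    }
    cache[[paste0("head", t, "_in")]] <- h
    cache[[paste0("head", t, "_z")]] <- z
    cache[[paste0("head", t, "_ln")]] <- ln
    h <- a
  }
  cache$head_out <- h
  logits <- p[["out.W"]] %*% h + p[["out.b"]]
  list(logits = logits, cache = cache)
}

.nnBackward <- function(model, cache, dlogits) {
  cfg <- model$cfg; p <- model$params
  k <- cfg$conv_kernel
  inputs <- cache$inputs; L <- inputs$L; N <- inputs$N
  grads <- list()

  grads[["out.W"]] <- tcrossprod(dlogits, cache$head_out)
  grads[["out.b"]] <- rowSums(dlogits)
  dh <- crossprod(p[["out.W"]], dlogits)
  for (t in 2:1) {
    mask <- cache[[paste0("head", t, "_mask")]]
    if (!is.null(mask)) dh <- dh * mask
    ln <- cache[[paste0("head", t, "_ln")]]
    dh <- .dlreluMulCpp(dh, ln$y)
    lb <- .lnBackward(ln, p[[paste0("head", t, ".g")]], dh)
    grads[[paste0("head", t, ".g")]] <- lb$dg
    grads[[paste0("head", t, ".s")]] <- lb$ds
    dz <- lb$dx
    grads[[paste0("head", t, ".W")]] <- tcrossprod(dz, cache[[paste0("head", t, "_in")]])
    grads[[paste0("head", t, ".b")]] <- rowSums(dz)
    dh <- crossprod(p[[paste0("head", t, ".W")]], dz)
  }
  E <- cfg$embed_dim
  dspec <- dh[seq_len(cfg$trunk_dim), , drop = FALSE]
  off <- cfg$trunk_dim
  for (sc in 1:2) {
    dso <- dh[off + seq_len(E), , drop = FALSE]
    off <- off + E
    ln <- cache[[paste0("scal", sc, "_ln")]]
    dso <- .dlreluMulCpp(dso, ln$y)
    lb <- .lnBackward(ln, p[[paste0("scal", sc, ".g")]], dso)
    grads[[paste0("scal", sc, ".g")]] <- lb$dg
    grads[[paste0("scal", sc, ".s")]] <- lb$ds
    dz <- lb$dx
    grads[[paste0("scal", sc, ".W")]] <-
      tcrossprod(dz, inputs$scal[sc, , drop = FALSE])
    grads[[paste0("scal", sc, ".b")]] <- rowSums(dz)
  }
  for (m in seq_len(cfg$n_meta)) {
    dem <- dh[off + seq_len(E), , drop = FALSE]
    off <- off + E
    dE <- matrix(0, E, ncol(p[[paste0("emb", m)]]))
    idx <- cache[[paste0("emb", m, "_idx")]]
    for (n in seq_len(N)) dE[, idx[n]] <- dE[, idx[n]] + dem[, n]
    grads[[paste0("emb", m)]] <- dE
  }

  dspec <- .dlreluMulCpp(dspec, cache$spec_pre)
  grads[["fcpool.W"]] <- tcrossprod(dspec, cache$flat)
  grads[["fcpool.b"]] <- rowSums(dspec)
  dflat <- crossprod(p[["fcpool.W"]], dspec)
  dpool <- matrix(dflat, cfg$conv_channels, cache$pool$Lp * N)
  dhh <- .poolBackward(cache$pool, dpool, cfg$pool_kernel, L, N)

  for (bl in rev(seq_along(cfg$dilations))) {
    pre <- cache[[paste0("block", bl, "_pre")]]
    dpre <- .dlreluMulCpp(dhh, pre)
    cb <- .convBackward(p, grads, paste0("block", bl),
                        cache[[paste0("block", bl, "_in")]], dpre, k,
                        cfg$dilations[bl], L, N)
    grads <- cb$grads
    dhh <- dhh + cb$dx  # residual connection
  }
  dhh <- .dlreluMulCpp(dhh, cache$conv0_pre)
  cb <- .convBackward(p, grads, "conv0", inputs$x, dhh, k, 1L, L, N)
  grads <- cb$grads
  grads
}

# AdamW step; state holds first/second moments and the step counter.
.adamStep <- function(params, grads, state, lr, wd, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / b1t
    vhat <- state$v[[nm]] / b2t
    params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + eps) +
                                           wd * params[[nm]])
  }
  list(params = params, state = state)
}
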