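# Minimal CNN training engine in vectorized R.
#
# Feature maps are stored as dense matrices with N*H*W rows (image-major,
# then row-major spatial order: row = (n-1)*H*W + (h-1)*W + w) and one
# column per channel. Convolutions are im2col gathers followed by one BLAS
# matrix product; im2col index tables are cached per (H, W, kernel, N).
# Everything is double precision and fully deterministic given the seed.

.idxCache <- new.env(parent = emptyenv())

# Per-offset gather indices for a k x k same-padding convolution over a
# batch of N images of H x W. Out-of-frame positions point at a sentinel
# zero row (N*H*W + 1). Offsets are enumerated dy, dx in -p..p (dy-major),
# so the offset negation needed by the backward pass is index reversal.
.convIndices <- function(H, W, k, N) {
  key <- paste("c", H, W, k, N, sep = "_")
  hit <- .idxCache[[key]]
  if (!is.null(hit)) return(hit)
  p <- (k - 1L) %/% 2L
  HW <- H * W
  h <- rep(seq_len(H), each = W)
  w <- rep(seq_len(W), H)
  base <- rep((seq_len(N) - 1L) * HW, each = HW)
  sentinel <- N * HW + 1L
  out <- vector("list", k * k)
  o <- 0L
  for (dy in -p:p) for (dx in -p:p) {
    o <- o + 1L
    hs <- h + dy
    ws <- w + dx
    idx1 <- (hs - 1L) * W + ws
    idx1[hs < 1L | hs > H | ws < 1L | ws > W] <- NA_integer_
    idx <- base + rep(idx1, N)
    idx[is.na(idx)] <- sentinel
    out[[o]] <- idx
  }
  .idxCache[[key]] <- out
  out
}

# Index vectors of the four 2x2 max-pool taps for a batch of N images.
.poolIndices <- function(H, W, N) {
  key <- paste("p", H, W, N, sep = "_")
  hit <- .idxCache[[key]]
  if (!is.null(hit)) return(hit)
  Ho <- H %/% 2L
  Wo <- W %/% 2L
  ho <- rep(seq_len(Ho), each = Wo)
  wo <- rep(seq_len(Wo), Ho)
  base <- rep((seq_len(N) - 1L) * H * W, each = Ho * Wo)
  at <- function(dh, dw) base + rep((2L * ho - 2L + dh) * W +
                                    (2L * wo - 1L + dw), N)
  out <- list(at(0L, 0L), at(0L, 1L), at(1L, 0L), at(1L, 1L))
  .idxCache[[key]] <- out
  out
}

.im2col <- function(A, H, W, k, N) {
  if (k == 1L) return(A)
  idxs <- .convIndices(H, W, k, N)
  A2 <- rbind(A, 0)
  do.call(cbind, lapply(idxs, function(ix) A2[ix, , drop = FALSE]))
}

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.1

# Forward pass. `mdl` is a mutable environment holding params/state;
# returns logits and, when training, per-layer caches for the backward
# pass. Batch-norm running statistics are updated in place when training.
.nnForward <- function(mdl, A, N, training = FALSE) {
  layers <- mdl$layers
  H <- W <- mdl$inputSize
  spatial <- TRUE
  caches <- if (training) vector("list", nrow(layers)) else NULL
  for (i in seq_len(nrow(layers))) {
    kind <- layers$kind[i]
    if (kind == "conv") {
      k <- layers$kernel[i]
      Xcol <- .im2col(A, H, W, k, N)
      P <- mdl$params[[i]]
      A <- Xcol %*% P$W
      A <- A + rep(P$b, each = nrow(A))
      if (training) caches[[i]] <- list(Xcol = Xcol, H = H, W = W, k = k)
    } else if (kind == "batch_norm") {
      P <- mdl$params[[i]]
      if (training) {
        mu <- colMeans(A)
        Ac <- A - rep(mu, each = nrow(A))
        v <- colMeans(Ac * Ac)
        invstd <- 1 / sqrt(v + .BN_EPS)
        xhat <- Ac * rep(invstd, each = nrow(A))
        st <- mdl$state[[i]]
        st$rm <- (1 - .BN_MOMENTUM) * st$rm + .BN_MOMENTUM * mu
        st$rv <- (1 - .BN_MOMENTUM) * st$rv + .BN_MOMENTUM * v
        mdl$state[[i]] <- st
        caches[[i]] <- list(xhat = xhat, invstd = invstd)
        A <- xhat * rep(P$gamma, each = nrow(A))
        A <- A + rep(P$beta, each = nrow(A))
      } else {
        st <- mdl$state[[i]]
        scale <- P$gamma / sqrt(st$rv + .BN_EPS)
        shift <- P$beta - st$rm * scale
        A <- A * rep(scale, each = nrow(A))
        A <- A + rep(shift, each = nrow(A))
      }
    } else if (kind == "activation") {
      if (training) caches[[i]] <- list(mask = A > 0)
      A <- A * (A > 0)
    } else if (kind == "max_pool") {
      idx <- .poolIndices(H, W, N)
      A1 <- A[idx[[1]], , drop = FALSE]
      A2 <- A[idx[[2]], , drop = FALSE]
      A3 <- A[idx[[3]], , drop = FALSE]
      A4 <- A[idx[[4]], , drop = FALSE]
      M <- pmax(A1, A2, A3, A4)
      if (training)
        caches[[i]] <- list(A1 = A1, A2 = A2, A3 = A3, A4 = A4, M = M,
                            H = H, W = W)
      A <- M
      H <- H %/% 2L
      W <- W %/% 2L
    } else if (kind == "global_avg_pool") {
      HW <- H * W
      g <- rep(seq_len(N), each = HW)
      if (training) caches[[i]] <- list(HW = HW, g = g)
      A <- rowsum(A, g, reorder = FALSE) / HW
      H <- W <- 1L
      spatial <- FALSE
    } else if (kind == "fully_connected") {
      if (spatial && H * W > 1L) {
        # flatten (N*H*W) x C -> N x (H*W*C), pixel-fastest within channel
        HW <- H * W
        C <- ncol(A)
        arr <- array(A, dim = c(HW, N, C))
        A <- t(matrix(aperm(arr, c(1, 3, 2)), ncol = N))
        if (training) caches[[i]] <- list(flat = TRUE, HW = HW, C = C)
        H <- W <- 1L
        spatial <- FALSE
      }
      P <- mdl$params[[i]]
      if (training) {
        cc <- caches[[i]]
        if (is.null(cc)) cc <- list(flat = FALSE)
        cc$X <- A
        caches[[i]] <- cc
      }
      A <- A %*% P$W
      A <- A + rep(P$b, each = nrow(A))
      spatial <- FALSE
    } else stop("unsupported layer kind in built model: ", kind)
  }
  list(logits = A, caches = caches)
}

# Backward pass from dLogits; fills `grads` (list parallel to params).
.nnBackward <- function(mdl, caches, dA, N) {
  layers <- mdl$layers
  grads <- vector("list", nrow(layers))
  for (i in rev(seq_len(nrow(layers)))) {
    kind <- layers$kind[i]
    cc <- caches[[i]]
    if (kind == "conv") {
      P <- mdl$params[[i]]
      grads[[i]] <- list(W = crossprod(cc$Xcol, dA), b = colSums(dA))
      k <- cc$k
      if (k == 1L) {
        dA <- tcrossprod(dA, P$W)
      } else {
        dXcol <- tcrossprod(dA, P$W)   # (NHW) x (k*k*Cin)
        idxs <- .convIndices(cc$H, cc$W, k, N)
        kk <- k * k
        Cin <- ncol(dXcol) %/% kk
        dAin <- matrix(0, nrow(dA), Cin)
        for (o in seq_len(kk)) {
          blk <- dXcol[, ((o - 1L) * Cin + 1L):(o * Cin), drop = FALSE]
          blk <- rbind(blk, 0)
          dAin <- dAin + blk[idxs[[kk + 1L - o]], , drop = FALSE]
        }
        dA <- dAin
      }
    } else if (kind == "batch_norm") {
      P <- mdl$params[[i]]
      m <- nrow(dA)
      grads[[i]] <- list(gamma = colSums(dA * cc$xhat), beta = colSums(dA))
      dxhat <- dA * rep(P$gamma, each = m)
      c1 <- colMeans(dxhat)
      c2 <- colMeans(dxhat * cc$xhat)
      dA <- (dxhat - rep(c1, each = m) - cc$xhat * rep(c2, each = m)) *
        rep(cc$invstd, each = m)
    } else if (kind == "activation") {
      dA <- dA * cc$mask
    } else if (kind == "max_pool") {
      idx <- .poolIndices(cc$H, cc$W, N)
      dAin <- matrix(0, N * cc$H * cc$W, ncol(dA))
      m1 <- cc$A1 == cc$M
      dAin[idx[[1]], ] <- dA * m1
      rem <- !m1
      m2 <- (cc$A2 == cc$M) & rem
      dAin[idx[[2]], ] <- dA * m2
      rem <- rem & !m2
      m3 <- (cc$A3 == cc$M) & rem
      dAin[idx[[3]], ] <- dA * m3
      dAin[idx[[4]], ] <- dA * (rem & !m3)
      dA <- dAin
    } else if (kind == "global_avg_pool") {
      dA <- dA[cc$g, , drop = FALSE] / cc$HW
    } else if (kind == "fully_connected") {
      P <- mdl$params[[i]]
      grads[[i]] <- list(W = crossprod(cc$X, dA), b = colSums(dA))
      dA <- tcrossprod(dA, P$W)
      if (isTRUE(cc$flat)) {
        # unflatten N x (H*W*C) -> (N*H*W) x C
        arr <- array(t(dA), dim = c(cc$HW, cc$C, N))
        dA <- matrix(aperm(arr, c(1, 3, 2)), ncol = cc$C)
      }
    }
  }
  grads
}

# Softmax cross-entropy; y is 0-based integer labels.
.softmaxLoss <- function(logits, y) {
  N <- nrow(logits)
  Z <- logits - apply(logits, 1, max)
  P <- exp(Z)
  P <- P / rowSums(P)
  picked <- P[cbind(seq_len(N), y + 1L)]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dZ <- P
  dZ[cbind(seq_len(N), y + 1L)] <- dZ[cbind(seq_len(N), y + 1L)] - 1
  list(loss = loss, dLogits = dZ / N)
}

# Evaluate an expression with a temporary RNG seed, restoring the caller's
# RNG state afterwards.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Build a trainable classifier from an architecture spec
#'
#' Allocates every trainable array of the architecture with deterministic
#' He-style initialization (weights ~ N(0, 2/fan_in), biases zero,
#' batch-norm scale 1 / shift 0) and zeroed batch-norm running
#' statistics. The count of allocated trainable entries is always exactly
#' \code{\link{parameterBudget}} of the spec.
#'
#' @param spec an \linkS4class{ArchitectureSpec}.
#' @param seed integer seed controlling initialization.
#' @return a \linkS4class{NeuralClassifier}.
#' @examples
#' m <- buildModel(smallReferenceSpec(32, 2), seed = 1)
#' trainableParameters(m)
#' @export
buildModel <- function(spec, seed = 1L) {
  stopifnot(is(spec, "ArchitectureSpec"))
  validObject(spec)
  layers <- spec@layers
  params <- vector("list", nrow(layers))
  state <- vector("list", nrow(layers))
  .withSeed(as.integer(seed), {
    for (i in seq_len(nrow(layers))) {
      kind <- layers$kind[i]
      n_in <- layers[["in"]][i]
      n_out <- layers$out[i]
      if (kind == "conv") {
        k <- layers$kernel[i]
        fan <- n_in * k * k
        params[[i]] <- list(
          W = matrix(stats::rnorm(fan * n_out, sd = sqrt(2 / fan)),
                     fan, n_out),
          b = if (layers$bias[i]) numeric(n_out) else NULL)
      } else if (kind == "batch_norm") {
        params[[i]] <- list(gamma = rep(1, n_out), beta = numeric(n_out))
        state[[i]] <- list(rm = numeric(n_out), rv = rep(1, n_out))
      } else if (kind == "fully_connected") {
        params[[i]] <- list(
          W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)),
                     n_in, n_out),
          b = if (layers$bias[i]) numeric(n_out) else NULL)
      } else if (!kind %in% .LAYER_KINDS) {
        stop("cannot build layer of kind: ", kind)
      }
    }
  })
  new("NeuralClassifier", spec = spec, params = params, state = state,
      seed = as.integer(seed))
}

#' @rdname trainableParameters
#' @export
setMethod("trainableParameters", "NeuralClassifier", function(object) {
  sum(vapply(object@params, function(p) {
    if (is.null(p)) 0 else sum(vapply(p, length, numeric(1)))
  }, numeric(1)))
})

# Materialize the mutable training environment from a NeuralClassifier.
.asEnv <- function(model) {
  mdl <- new.env(parent = emptyenv())
  mdl$layers <- model@spec@layers
  mdl$inputSize <- model@spec@inputSize
  mdl$params <- model@params
  mdl$state <- model@state
  mdl
}

.fromEnv <- function(mdl, model) {
  model@params <- mdl$params
  model@state <- mdl$state
  model
}

# Assemble the (n*H*W) x C activation matrix for images `ix` from the
# dataset array X of dim (H*W, C, N).
.batchMatrix <- function(X, ix) {
  d <- dim(X)
  sub <- X[, , ix, drop = FALSE]
  matrix(aperm(sub, c(1, 3, 2)), nrow = d[1] * length(ix), ncol = d[2])
}

.adamInit <- function(params) {
  lapply(params, function(p) {
    if (is.null(p)) return(NULL)
    lapply(p, function(a) if (is.null(a)) NULL else
      list(m = a * 0, v = a * 0))
  })
}

.ADAM_B1 <- 0.9
.ADAM_B2 <- 0.999
.ADAM_EPS <- 1e-8

.adamStep <- function(mdl, grads, opt, lr, wd, t) {
  bc1 <- 1 - .ADAM_B1^t
  bc2 <- 1 - .ADAM_B2^t
  for (i in seq_along(mdl$params)) {
    p <- mdl$params[[i]]
    g <- grads[[i]]
    if (is.null(p) || is.null(g)) next
    for (nm in names(p)) {
      if (is.null(p[[nm]])) next
      st <- opt$s[[i]][[nm]]
      st$m <- .ADAM_B1 * st$m + (1 - .ADAM_B1) * g[[nm]]
      st$v <- .ADAM_B2 * st$v + (1 - .ADAM_B2) * g[[nm]]^2
      opt$s[[i]][[nm]] <- st
      upd <- (st$m / bc1) / (sqrt(st$v / bc2) + .ADAM_EPS)
      # decoupled weight decay on weights only (AdamW)
      decay <- if (nm == "W") wd * p[[nm]] else 0
      p[[nm]] <- p[[nm]] - lr * (upd + decay)
    }
    mdl$params[[i]] <- p
  }
  invisible(NULL)
}

#' Plateau-driven learning-rate schedule
#'
#' Implements the halve-on-plateau rule used during screening: at every
#' \code{plateauWindow}-batch boundary, the mean training loss over the
#' most recent window is compared with the mean over the window before
#' it; if the recent mean is not lower, the learning rate is multiplied
#' by \code{lrHalvingFactor} (floored at \code{minLearningRate}).
#' Anywhere else in the loss history — including when fewer than two full
#' windows have accumulated — the rate is returned unchanged.
#'
#' @param lossHistory numeric vector of per-batch losses in batch order.
#' @param currentLr current learning rate.
#' @param config a \linkS4class{CleanerConfig} supplying
#'   \code{plateauWindow}, \code{lrHalvingFactor} and
#'   \code{minLearningRate}.
#' @return the (possibly reduced) learning rate.
#' @examples
#' cfg <- cleanerConfig(plateauWindow = 5)
#' updateLearningRate(rep(1, 10), 1e-3, cfg)  # flat loss: halved
#' updateLearningRate(10:1, 1e-3, cfg)        # decreasing: unchanged
#' @export
updateLearningRate <- function(lossHistory, currentLr, config) {
  stopifnot(is(config, "CleanerConfig"))
  w <- config@plateauWindow
  n <- length(lossHistory)
  if (n < 2L * w || n %% w != 0L) return(currentLr)
  recent <- mean(lossHistory[(n - w + 1L):n])
  previous <- mean(lossHistory[(n - 2L * w + 1L):(n - w)])
  if (recent < previous) return(currentLr)
  max(currentLr * config@lrHalvingFactor, config@minLearningRate)
}

# Train `model` on dataset array X (H*W x C x N) with 0-based labels y.
# Returns list(model, lossHistory, finalLr). Deterministic given seed.
.nnFit <- function(model, X, y, config, seed) {
  N <- dim(X)[3]
  stopifnot(length(y) == N, N >= 1)
  mdl <- .asEnv(model)
  opt <- new.env(parent = emptyenv())
  opt$s <- .adamInit(mdl$params)
  lr <- config@initialLearningRate
  losses <- numeric(0)
  t <- 0L
  .withSeed(seed, {
    for (epoch in seq_len(config@epochsPerRound)) {
      ord <- sample.int(N)
      starts <- seq(1L, N, by = config@batchSize)
      for (s in starts) {
        ix <- ord[s:min(s + config@batchSize - 1L, N)]
        A <- .batchMatrix(X, ix)
        fw <- .nnForward(mdl, A, length(ix), training = TRUE)
        sl <- .softmaxLoss(fw$logits, y[ix])
        grads <- .nnBackward(mdl, fw$caches, sl$dLogits, length(ix))
        t <- t + 1L
        .adamStep(mdl, grads, opt, lr, config@weightDecay, t)
        losses[t] <- sl$loss
        lr <- updateLearningRate(losses, lr, config)
      }
    }
  })
  list(model = .fromEnv(mdl, model), lossHistory = losses, finalLr = lr)
}

# Predict 0-based class indices for dataset array X (inference mode,
# batch-norm running statistics, no augmentation). Exact logit ties
# resolve to the lower class index.
.nnPredict <- function(model, X, batchSize = 256L) {
  N <- dim(X)[3]
  mdl <- .asEnv(model)
  out <- integer(N)
  for (s in seq(1L, N, by = batchSize)) {
    ix <- s:min(s + batchSize - 1L, N)
    A <- .batchMatrix(X, ix)
    fw <- .nnForward(mdl, A, length(ix), training = FALSE)
    out[ix] <- max.col(fw$logits, ties.method = "first") - 1L
  }
  out
}

#' Forward pass of a built model on a batch of images
#'
#' Runs the network in inference mode and returns one logit vector of
#' length \code{numClasses} per image.
#'
#' @param model a \linkS4class{NeuralClassifier}.
#' @param x a numeric array of dim (H*W, 3, N) — the package's internal
#'   image layout — or (H, W, 3, N).
#' @return numeric matrix N x numClasses of logits.
#' @export
modelLogits <- function(model, x) {
  stopifnot(is(model, "NeuralClassifier"))
  if (length(dim(x)) == 4L) {
    d <- dim(x)
    x <- array(aperm(x, c(2, 1, 3, 4)), dim = c(d[1] * d[2], d[3], d[4]))
  }
  S <- model@spec@inputSize
  if (dim(x)[1] != S * S)
    stop("images must be ", S, "x", S, " for architecture '",
         model@spec@name, "'")
  mdl <- .asEnv(model)
  N <- dim(x)[3]
  .nnForward(mdl, .batchMatrix(x, seq_len(N)), N, training = FALSE)$logits
}
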