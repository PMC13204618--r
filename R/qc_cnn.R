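# Tissue-quality CNN: three convolution-pooling blocks (12, 24, 24 filters,
# 5x5 kernels, each followed by 2x2 max-pooling) and a binary head (global
# flatten + one linear unit + sigmoid, threshold 0.5). Written directly on
# base-R arrays: convolutions are accumulated per kernel offset as strided
# slice x weight-slice matrix products, which keeps everything in BLAS.
# Activations are n x H x W x C arrays throughout.

conv_forward <- function(X, W, b) {
  dn <- dim(X); n <- dn[1]; H <- dn[2]; Wd <- dn[3]; C <- dn[4]
  k <- dim(W)[1]; OC <- dim(W)[4]
  OH <- H - k + 1L; OW <- Wd - k + 1L
  out <- matrix(rep(b, each = n * OH * OW), n * OH * OW, OC)
  for (di in seq_len(k)) for (dj in seq_len(k)) {
    Xs <- X[, di:(di + OH - 1L), dj:(dj + OW - 1L), , drop = FALSE]
    dim(Xs) <- c(n * OH * OW, C)
    out <- out + Xs %*% matrix(W[di, dj, , ], C, OC)
  }
  dim(out) <- c(n, OH, OW, OC)
  out
}

conv_backward <- function(X, W, dOut) {
  dn <- dim(X); n <- dn[1]; C <- dn[4]
  k <- dim(W)[1]; OC <- dim(W)[4]
  OH <- dim(dOut)[2]; OW <- dim(dOut)[3]
  dOm <- dOut; dim(dOm) <- c(n * OH * OW, OC)
  dW <- array(0, dim(W)); dX <- array(0, dim(X))
  db <- colSums(dOm)
  for (di in seq_len(k)) for (dj in seq_len(k)) {
    Xs <- X[, di:(di + OH - 1L), dj:(dj + OW - 1L), , drop = FALSE]
    dim(Xs) <- c(n * OH * OW, C)
    dW[di, dj, , ] <- crossprod(Xs, dOm)
    dXs <- dOm %*% t(matrix(W[di, dj, , ], C, OC))
    dim(dXs) <- c(n, OH, OW, C)
    dX[, di:(di + OH - 1L), dj:(dj + OW - 1L), ] <-
      dX[, di:(di + OH - 1L), dj:(dj + OW - 1L), , drop = FALSE] + dXs
  }
  list(dX = dX, dW = dW, db = db)
}

# 2x2 max-pool, stride 2 (H, W even). Ties route to the first slice.
pool_forward <- function(X) {
  dn <- dim(X); H <- dn[2]; W <- dn[3]
  i1 <- seq(1L, H, 2L); i2 <- seq(2L, H, 2L)
  j1 <- seq(1L, W, 2L); j2 <- seq(2L, W, 2L)
  s <- list(X[, i1, j1, , drop = FALSE], X[, i1, j2, , drop = FALSE],
            X[, i2, j1, , drop = FALSE], X[, i2, j2, , drop = FALSE])
  out <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  list(out = out, slices = s)
}

pool_backward <- function(pf, dOut) {
  dn <- dim(pf$slices[[1]])
  H2 <- dn[2] * 2L; W2 <- dn[3] * 2L
  dX <- array(0, c(dn[1], H2, W2, dn[4]))
  i1 <- seq(1L, H2, 2L); i2 <- seq(2L, H2, 2L)
  j1 <- seq(1L, W2, 2L); j2 <- seq(2L, W2, 2L)
  rows <- list(i1, i1, i2, i2); cols <- list(j1, j2, j1, j2)
  taken <- array(FALSE, dim(dOut))
  for (m in 1:4) {
    mask <- (pf$slices[[m]] == pf$out) & !taken
    taken <- taken | mask
    dX[, rows[[m]], cols[[m]], ] <- dOut * mask
  }
  dX
}

qc_forward <- function(p, X, keep_cache = FALSE) {
  c1 <- conv_forward(X, p$W1, p$b1); a1 <- pmax(c1, 0); p1 <- pool_forward(a1)
  c2 <- conv_forward(p1$out, p$W2, p$b2); a2 <- pmax(c2, 0); p2 <- pool_forward(a2)
  c3 <- conv_forward(p2$out, p$W3, p$b3); a3 <- pmax(c3, 0); p3 <- pool_forward(a3)
  feat <- p3$out; dim(feat) <- c(dim(X)[1], length(p$w_head))
  logit <- drop(feat %*% p$w_head) + p$b_head
  prob <- sigmoid(logit)
  if (!keep_cache) return(list(prob = prob))
  list(prob = prob, logit = logit, feat = feat,
       c1 = c1, p1 = p1, c2 = c2, p2 = p2, c3 = c3, p3 = p3)
}

qc_backward <- function(p, X, cache, y) {
  n <- length(y)
  dlogit <- (cache$prob - y) / n                   # BCE w.r.t. logit
  dw_head <- drop(crossprod(cache$feat, dlogit))
  db_head <- sum(dlogit)
  dfeat <- outer(dlogit, p$w_head)
  dp3 <- dfeat; dim(dp3) <- dim(cache$p3$out)
  da3 <- pool_backward(cache$p3, dp3) * (cache$c3 > 0)
  bk3 <- conv_backward(cache$p2$out, p$W3, da3)
  da2 <- pool_backward(cache$p2, bk3$dX) * (cache$c2 > 0)
  bk2 <- conv_backward(cache$p1$out, p$W2, da2)
  da1 <- pool_backward(cache$p1, bk2$dX) * (cache$c1 > 0)
  bk1 <- conv_backward(X, p$W1, da1)
  list(W1 = bk1$dW, b1 = bk1$db, W2 = bk2$dW, b2 = bk2$db,
       W3 = bk3$dW, b3 = bk3$db, w_head = dw_head, b_head = db_head)
}

qc_init <- function(size = 36L) {
  filt <- c(12L, 24L, 24L); k <- 5L
  mk <- function(cin, cout) {
    lim <- sqrt(6 / (k * k * cin + cout))
    array(stats::runif(k * k * cin * cout, -lim, lim), c(k, k, cin, cout))
  }
  # 36 -> 32 -> 16 -> 12 -> 6 -> 2 -> 1: head sees 1x1x24 features
  list(W1 = mk(1L, filt[1]), b1 = numeric(filt[1]),
       W2 = mk(filt[1], filt[2]), b2 = numeric(filt[2]),
       W3 = mk(filt[2], filt[3]), b3 = numeric(filt[3]),
       w_head = stats::runif(filt[3], -0.3, 0.3), b_head = 0)
}

#' Train the tissue-vs-non-tissue QC classifier
#'
#' Fits the quality-control CNN on grayscale tiles (see [make_qc_tiles()]).
#' The trunk is fixed by design — three convolution blocks of 12, 24 and 24
#' filters, all 5x5 kernels, each followed by 2x2 max-pooling — and the
#' binary head is a single linear unit with sigmoid on the pooled features.
#' Optimised with minibatch Adam on binary cross-entropy; fully
#' deterministic given `seed`.
#'
#' @param tiles n x 36 x 36 array of intensities in \[0, 1\].
#' @param labels factor or character, `tissue` vs `non_tissue`.
#' @param seed RNG seed (initialisation and batch order).
#' @param epochs training epochs (default 8; the synthetic classes are
#'   close to linearly separable and converge quickly).
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @return object of class `qc_model`; its `architecture` field records
#'   filter counts, kernel and pool sizes for introspection.
#' @export
fit_tissue_qc <- function(tiles, labels, seed = 1L, epochs = 8L, lr = 3e-3,
                          batch_size = 64L) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop_param("need both classes to train the QC model")
  if (length(dim(tiles)) != 3 || dim(tiles)[2] != 36 || dim(tiles)[3] != 36)
    stop_param("tiles must be an n x 36 x 36 array")
  n <- dim(tiles)[1]
  if (length(labels) != n) stop_param("labels must align with tiles")
  y <- as.numeric(labels == "tissue")
  X <- tiles; dim(X) <- c(n, 36, 36, 1)
  set.seed(seed)
  params <- qc_init()
  st <- adam_init(params)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      cache <- qc_forward(params, X[idx, , , , drop = FALSE], keep_cache = TRUE)
      grads <- qc_backward(params, X[idx, , , , drop = FALSE], cache, y[idx])
      up <- adam_step(params, grads, st, lr)
      params <- up$params; st <- up$state
    }
  }
  structure(list(params = params,
                 architecture = list(filters = c(12L, 24L, 24L),
                                     kernel = c(5L, 5L), pool = c(2L, 2L),
                                     input = c(36L, 36L),
                                     head = "global flatten + linear + sigmoid"),
                 threshold = 0.5, seed = seed, epochs = epochs),
            class = "qc_model")
}

#' @export
print.qc_model <- function(x, ...) {
  a <- x$architecture
  cat(sprintf("<qc_model> conv %s (kernel %dx%d, pool %dx%d), %s\n",
              paste(a$filters, collapse = "/"), a$kernel[1], a$kernel[2],
              a$pool[1], a$pool[2], a$head))
  invisible(x)
}

#' Score tiles with a fitted QC model
#'
#' @param model a `qc_model`.
#' @param tiles n x 36 x 36 array.
#' @return numeric vector of tissue probabilities; classify as tissue at
#'   `>= model$threshold`.
#' @export
predict_qc <- function(model, tiles) {
  if (!inherits(model, "qc_model")) stop_param("model must be a qc_model")
  if (length(dim(tiles)) != 3) stop_param("tiles must be an n x 36 x 36 array")
  n <- dim(tiles)[1]
  X <- tiles; dim(X) <- c(n, dim(tiles)[2], dim(tiles)[3], 1)
  qc_forward(model$params, X)$prob
}

#' QC-screen a synthetic slide bag
#'
#' Bags carry embeddings, not pixels, so the QC CNN cannot read them
#' directly. For synthetic cohorts this helper renders one proxy tile per
#' patch — an artifact tile for patches of tissue class `artifact`
#' (subtype cycling through background/marker/blur), a textured tissue
#' tile otherwise — and scores the tiles with the CNN. The scores feed
#' [select_patches()] in `all_tissue` mode.
#'
#' @param bag a `slide_bag`.
#' @param model a fitted `qc_model`.
#' @param seed RNG seed for tile rendering.
#' @return per-patch tissue probabilities.
#' @export
qc_screen_bag <- function(bag, model, seed = 1L) {
  if (!inherits(bag, "slide_bag")) stop_param("bag must be a slide_bag")
  n <- length(bag$tissue_class)
  set.seed(seed)
  tiles <- array(0, c(n, 36, 36))
  subtypes <- c("background", "marker", "blur")
  for (i in seq_len(n)) {
    kind <- if (bag$tissue_class[i] == "artifact")
      subtypes[(i %% 3) + 1] else "texture"
    tiles[i, , ] <- render_qc_tile(kind)
  }
  predict_qc(model, tiles)
}
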