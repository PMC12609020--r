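# Compact convolutional network for scalogram classification:
# [Conv(3x3, same) - BatchNorm - ReLU - MaxPool(2x2)] x 3 (16/32/64 filters)
# -> Dropout(0.4) -> fully connected -> softmax over {HC, OA}.
# Implemented with im2col gathers and BLAS matrix products; gradients are
# hand-derived and verified against finite differences in the test suite.

#' CNN configuration
#'
#' Defaults follow the pipeline settings: three blocks with increasing
#' filter counts, 3x3 kernels with same padding, 2x2 max pooling, dropout
#' 0.4, Adam (step size 1e-3) for 30 epochs, batch size 32, L2 penalty
#' 0.01, and an asymmetric HC-probability cutoff of 0.7.
#'
#' @param filters Filter counts for the three blocks (strictly increasing).
#' @param dropout Dropout rate before the dense layer.
#' @param epochs Training epochs.
#' @param batch Mini-batch size.
#' @param l2 L2 penalty on convolutional and dense weights.
#' @param lr Adam step size.
#' @param hc_threshold HC-probability cutoff; below it, cases go to OA.
#' @param seed Integer seed.
#' @return A list of class `vag_cnn_config`.
#' @export
cnn_config <- function(filters = c(16L, 32L, 64L), dropout = 0.4,
                       epochs = 30L, batch = 32L, l2 = 0.01, lr = 1e-3,
                       hc_threshold = 0.7, seed = 1L) {
  stopifnot(length(filters) == 3, all(diff(filters) > 0),
            dropout >= 0, dropout < 1, epochs >= 1, batch >= 1, l2 >= 0,
            lr > 0, hc_threshold >= 0, hc_threshold <= 1)
  structure(list(filters = as.integer(filters), dropout = dropout,
                 epochs = as.integer(epochs), batch = as.integer(batch),
                 l2 = l2, lr = lr, hc_threshold = hc_threshold,
                 seed = as.integer(seed)),
            class = "vag_cnn_config")
}

# im2col gather indices for a 3x3 same-padding convolution on an H x W map.
im2col_indices <- function(H, W) {
  Hp <- H + 2L
  rc <- expand.grid(r = seq_len(H), c = seq_len(W))
  off <- expand.grid(di = 0:2, dj = 0:2)
  idx <- matrix(0L, nrow = 9, ncol = H * W)
  for (k in seq_len(9)) {
    pr <- rc$r + off$di[k]
    pc <- rc$c + off$dj[k]
    idx[k, ] <- (pc - 1L) * Hp + pr
  }
  interior <- (rc$c) * Hp + rc$r + 1L  # position of X[r,c] inside the padded map
  list(idx = as.vector(idx), interior = interior, n_pad = Hp * (W + 2L))
}

# Linear spatial indices of the four 2x2 pooling sub-grids.
pool_indices <- function(H, W) {
  ro <- seq(1L, H, by = 2L); co <- seq(1L, W, by = 2L)
  grid <- expand.grid(r = ro, c = co)
  lapply(list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L)), function(d) {
    (grid$c + d[2] - 1L) * H + grid$r + d[1]
  })
}

#' Build an untrained CNN
#'
#' @param config A [cnn_config()].
#' @param input_resolution Input image side, 128 or 256 (any multiple of 8
#'   works; the dense layer sees a `resolution/8` square map).
#' @param n_channels Input channels (3 for RGB scalograms).
#' @return A list of class `vag_cnn` with He-initialised weights, batch-norm
#'   parameters, the dense layer, and a `n_parameters` count. Initialisation
#'   is deterministic under `config$seed`.
#' @export
build_cnn <- function(config, input_resolution = 128L, n_channels = 3L) {
  stopifnot(inherits(config, "vag_cnn_config"))
  if (input_resolution %% 8 != 0) abort("`input_resolution` must be a multiple of 8.")
  sizes <- input_resolution / c(1L, 2L, 4L)
  c_in <- c(n_channels, config$filters[1], config$filters[2])
  blocks <- list()
  with_seed(config$seed, {
    for (b in 1:3) {
      fan_in <- c_in[b] * 9
      blocks[[b]] <- list(
        W = matrix(rnorm(config$filters[b] * fan_in, sd = sqrt(2 / fan_in)),
                   nrow = config$filters[b]),
        b = numeric(config$filters[b]),
        gamma = rep(1, config$filters[b]),
        beta = numeric(config$filters[b]),
        run_mean = numeric(config$filters[b]),
        run_var = rep(1, config$filters[b]),
        C_in = c_in[b], C_out = config$filters[b],
        H = sizes[b], W_sp = sizes[b],
        col = im2col_indices(sizes[b], sizes[b]),
        pool = pool_indices(sizes[b], sizes[b])
      )
    }
    feat_dim <- config$filters[3] * (input_resolution / 8)^2
    fc <- list(W = matrix(rnorm(2 * feat_dim, sd = sqrt(2 / feat_dim)), nrow = 2),
               b = numeric(2))
  })
  n_par <- sum(vapply(blocks, function(bl) length(bl$W) + length(bl$b) +
                        2 * length(bl$gamma), numeric(1))) +
    length(fc$W) + length(fc$b)
  structure(list(config = config, resolution = as.integer(input_resolution),
                 n_channels = as.integer(n_channels), blocks = blocks, fc = fc,
                 feat_dim = as.integer(feat_dim), n_parameters = n_par,
                 classes = c("HC", "OA")),
            class = "vag_cnn")
}

#' @export
print.vag_cnn <- function(x, ...) {
  cat(sprintf("<vag_cnn> %dx%dx%d input, filters %s, %d parameters\n",
              x$resolution, x$resolution, x$n_channels,
              paste(x$config$filters, collapse = "/"), x$n_parameters))
  invisible(x)
}

conv_im2col <- function(Xb, block, B) {
  # Xb: (C_in, HW * B). Returns list(Y = (C_out, HW * B), patches per image).
  HW <- block$H * block$W_sp
  Y <- matrix(0, block$C_out, HW * B)
  for (img in seq_len(B)) {
    cols <- ((img - 1) * HW + 1):(img * HW)
    Xp <- matrix(0, block$C_in, block$col$n_pad)
    Xp[, block$col$interior] <- Xb[, cols, drop = FALSE]
    patches <- Xp[, block$col$idx, drop = FALSE]
    dim(patches) <- c(block$C_in * 9, HW)
    Y[, cols] <- block$W %*% patches + block$b
  }
  Y
}

conv_backward <- function(Xb, dY, block, B) {
  HW <- block$H * block$W_sp
  dW <- matrix(0, nrow(block$W), ncol(block$W))
  db <- numeric(block$C_out)
  dX <- matrix(0, block$C_in, HW * B)
  for (img in seq_len(B)) {
    cols <- ((img - 1) * HW + 1):(img * HW)
    Xp <- matrix(0, block$C_in, block$col$n_pad)
    Xp[, block$col$interior] <- Xb[, cols, drop = FALSE]
    patches <- Xp[, block$col$idx, drop = FALSE]
    dim(patches) <- c(block$C_in * 9, HW)
    dYi <- dY[, cols, drop = FALSE]
    dW <- dW + dYi %*% t(patches)
    db <- db + rowSums(dYi)
    dpatch <- t(block$W) %*% dYi          # (C_in*9, HW)
    dim(dpatch) <- c(block$C_in, 9 * HW)
    acc <- rowsum(t(dpatch), group = block$col$idx)  # (n unique pad pos, C_in)
    dXp <- matrix(0, block$col$n_pad, block$C_in)
    dXp[as.integer(rownames(acc)), ] <- acc
    dX[, cols] <- t(dXp)[, block$col$interior, drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

bn_forward <- function(Y, block, training, eps = 1e-5) {
  if (training) {
    mu <- rowMeans(Y)
    v <- rowMeans((Y - mu)^2)
  } else {
    mu <- block$run_mean
    v <- block$run_var
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- (Y - mu) * inv
  list(out = block$gamma * xhat + block$beta, xhat = xhat, inv = inv,
       mu = mu, var = v)
}

bn_backward <- function(dOut, cache, block) {
  m <- ncol(cache$xhat)
  dgamma <- rowSums(dOut * cache$xhat)
  dbeta <- rowSums(dOut)
  dxhat <- dOut * block$gamma
  dY <- cache$inv * (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dY = dY, dgamma = dgamma, dbeta = dbeta)
}

pool_forward <- function(A, block, B) {
  HW <- block$H * block$W_sp
  HW4 <- HW / 4
  C <- nrow(A)
  out <- matrix(0, C, HW4 * B)
  arg <- matrix(0L, C, HW4 * B)
  for (img in seq_len(B)) {
    cols <- ((img - 1) * HW + 1):(img * HW)
    Ai <- A[, cols, drop = FALSE]
    subs <- lapply(block$pool, function(p) Ai[, p, drop = FALSE])
    stacked <- cbind(as.vector(subs[[1]]), as.vector(subs[[2]]),
                     as.vector(subs[[3]]), as.vector(subs[[4]]))
    which_q <- max.col(stacked, ties.method = "first")
    ocols <- ((img - 1) * HW4 + 1):(img * HW4)
    out[, ocols] <- matrix(stacked[cbind(seq_len(nrow(stacked)), which_q)], nrow = C)
    arg[, ocols] <- matrix(which_q, nrow = C)
  }
  list(out = out, arg = arg)
}

pool_backward <- function(dOut, arg, block, B) {
  HW <- block$H * block$W_sp
  HW4 <- HW / 4
  C <- nrow(dOut)
  dA <- matrix(0, C, HW * B)
  for (img in seq_len(B)) {
    ocols <- ((img - 1) * HW4 + 1):(img * HW4)
    cols <- ((img - 1) * HW + 1):(img * HW)
    dAi <- matrix(0, C, HW)
    for (q in 1:4) {
      sel <- arg[, ocols, drop = FALSE] == q
      if (any(sel)) {
        tgt <- block$pool[[q]]
        dsub <- dOut[, ocols, drop = FALSE] * sel
        dAi[, tgt] <- dAi[, tgt] + dsub
      }
    }
    dA[, cols] <- dAi
  }
  dA
}

# Full forward pass. Returns caches for backprop when training.
cnn_forward <- function(model, Xlist, training = FALSE, drop_mask = NULL) {
  B <- length(Xlist)
  res <- model$resolution
  A <- matrix(0, model$n_channels, res * res * B)
  for (img in seq_len(B)) {
    x <- Xlist[[img]]
    A[, ((img - 1) * res * res + 1):(img * res * res)] <-
      t(matrix(as.vector(x), ncol = model$n_channels))
  }
  caches <- list()
  for (b in 1:3) {
    blk <- model$blocks[[b]]
    Xin <- A
    Y <- conv_im2col(Xin, blk, B)
    bn <- bn_forward(Y, blk, training)
    R <- pmax(bn$out, 0)
    pl <- pool_forward(R, blk, B)
    caches[[b]] <- list(Xin = Xin, bn = bn, relu_mask = bn$out > 0, arg = pl$arg)
    A <- pl$out
  }
  HW3 <- (res / 8)^2
  Feat <- matrix(0, model$feat_dim, B)
  for (img in seq_len(B)) {
    Feat[, img] <- as.vector(A[, ((img - 1) * HW3 + 1):(img * HW3), drop = FALSE])
  }
  if (training && model$config$dropout > 0) {
    if (is.null(drop_mask)) {
      drop_mask <- matrix(stats::runif(length(Feat)) >= model$config$dropout,
                          nrow = nrow(Feat)) / (1 - model$config$dropout)
    }
    Feat_d <- Feat * drop_mask
  } else {
    drop_mask <- NULL
    Feat_d <- Feat
  }
  logits <- model$fc$W %*% Feat_d + model$fc$b
  mx <- apply(logits, 2, max)
  ex <- exp(sweep(logits, 2, mx))
  probs <- sweep(ex, 2, colSums(ex), "/")
  list(probs = probs, logits = logits, Feat = Feat, Feat_d = Feat_d,
       drop_mask = drop_mask, caches = caches, B = B)
}

# Backward pass. y_idx: integer class per image (1 = HC, 2 = OA).
cnn_backward <- function(model, fwd, y_idx) {
  B <- fwd$B
  onehot <- matrix(0, 2, B)
  onehot[cbind(y_idx, seq_len(B))] <- 1
  dlogits <- (fwd$probs - onehot) / B
  grads <- list(fc = list(
    W = dlogits %*% t(fwd$Feat_d) + 2 * model$config$l2 * model$fc$W,
    b = rowSums(dlogits)
  ))
  dFeat <- t(model$fc$W) %*% dlogits
  if (!is.null(fwd$drop_mask)) dFeat <- dFeat * fwd$drop_mask
  res <- model$resolution
  HW3 <- (res / 8)^2
  C3 <- model$config$filters[3]
  dA <- matrix(0, C3, HW3 * B)
  for (img in seq_len(B)) {
    dA[, ((img - 1) * HW3 + 1):(img * HW3)] <- matrix(dFeat[, img], nrow = C3)
  }
  grads$blocks <- vector("list", 3)
  for (b in 3:1) {
    blk <- model$blocks[[b]]
    ch <- fwd$caches[[b]]
    dR <- pool_backward(dA, ch$arg, blk, B)
    dBnOut <- dR * ch$relu_mask
    bnb <- bn_backward(dBnOut, ch$bn, blk)
    cb <- conv_backward(ch$Xin, bnb$dY, blk, B)
    grads$blocks[[b]] <- list(W = cb$dW + 2 * model$config$l2 * blk$W,
                              b = cb$db, gamma = bnb$dgamma, beta = bnb$dbeta)
    dA <- cb$dX
  }
  grads
}

# Cross-entropy + L2 loss of a forward pass (used by the gradient check).
cnn_loss <- function(model, fwd, y_idx) {
  B <- fwd$B
  ce <- -mean(log(pmax(fwd$probs[cbind(y_idx, seq_len(B))], 1e-12)))
  l2 <- model$config$l2 *
    (sum(vapply(model$blocks, function(b) sum(b$W^2), numeric(1))) + sum(model$fc$W^2))
  ce + l2
}

adam_init <- function(model) {
  zero_like <- function(p) lapply(p, function(v) v * 0)
  list(
    blocks = lapply(model$blocks, function(b) {
      list(m = zero_like(b[c("W", "b", "gamma", "beta")]),
           v = zero_like(b[c("W", "b", "gamma", "beta")]))
    }),
    fc = list(m = zero_like(model$fc), v = zero_like(model$fc)),
    t = 0L
  )
}

adam_update <- function(param, grad, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  m <- b1 * m + (1 - b1) * grad
  v <- b2 * v + (1 - b2) * grad^2
  mhat <- m / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

apply_adam <- function(model, grads, state) {
  state$t <- state$t + 1L
  lr <- model$config$lr
  for (b in 1:3) {
    for (nm in c("W", "b", "gamma", "beta")) {
      up <- adam_update(model$blocks[[b]][[nm]], grads$blocks[[b]][[nm]],
                        state$blocks[[b]]$m[[nm]], state$blocks[[b]]$v[[nm]],
                        lr, state$t)
      model$blocks[[b]][[nm]] <- up$param
      state$blocks[[b]]$m[[nm]] <- up$m
      state$blocks[[b]]$v[[nm]] <- up$v
    }
  }
  for (nm in c("W", "b")) {
    up <- adam_update(model$fc[[nm]], grads$fc[[nm]],
                      state$fc$m[[nm]], state$fc$v[[nm]], lr, state$t)
    model$fc[[nm]] <- up$param
    state$fc$m[[nm]] <- up$m
    state$fc$v[[nm]] <- up$v
  }
  list(model = model, state = state)
}

# Recalibrate batch-norm running statistics with full forward passes over
# the training set (robust when the number of optimisation steps is small).
recalibrate_bn <- function(model, Xlist, batch) {
  n <- length(Xlist)
  idx_sets <- split(seq_len(n), ceiling(seq_len(n) / batch))
  sums <- lapply(model$blocks, function(b) list(mu = 0, var = 0))
  for (ii in idx_sets) {
    fwd <- cnn_forward(model, Xlist[ii], training = TRUE)
    for (b in 1:3) {
      sums[[b]]$mu <- sums[[b]]$mu + fwd$caches[[b]]$bn$mu
      sums[[b]]$var <- sums[[b]]$var + fwd$caches[[b]]$bn$var
    }
  }
  for (b in 1:3) {
    model$blocks[[b]]$run_mean <- sums[[b]]$mu / length(idx_sets)
    model$blocks[[b]]$run_var <- sums[[b]]$var / length(idx_sets)
  }
  model
}

#' Asymmetric HC-probability decision rule
#'
#' Predicts HC when `p_hc >= cutoff`; cases with probability strictly below
#' the threshold go to OA.
#'
#' @param p_hc HC-class probability (or vector of them) in `[0, 1]`.
#' @param cutoff Decision threshold (0.7).
#' @return Character vector of `"HC"` / `"OA"`.
#' @export
apply_threshold <- function(p_hc, cutoff = 0.7) {
  if (any(!is.finite(p_hc)) || any(p_hc < 0) || any(p_hc > 1)) {
    abort("`p_hc` must lie in [0, 1].")
  }
  ifelse(p_hc >= cutoff, "HC", "OA")
}

# --- augmentation -----------------------------------------------------------

# Bilinear sampling of one channel at (possibly fractional) source coords.
sample_bilinear <- function(m, sy, sx) {
  h <- nrow(m); w <- ncol(m)
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  val <- function(yy, xx) {
    inside <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
    out <- numeric(length(yy))
    out[inside] <- m[cbind(yy[inside], xx[inside])]
    out
  }
  val(y0, x0) * (1 - fy) * (1 - fx) + val(y0, x0 + 1) * (1 - fy) * fx +
    val(y0 + 1, x0) * fy * (1 - fx) + val(y0 + 1, x0 + 1) * fy * fx
}

#' Random training augmentation of one image
#'
#' Random rotation (+/-10 degrees), isotropic scaling (0.9-1.1), horizontal
#' and vertical translation (+/-5 px) and horizontal flipping, composed as
#' one affine warp with bilinear sampling (zero fill outside). Applied to
#' training folds only.
#'
#' @param img `H x W x C` numeric array in `[0, 1]`.
#' @param rotation_deg,scale_range,translate_px Augmentation ranges.
#' @param hflip Allow horizontal flips.
#' @return Augmented array of the same shape. Uses the current RNG stream.
#' @export
augment_image <- function(img, rotation_deg = 10, scale_range = c(0.9, 1.1),
                          translate_px = 5, hflip = TRUE) {
  h <- dim(img)[1]; w <- dim(img)[2]; nc <- dim(img)[3]
  th <- stats::runif(1, -rotation_deg, rotation_deg) * pi / 180
  sc <- stats::runif(1, scale_range[1], scale_range[2])
  tx <- stats::runif(1, -translate_px, translate_px)
  ty <- stats::runif(1, -translate_px, translate_px)
  flip <- hflip && stats::runif(1) < 0.5
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  g <- expand.grid(y = seq_len(h), x = seq_len(w))
  u <- g$x - cx - tx
  v <- g$y - cy - ty
  if (flip) u <- -u
  # inverse rotation + inverse scale
  sx <- (cos(-th) * u - sin(-th) * v) / sc + cx
  sy <- (sin(-th) * u + cos(-th) * v) / sc + cy
  out <- array(0, dim(img))
  for (ch in seq_len(nc)) {
    out[, , ch] <- matrix(sample_bilinear(img[, , ch], sy, sx), nrow = h)
  }
  out
}

# Coerce scalogram images / arrays to [0,1] float arrays.
as_image_array <- function(img) {
  if (inherits(img, "vag_scalogram_image")) return(img$pixels / 255)
  a <- img
  if (max(a) > 1) a <- a / 255
  a
}

#' Train and evaluate the CNN with stratified k-fold cross-validation
#'
#' Per fold: augment the training split only, train for `config$epochs`
#' epochs with Adam, recalibrate batch-norm statistics on the training data,
#' then score the held-out fold. The decision rule is the asymmetric HC
#' threshold ([apply_threshold()]); the ROC/AUC uses the raw OA probability
#' `1 - P(HC)`. Positive class for the metric panel is OA.
#'
#' @param images List of `vag_scalogram_image`s or `H x W x 3` arrays.
#' @param labels `"HC"` / `"OA"` labels, one per image.
#' @param config A [cnn_config()].
#' @param augment Apply training-set augmentation.
#' @param k Number of folds.
#' @return A `vag_cv_report` (same shape as [svm_rbf_cv()]'s).
#' @export
cnn_train_cv <- function(images, labels, config = cnn_config(), augment = TRUE,
                         k = 5L) {
  labs <- as.character(labels)
  stopifnot(length(images) == length(labs), all(labs %in% c("HC", "OA")))
  Xs <- lapply(images, as_image_array)
  res <- dim(Xs[[1]])[1]
  folds <- stratified_folds(labs, k, derive_seed(config$seed, "cnn-folds"))
  y_idx <- ifelse(labs == "HC", 1L, 2L)
  fold_rows <- list(); roc_rows <- list(); conf_rows <- list(); pred_rows <- list()
  for (f in seq_len(k)) {
    tr <- which(folds != f); te <- which(folds == f)
    model <- build_cnn(config, input_resolution = res)
    model$config$seed <- derive_seed(config$seed, paste0("cnn-fold", f))
    state <- adam_init(model)
    with_seed(derive_seed(config$seed, paste0("cnn-train", f)), {
      for (ep in seq_len(config$epochs)) {
        ord <- sample(tr)
        batches <- split(ord, ceiling(seq_along(ord) / config$batch))
        for (bt in batches) {
          Xb <- lapply(Xs[bt], function(x) if (augment) augment_image(x) else x)
          fwd <- cnn_forward(model, Xb, training = TRUE)
          grads <- cnn_backward(model, fwd, y_idx[bt])
          up <- apply_adam(model, grads, state)
          model <- up$model; state <- up$state
        }
      }
    })
    model <- recalibrate_bn(model, Xs[tr], config$batch)
    # score held-out fold in evaluation mode
    p_hc <- numeric(length(te))
    chunks <- split(seq_along(te), ceiling(seq_along(te) / config$batch))
    for (cc in chunks) {
      fwd <- cnn_forward(model, Xs[te[cc]], training = FALSE)
      p_hc[cc] <- fwd$probs[1, ]
    }
    pred <- apply_threshold(p_hc, config$hc_threshold)
    truth <- labs[te]
    tp <- sum(pred == "OA" & truth == "OA")
    fn <- sum(pred != "OA" & truth == "OA")
    tn <- sum(pred != "OA" & truth != "OA")
    fp <- sum(pred == "OA" & truth != "OA")
    met <- metrics_from_confusion(tp, fn, tn, fp)
    ra <- roc_auc(1 - p_hc, truth, positive = "OA")
    fold_rows[[f]] <- dplyr::bind_cols(tibble::tibble(fold = f), met,
                                       tibble::tibble(auc = ra$auc))
    roc_rows[[f]] <- dplyr::mutate(ra$roc, fold = f)
    conf_rows[[f]] <- tibble::tibble(fold = f, tp = tp, fn = fn, tn = tn, fp = fp)
    pred_rows[[f]] <- tibble::tibble(fold = f, truth = truth, predicted = pred,
                                     score = 1 - p_hc)
  }
  fold_tbl <- dplyr::bind_rows(fold_rows)
  metric_cols <- setdiff(names(fold_tbl), "fold")
  summary <- fold_tbl |>
    tidyr::pivot_longer(dplyr::all_of(metric_cols), names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     sd = stats::sd(.data$value, na.rm = TRUE), .groups = "drop")
  structure(list(folds = fold_tbl, summary = summary,
                 roc = dplyr::bind_rows(roc_rows),
                 confusion = dplyr::bind_rows(conf_rows),
                 predictions = dplyr::bind_rows(pred_rows),
                 positive = "OA", k = k, seed = config$seed),
            class = "vag_cv_report")
}
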