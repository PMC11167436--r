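## A compact convolutional patch classifier, implemented directly in base
## R with im2col convolutions. The reference configuration in the field
## is an 18-layer residual network with a 512-wide pre-final layer; the
## architecture here keeps that network's interface contract (softmax
## disease probability; nonnegative pre-final-layer feature vector fed by
## global average pooling; saliency from the last convolutional block) at
## a CPU-trainable size:
##
##   conv3x3(3 -> c1) + ReLU + maxpool2
##   conv3x3(c1 -> c2) + ReLU + maxpool2
##   conv3x3(c2 -> F) + ReLU          <- saliency target layer
##   global average pool -> F         <- pre-final-layer features (>= 0)
##   dense F -> 2 logits, softmax
##
## Because the classifier head acts on a global average pool, the
## gradient-weighted class-activation map has closed-form channel weights
## (the head's weights divided by the spatial area), so saliency needs no
## numerical backward pass.

#' Configuration for the compact CNN
#'
#' @param input_size square input side in pixels (patches are resized to
#'   this; default 64, the desk-scale test default).
#' @param channels widths of the two downsampling conv blocks.
#' @param feature_width width F of the pre-final feature layer.
#' @param epochs training epochs (default 18).
#' @param lr SGD learning rate.
#' @param momentum SGD momentum.
#' @param batch_size minibatch size.
#' @param augment logical: random flips/rotations during training.
#' @param val_fraction fraction of subjects held out for validation
#'   (default 0.2, the 80/20 convention).
#' @param seed integer seed controlling the split, initialization and
#'   data order.
#' @return list of class `cnn_config`.
#' @export
cnn_config <- function(input_size = 64, channels = c(8, 16), feature_width = 32,
                       epochs = 18, lr = 0.02, momentum = 0.9,
                       batch_size = 16, augment = TRUE, val_fraction = 0.2,
                       seed = 1) {
  structure(list(input_size = check_count(input_size, "input_size", 8L),
                 channels = channels, feature_width = feature_width,
                 epochs = check_count(epochs, "epochs"),
                 lr = lr, momentum = momentum,
                 batch_size = check_count(batch_size, "batch_size"),
                 augment = isTRUE(augment),
                 val_fraction = check_fraction(val_fraction, "val_fraction", 0, 0.9),
                 seed = seed),
            class = "cnn_config")
}

## --- primitive layers -------------------------------------------------------

im2col_idx <- function(H, W, C) {
  Hp <- H + 2L; Wp <- W + 2L
  i <- rep(seq_len(H), times = W)
  j <- rep(seq_len(W), each = H)
  cols <- vector("list", 9L * C)
  m <- 0L
  for (ch in seq_len(C)) for (dj in 0:2) for (di in 0:2) {
    m <- m + 1L
    cols[[m]] <- (i + di) + (j + dj - 1L) * Hp + (ch - 1L) * Hp * Wp
  }
  do.call(cbind, cols)
}

pad1 <- function(x) {
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2L, d[2] + 2L, d[3]))
  out[2:(d[1] + 1L), 2:(d[2] + 1L), ] <- x
  out
}

conv_forward <- function(x, Wm, b, idx) {
  d <- dim(x)
  xp <- pad1(x)
  X2 <- xp[idx]
  dim(X2) <- dim(idx)
  out <- X2 %*% Wm
  out <- sweep(out, 2, b, "+")
  list(out = array(out, dim = c(d[1], d[2], ncol(Wm))), X2 = X2, dims = d)
}

conv_backward <- function(dout, X2, Wm, idx, dims) {
  HW <- nrow(X2)
  dO <- matrix(dout, HW, dim(dout)[3])
  dW <- crossprod(X2, dO)
  db <- colSums(dO)
  dX2 <- dO %*% t(Wm)
  Hp <- dims[1] + 2L; Wp <- dims[2] + 2L
  dxp <- numeric(Hp * Wp * dims[3])
  for (m in seq_len(ncol(idx))) {
    ii <- idx[, m]
    dxp[ii] <- dxp[ii] + dX2[, m]
  }
  dim(dxp) <- c(Hp, Wp, dims[3])
  list(dx = dxp[2:(dims[1] + 1L), 2:(dims[2] + 1L), , drop = FALSE],
       dW = dW, db = db)
}

relu <- function(x) { x[x < 0] <- 0; x }

maxpool2 <- function(x) {
  d <- dim(x)
  o1 <- seq(1L, d[1], 2L); o2 <- seq(2L, d[1], 2L)
  e1 <- seq(1L, d[2], 2L); e2 <- seq(2L, d[2], 2L)
  a <- x[o1, e1, , drop = FALSE]; b <- x[o1, e2, , drop = FALSE]
  cc <- x[o2, e1, , drop = FALSE]; dd <- x[o2, e2, , drop = FALSE]
  out <- pmax(a, b, cc, dd)
  list(out = out, parts = list(a, b, cc, dd), dims = d)
}

maxpool2_backward <- function(dout, pool) {
  d <- pool$dims
  out <- pmax(pool$parts[[1]], pool$parts[[2]], pool$parts[[3]], pool$parts[[4]])
  dx <- array(0, dim = d)
  o1 <- seq(1L, d[1], 2L); o2 <- seq(2L, d[1], 2L)
  e1 <- seq(1L, d[2], 2L); e2 <- seq(2L, d[2], 2L)
  taken <- array(FALSE, dim = dim(out))
  sel <- list(list(o1, e1), list(o1, e2), list(o2, e1), list(o2, e2))
  for (k in 1:4) {
    m <- (pool$parts[[k]] == out) & !taken
    taken <- taken | m
    g <- dout * m
    dx[sel[[k]][[1]], sel[[k]][[2]], ] <- g
  }
  dx
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

## --- model ------------------------------------------------------------------

init_cnn <- function(config) {
  c1 <- config$channels[1]; c2 <- config$channels[2]; f <- config$feature_width
  rnorm_mat <- function(nr, nc, fanin)
    matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fanin)), nr, nc)
  list(W1 = rnorm_mat(9 * 3, c1, 9 * 3), b1 = numeric(c1),
       W2 = rnorm_mat(9 * c1, c2, 9 * c1), b2 = numeric(c2),
       W3 = rnorm_mat(9 * c2, f, 9 * c2), b3 = numeric(f),
       Wd = rnorm_mat(f, 2, f), bd = numeric(2))
}

cnn_forward <- function(par, x, idx, keep_cache = FALSE) {
  c1f <- conv_forward(x, par$W1, par$b1, idx$l1)
  a1 <- relu(c1f$out)
  p1 <- maxpool2(a1)
  c2f <- conv_forward(p1$out, par$W2, par$b2, idx$l2)
  a2 <- relu(c2f$out)
  p2 <- maxpool2(a2)
  c3f <- conv_forward(p2$out, par$W3, par$b3, idx$l3)
  a3 <- relu(c3f$out)
  gap <- apply(a3, 3, mean)
  logits <- as.numeric(crossprod(par$Wd, gap)) + par$bd
  probs <- softmax(logits)
  out <- list(probs = probs, logits = logits, gap = gap, a3 = a3)
  if (keep_cache)
    out$cache <- list(x = x, c1f = c1f, a1 = a1, p1 = p1, c2f = c2f,
                      a2 = a2, p2 = p2, c3f = c3f, a3 = a3)
  out
}

cnn_backward <- function(par, fwd, y_index, idx) {
  ch <- fwd$cache
  dlogits <- fwd$probs
  dlogits[y_index] <- dlogits[y_index] - 1
  dWd <- outer(fwd$gap, dlogits)
  dbd <- dlogits
  dgap <- as.numeric(par$Wd %*% dlogits)
  d3 <- dim(ch$a3)
  da3 <- array(rep(dgap / (d3[1] * d3[2]), each = d3[1] * d3[2]), dim = d3)
  da3[ch$a3 <= 0] <- 0
  cb3 <- conv_backward(da3, ch$c3f$X2, par$W3, idx$l3, ch$c3f$dims)
  dp2 <- maxpool2_backward(cb3$dx, ch$p2)
  dp2[ch$a2 <= 0] <- 0
  cb2 <- conv_backward(dp2, ch$c2f$X2, par$W2, idx$l2, ch$c2f$dims)
  dp1 <- maxpool2_backward(cb2$dx, ch$p1)
  dp1[ch$a1 <= 0] <- 0
  cb1 <- conv_backward(dp1, ch$c1f$X2, par$W1, idx$l1, ch$c1f$dims)
  list(W1 = cb1$dW, b1 = cb1$db, W2 = cb2$dW, b2 = cb2$db,
       W3 = cb3$dW, b3 = cb3$db, Wd = dWd, bd = dbd)
}

preprocess_patch <- function(pixels, input_size) {
  if (dim(pixels)[1] != input_size || dim(pixels)[2] != input_size)
    pixels <- resize_bilinear(pixels, input_size, input_size)
  pixels - 0.5
}

make_idx <- function(config) {
  P <- config$input_size
  list(l1 = im2col_idx(P, P, 3L),
       l2 = im2col_idx(P / 2L, P / 2L, config$channels[1]),
       l3 = im2col_idx(P / 4L, P / 4L, config$channels[2]))
}

#' Train the compact CNN patch classifier
#'
#' Splits subjects (never patches) 80/20 into training and validation,
#' trains by minibatch SGD with momentum on softmax cross-entropy, and
#' logs per-epoch training loss and validation accuracy. Every patch
#' inherits its subject's label (control subjects are assumed lesion-free
#' throughout). The split, initialization and data order are all
#' functions of the config seed.
#'
#' @param patches list of labeled patches from [extract_patches()] (each
#'   needs `pixels`, `parent`, `label`).
#' @param config a [cnn_config()].
#' @return object of class `histo_model`: list with `par` (weights),
#'   `config`, `classes`, `split` (subject-level manifest data.frame),
#'   `log` (per-epoch data.frame).
#' @export
train_classifier <- function(patches, config = cnn_config()) {
  labels <- vapply(patches, function(p) p$label, "")
  subjects <- vapply(patches, function(p) p$parent, "")
  classes <- c("control", "disease")
  if (!all(labels %in% classes))
    stop_invalid("labels must be 'disease' or 'control'")
  if (length(unique(labels)) < 2L)
    stop_invalid("training requires both classes")
  subj_label <- tapply(labels, subjects, function(x) x[1])
  for (cl in classes)
    if (sum(subj_label == cl) < 2L)
      stop_invalid("need >= 2 subjects per class for a subject-level split")

  with_seed(substream_seed(config$seed, 20L), {
    ## stratified subject-level 80/20 split
    split_role <- character(0)
    for (cl in classes) {
      s <- names(subj_label)[subj_label == cl]
      s <- sample(s)
      n_val <- max(1L, round(config$val_fraction * length(s)))
      split_role[s] <- c(rep("validation", n_val),
                         rep("train", length(s) - n_val))
    }
    manifest <- data.frame(subject = names(split_role),
                           label = as.character(subj_label[names(split_role)]),
                           role = as.character(split_role),
                           stringsAsFactors = FALSE)
    manifest <- manifest[order(manifest$subject), ]
    rownames(manifest) <- NULL

    idx <- make_idx(config)
    X <- lapply(patches, function(p) preprocess_patch(p$pixels, config$input_size))
    y <- match(labels, classes)
    tr <- which(split_role[subjects] == "train")
    va <- which(split_role[subjects] == "validation")
    par <- init_cnn(config)
    vel <- lapply(par, function(p) p * 0)
    log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_accuracy = numeric(0))
    for (ep in seq_len(config$epochs)) {
      ## step decay: 1x -> 0.3x -> 0.1x over the run, settling the late epochs
      lr_ep <- config$lr * c(1, 0.3, 0.1)[1L + findInterval(
        ep, config$epochs * c(0.6, 0.85) + 0.5)]
      ord <- sample(tr)
      ep_loss <- 0
      nb <- 0L
      for (start in seq(1L, length(ord), by = config$batch_size)) {
        batch <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        grads <- NULL
        bloss <- 0
        for (i in batch) {
          xi <- X[[i]]
          if (config$augment) {
            if (stats::runif(1) < 0.5) xi <- xi[, dim(xi)[2]:1, , drop = FALSE]
            if (stats::runif(1) < 0.5) xi <- xi[dim(xi)[1]:1, , , drop = FALSE]
            k <- sample(0:3, 1)
            if (k > 0) for (r in seq_len(k))
              xi <- aperm(xi, c(2, 1, 3))[dim(xi)[2]:1, , , drop = FALSE]
          }
          fwd <- cnn_forward(par, xi, idx, keep_cache = TRUE)
          bloss <- bloss - log(max(fwd$probs[y[i]], 1e-12))
          g <- cnn_backward(par, fwd, y[i], idx)
          grads <- if (is.null(grads)) g else mapply(`+`, grads, g, SIMPLIFY = FALSE)
        }
        grads <- lapply(grads, `/`, length(batch))
        for (nm in names(par)) {
          vel[[nm]] <- config$momentum * vel[[nm]] - lr_ep * grads[[nm]]
          par[[nm]] <- par[[nm]] + vel[[nm]]
        }
        ep_loss <- ep_loss + bloss / length(batch)
        nb <- nb + 1L
      }
      val_acc <- if (length(va)) {
        preds <- vapply(va, function(i)
          which.max(cnn_forward(par, X[[i]], idx)$probs), 1L)
        mean(preds == y[va])
      } else NA_real_
      log <- rbind(log, data.frame(epoch = ep, train_loss = ep_loss / max(nb, 1L),
                                   val_accuracy = val_acc))
    }
    structure(list(par = par, config = config, classes = classes,
                   split = manifest, log = log),
              class = "histo_model")
  })
}

#' @export
print.histo_model <- function(x, ...) {
  cat(sprintf("histo_model: %dx%d input, feature width %d, %d epochs\n",
              x$config$input_size, x$config$input_size,
              x$config$feature_width, nrow(x$log)))
  cat(sprintf("  final train loss %.3f, validation accuracy %.3f\n",
              utils::tail(x$log$train_loss, 1),
              utils::tail(x$log$val_accuracy, 1)))
  invisible(x)
}

#' Save / load a trained model
#'
#' The checkpoint is R's native serialization; a JSON sidecar
#' (`<path>.json`) records the config, seed, classes and subject-level
#' split manifest for audit without deserializing.
#'
#' @param model a `histo_model`.
#' @param path checkpoint file path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
save_histo_model <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(
    list(config = unclass(model$config), classes = model$classes,
         split = model$split, final_log = utils::tail(model$log, 1)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_histo_model
#' @export
load_histo_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "histo_model"))
    stop_invalid("%s is not a histo_model checkpoint", path)
  model
}

#' Disease probability for a patch
#'
#' @param model a trained `histo_model`.
#' @param pixels patch array (resized to the model input internally).
#' @return list with `disease_probability` and the full `probs` vector
#'   (named by class; sums to 1).
#' @export
predict_patch <- function(model, pixels) {
  fwd <- cnn_forward(model$par, preprocess_patch(pixels, model$config$input_size),
                     make_idx(model$config))
  probs <- stats::setNames(fwd$probs, model$classes)
  list(disease_probability = unname(probs["disease"]), probs = probs)
}

#' Pre-final-layer feature vector for a patch
#'
#' The global-average-pooled activations of the last convolutional block:
#' a nonnegative length-F morphological fingerprint. Applying the
#' classifier head to this vector reproduces the model's logits exactly.
#'
#' @inheritParams predict_patch
#' @return list with `vector` (length F, >= 0), `disease_probability`,
#'   and `logits`.
#' @export
extract_features <- function(model, pixels) {
  fwd <- cnn_forward(model$par, preprocess_patch(pixels, model$config$input_size),
                     make_idx(model$config))
  list(vector = fwd$gap,
       disease_probability = unname(fwd$probs[match("disease", model$classes)]),
       logits = fwd$logits)
}

#' Class-activation saliency map for a patch
#'
#' Gradient-weighted class activation mapping on the last convolutional
#' block. With a global-average-pooling head the channel weights are the
#' head's weights for the target class divided by the spatial area, so
#' the map is computed in closed form: the rectified weighted channel
#' sum, min-max normalized to \[0, 1\] and bilinearly upsampled to the
#' patch size.
#'
#' @inheritParams predict_patch
#' @param target_class `"disease"` or `"control"`.
#' @return list with `heat` (patch-sized matrix in \[0,1\]) and
#'   `target_class`. A constant map is returned all-zero with a warning.
#' @export
gradcam <- function(model, pixels, target_class = "disease") {
  ci <- match(target_class, model$classes)
  if (is.na(ci)) stop_invalid("unknown class '%s'", target_class)
  fwd <- cnn_forward(model$par, preprocess_patch(pixels, model$config$input_size),
                     make_idx(model$config))
  A <- fwd$a3
  hw <- dim(A)[1] * dim(A)[2]
  alpha <- model$par$Wd[, ci] / hw
  cam <- apply(sweep(A, 3, alpha, "*"), c(1, 2), sum)
  cam[cam < 0] <- 0
  rng <- range(cam)
  if (diff(rng) < 1e-12) {
    warning("constant activation map; returning all zeros")
    cam[] <- 0
  } else {
    cam <- (cam - rng[1]) / diff(rng)
  }
  P <- dim(pixels)[1]
  heat <- resize_bilinear(array(cam, dim = c(dim(cam), 1L)), P, dim(pixels)[2])[, , 1]
  list(heat = heat, target_class = target_class)
}

#' Evaluate a model on labeled patches
#'
#' @param model a trained `histo_model`.
#' @param patches labeled patch list.
#' @return list with `confusion` (rows = true class, columns = predicted),
#'   `per_class_accuracy`, and overall `accuracy`.
#' @export
evaluate <- function(model, patches) {
  if (length(patches) == 0L) stop_invalid("no patches to evaluate")
  truth <- vapply(patches, function(p) p$label, "")
  idx <- make_idx(model$config)
  pred <- vapply(patches, function(p) {
    fwd <- cnn_forward(model$par,
                       preprocess_patch(p$pixels, model$config$input_size), idx)
    model$classes[which.max(fwd$probs)]
  }, "")
  cm <- table(factor(truth, levels = model$classes),
              factor(pred, levels = model$classes))
  cm <- unclass(as.matrix(cm))
  names(dimnames(cm)) <- c("true", "predicted")
  pca <- diag(cm) / pmax(rowSums(cm), 1L)
  list(confusion = cm, per_class_accuracy = pca,
       accuracy = sum(diag(cm)) / sum(cm))
}
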