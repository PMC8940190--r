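# Frame-level classifiers: DNN, LSTM, BiLSTM, GRU (hand-written networks with
# compiled recurrent kernels) and a random-forest baseline. All networks end
# in a single linear + softmax head over the K disorder classes; recurrent
# stacks use 2 layers of 50 cells, the BiLSTM sums (not concatenates) its
# forward and backward outputs per layer so the hidden width stays 50.

glorot <- function(n_in, n_out) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out)
}

#' Model configuration
#'
#' @param kind one of `"dnn"`, `"lstm"`, `"bilstm"`, `"gru"`, `"rf"`
#' @param n_classes number of disorder classes K
#' @param layer_sizes DNN hidden sizes (default three layers of 200)
#' @param cells recurrent cells per layer (default 50)
#' @param n_layers recurrent layers / BiLSTM blocks (default 2)
#' @param dropout dropout rate on recurrent-layer outputs (default 0.2)
#' @param n_trees random-forest ensemble size (default 26)
#' @return object of class `model_config`
#' @export
model_config <- function(kind = c("bilstm", "lstm", "gru", "dnn", "rf"),
                         n_classes = 4L, layer_sizes = c(200L, 200L, 200L),
                         cells = 50L, n_layers = 2L, dropout = 0.2,
                         n_trees = 26L) {
  kind <- match.arg(kind)
  if (dropout < 0 || dropout >= 1) stopf("dropout must be in [0, 1)")
  if (any(layer_sizes <= 0) || cells <= 0 || n_layers <= 0 || n_trees <= 0)
    stopf("sizes must be positive")
  structure(list(kind = kind, n_classes = as.integer(n_classes),
                 layer_sizes = as.integer(layer_sizes),
                 cells = as.integer(cells), n_layers = as.integer(n_layers),
                 dropout = dropout, n_trees = as.integer(n_trees)),
            class = "model_config")
}

#' Build an untrained classifier
#'
#' Initializes network weights (Glorot uniform; LSTM forget-gate biases start
#' at 1) from the current RNG state. Random-forest models are built lazily at
#' training time.
#'
#' @param cfg a [model_config()]
#' @param input_dim feature dimension (26 for MFCC+delta)
#' @return object of class `voice_model`
#' @export
build_model <- function(cfg, input_dim = 26L) {
  if (!inherits(cfg, "model_config")) stopf("cfg must be a model_config")
  D <- as.integer(input_dim); K <- cfg$n_classes; H <- cfg$cells
  params <- switch(cfg$kind,
    dnn = {
      sizes <- c(D, cfg$layer_sizes)
      p <- list()
      for (i in seq_along(cfg$layer_sizes)) {
        p[[paste0("W", i)]] <- glorot(sizes[i], sizes[i + 1])
        p[[paste0("b", i)]] <- numeric(sizes[i + 1])
      }
      p$Wo <- glorot(sizes[length(sizes)], K); p$bo <- numeric(K)
      p
    },
    lstm = ,
    bilstm = {
      p <- list()
      d_in <- D
      for (l in seq_len(cfg$n_layers)) {
        mk <- function() {
          b <- numeric(4 * H); b[(H + 1):(2 * H)] <- 1  # forget bias
          list(Wx = glorot(d_in, 4 * H), Wh = glorot(H, 4 * H), b = b)
        }
        if (cfg$kind == "bilstm") {
          p[[paste0("l", l)]] <- list(fwd = mk(), bwd = mk())
        } else {
          p[[paste0("l", l)]] <- mk()
        }
        d_in <- H
      }
      p$Wo <- glorot(H, K); p$bo <- numeric(K)
      p
    },
    gru = {
      p <- list()
      d_in <- D
      for (l in seq_len(cfg$n_layers)) {
        p[[paste0("l", l)]] <- list(Wx = glorot(d_in, 3 * H),
                                    Wh = glorot(H, 3 * H),
                                    bx = numeric(3 * H), bh = numeric(3 * H))
        d_in <- H
      }
      p$Wo <- glorot(H, K); p$bo <- numeric(K)
      p
    },
    rf = NULL)
  structure(list(kind = cfg$kind, cfg = cfg, input_dim = D, params = params,
                 rf = NULL, classes = NULL),
            class = "voice_model")
}

n_params <- function(model) {
  if (model$kind == "rf") return(NA_integer_)
  sum(rapply(model$params, length, how = "unlist"))
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# ---- forward passes (with caches for training) ------------------------------

fwd_dnn <- function(params, X, n_hidden) {
  A <- list(); Zin <- X
  for (i in seq_len(n_hidden)) {
    Zi <- Zin %*% params[[paste0("W", i)]] +
      rep(params[[paste0("b", i)]], each = nrow(X))
    Zin <- pmax(Zi, 0)
    A[[i]] <- Zin
  }
  logits <- Zin %*% params$Wo + rep(params$bo, each = nrow(X))
  list(probs = softmax_rows(logits), hidden = A, X = X)
}

bwd_dnn <- function(params, cache, dlogits, n_hidden) {
  g <- list()
  top <- cache$hidden[[n_hidden]]
  g$Wo <- t(top) %*% dlogits
  g$bo <- colSums(dlogits)
  dZ <- dlogits %*% t(params$Wo)
  for (i in rev(seq_len(n_hidden))) {
    dZ <- dZ * (cache$hidden[[i]] > 0)
    below <- if (i == 1L) cache$X else cache$hidden[[i - 1L]]
    g[[paste0("W", i)]] <- t(below) %*% dZ
    g[[paste0("b", i)]] <- colSums(dZ)
    if (i > 1L) dZ <- dZ %*% t(params[[paste0("W", i)]])
  }
  g
}

# dropout masks are drawn in R (keeps all RNG in the seeded R stream)
make_drop_mask <- function(T_, H, rate) {
  if (rate <= 0) return(NULL)
  matrix(stats::rbinom(T_ * H, 1L, 1 - rate), T_, H) / (1 - rate)
}

fwd_recurrent <- function(model, X, train = FALSE) {
  p <- model$params; cfg <- model$cfg; L <- cfg$n_layers
  caches <- vector("list", L)
  Z <- X
  for (l in seq_len(L)) {
    lay <- p[[paste0("l", l)]]
    if (model$kind == "lstm") {
      fw <- lstm_seq_forward_cpp(Z, lay$Wx, lay$Wh, lay$b)
      out <- fw$H
      caches[[l]] <- list(in_ = Z, fw = fw)
    } else if (model$kind == "gru") {
      fw <- gru_seq_forward_cpp(Z, lay$Wx, lay$Wh, lay$bx, lay$bh)
      out <- fw$H
      caches[[l]] <- list(in_ = Z, fw = fw)
    } else {  # bilstm: directional outputs are summed, width stays `cells`
      T_ <- nrow(Z)
      rev_idx <- rev(seq_len(T_))
      fwd <- lstm_seq_forward_cpp(Z, lay$fwd$Wx, lay$fwd$Wh, lay$fwd$b)
      bwd <- lstm_seq_forward_cpp(Z[rev_idx, , drop = FALSE],
                                  lay$bwd$Wx, lay$bwd$Wh, lay$bwd$b)
      out <- fwd$H + bwd$H[rev_idx, , drop = FALSE]
      caches[[l]] <- list(in_ = Z, fwd = fwd, bwd = bwd, rev_idx = rev_idx)
    }
    if (train && cfg$dropout > 0) {
      m <- make_drop_mask(nrow(out), ncol(out), cfg$dropout)
      out <- out * m
      caches[[l]]$drop <- m
    }
    Z <- out
  }
  logits <- Z %*% p$Wo + rep(p$bo, each = nrow(Z))
  list(probs = softmax_rows(logits), top = Z, caches = caches)
}

bwd_recurrent <- function(model, cache, dlogits) {
  p <- model$params; L <- model$cfg$n_layers
  g <- list(Wo = t(cache$top) %*% dlogits, bo = colSums(dlogits))
  dZ <- dlogits %*% t(p$Wo)
  for (l in rev(seq_len(L))) {
    cl <- cache$caches[[l]]
    lay <- p[[paste0("l", l)]]
    if (!is.null(cl$drop)) dZ <- dZ * cl$drop
    if (model$kind == "lstm") {
      bk <- lstm_seq_backward_cpp(cl$in_, lay$Wx, lay$Wh, cl$fw$H, cl$fw$C,
                                  cl$fw$I, cl$fw$F, cl$fw$G, cl$fw$O, dZ)
      g[[paste0("l", l)]] <- list(Wx = bk$dWx, Wh = bk$dWh, b = as.numeric(bk$db))
      dZ <- bk$dX
    } else if (model$kind == "gru") {
      bk <- gru_seq_backward_cpp(cl$in_, lay$Wx, lay$Wh, cl$fw$H, cl$fw$Z,
                                 cl$fw$R, cl$fw$N, cl$fw$M, dZ)
      g[[paste0("l", l)]] <- list(Wx = bk$dWx, Wh = bk$dWh,
                                  bx = as.numeric(bk$dbx),
                                  bh = as.numeric(bk$dbh))
      dZ <- bk$dX
    } else {
      ri <- cl$rev_idx
      bf <- lstm_seq_backward_cpp(cl$in_, lay$fwd$Wx, lay$fwd$Wh, cl$fwd$H,
                                  cl$fwd$C, cl$fwd$I, cl$fwd$F, cl$fwd$G,
                                  cl$fwd$O, dZ)
      Xr <- cl$in_[ri, , drop = FALSE]
      bb <- lstm_seq_backward_cpp(Xr, lay$bwd$Wx, lay$bwd$Wh, cl$bwd$H,
                                  cl$bwd$C, cl$bwd$I, cl$bwd$F, cl$bwd$G,
                                  cl$bwd$O, dZ[ri, , drop = FALSE])
      g[[paste0("l", l)]] <- list(
        fwd = list(Wx = bf$dWx, Wh = bf$dWh, b = as.numeric(bf$db)),
        bwd = list(Wx = bb$dWx, Wh = bb$dWh, b = as.numeric(bb$db)))
      dZ <- bf$dX + bb$dX[ri, , drop = FALSE]
    }
  }
  g
}

#' Frame-level class posteriors
#'
#' Runs a built (or trained) model over one utterance's MFCC matrix.
#' Recurrent models consume the whole sequence; the DNN and random forest
#' act frame-wise. Dropout is disabled.
#'
#' @param model a `voice_model` (or fitted [voice_classifier()])
#' @param mfcc frames x 26 feature matrix
#' @return frames x K matrix of class posteriors (rows sum to 1)
#' @export
forward_frames <- function(model, mfcc) {
  if (inherits(model, "voice_classifier")) model <- model$model
  mfcc <- as.matrix(mfcc)
  if (ncol(mfcc) != model$input_dim)
    stopf("feature dimension %d does not match model input %d",
          ncol(mfcc), model$input_dim)
  if (model$kind == "rf") {
    if (is.null(model$rf)) stopf("random forest model has not been trained")
    colnames(mfcc) <- model$rf_feature_names
    p <- stats::predict(model$rf, as.data.frame(mfcc), type = "prob")
    return(unname(as.matrix(p)))
  }
  if (model$kind == "dnn")
    fwd_dnn(model$params, mfcc, length(model$cfg$layer_sizes))$probs
  else
    fwd_recurrent(model, mfcc, train = FALSE)$probs
}

#' Last-hidden-layer features with utterance-level pooling
#'
#' Returns the per-frame activations of the final recurrent layer (the input
#' of the feed-forward head) together with their frame mean, the
#' utterance-wise representation used for PCA visualization.
#'
#' @param model a recurrent `voice_model` or fitted classifier
#' @param mfcc frames x 26 feature matrix
#' @return list(frame_features (frames x H), pooled (length H))
#' @export
extract_hidden_features <- function(model, mfcc) {
  if (inherits(model, "voice_classifier")) model <- model$model
  if (!model$kind %in% c("lstm", "bilstm", "gru"))
    stopf("hidden-feature extraction supports recurrent models only")
  top <- fwd_recurrent(model, as.matrix(mfcc), train = FALSE)$top
  list(frame_features = top, pooled = colMeans(top))
}
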