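#' CNN configuration
#'
#' Architecture and training hyperparameters of the small 1-D convolutional
#' classifier. The 90-dimensional feature vector is consumed as a length-90,
#' single-channel signal; each convolutional stage is convolution +
#' activation + non-overlapping max-pooling, followed by a dense layer and a
#' sigmoid output giving the probability of the positive class.
#'
#' The default two-stage architecture (kernels 7 and 13, pools 2 and 2)
#' produces final convolutional feature maps of length 15 per filter:
#' 90 -> 84 -> 42 -> 30 -> 15. The configuration is validated so that the
#' stage arithmetic reaches exactly `conv_output_length`; any architecture
#' satisfying that contract may be substituted.
#'
#' @param filters_per_layer Integer vector, one entry per conv stage.
#' @param kernel_sizes Integer vector of convolution widths, same length.
#' @param pool_sizes Integer vector of non-overlapping max-pool widths.
#' @param conv_output_length Required feature-map length after the last stage
#'   (default 15).
#' @param activation `"relu"`, `"tanh"` or `"sigmoid"`.
#' @param dense_units Width of the dense layer after flattening.
#' @param dropout_rate Dropout on the dense layer during training, in `[0,1)`.
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param input_length Input signal length (90 for the standard features).
#' @param seed Integer seed controlling weight initialization, batch order and
#'   dropout; fixed seed and inputs give bit-identical training.
#' @return A validated `cnn_config`.
#' @export
cnn_config <- function(filters_per_layer = c(32L, 32L),
                       kernel_sizes = c(7L, 13L),
                       pool_sizes = c(2L, 2L),
                       conv_output_length = 15L,
                       activation = c("relu", "tanh", "sigmoid"),
                       dense_units = 32L,
                       dropout_rate = 0.3,
                       learning_rate = 1e-3,
                       epochs = 100L,
                       batch_size = 32L,
                       input_length = 90L,
                       seed = 1L) {
  activation <- match.arg(activation)
  n_layers <- length(filters_per_layer)
  if (length(kernel_sizes) != n_layers || length(pool_sizes) != n_layers) {
    stop(
      "filters_per_layer, kernel_sizes and pool_sizes must have equal length",
      call. = FALSE
    )
  }
  stopifnot(
    n_layers >= 1, all(filters_per_layer >= 1), all(kernel_sizes >= 1),
    all(pool_sizes >= 1), dropout_rate >= 0, dropout_rate < 1,
    learning_rate > 0, epochs >= 0, batch_size >= 1
  )
  cfg <- list(
    n_conv_layers = n_layers,
    filters_per_layer = as.integer(filters_per_layer),
    kernel_sizes = as.integer(kernel_sizes),
    pool_sizes = as.integer(pool_sizes),
    conv_output_length = as.integer(conv_output_length),
    activation = activation,
    dense_units = as.integer(dense_units),
    dropout_rate = dropout_rate,
    learning_rate = learning_rate,
    epochs = as.integer(epochs),
    batch_size = as.integer(batch_size),
    input_length = as.integer(input_length),
    seed = as.integer(seed)
  )
  class(cfg) <- "cnn_config"
  lens <- conv_stage_lengths(cfg) # validates arithmetic
  if (utils::tail(lens$pooled, 1) != cfg$conv_output_length) {
    stop(
      "architecture yields final feature-map length ",
      utils::tail(lens$pooled, 1), ", not conv_output_length = ",
      cfg$conv_output_length, " (per-stage lengths: conv ",
      paste(lens$conv, collapse = ","), "; pooled ",
      paste(lens$pooled, collapse = ","), ")",
      call. = FALSE
    )
  }
  cfg
}

# Per-stage signal lengths implied by the configuration.
conv_stage_lengths <- function(cfg) {
  len <- cfg$input_length
  conv <- pooled <- integer(cfg$n_conv_layers)
  for (i in seq_len(cfg$n_conv_layers)) {
    lc <- len - cfg$kernel_sizes[i] + 1L
    if (lc < 1L) {
      stop(
        "kernel size ", cfg$kernel_sizes[i], " at stage ", i,
        " exceeds incoming length ", len,
        call. = FALSE
      )
    }
    lp <- lc %/% cfg$pool_sizes[i]
    if (lp < 1L) {
      stop(
        "pool size ", cfg$pool_sizes[i], " at stage ", i,
        " exceeds conv output length ", lc,
        call. = FALSE
      )
    }
    conv[i] <- lc
    pooled[i] <- lp
    len <- lp
  }
  list(conv = conv, pooled = pooled)
}

activation_fn <- function(name) {
  switch(name,
    relu = function(x) pmax(x, 0),
    tanh = tanh,
    sigmoid = function(x) 1 / (1 + exp(-x))
  )
}

# Derivative as a function of the pre-activation input.
activation_grad <- function(name) {
  switch(name,
    relu = function(x) (x > 0) * 1,
    tanh = function(x) 1 - tanh(x)^2,
    sigmoid = function(x) {
      s <- 1 / (1 + exp(-x))
      s * (1 - s)
    }
  )
}

# im2col linear-index matrix for an array of shape (B, L, C):
# row (t-1)*B + b, column (c-1)*K + j -> index of A[b, t+j-1, c].
# Cached per shape: the same small set of batch shapes recurs thousands of
# times during training.
.im2col_cache <- new.env(parent = emptyenv())

im2col_indices <- function(B, L, K, Cin, Lout) {
  key <- paste(B, L, K, Cin, sep = "_")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) {
    return(hit)
  }
  base <- rep(seq_len(B), times = Lout) + B * (rep(seq_len(Lout), each = B) - 1L)
  idx <- matrix(0L, B * Lout, K * Cin)
  for (c in seq_len(Cin)) {
    for (j in seq_len(K)) {
      idx[, (c - 1L) * K + j] <- base + (j - 1L) * B + (c - 1L) * B * L
    }
  }
  out <- list(idxvec = as.vector(idx), base = base)
  .im2col_cache[[key]] <- out
  out
}

#' Build an untrained CNN
#'
#' Initializes weights (He-scaled normal draws) under `cfg$seed`; two builds
#' from the same configuration are identical.
#'
#' @param cfg A [cnn_config()].
#' @return A `cnn_model` handle (config + initial parameters).
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "cnn_config"))
  lens <- conv_stage_lengths(cfg)
  params <- withr::with_seed(cfg$seed, {
    p <- list()
    cin <- 1L
    for (i in seq_len(cfg$n_conv_layers)) {
      k <- cfg$kernel_sizes[i]
      f <- cfg$filters_per_layer[i]
      fan_in <- k * cin
      p[[paste0("convW", i)]] <- matrix(
        stats::rnorm(fan_in * f, sd = sqrt(2 / fan_in)), fan_in, f
      )
      p[[paste0("convb", i)]] <- rep(0, f)
      cin <- f
    }
    flat_dim <- utils::tail(lens$pooled, 1) * cin
    p$W1 <- matrix(
      stats::rnorm(flat_dim * cfg$dense_units, sd = sqrt(2 / flat_dim)),
      flat_dim, cfg$dense_units
    )
    p$b1 <- rep(0, cfg$dense_units)
    p$W2 <- matrix(stats::rnorm(cfg$dense_units, sd = sqrt(2 / cfg$dense_units)),
      cfg$dense_units, 1L
    )
    p$b2 <- 0
    p
  })
  structure(list(config = cfg, params = params), class = "cnn_model")
}

# Forward pass over a feature matrix X (B x input_length).
# training = TRUE draws dropout masks from the current RNG and keeps the
# caches needed for backprop; keep_layers = TRUE retains post-pool activations.
cnn_forward <- function(params, cfg, X, training = FALSE, keep_layers = FALSE) {
  act <- activation_fn(cfg$activation)
  B <- nrow(X)
  A <- array(X, c(B, cfg$input_length, 1L))
  caches <- vector("list", cfg$n_conv_layers)
  layers <- if (keep_layers) vector("list", cfg$n_conv_layers) else NULL
  for (i in seq_len(cfg$n_conv_layers)) {
    d <- dim(A)
    L <- d[2]
    cin <- d[3]
    K <- cfg$kernel_sizes[i]
    f <- cfg$filters_per_layer[i]
    p <- cfg$pool_sizes[i]
    lout <- L - K + 1L
    lp <- lout %/% p
    im <- im2col_indices(B, L, K, cin, lout)
    Acol <- matrix(A[im$idxvec], B * lout, K * cin)
    Zpre <- Acol %*% params[[paste0("convW", i)]]
    Zpre <- sweep(Zpre, 2L, params[[paste0("convb", i)]], "+")
    H <- array(act(Zpre), c(B, lout, f))
    sel1 <- seq(1L, by = p, length.out = lp)
    best <- H[, sel1, , drop = FALSE]
    argm <- array(1L, dim(best))
    if (p > 1L) {
      for (s in 2:p) {
        cand <- H[, seq(s, by = p, length.out = lp), , drop = FALSE]
        upd <- cand > best
        best[upd] <- cand[upd]
        argm[upd] <- s
      }
    }
    if (training) {
      caches[[i]] <- list(
        Acol = Acol, Zpre = Zpre, argm = argm, im = im,
        L = L, cin = cin, lout = lout, lp = lp
      )
    }
    if (keep_layers) layers[[i]] <- best
    A <- best
  }
  f_last <- dim(A)[3]
  lp_last <- dim(A)[2]
  Flat <- matrix(A, B, lp_last * f_last)
  Z1 <- sweep(Flat %*% params$W1, 2L, params$b1, "+")
  H1 <- act(Z1)
  mask <- NULL
  if (training && cfg$dropout_rate > 0) {
    mask <- matrix(
      (stats::runif(length(H1)) >= cfg$dropout_rate) / (1 - cfg$dropout_rate),
      nrow(H1), ncol(H1)
    )
    H1 <- H1 * mask
  }
  z2 <- drop(H1 %*% params$W2) + params$b2
  prob <- 1 / (1 + exp(-z2))
  list(
    prob = prob, caches = caches, layers = layers,
    Flat = Flat, Z1 = Z1, H1 = H1, mask = mask,
    lp_last = lp_last, f_last = f_last
  )
}

# Backward pass; returns gradients named like the parameters.
cnn_backward <- function(params, cfg, fwd, y) {
  agrad <- activation_grad(cfg$activation)
  B <- length(y)
  g <- list()
  dz2 <- matrix((fwd$prob - y) / B, B, 1L)
  g$W2 <- crossprod(fwd$H1, dz2)
  g$b2 <- sum(dz2)
  dH1 <- dz2 %*% t(params$W2)
  if (!is.null(fwd$mask)) dH1 <- dH1 * fwd$mask
  dZ1 <- dH1 * agrad(fwd$Z1)
  g$W1 <- crossprod(fwd$Flat, dZ1)
  g$b1 <- colSums(dZ1)
  dFlat <- dZ1 %*% t(params$W1)
  dA <- array(dFlat, c(B, fwd$lp_last, fwd$f_last))
  for (i in rev(seq_len(cfg$n_conv_layers))) {
    cc <- fwd$caches[[i]]
    p <- cfg$pool_sizes[i]
    f <- cfg$filters_per_layer[i]
    dH <- array(0, c(B, cc$lout, f))
    for (s in seq_len(p)) {
      sel <- seq(s, by = p, length.out = cc$lp)
      dH[, sel, ] <- dA * (cc$argm == s)
    }
    dZmat <- matrix(dH, B * cc$lout, f) * agrad(cc$Zpre)
    g[[paste0("convW", i)]] <- crossprod(cc$Acol, dZmat)
    g[[paste0("convb", i)]] <- colSums(dZmat)
    if (i > 1L) {
      dAcol <- dZmat %*% t(params[[paste0("convW", i)]])
      # col2im scatter-add, one vectorized pass per kernel offset
      K <- cfg$kernel_sizes[i]
      dM <- matrix(0, B * cc$L, cc$cin)
      for (j in seq_len(K)) {
        rows_j <- cc$im$base + (j - 1L) * B
        dM[rows_j, ] <- dM[rows_j, ] +
          dAcol[, seq(j, by = K, length.out = cc$cin), drop = FALSE]
      }
      dA <- array(dM, c(B, cc$L, cc$cin))
    }
  }
  g
}

#' Train the CNN
#'
#' Minimizes binary cross-entropy with Adam over `cfg$epochs` epochs of
#' seeded, shuffled mini-batches. Training is single-threaded, pure R, and
#' bit-reproducible: the same configuration, features and labels always give
#' the same weights.
#'
#' @param model An untrained handle from [build_model()].
#' @param X Feature matrix (`n x 90` for the standard features).
#' @param y Labels: `"positive"`/`"negative"`, 0/1, or logical.
#' @param profile The [fit_class_means()] profile used to featurize the
#'   training data; stored in the model so prediction reuses the exact
#'   training-time class means.
#' @param threshold Decision threshold for [classify()] (default 0.5).
#' @param model_role `"lncRNA"` or `"dna_site"`.
#' @return A `trained_cnn` with weights, config, profile, threshold, role and
#'   the per-epoch training-loss history.
#' @export
train_cnn <- function(model, X, y, profile = NULL, threshold = 0.5,
                      model_role = c("lncRNA", "dna_site")) {
  stopifnot(inherits(model, "cnn_model"))
  model_role <- match.arg(model_role)
  cfg <- model$config
  if (ncol(X) != cfg$input_length) {
    stop("feature matrix has ", ncol(X), " columns; expected ", cfg$input_length,
      call. = FALSE
    )
  }
  bad <- which(!apply(X, 1L, function(r) all(is.finite(r))))
  if (length(bad) > 0L) {
    stop(
      "non-finite features in row(s): ",
      paste(utils::head(bad, 5), collapse = ", "),
      call. = FALSE
    )
  }
  yb <- as_binary(y)
  if (length(yb) != nrow(X)) stop("X and y size mismatch", call. = FALSE)
  if (length(unique(yb)) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }
  params <- model$params
  n <- nrow(X)
  history <- numeric(cfg$epochs)
  if (cfg$epochs > 0L) {
    adam_m <- lapply(params, function(p) p * 0)
    adam_v <- lapply(params, function(p) p * 0)
    t_step <- 0L
    b1 <- 0.9
    b2 <- 0.999
    eps <- 1e-8
    withr::with_seed(cfg$seed, {
      for (epoch in seq_len(cfg$epochs)) {
        perm <- sample.int(n)
        starts <- seq(1L, n, by = cfg$batch_size)
        losses <- numeric(length(starts))
        for (bi in seq_along(starts)) {
          rows <- perm[starts[bi]:min(starts[bi] + cfg$batch_size - 1L, n)]
          Xb <- X[rows, , drop = FALSE]
          yb_b <- yb[rows]
          fwd <- cnn_forward(params, cfg, Xb, training = TRUE)
          pcl <- pmin(pmax(fwd$prob, 1e-12), 1 - 1e-12)
          losses[bi] <- -mean(yb_b * log(pcl) + (1 - yb_b) * log(1 - pcl))
          grads <- cnn_backward(params, cfg, fwd, yb_b)
          t_step <- t_step + 1L
          for (nm in names(params)) {
            adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * grads[[nm]]
            adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * grads[[nm]]^2
            mhat <- adam_m[[nm]] / (1 - b1^t_step)
            vhat <- adam_v[[nm]] / (1 - b2^t_step)
            params[[nm]] <- params[[nm]] - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
          }
        }
        history[epoch] <- mean(losses)
      }
    })
  }
  structure(
    list(
      config = cfg, params = params, profile = profile,
      threshold = threshold, model_role = model_role, history = history
    ),
    class = "trained_cnn"
  )
}

#' @export
print.trained_cnn <- function(x, ...) {
  cat(sprintf(
    "<trained_cnn role=%s> %d conv stage(s), threshold %.2f, %d epoch(s)\n",
    x$model_role, x$config$n_conv_layers, x$threshold, x$config$epochs
  ))
  invisible(x)
}

# Normalize label encodings to 0/1 with positive = 1.
as_binary <- function(y) {
  if (is.logical(y)) {
    return(as.numeric(y))
  }
  if (is.numeric(y)) {
    if (!all(y %in% c(0, 1))) stop("numeric labels must be 0/1", call. = FALSE)
    return(as.numeric(y))
  }
  y <- as.character(y)
  if (!all(y %in% c("positive", "negative"))) {
    stop("labels must be 'positive'/'negative', 0/1 or logical", call. = FALSE)
  }
  as.numeric(y == "positive")
}

# Forward in prediction mode, batched to bound im2col memory.
predict_matrix <- function(model, X, batch = 512L) {
  cfg <- model$config
  out <- numeric(nrow(X))
  starts <- seq(1L, nrow(X), by = batch)
  for (s in starts) {
    rows <- s:min(s + batch - 1L, nrow(X))
    out[rows] <- cnn_forward(model$params, cfg, X[rows, , drop = FALSE])$prob
  }
  out
}

#' Predict triplex-forming probability
#'
#' Featurizes the records with the model's stored training-time class-mean
#' profile and returns the network's positive-class probability for each.
#'
#' @param model A `trained_cnn`.
#' @param data A [dataset()] or an already-featurized numeric matrix.
#' @return Named numeric vector of probabilities in `[0,1]`, aligned to record
#'   order.
#' @export
predict_proba <- function(model, data) {
  stopifnot(inherits(model, "trained_cnn"))
  if (is.matrix(data)) {
    return(stats::setNames(predict_matrix(model, data), rownames(data)))
  }
  if (is.null(model$profile)) {
    stop("model has no stored class-mean profile; cannot featurize", call. = FALSE)
  }
  X <- featurize_dataset(data, model$profile)
  stats::setNames(predict_matrix(model, X), data$id)
}

#' Classify records
#'
#' @param model A `trained_cnn`.
#' @param data A [dataset()] or feature matrix.
#' @return Named character vector: `"positive"` where the predicted
#'   probability is `>= model$threshold`, else `"negative"`.
#' @export
classify <- function(model, data) {
  p <- predict_proba(model, data)
  stats::setNames(ifelse(p >= model$threshold, "positive", "negative"), names(p))
}

#' Save / load a trained model
#'
#' The model directory holds `config.json`, `weights.json`, `profile.json`
#' and `manifest.json` (format version and role); a save/load round trip
#' reproduces predictions exactly.
#'
#' @param model A `trained_cnn`.
#' @param dir Model directory.
#' @return `dir` (save) or the restored `trained_cnn` (load).
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "trained_cnn"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- unclass(model$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
    auto_unbox = TRUE, digits = NA
  )
  weights <- lapply(model$params, function(p) {
    list(dim = if (is.matrix(p)) dim(p) else length(p), data = as.vector(p))
  })
  jsonlite::write_json(weights, file.path(dir, "weights.json"), digits = NA)
  if (!is.null(model$profile)) {
    write_profile(model$profile, file.path(dir, "profile.json"))
  }
  jsonlite::write_json(
    list(
      format_version = 1L,
      package_version = as.character(utils::packageVersion("triplexpot")),
      model_role = model$model_role,
      threshold = model$threshold
    ),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("'", dir, "' is not a model directory (no manifest.json)", call. = FALSE)
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (is.null(manifest$format_version) || manifest$format_version != 1L) {
    stop("unsupported model format version in '", dir, "'", call. = FALSE)
  }
  raw_cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  cfg <- cnn_config(
    filters_per_layer = raw_cfg$filters_per_layer,
    kernel_sizes = raw_cfg$kernel_sizes,
    pool_sizes = raw_cfg$pool_sizes,
    conv_output_length = raw_cfg$conv_output_length,
    activation = raw_cfg$activation,
    dense_units = raw_cfg$dense_units,
    dropout_rate = raw_cfg$dropout_rate,
    learning_rate = raw_cfg$learning_rate,
    epochs = raw_cfg$epochs,
    batch_size = raw_cfg$batch_size,
    input_length = raw_cfg$input_length,
    seed = raw_cfg$seed
  )
  raw_w <- jsonlite::read_json(file.path(dir, "weights.json"), simplifyVector = TRUE)
  params <- lapply(raw_w, function(w) {
    if (length(w$dim) == 2L) {
      matrix(w$data, w$dim[1], w$dim[2])
    } else if (length(w$data) == 1L) {
      w$data
    } else {
      as.numeric(w$data)
    }
  })
  profile_path <- file.path(dir, "profile.json")
  profile <- if (file.exists(profile_path)) read_profile(profile_path) else NULL
  structure(
    list(
      config = cfg, params = params, profile = profile,
      threshold = manifest$threshold, model_role = manifest$model_role,
      history = numeric(0)
    ),
    class = "trained_cnn"
  )
}

#' Per-class mean activations (feature maps)
#'
#' Computes, for each class, the mean activation at a given network depth:
#' layer 0 is the 90-dimensional input feature vector, layers 1..n are the
#' post-pooling activations of the corresponding convolutional stage (a
#' `length x filters` matrix; length 15 at the final stage under the default
#' architecture). These are the data behind per-class heatmaps of what the
#' network responds to.
#'
#' @param model A `trained_cnn` with a stored profile.
#' @param data Labeled [dataset()].
#' @param layer 0 (input features) or a conv stage index.
#' @param path Optional TSV output (long format: class, position, filter,
#'   value).
#' @return Named list (one element per class) of mean-activation matrices
#'   (layer 0: a 1 x 90 matrix).
#' @export
export_feature_maps <- function(model, data, layer, path = NULL) {
  stopifnot(inherits(model, "trained_cnn"))
  if (anyNA(data$label)) stop("all records must be labeled", call. = FALSE)
  cfg <- model$config
  if (!(layer %in% 0:cfg$n_conv_layers)) {
    stop("layer must be in 0..", cfg$n_conv_layers, call. = FALSE)
  }
  X <- featurize_dataset(data, model$profile)
  classes <- sort(unique(data$label))
  out <- list()
  for (cls in classes) {
    rows <- which(data$label == cls)
    if (layer == 0L) {
      m <- matrix(colMeans(X[rows, , drop = FALSE]), 1L)
      colnames(m) <- colnames(X)
    } else {
      # batched accumulation of the post-pool activation mean
      sum_act <- NULL
      starts <- seq(1L, length(rows), by = 256L)
      for (s in starts) {
        idx <- rows[s:min(s + 255L, length(rows))]
        fwd <- cnn_forward(model$params, cfg, X[idx, , drop = FALSE],
          keep_layers = TRUE
        )
        a <- fwd$layers[[layer]]
        batch_sum <- apply(a, c(2L, 3L), sum)
        sum_act <- if (is.null(sum_act)) batch_sum else sum_act + batch_sum
      }
      m <- sum_act / length(rows)
      dimnames(m) <- list(
        paste0("pos", seq_len(nrow(m))),
        paste0("filter", seq_len(ncol(m)))
      )
    }
    out[[cls]] <- m
  }
  if (!is.null(path)) {
    long <- do.call(rbind, lapply(names(out), function(cls) {
      m <- out[[cls]]
      data.frame(
        class = cls,
        position = rep(seq_len(nrow(m)), ncol(m)),
        filter = rep(seq_len(ncol(m)), each = nrow(m)),
        value = as.vector(m)
      )
    }))
    utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
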