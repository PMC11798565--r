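#' Multilayer-perceptron architecture specification
#'
#' The case classifier is a feed-forward network with rectified-linear hidden
#' layers and a single sigmoid output unit; weights are initialised with the
#' He scheme (zero-mean normal, variance 2/fan-in) and biases at zero. The
#' default stack of five hidden layers with 128, 64, 32, 16 and 8 neurons
#' mirrors the reference classifier's architecture.
#'
#' @param hidden_sizes Integer vector of hidden-layer widths.
#' @param threshold Decision threshold on the sigmoid output, in (0, 1);
#'   predictions at or above it are labelled positive.
#' @return An `mlp_spec` object.
#' @export
#' @examples
#' mlp_spec()
mlp_spec <- function(hidden_sizes = c(128L, 64L, 32L, 16L, 8L),
                     threshold = 0.5) {
  hidden_sizes <- as.integer(hidden_sizes)
  if (length(hidden_sizes) < 1 || any(hidden_sizes < 1)) {
    stop("hidden layer sizes must be positive integers", call. = FALSE)
  }
  stopifnot(threshold > 0, threshold < 1)
  structure(list(hidden_sizes = hidden_sizes, threshold = threshold),
            class = "mlp_spec")
}

#' Initialise an untrained network
#'
#' He-normal weights (SD `sqrt(2 / fan_in)` per layer) and zero biases, the
#' standard pairing for rectified-linear hidden units.
#'
#' @param spec An [mlp_spec()].
#' @param input_width Number of encoded input features.
#' @param seed Integer seed; identical seeds give identical weights.
#' @return An `mlp_classifier` with untrained weights and no encoder.
#' @export
init_mlp <- function(spec = mlp_spec(), input_width, seed = NULL) {
  stopifnot(input_width >= 1)
  dims <- c(input_width, spec$hidden_sizes, 1L)
  with_seed(seed, {
    weights <- biases <- vector("list", length(dims) - 1)
    for (l in seq_along(weights)) {
      fan_in <- dims[l]
      weights[[l]] <- matrix(stats::rnorm(fan_in * dims[l + 1], 0,
                                          sqrt(2 / fan_in)),
                             nrow = fan_in, ncol = dims[l + 1])
      biases[[l]] <- numeric(dims[l + 1])
    }
    structure(list(spec = spec, input_width = as.integer(input_width),
                   weights = weights, biases = biases, encoder = NULL,
                   history = NULL),
              class = "mlp_classifier")
  })
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# forward pass on an encoded numeric matrix; returns activations per layer
mlp_forward_full <- function(model, x) {
  acts <- vector("list", length(model$weights) + 1)
  acts[[1]] <- x
  nl <- length(model$weights)
  for (l in seq_len(nl)) {
    z <- acts[[l]] %*% model$weights[[l]] +
      matrix(model$biases[[l]], nrow(x), ncol(model$weights[[l]]), byrow = TRUE)
    acts[[l + 1]] <- if (l < nl) pmax(z, 0) else sigmoid(z)
  }
  acts
}

#' Forward pass: predicted case probabilities
#'
#' @param model An `mlp_classifier`.
#' @param x Encoded numeric matrix (rows = observations) whose width matches
#'   the model input, or a participant table if the model carries an encoder.
#' @return Numeric vector of probabilities strictly inside (0, 1).
#' @export
mlp_forward <- function(model, x) {
  if (is.data.frame(x)) {
    if (is.null(model$encoder)) {
      stop("model has no feature encoder; supply an encoded matrix",
           call. = FALSE)
    }
    x <- encode_features(model$encoder, x)
  }
  x <- as.matrix(x)
  if (ncol(x) != model$input_width) {
    stop(sprintf("input has %d columns but the model expects %d",
                 ncol(x), model$input_width), call. = FALSE)
  }
  p <- as.numeric(mlp_forward_full(model, x)[[length(model$weights) + 1]])
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps)
}

#' Training control parameters
#'
#' Training uses class-weighted binary cross-entropy, Adam updates,
#' mini-batches, and early stopping on a stratified validation split. These
#' are conventional defaults for a tabular problem with a roughly 10%
#' positive class; the reference architecture's own training hyperparameters
#' are not published.
#'
#' @param epochs Maximum epochs.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param val_fraction Fraction of rows held out (stratified) for early
#'   stopping; 0 disables early stopping.
#' @param patience Epochs without validation-loss improvement before stopping.
#' @param class_weights Weight positives/negatives by inverse class frequency.
#' @return A list of class `mlp_control`.
#' @export
mlp_control <- function(epochs = 150L, batch_size = 32L, learning_rate = 1e-3,
                        val_fraction = 0.2, patience = 10L,
                        class_weights = TRUE) {
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, val_fraction = val_fraction,
                 patience = as.integer(patience), class_weights = class_weights),
            class = "mlp_control")
}

# ---- feature encoding ------------------------------------------------------

# one-hot for character/factor columns, z-standardisation for numeric ones;
# parameters are learned from the fitting rows only, never from held-out data
build_encoder <- function(data) {
  drop <- intersect(c("id", "latent_class", "predicted_label"), names(data))
  data <- data[setdiff(names(data), drop)]
  cols <- purrr::imap(data, function(x, nm) {
    if (is.numeric(x)) {
      s <- stats::sd(x)
      list(name = nm, kind = "numeric", center = mean(x),
           scale = if (is.na(s) || s < 1e-12) 1 else s)
    } else {
      list(name = nm, kind = "onehot",
           levels = if (is.factor(x)) levels(x) else sort(unique(as.character(x))))
    }
  })
  structure(list(columns = unname(cols)), class = "mlp_encoder")
}

encode_features <- function(encoder, data) {
  mats <- lapply(encoder$columns, function(col) {
    if (!col$name %in% names(data)) {
      stop("data is missing feature column: ", col$name, call. = FALSE)
    }
    x <- data[[col$name]]
    if (col$kind == "numeric") {
      m <- matrix((as.numeric(x) - col$center) / col$scale, ncol = 1)
      colnames(m) <- col$name
    } else {
      x <- as.character(x)
      m <- vapply(col$levels, function(lv) as.numeric(x == lv),
                  numeric(length(x)))
      if (length(x) == 1) m <- matrix(m, nrow = 1)
      colnames(m) <- paste(col$name, col$levels, sep = ".")
    }
    m
  })
  do.call(cbind, mats)
}

# ---- training --------------------------------------------------------------

weighted_bce <- function(p, y, w) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(w * (y * log(p) + (1 - y) * log(1 - p))) / sum(w)
}

#' Train the case classifier
#'
#' Fits the multilayer perceptron to a participant table with binary labels.
#' Categorical features are one-hot encoded and numeric features
#' z-standardised, with encoding parameters learned on the training split
#' only. Optimisation is mini-batch Adam on class-weighted binary
#' cross-entropy, with early stopping on a stratified validation split; the
#' weights from the best validation epoch are kept.
#'
#' @param data A participant table; `id`, `latent_class` and
#'   `predicted_label` columns are ignored, everything else is a feature.
#' @param labels Binary vector (0/1 or logical), one per row.
#' @param spec An [mlp_spec()].
#' @param control An [mlp_control()].
#' @param seed Integer seed covering initialisation, the validation split and
#'   batch shuffling.
#' @return A fitted `mlp_classifier` with `history` (per-epoch training and
#'   validation loss) and the feature encoder attached.
#' @export
train_mlp <- function(data, labels, spec = mlp_spec(),
                      control = mlp_control(), seed = NULL) {
  y_all <- as.numeric(labels)
  stopifnot(length(y_all) == nrow(data), all(y_all %in% c(0, 1)))
  if (length(unique(y_all)) < 2) {
    stop("labels contain a single class; two classes are required",
         call. = FALSE)
  }
  with_seed(seed, {
    n <- nrow(data)
    # stratified validation split
    if (control$val_fraction > 0) {
      val_idx <- unlist(lapply(c(0, 1), function(k) {
        rows <- which(y_all == k)
        nv <- max(1L, floor(length(rows) * control$val_fraction))
        rows[sample.int(length(rows), nv)]
      }))
    } else {
      val_idx <- integer(0)
    }
    tr_idx <- setdiff(seq_len(n), val_idx)
    encoder <- build_encoder(data[tr_idx, , drop = FALSE])
    x_tr <- encode_features(encoder, data[tr_idx, , drop = FALSE])
    y_tr <- y_all[tr_idx]
    x_val <- if (length(val_idx)) encode_features(encoder, data[val_idx, , drop = FALSE])
    y_val <- y_all[val_idx]

    w_class <- if (control$class_weights) {
      length(y_tr) / (2 * c(sum(y_tr == 0), sum(y_tr == 1)))
    } else c(1, 1)
    w_tr <- w_class[y_tr + 1]

    model <- init_mlp(spec, ncol(x_tr))
    nl <- length(model$weights)
    adam <- list(mw = lapply(model$weights, function(w) w * 0),
                 vw = lapply(model$weights, function(w) w * 0),
                 mb = lapply(model$biases, function(b) b * 0),
                 vb = lapply(model$biases, function(b) b * 0))
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
    lr <- control$learning_rate

    best <- list(loss = Inf, weights = model$weights, biases = model$biases,
                 epoch = 0L)
    wait <- 0L
    hist <- list()
    for (epoch in seq_len(control$epochs)) {
      ord <- sample.int(length(y_tr))
      starts <- seq(1, length(ord), by = control$batch_size)
      for (s in starts) {
        rows <- ord[s:min(s + control$batch_size - 1, length(ord))]
        xb <- x_tr[rows, , drop = FALSE]
        yb <- y_tr[rows]
        wb <- w_tr[rows]
        acts <- mlp_forward_full(model, xb)
        p <- as.numeric(acts[[nl + 1]])
        # gradient of weighted BCE wrt the output pre-activation
        delta <- matrix((p - yb) * wb / sum(wb), ncol = 1)
        t <- t + 1
        for (l in nl:1) {
          gw <- crossprod(acts[[l]], delta)
          gb <- colSums(delta)
          if (l > 1) {
            delta <- (delta %*% t(model$weights[[l]])) * (acts[[l]] > 0)
          }
          adam$mw[[l]] <- b1 * adam$mw[[l]] + (1 - b1) * gw
          adam$vw[[l]] <- b2 * adam$vw[[l]] + (1 - b2) * gw^2
          adam$mb[[l]] <- b1 * adam$mb[[l]] + (1 - b1) * gb
          adam$vb[[l]] <- b2 * adam$vb[[l]] + (1 - b2) * gb^2
          mw_hat <- adam$mw[[l]] / (1 - b1^t)
          vw_hat <- adam$vw[[l]] / (1 - b2^t)
          mb_hat <- adam$mb[[l]] / (1 - b1^t)
          vb_hat <- adam$vb[[l]] / (1 - b2^t)
          model$weights[[l]] <- model$weights[[l]] - lr * mw_hat / (sqrt(vw_hat) + eps)
          model$biases[[l]] <- model$biases[[l]] - lr * mb_hat / (sqrt(vb_hat) + eps)
        }
      }
      tr_loss <- weighted_bce(mlp_forward(model, x_tr), y_tr, w_tr)
      if (length(val_idx)) {
        val_loss <- weighted_bce(mlp_forward(model, x_val), y_val,
                                 w_class[y_val + 1])
        if (val_loss < best$loss - 1e-6) {
          best <- list(loss = val_loss, weights = model$weights,
                       biases = model$biases, epoch = epoch)
          wait <- 0L
        } else {
          wait <- wait + 1L
        }
      } else {
        val_loss <- NA_real_
      }
      hist[[epoch]] <- c(epoch = epoch, train_loss = tr_loss,
                         val_loss = val_loss)
      if (length(val_idx) && wait >= control$patience) break
    }
    if (length(val_idx)) {
      model$weights <- best$weights
      model$biases <- best$biases
    }
    model$encoder <- encoder
    model$history <- tibble::as_tibble(do.call(rbind, hist))
    model$control <- control
    model
  })
}

#' @export
print.mlp_classifier <- function(x, ...) {
  cat("Multilayer perceptron case classifier\n")
  cat("  hidden layers:", paste(x$spec$hidden_sizes, collapse = "-"), "\n")
  cat("  input width:", x$input_width,
      if (is.null(x$encoder)) "(untrained)" else "(trained)", "\n")
  cat("  decision threshold:", x$spec$threshold, "\n")
  invisible(x)
}

#' Predict case probabilities or labels
#'
#' @param object A fitted `mlp_classifier`.
#' @param newdata A participant table (or encoded matrix).
#' @param type `"prob"` for sigmoid probabilities, `"class"` for 0/1 labels
#'   at the model threshold (positive when probability >= threshold).
#' @param ... Unused.
#' @return Numeric (prob) or integer (class) vector.
#' @export
predict.mlp_classifier <- function(object, newdata,
                                   type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- mlp_forward(object, newdata)
  if (type == "prob") p else as.integer(p >= object$spec$threshold)
}

#' Label a participant table with the classifier
#'
#' Thin wrapper around [predict.mlp_classifier()] that appends a
#' `predicted_label` column (1 when the predicted probability is at or above
#' the model threshold).
#'
#' @param model A fitted `mlp_classifier`.
#' @param table A participant table.
#' @param threshold Optional override of the model threshold; probabilities
#'   `>= threshold` are positive, so `threshold = 1` labels everything 0
#'   (sigmoid outputs are strictly below 1).
#' @return The table with `predicted_label` appended.
#' @export
classify <- function(model, table, threshold = NULL) {
  p <- mlp_forward(model, table)
  thr <- threshold %||% model$spec$threshold
  out <- tibble::as_tibble(table)
  out$predicted_prob <- p
  out$predicted_label <- as.integer(p >= thr)
  out
}

#' @exportS3Method generics::glance
glance.mlp_classifier <- function(x, ...) {
  tibble::tibble(
    n_hidden_layers = length(x$spec$hidden_sizes),
    n_parameters = sum(vapply(x$weights, length, integer(1))) +
      sum(vapply(x$biases, length, integer(1))),
    epochs_trained = if (is.null(x$history)) 0L else nrow(x$history),
    final_train_loss = if (is.null(x$history)) NA_real_ else
      utils::tail(x$history$train_loss, 1),
    best_val_loss = if (is.null(x$history)) NA_real_ else
      suppressWarnings(min(x$history$val_loss, na.rm = TRUE))
  )
}
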