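#' Training configuration
#'
#' Defaults are the study protocol: mini-batches of 4 slices, Adagrad at
#' learning rate 0.05, 1000 epochs with the epoch-50 weights selected as
#' the deployed model (convergence is reached well before the end of
#' training; the fixed-epoch rule is the reference policy, best-validation
#' selection is available as an alternative).
#'
#' @param batch_size Slices per mini-batch (default 4).
#' @param learning_rate Adagrad learning rate (default 0.05).
#' @param max_epochs Total training epochs (default 1000).
#' @param select_epoch Epoch whose weights are deployed (default 50).
#' @param seed Seed controlling initialisation and batch order.
#' @param slice_sampling `"all"` (default: every axial slice, empty ones
#'   included) or `"foreground"` (only slices containing label foreground).
#' @param checkpoint_every Keep a checkpoint every this many epochs (the
#'   `select_epoch` and final checkpoints are always kept).
#' @param loss A [loss_config()].
#' @return Object of class `train_config`.
#' @export
train_config <- function(batch_size = 4L, learning_rate = 0.05,
                         max_epochs = 1000L, select_epoch = 50L,
                         seed = 1L,
                         slice_sampling = c("all", "foreground"),
                         checkpoint_every = 10L, loss = loss_config()) {
  slice_sampling <- match.arg(slice_sampling)
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (select_epoch < 1L || select_epoch > max_epochs) {
    stop("select_epoch must lie in 1..max_epochs")
  }
  structure(list(batch_size = as.integer(batch_size),
                 optimizer = "adagrad",
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 select_epoch = as.integer(select_epoch),
                 seed = as.integer(seed),
                 slice_sampling = slice_sampling,
                 checkpoint_every = as.integer(checkpoint_every),
                 loss = loss),
            class = "train_config")
}

#' Age-balanced k-fold split
#'
#' Sorts subjects by age and deals them round-robin into `k` folds, which
#' keeps the age distribution fairly uniform across folds. Each round
#' designates one fold as the test set, draws a validation fold at random
#' (seeded) among the remaining folds, and trains on the rest; across the
#' `k` rounds every fold is the test fold exactly once.
#'
#' @param subjects `data.frame` with columns `subject_id` and `age`.
#' @param k Number of folds (default 5).
#' @param seed Seed for the validation-fold draws.
#' @return Object of class `fold_split`: `assignment` (named integer
#'   vector, fold index 0-based per subject) and `rounds` (list of
#'   `test`, `validation`, `train` fold indices).
#' @export
make_folds <- function(subjects, k = 5L, seed = 1L) {
  stopifnot(all(c("subject_id", "age") %in% names(subjects)))
  n <- nrow(subjects)
  if (n < k) stop("need at least k = ", k, " subjects, got ", n)
  ord <- order(subjects$age, subjects$subject_id)
  assignment <- integer(n)
  assignment[ord] <- (seq_len(n) - 1L) %% k
  names(assignment) <- subjects$subject_id
  set.seed(seed)
  rounds <- lapply(0:(k - 1L), function(test) {
    validation <- sample(setdiff(0:(k - 1L), test), 1L)
    list(test = test, validation = validation,
         train = setdiff(0:(k - 1L), c(test, validation)))
  })
  structure(list(assignment = assignment, rounds = rounds, k = k),
            class = "fold_split")
}

#' @export
print.fold_split <- function(x, ...) {
  cat(sprintf("<fold_split> %d subjects in %d folds (sizes %s)\n",
              length(x$assignment), x$k,
              paste(tabulate(x$assignment + 1L, x$k), collapse = "/")))
  invisible(x)
}

# --- Adagrad ---------------------------------------------------------------

zeros_like <- function(x) {
  if (is.list(x)) lapply(x, zeros_like) else x * 0
}

adagrad_step <- function(params, grads, state, lr, eps = 1e-10) {
  if (is.list(params)) {
    for (nm in names(params)) {
      r <- adagrad_step(params[[nm]], grads[[nm]], state[[nm]], lr, eps)
      params[[nm]] <- r$params
      state[[nm]] <- r$state
    }
    return(list(params = params, state = state))
  }
  if (is.null(grads)) return(list(params = params, state = state))
  state <- state + grads^2
  list(params = params - lr * grads / (sqrt(state) + eps), state = state)
}

# Per-scale soft-dice loss and logit gradient for a stacked batch.
# p, y: (Hs*Ws*N) x 1; returns per-sample losses and d loss / d logit.
batch_dice_terms <- function(p, y, N, smooth) {
  hw <- length(p) %/% N
  grp <- rep(seq_len(N), each = hw)
  I <- rowsum(p * y, grp)
  Sp <- rowsum(p, grp)
  Sy <- rowsum(y, grp)
  denom <- Sp + Sy + smooth
  loss_n <- 1 - (2 * I + smooth) / denom
  dldp <- ((2 * I + smooth) / denom^2)[grp] - 2 * y / denom[grp]
  list(loss = as.vector(loss_n), dldp = dldp)
}

#' Train the segmentation network
#'
#' Runs the full training loop: shuffled mini-batches, multi-scale
#' deep-supervision soft-dice loss backpropagated through the node grid,
#' Adagrad updates, per-epoch train/validation loss logging and in-memory
#' checkpoints on the configured schedule. A fixed seed reproduces both
#' the initialisation and the batch order exactly.
#'
#' @param train List of slice pairs, each `list(image = matrix,
#'   label = matrix)` with sides divisible by `2^(levels - 1)`
#'   (see [to_slices()]).
#' @param val Optional validation slice pairs in the same format.
#' @param spec A [network_spec()].
#' @param config A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return Object of class `pvs_fit`: final `net`, `checkpoints`,
#'   `history` (`data.frame` epoch / train_loss / val_loss), `config`.
#' @export
train_model <- function(train, val = NULL, spec = network_spec(),
                        config = train_config(), verbose = FALSE) {
  if (length(train) == 0L) stop("empty training set")
  if (config$slice_sampling == "foreground") {
    train <- Filter(function(s) any(s$label > 0), train)
    if (length(train) == 0L) {
      stop("no slices with foreground under slice_sampling = 'foreground'")
    }
  }
  L <- spec$levels
  set.seed(config$seed)
  net <- build_network(spec)
  state <- zeros_like(net$params)
  w <- config$loss$scale_weights
  if (is.null(w)) w <- rep(1, L)
  smooth <- config$loss$smooth
  pyr_cache <- lapply(train, function(s) hf_downsample(s$label, L))
  val_pyr <- if (!is.null(val)) {
    lapply(val, function(s) hf_downsample(s$label, L))
  }
  H <- nrow(train[[1L]]$image); W <- ncol(train[[1L]]$image)
  n_tr <- length(train)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  checkpoints <- list()
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n_tr)
    ep_losses <- c()
    for (start in seq(1L, n_tr, by = config$batch_size)) {
      idx <- ord[start:min(n_tr, start + config$batch_size - 1L)]
      N <- length(idx)
      x <- matrix(unlist(lapply(train[idx], function(s) as.vector(s$image)),
                         use.names = FALSE), ncol = spec$in_channels)
      fw <- net_forward_full(net, x, H, W, N, training = TRUE,
                             keep_cache = TRUE)
      dlogits <- vector("list", L)
      batch_loss <- 0
      for (s in seq_len(L)) {
        y <- unlist(lapply(pyr_cache[idx], function(pc) {
          as.vector(pc[[s]])
        }), use.names = FALSE)
        p <- fw$probs[[s]]
        terms <- batch_dice_terms(as.vector(p), y, N, smooth)
        batch_loss <- batch_loss + w[s] * mean(terms$loss)
        scale_w <- w[s] / (sum(w) * N)
        dlogits[[s]] <- matrix(scale_w * terms$dldp * p * (1 - p),
                               ncol = 1L)
      }
      batch_loss <- batch_loss / sum(w)
      if (!is.finite(batch_loss)) {
        stop("non-finite loss at epoch ", epoch,
             " (learning rate too high or degenerate input)")
      }
      grads <- net_backward_full(net, fw, dlogits)
      upd <- adagrad_step(net$params, grads, state, config$learning_rate)
      net$params <- upd$params
      state <- upd$state
      net$bn <- fw$new_bn
      ep_losses <- c(ep_losses, batch_loss)
    }
    val_loss <- NA_real_
    if (!is.null(val)) {
      val_loss <- eval_loss(net, val, val_pyr, w, smooth)
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(ep_losses),
                                         val_loss = val_loss))
    if (verbose) {
      message(sprintf("epoch %d: train %.4f val %.4f", epoch,
                      mean(ep_losses), val_loss))
    }
    if (epoch %% config$checkpoint_every == 0L ||
        epoch == config$select_epoch || epoch == config$max_epochs) {
      checkpoints[[as.character(epoch)]] <-
        list(epoch = epoch, params = net$params, bn = net$bn)
    }
  }
  structure(list(net = net, checkpoints = checkpoints, history = history,
                 spec = spec, config = config),
            class = "pvs_fit")
}

eval_loss <- function(net, slices, pyrs, w, smooth, batch_size = 8L) {
  L <- net$spec$levels
  H <- nrow(slices[[1L]]$image); W <- ncol(slices[[1L]]$image)
  n <- length(slices)
  total <- 0; count <- 0
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(n, start + batch_size - 1L)
    N <- length(idx)
    x <- matrix(unlist(lapply(slices[idx], function(s) as.vector(s$image)),
                       use.names = FALSE), ncol = net$spec$in_channels)
    fw <- net_forward_full(net, x, H, W, N, training = FALSE,
                           keep_cache = FALSE)
    batch_loss <- 0
    for (s in seq_len(L)) {
      y <- unlist(lapply(pyrs[idx], function(pc) as.vector(pc[[s]])),
                  use.names = FALSE)
      terms <- batch_dice_terms(as.vector(fw$probs[[s]]), y, N, smooth)
      batch_loss <- batch_loss + w[s] * mean(terms$loss)
    }
    total <- total + batch_loss / sum(w) * N
    count <- count + N
  }
  total / count
}

#' @export
print.pvs_fit <- function(x, ...) {
  cat(sprintf(
    "<pvs_fit> %d epochs (batch %d, Adagrad lr %.3g), final train loss %.4f\n  checkpoints at epochs: %s\n",
    nrow(x$history), x$config$batch_size, x$config$learning_rate,
    x$history$train_loss[nrow(x$history)],
    paste(names(x$checkpoints), collapse = ", ")))
  invisible(x)
}

#' @export
summary.pvs_fit <- function(object, ...) {
  h <- object$history
  cat("Training summary\n")
  cat(sprintf("  epochs: %d, slices per batch: %d, lr: %.3g (Adagrad)\n",
              nrow(h), object$config$batch_size,
              object$config$learning_rate))
  cat(sprintf("  train loss: first %.4f, min %.4f (epoch %d), last %.4f\n",
              h$train_loss[1L], min(h$train_loss),
              h$epoch[which.min(h$train_loss)],
              h$train_loss[nrow(h)]))
  if (any(is.finite(h$val_loss))) {
    cat(sprintf("  val loss: min %.4f (epoch %d)\n",
                min(h$val_loss, na.rm = TRUE),
                h$epoch[which.min(h$val_loss)]))
  }
  invisible(object)
}

#' @export
plot.pvs_fit <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "multi-scale soft dice loss", ...)
  if (any(is.finite(h$val_loss))) {
    graphics::lines(h$epoch, h$val_loss, lty = 2)
    graphics::legend("topright", c("train", "validation"), lty = 1:2,
                     bty = "n")
  }
  invisible(x)
}

#' Select a trained checkpoint
#'
#' The reference policy returns exactly the weights saved at
#' `config$select_epoch` (no best-validation search). The alternative
#' `"best_val"` policy returns the kept checkpoint with the lowest
#' validation loss.
#'
#' @param fit A [train_model()] result.
#' @param epoch Requested epoch (default: the configured select epoch).
#' @param policy `"fixed"` (default) or `"best_val"`.
#' @return A `pvs_net` carrying the selected weights.
#' @export
select_checkpoint <- function(fit, epoch = fit$config$select_epoch,
                              policy = c("fixed", "best_val")) {
  policy <- match.arg(policy)
  if (policy == "best_val") {
    h <- fit$history
    kept <- as.integer(names(fit$checkpoints))
    hv <- h[h$epoch %in% kept & is.finite(h$val_loss), ]
    if (nrow(hv) == 0L) stop("no validation losses recorded")
    epoch <- hv$epoch[which.min(hv$val_loss)]
  }
  ck <- fit$checkpoints[[as.character(epoch)]]
  if (is.null(ck)) {
    stop("no checkpoint at epoch ", epoch, "; available: ",
         paste(names(fit$checkpoints), collapse = ", "))
  }
  net <- fit$net
  net$params <- ck$params
  net$bn <- ck$bn
  net
}

# Build the training slice pool for a set of phantom subjects.
subject_slices <- function(dataset, which_subjects, pad_to) {
  pairs <- list()
  for (sub in dataset[which_subjects]) {
    vol <- normalize_volume(sub$volume)
    lab <- pvs_volume(sub$truth$mask + 0, vol$voxel_size_mm,
                      sub$subject_id)
    ss <- to_slices(vol, lab, pad_to = pad_to)
    for (k in seq_along(ss$images)) {
      pairs[[length(pairs) + 1L]] <- list(image = ss$images[[k]],
                                          label = ss$labels[[k]])
    }
  }
  pairs
}

#' Five-fold cross-validated training and prediction
#'
#' Realises the full protocol: age-balanced folds, per-round training on
#' three folds with one seeded validation fold, checkpoint selection at
#' the configured epoch, and slice-wise prediction of every test-fold
#' subject (finest-scale head, threshold 0.5), so that each subject
#' receives exactly one predicted mask over the whole procedure.
#'
#' @param dataset A [phantom_dataset()] (or any list of subjects with
#'   `volume`, `truth$mask`, `subject_id`, `age`).
#' @param spec A [network_spec()].
#' @param config A [train_config()].
#' @param k Number of folds (default 5).
#' @param threshold Binarisation threshold for predicted masks.
#' @param verbose Print round progress.
#' @return Object of class `pvs_crossval`: `predictions` (named list of
#'   mask volumes), `metrics` (`data.frame` with one row per subject,
#'   tagged with the round in which the subject was in the test fold),
#'   `folds`, `histories`.
#' @export
run_crossval <- function(dataset, spec = network_spec(),
                         config = train_config(), k = 5L,
                         threshold = 0.5, verbose = FALSE) {
  subjects <- data.frame(
    subject_id = vapply(dataset, function(s) s$subject_id, character(1)),
    age = vapply(dataset, function(s) as.numeric(s$age %||% NA_real_),
                 numeric(1))
  )
  if (anyNA(subjects$age)) stop("every subject needs an age for fold balancing")
  folds <- make_folds(subjects, k = k, seed = config$seed)
  pad_to <- 2L^(spec$levels - 1L)
  predictions <- list()
  metrics <- list()
  histories <- list()
  for (r in seq_along(folds$rounds)) {
    rd <- folds$rounds[[r]]
    in_fold <- function(f) which(folds$assignment[subjects$subject_id] %in% f)
    tr_idx <- in_fold(rd$train)
    va_idx <- in_fold(rd$validation)
    te_idx <- in_fold(rd$test)
    if (verbose) {
      message("round ", r, ": train ", length(tr_idx), " subjects, test ",
              length(te_idx))
    }
    cfg <- config
    cfg$seed <- config$seed + r  # independent batch order per round
    fit <- train_model(subject_slices(dataset, tr_idx, pad_to),
                       subject_slices(dataset, va_idx, pad_to),
                       spec = spec, config = cfg)
    net <- select_checkpoint(fit)
    histories[[r]] <- fit$history
    for (ti in te_idx) {
      sub <- dataset[[ti]]
      mask <- predict(net, sub$volume, threshold = threshold)
      predictions[[sub$subject_id]] <- mask
      rec <- metrics_record(mask$data, sub$truth$mask, sub$subject_id)
      rec$round <- r
      metrics[[length(metrics) + 1L]] <- rec
    }
  }
  metrics <- do.call(rbind, metrics)
  structure(list(predictions = predictions, metrics = metrics,
                 folds = folds, histories = histories, spec = spec,
                 config = config),
            class = "pvs_crossval")
}

#' @export
print.pvs_crossval <- function(x, ...) {
  cat(sprintf(
    "<pvs_crossval> %d subjects, %d rounds; mean DSC %.3f, SEN %.3f, PPV %.3f\n",
    nrow(x$metrics), length(x$histories), mean(x$metrics$DSC),
    mean(x$metrics$SEN), mean(x$metrics$PPV)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
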