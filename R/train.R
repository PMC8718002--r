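# Training and evaluation of the echo-spectrogram classifier.

# Spectrograms are computed on demand from IR + call and memoised per echo
# (flower x plane x angle), since every chunk scheme reuses the same echoes.
.spectrogram_provider <- function(scans, call_hp, echo_length, window = 256L,
                                  hop = 26L) {
  cache <- new.env(parent = emptyenv())
  function(flower_id, plane, angle_idx) {
    key <- paste(flower_id, plane, angle_idx, sep = "|")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    ir <- scans[[flower_id]]$planes[[plane]][angle_idx, ]
    sp <- echo_spectrogram(make_echo(ir, call_hp, echo_length),
                           window = window, hop = hop)
    cache[[key]] <- sp
    sp
  }
}

# assemble array (H, W, k, B) for a list of chunks
.chunk_batch <- function(chunks, provider, shape, k) {
  B <- length(chunks)
  x <- array(0, dim = c(shape[1], shape[2], k, B))
  for (b in seq_len(B)) {
    ch <- chunks[[b]]
    for (j in seq_len(k)) {
      x[, , j, b] <- provider(ch$flower_id, ch$rows$plane[j],
                              ch$rows$angle_idx[j])
    }
  }
  x
}

#' Train the multi-input echo classifier
#'
#' Builds echo chunks for the train and validation flowers, then runs the
#' standard supervised loop: shuffled mini-batches, cross-entropy loss, Adam
#' updates, an unshuffled validation pass per epoch, and early stopping on
#' the validation loss (training halts when it has not improved for
#' `patience` epochs; the best-validation parameters are kept). Echo
#' spectrograms are computed on demand from impulse response and call.
#'
#' @param scans a [scan_set()].
#' @param split a [split_by_flower()] result.
#' @param call echolocation call waveform (raw; it is high-pass filtered at
#'   `hp_cutoff` before convolution).
#' @param k echoes per chunk.
#' @param scheme chunk sampling scheme, `"random"` or `"interval"`.
#' @param epochs maximum number of epochs.
#' @param lr Adam learning rate.
#' @param batch_size mini-batch size.
#' @param patience early-stopping patience in epochs.
#' @param echo_length fixed echo length in samples.
#' @param sample_rate sampling rate of `call` in Hz.
#' @param hp_cutoff high-pass cutoff in Hz.
#' @param dense dense-layer widths.
#' @param seed integer seed controlling initialisation, chunking and batch
#'   shuffling.
#' @param max_chunks_per_flower optional cap on train/validation chunks per
#'   flower (see [build_chunks()]); keeps small studies cheap.
#' @param verbose print per-epoch progress.
#' @return object of class `echonet_fit` with the trained parameters, the
#'   network spec, the class levels, and `history` (per-epoch train /
#'   validation loss and accuracy).
#' @export
train_echonet <- function(scans, split, call, k = 3L,
                          scheme = c("random", "interval"), epochs = 60L,
                          lr = 1e-4, batch_size = 16L, patience = 8L,
                          echo_length = 1280L, sample_rate = 5e5,
                          hp_cutoff = 5e3, dense = c(256L, 128L),
                          seed = 1L, max_chunks_per_flower = Inf,
                          verbose = FALSE) {
  scheme <- match.arg(scheme)
  call_hp <- highpass_call(call, sample_rate, hp_cutoff)
  train_chunks <- build_chunks(scans, split$train, k, scheme,
                               seed = seed * 1000L,
                               max_chunks_per_flower = max_chunks_per_flower)
  val_chunks <- build_chunks(scans, split$validation, k, scheme,
                             seed = seed * 1000L + 500L,
                             max_chunks_per_flower = max_chunks_per_flower)
  levels <- sort(unique(vapply(scans[c(split$train, split$validation)],
                               `[[`, character(1), "species")))
  y_train <- match(vapply(train_chunks, `[[`, character(1), "species"),
                   levels)
  y_val <- match(vapply(val_chunks, `[[`, character(1), "species"), levels)
  provider <- .spectrogram_provider(scans, call_hp, echo_length)
  shape <- dim(provider(train_chunks[[1]]$flower_id,
                        train_chunks[[1]]$rows$plane[1],
                        train_chunks[[1]]$rows$angle_idx[1]))
  spec <- echonet_spec(k, shape, n_classes = length(levels), dense = dense)
  params <- build_echonet(spec, seed = seed)
  state <- .adam_init(params)
  x_val <- .chunk_batch(val_chunks, provider, shape, k)
  history <- data.frame()
  best <- list(loss = Inf, params = params, epoch = 0L)
  stalled <- 0L
  with_seed(seed + 99L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(train_chunks))
      tr_loss <- 0; tr_hit <- 0
      for (start in seq(1, length(ord), by = batch_size)) {
        sel <- ord[start:min(start + batch_size - 1, length(ord))]
        xb <- .chunk_batch(train_chunks[sel], provider, shape, k)
        yb <- y_train[sel]
        fwd <- .echonet_forward(params, spec, xb, keep_cache = TRUE)
        if (!all(is.finite(fwd$probs)))
          stopf("training diverged (non-finite loss) at epoch %d", ep)
        tr_loss <- tr_loss + .cross_entropy(fwd$probs, yb) * length(sel)
        tr_hit <- tr_hit + sum(max.col(t(fwd$probs)) == yb)
        grads <- .echonet_backward(params, spec, fwd, yb)
        upd <- .adam_step(params, grads, state, lr = lr)
        params <- upd$params; state <- upd$state
      }
      vfwd <- .echonet_forward(params, spec, x_val)
      v_loss <- .cross_entropy(vfwd$probs, y_val)
      v_acc <- mean(max.col(t(vfwd$probs)) == y_val)
      history <- rbind(history, data.frame(
        epoch = ep, train_loss = tr_loss / length(ord),
        train_acc = tr_hit / length(ord),
        val_loss = v_loss, val_acc = v_acc))
      if (verbose)
        message(sprintf("epoch %2d  train loss %.3f acc %.3f | val loss %.3f acc %.3f",
                        ep, tr_loss / length(ord), tr_hit / length(ord),
                        v_loss, v_acc))
      if (v_loss < best$loss) {
        best <- list(loss = v_loss, params = params, epoch = ep)
        stalled <- 0L
      } else {
        stalled <- stalled + 1L
        if (stalled >= patience) break
      }
    }
  })
  structure(list(params = best$params, spec = spec, levels = levels,
                 history = history, k = k, scheme = scheme,
                 echo_length = echo_length, sample_rate = sample_rate,
                 hp_cutoff = hp_cutoff, best_epoch = best$epoch,
                 early_stopped = nrow(history) < epochs,
                 epochs_run = nrow(history), seed = seed),
            class = "echonet_fit")
}

#' @export
print.echonet_fit <- function(x, ...) {
  cat(sprintf("Echo classifier: %d-input CNN, %d classes, scheme %s\n",
              x$k, x$spec$n_classes, x$scheme))
  cat(sprintf("  epochs run %d (best validation at %d%s)\n", x$epochs_run,
              x$best_epoch,
              if (x$early_stopped) ", early stopped" else ""))
  h <- x$history[nrow(x$history), ]
  cat(sprintf("  final: train acc %.3f, val acc %.3f\n",
              h$train_acc, h$val_acc))
  invisible(x)
}

#' Predict species probabilities for echo chunks
#'
#' @param object an `echonet_fit`.
#' @param chunks list of `echo_chunk` objects.
#' @param scans the [scan_set()] the chunks index into.
#' @param call raw call waveform (filtered internally as during training).
#' @param ... unused.
#' @return matrix (n_chunks x n_classes) of class probabilities; rows sum to
#'   one.
#' @export
predict.echonet_fit <- function(object, chunks, scans, call, ...) {
  call_hp <- highpass_call(call, object$sample_rate, object$hp_cutoff)
  provider <- .spectrogram_provider(scans, call_hp, object$echo_length)
  shape <- object$spec$input_shape
  probs <- matrix(NA_real_, length(chunks), object$spec$n_classes,
                  dimnames = list(NULL, object$levels))
  for (start in seq(1, length(chunks), by = 64)) {
    sel <- start:min(start + 63, length(chunks))
    xb <- .chunk_batch(chunks[sel], provider, shape, object$k)
    probs[sel, ] <- t(.echonet_forward(object$params, object$spec,
                                       xb)$probs)
  }
  probs
}

#' Evaluate the classifier on held-out flowers
#'
#' Builds test chunks with the fit's own scheme and chunk size, predicts,
#' and reports overall accuracy, the species confusion matrix (rows = true),
#' and per-syndrome accuracy pooled over species with 95 percent
#' Clopper-Pearson binomial confidence intervals.
#'
#' @param fit an `echonet_fit`.
#' @param scans a [scan_set()].
#' @param test_ids flower ids held out from training.
#' @param call raw call waveform.
#' @param seed seed for test chunking.
#' @param scheme chunking scheme for the test set; defaults to the scheme
#'   the model was trained with, but a common scheme can be forced when
#'   comparing models trained under different schemes.
#' @return object of class `echonet_eval`: list with `accuracy`,
#'   `confusion`, `per_syndrome` (data frame with accuracy and CI) and
#'   `n_chunks`.
#' @export
evaluate_echonet <- function(fit, scans, test_ids, call, seed = 1L,
                             scheme = fit$scheme) {
  chunks <- build_chunks(scans, test_ids, fit$k, scheme,
                         seed = seed * 7000L)
  probs <- predict(fit, chunks, scans, call)
  pred <- fit$levels[max.col(probs)]
  truth <- vapply(chunks, `[[`, character(1), "species")
  syn <- vapply(chunks, `[[`, character(1), "syndrome")
  confusion <- table(true = factor(truth, levels = fit$levels),
                     predicted = factor(pred, levels = fit$levels))
  hit <- pred == truth
  per_syn <- do.call(rbind, lapply(sort(unique(syn)), function(s) {
    n <- sum(syn == s); x <- sum(hit[syn == s])
    ci <- binom.test(x, n)$conf.int   # Clopper-Pearson
    data.frame(syndrome = s, n = n, accuracy = x / n,
               ci_low = ci[1], ci_high = ci[2])
  }))
  structure(list(accuracy = mean(hit), confusion = confusion,
                 per_syndrome = per_syn, n_chunks = length(chunks)),
            class = "echonet_eval")
}

#' @export
print.echonet_eval <- function(x, ...) {
  cat(sprintf("Test accuracy: %.1f%% over %d chunks\n", 100 * x$accuracy,
              x$n_chunks))
  for (i in seq_len(nrow(x$per_syndrome))) {
    r <- x$per_syndrome[i, ]
    cat(sprintf("  %-6s %.1f%% (95%% CI %.1f-%.1f%%, n = %d)\n",
                r$syndrome, 100 * r$accuracy, 100 * r$ci_low,
                100 * r$ci_high, r$n))
  }
  invisible(x)
}

#' Clopper-Pearson binomial confidence interval
#'
#' Exact binomial interval for a classification accuracy, via the beta
#' quantile form.
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level.
#' @return two-element vector (lower, upper).
#' @export
clopper_pearson <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lower <- if (x == 0) 0 else qbeta(a, x, n - x + 1)
  upper <- if (x == n) 1 else qbeta(1 - a, x + 1, n - x)
  c(lower, upper)
}
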