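# Training loop, ancestral sampling loop, Adam optimizer and checkpoints.

tree_map1 <- function(a, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) {
      if (!is.null(a[[i]])) out[[i]] <- tree_map1(a[[i]], f)
    }
    out
  } else {
    f(a)
  }
}

adam_init <- function(params) {
  list(m = tree_map1(params, function(x) x * 0),
       v = tree_map1(params, function(x) x * 0),
       step = 0L)
}

# one Adam update; returns list(params, state)
adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$step <- state$step + 1L
  t <- state$step
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      nms <- names(p)
      for (i in seq_along(p)) {
        if (is.null(p[[i]])) next
        key <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else i
        r <- rec(p[[key]], g[[key]], m[[key]], v[[key]])
        p[[key]] <- r$p; m[[key]] <- r$m; v[[key]] <- r$v
      }
      list(p = p, m = m, v = v)
    } else {
      m2 <- beta1 * m + (1 - beta1) * g
      v2 <- beta2 * v + (1 - beta2) * g * g
      list(p = p - lr * (m2 / bc1) / (sqrt(v2 / bc2) + eps), m = m2, v = v2)
    }
  }
  r <- rec(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, step = t))
}

#' Training configuration
#'
#' Defaults follow the reference protocol for 28x28 chest X-ray stacks:
#' 40 epochs of 300 optimizer updates, batch size 32 with incomplete batches
#' dropped, Huber loss (delta = 1) and Adam at learning rate 1e-3.
#'
#' @param epochs,steps_per_epoch,batch_size positive integers.
#' @param learning_rate positive Adam step size.
#' @param loss_kind `"huber"`, `"l1"` or `"l2"`.
#' @param huber_delta positive Huber threshold.
#' @param seed master seed; every random sub-stream (shuffling, timestep and
#'   noise draws) is derived from it via [derive_seed()].
#' @param drop_last drop the final incomplete batch of each data pass.
#' @param checkpoint_path optional file to write the end-of-run checkpoint to.
#' @param checkpoint_every_epoch also checkpoint after each epoch.
#' @return a `training_config` list.
#' @export
training_config <- function(epochs = 40L, steps_per_epoch = 300L,
                            batch_size = 32L, learning_rate = 1e-3,
                            loss_kind = c("huber", "l1", "l2"),
                            huber_delta = 1, seed = 0L, drop_last = TRUE,
                            checkpoint_path = NULL,
                            checkpoint_every_epoch = FALSE) {
  loss_kind <- match.arg(tolower(loss_kind), c("huber", "l1", "l2"))
  for (nm in c("epochs", "steps_per_epoch", "batch_size")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 ||
        v != round(v)) {
      stop(sprintf("`%s` must be a positive integer", nm), call. = FALSE)
    }
  }
  if (learning_rate <= 0) stop("`learning_rate` must be positive",
                               call. = FALSE)
  if (huber_delta <= 0) stop("`huber_delta` must be positive", call. = FALSE)
  structure(list(epochs = as.integer(epochs),
                 steps_per_epoch = as.integer(steps_per_epoch),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, loss_kind = loss_kind,
                 huber_delta = huber_delta, seed = as.integer(seed),
                 drop_last = isTRUE(drop_last),
                 checkpoint_path = checkpoint_path,
                 checkpoint_every_epoch = isTRUE(checkpoint_every_epoch)),
            class = "training_config")
}

#' One training step
#'
#' Draws one timestep per batch element uniformly on `1..T` and one Gaussian
#' noise field, corrupts the batch with [q_sample()], compares the model's
#' noise prediction against the injected noise under the chosen loss, and
#' (for trainable models) applies one Adam update. Randomness comes from the
#' caller's RNG state; seed it before calling for reproducibility.
#'
#' Models that are not `denoiser_model`s (e.g. analytic stubs implementing
#' the [denoise()] generic) are evaluated but not updated.
#'
#' @param model a noise predictor implementing [denoise()].
#' @param x0_batch normalized [image_batch()].
#' @param s a [make_linear_schedule()].
#' @param loss_kind,huber_delta see [noise_prediction_loss()].
#' @param opt Adam state from a previous call, or `NULL` to start fresh.
#' @param learning_rate Adam step size.
#' @return a list with `model`, `opt`, `loss` (the pre-update loss), and the
#'   drawn `t`.
#' @export
train_step <- function(model, x0_batch, s, loss_kind = "huber",
                       huber_delta = 1, opt = NULL, learning_rate = 1e-3) {
  check_normalized(x0_batch, "x0_batch")
  d <- dim(x0_batch)
  n <- d[1]
  tv <- sample.int(s$timesteps, n, replace = TRUE)
  eps <- array(stats::rnorm(length(x0_batch)), d)
  xt <- q_sample(x0_batch, tv, eps, s)
  if (inherits(model, "denoiser_model")) {
    xi <- aperm(unclass(xt), c(3, 4, 1, 2))
    fwd <- unet_fwd(model$spec, model$params, xi, tv)
    eps_i <- aperm(eps, c(3, 4, 1, 2))
    loss <- noise_prediction_loss(fwd$y, eps_i, loss_kind, huber_delta)
    if (!is.finite(loss)) {
      stop("training diverged: non-finite loss", call. = FALSE)
    }
    dy <- loss_gradient(fwd$y, eps_i, loss_kind, huber_delta)
    grads <- unet_bwd(model$spec, model$params, fwd$cache, dy)
    if (is.null(opt)) opt <- adam_init(model$params)
    upd <- adam_update(model$params, grads, opt, learning_rate)
    model$params <- upd$params
    opt <- upd$state
  } else {
    eps_hat <- denoise(model, xt, tv)
    loss <- noise_prediction_loss(unclass(eps_hat), eps, loss_kind,
                                  huber_delta)
  }
  list(model = model, opt = opt, loss = loss, t = tv)
}

#' Train a denoiser
#'
#' Runs `epochs x steps_per_epoch` optimizer updates over the dataset,
#' cycling reshuffled batches, and records the mean pre-update loss of each
#' epoch. Fully reproducible: all randomness is derived from `config$seed`,
#' and the global RNG state is left untouched.
#'
#' @param model a [build_denoiser()] model.
#' @param dataset normalized [image_batch()] of training images.
#' @param config a [training_config()].
#' @param s a [make_linear_schedule()].
#' @param verbose log per-epoch progress. Default `TRUE`.
#' @return a `training_run`: list with `config`, `epoch_losses`, `model`,
#'   `schedule`, `checkpoint_path`.
#' @export
train <- function(model, dataset, config, s, verbose = TRUE) {
  stopifnot(inherits(config, "training_config"),
            inherits(s, "noise_schedule"))
  check_normalized(dataset, "dataset")
  n <- dim(dataset)[1]
  bs <- config$batch_size
  n_batches <- if (config$drop_last) n %/% bs else ceiling(n / bs)
  if (n_batches < 1L) {
    stop(sprintf(
      "dataset yields no full batch: %d image(s) < batch size %d", n, bs),
      call. = FALSE)
  }
  epoch_losses <- numeric(0)
  order_idx <- integer(0)
  cursor <- 0L
  pass <- 0L
  global_step <- 0L
  opt <- NULL
  for (epoch in seq_len(config$epochs)) {
    losses <- numeric(config$steps_per_epoch)
    for (step in seq_len(config$steps_per_epoch)) {
      remaining <- length(order_idx) - cursor
      if (remaining < bs && (config$drop_last || remaining == 0L)) {
        pass <- pass + 1L
        order_idx <- with_seed(
          derive_seed(config$seed, paste0("shuffle-pass-", pass)),
          sample.int(n))
        cursor <- 0L
      }
      take <- order_idx[(cursor + 1L):min(cursor + bs, length(order_idx))]
      cursor <- cursor + length(take)
      batch <- as_batch(unclass(dataset)[take, , , , drop = FALSE])
      global_step <- global_step + 1L
      res <- with_seed(
        derive_seed(config$seed, paste0("train-step-", global_step)),
        tryCatch(
          train_step(model, batch, s, config$loss_kind, config$huber_delta,
                     opt = opt, learning_rate = config$learning_rate),
          error = function(e) {
            stop(sprintf("epoch %d step %d: %s", epoch, step,
                         conditionMessage(e)), call. = FALSE)
          }))
      model <- res$model
      opt <- res$opt
      losses[step] <- res$loss
    }
    epoch_losses <- c(epoch_losses, mean(losses))
    if (verbose) {
      log_info("train", epoch = epoch, steps = config$steps_per_epoch,
               loss = mean(losses))
    }
    if (config$checkpoint_every_epoch && !is.null(config$checkpoint_path)) {
      save_checkpoint(make_run(model, config, s, epoch_losses),
                      config$checkpoint_path)
    }
  }
  run <- make_run(model, config, s, epoch_losses)
  if (!is.null(config$checkpoint_path)) {
    save_checkpoint(run, config$checkpoint_path)
  }
  run
}

make_run <- function(model, config, s, epoch_losses) {
  model$schedule_meta <- schedule_to_list(s)
  structure(list(config = config, epoch_losses = epoch_losses,
                 model = model, schedule = s,
                 checkpoint_path = config$checkpoint_path),
            class = "training_run")
}

#' @export
print.training_run <- function(x, ...) {
  cat(sprintf(
    "<training_run> %d/%d epoch(s) x %d steps, %s loss; last epoch %.5f\n",
    length(x$epoch_losses), x$config$epochs, x$config$steps_per_epoch,
    x$config$loss_kind,
    if (length(x$epoch_losses)) x$epoch_losses[length(x$epoch_losses)]
    else NA_real_))
  invisible(x)
}

#' Plot the per-epoch loss history of one or more runs
#'
#' @param x a `training_run`, or a named list of them (one curve per run).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.training_run <- function(x, ...) {
  plot_loss_histories(list(run = x), ...)
}

#' @rdname plot.training_run
#' @param runs named list of `training_run` objects.
#' @export
plot_loss_histories <- function(runs, ...) {
  losses <- lapply(runs, function(r) r$epoch_losses)
  m <- do.call(cbind, losses)
  graphics::matplot(seq_len(nrow(m)), m, type = "l", lty = 1, lwd = 2,
                    xlab = "epoch", ylab = "training loss", ...)
  graphics::legend("topright", legend = names(runs), lty = 1, lwd = 2,
                   col = seq_len(ncol(m)))
  invisible(runs)
}

#' Write a loss history as a two-column CSV (`epoch,loss`)
#'
#' @param run a `training_run`.
#' @param path output file.
#' @export
write_loss_history <- function(run, path) {
  utils::write.csv(
    data.frame(epoch = seq_along(run$epoch_losses), loss = run$epoch_losses),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate images by ancestral reverse diffusion
#'
#' Starts from pure Gaussian noise and applies [p_sample_step()] for
#' `t = T .. 1` with the model's noise prediction, optionally recording
#' intermediate states. `snapshot_after` counts completed reverse updates:
#' with `T = 300` and `snapshot_after = c(99, 149, 259, 279, 299)` the
#' trajectory is captured five times before the final image, mirroring the
#' staged-denoising panels customarily shown for these models.
#'
#' The unclamped trajectory is kept internally; each emitted snapshot and the
#' final batch are clamped to `[-1, 1]` and converted to uint8.
#'
#' @param model a noise predictor implementing [denoise()]; if it carries
#'   checkpoint metadata its schedule length must agree with `s`.
#' @param s a [make_linear_schedule()].
#' @param n_images number of images to generate.
#' @param seed sampler seed (its own stream; independent of training).
#' @param snapshot_after integer vector of completed-update counts in
#'   `1..T` at which to record a snapshot.
#' @param image_size height/width of the generated images. Default 28.
#' @param verbose log progress.
#' @return list with `final` (uint8 [image_batch()]) and `snapshots` (named
#'   list of uint8 batches, names = completed-update counts).
#' @export
sample_images <- function(model, s, n_images, seed = 0L,
                          snapshot_after = integer(0), image_size = 28L,
                          verbose = FALSE) {
  stopifnot(inherits(s, "noise_schedule"), n_images >= 1)
  if (length(snapshot_after)) {
    if (anyNA(snapshot_after) || any(snapshot_after != round(snapshot_after)) ||
        any(snapshot_after < 1) || any(snapshot_after > s$timesteps)) {
      stop(sprintf("`snapshot_after` entries must lie in 1..%d",
                   s$timesteps), call. = FALSE)
    }
    snapshot_after <- sort(unique(as.integer(snapshot_after)))
  }
  meta <- model$schedule_meta
  if (!is.null(meta) && meta$timesteps != s$timesteps) {
    stop(sprintf(
      "model was trained with T=%d but the schedule has T=%d",
      meta$timesteps, s$timesteps), call. = FALSE)
  }
  d <- c(n_images, 1L, image_size, image_size)
  with_seed(derive_seed(seed, "sampler"), {
    x <- as_batch(array(stats::rnorm(prod(d)), d))
    snapshots <- list()
    for (t in s$timesteps:1) {
      eps_hat <- denoise(model, x, t)
      z <- if (t > 1L) array(stats::rnorm(prod(d)), d) else array(0, d)
      x <- p_sample_step(x, t, unclass(eps_hat), z, s)
      done <- s$timesteps - t + 1L
      if (done %in% snapshot_after) {
        snapshots[[as.character(done)]] <-
          denormalize_images(as_batch(clamp(unclass(x), -1, 1)))
      }
      if (verbose && (done %% 50L == 0L)) {
        log_info("sample", completed = done, total = s$timesteps)
      }
    }
    list(final = denormalize_images(as_batch(clamp(unclass(x), -1, 1))),
         snapshots = snapshots)
  })
}

# ---- checkpoints ------------------------------------------------------------

CHECKPOINT_VERSION <- 1L

#' Save / load a training checkpoint
#'
#' A checkpoint is a single RDS archive holding a format version, the
#' denoiser architecture, all parameters, the schedule parameters, the
#' training configuration and the loss history, so a run can be resumed for
#' sampling with nothing else on hand.
#'
#' @param run a `training_run` (or a bare `denoiser_model`).
#' @param path file path.
#' @return `load_checkpoint()` returns a `training_run`.
#' @export
save_checkpoint <- function(run, path) {
  if (inherits(run, "denoiser_model")) {
    run <- structure(list(config = NULL, epoch_losses = numeric(0),
                          model = run, schedule = NULL,
                          checkpoint_path = path),
                     class = "training_run")
  }
  stopifnot(inherits(run, "training_run"))
  obj <- list(version = CHECKPOINT_VERSION,
              spec = run$model$spec,
              params = run$model$params,
              rng_seed = run$model$rng_seed,
              schedule = if (!is.null(run$schedule))
                schedule_to_list(run$schedule),
              config = run$config,
              epoch_losses = run$epoch_losses)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, CHECKPOINT_VERSION)) {
    stop(sprintf("unsupported checkpoint version %s", obj$version),
         call. = FALSE)
  }
  model <- structure(
    list(spec = obj$spec, params = obj$params, rng_seed = obj$rng_seed,
         n_params = count_params(obj$params),
         schedule_meta = obj$schedule),
    class = "denoiser_model")
  s <- if (!is.null(obj$schedule)) schedule_from_list(obj$schedule)
  structure(list(config = obj$config, epoch_losses = obj$epoch_losses,
                 model = model, schedule = s, checkpoint_path = path),
            class = "training_run")
}
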