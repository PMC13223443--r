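# YAML run configuration: defaults, validation, round-tripping.

#' The default run configuration
#'
#' All defaults follow the reference protocol for 28x28 chest X-ray stacks:
#' a 300-step linear schedule from 1e-4 to 0.02, a U-Net with base width 28
#' and multipliers (1, 2, 4), 40 epochs of 300 steps at batch size 32 under
#' the Huber loss, and FID evaluation at feature dimensions 2048 and 64 over
#' 20,480 generated samples.
#'
#' @return a nested `run_config` list with sections `schedule`, `model`,
#'   `training`, `sampling`, `eval`, `paths` and a top-level `seed`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 0L,
    schedule = list(timesteps = 300L, beta_start = 1e-4, beta_end = 0.02,
                    sigma_variant = "beta"),
    model = list(base_channels = 28L, channel_multipliers = c(1L, 2L, 4L),
                 blocks_per_stage = 2L, time_embedding_dim = 112L,
                 attention_levels = c(1L, 2L, 3L), num_heads = 4L,
                 image_size = 28L),
    training = list(epochs = 40L, steps_per_epoch = 300L, batch_size = 32L,
                    learning_rate = 1e-3, loss_kind = "huber",
                    huber_delta = 1, drop_last = TRUE),
    sampling = list(n_images = 64L,
                    snapshot_after = c(99L, 149L, 259L, 279L, 299L)),
    eval = list(extractor = "projection-pool", dims = c(64L, 2048L),
                n_generate = 20480L),
    paths = list(data = NULL, output = ".")),
    class = "run_config")
}

#' Load and validate a run configuration
#'
#' Reads a YAML file, overlays it on [default_run_config()] (absent keys
#' keep their defaults; an empty file yields the full default
#' configuration), validates every section, and reports *all* violations at
#' once. Unknown keys are rejected rather than ignored.
#'
#' @param path YAML file.
#' @param overrides optional named list of `section.key = value` overrides
#'   (applied after the file), e.g. `list("training.epochs" = 5)`.
#' @return a validated `run_config`.
#' @export
load_config <- function(path, overrides = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- unclass(default_run_config())
  problems <- character(0)
  if (!is.list(user)) {
    stop("configuration file must hold a YAML mapping", call. = FALSE)
  }
  unknown_top <- setdiff(names(user), names(cfg))
  if (length(unknown_top)) {
    problems <- c(problems,
                  sprintf("unknown section(s): %s",
                          paste(unknown_top, collapse = ", ")))
  }
  for (sec in intersect(names(user), names(cfg))) {
    if (sec == "seed") {
      cfg$seed <- user$seed
      next
    }
    unknown <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
    if (length(unknown)) {
      problems <- c(problems,
                    sprintf("unknown key(s) in `%s`: %s", sec,
                            paste(unknown, collapse = ", ")))
    }
    for (key in intersect(names(user[[sec]]), names(cfg[[sec]]))) {
      cfg[[sec]][key] <- list(user[[sec]][[key]])
    }
  }
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      if (length(parts) == 1L && parts == "seed") {
        cfg$seed <- overrides[[nm]]
      } else if (length(parts) == 2L && parts[1] %in% names(cfg) &&
                 parts[2] %in% names(cfg[[parts[1]]])) {
        cfg[[parts[1]]][parts[2]] <- list(overrides[[nm]])
      } else {
        problems <- c(problems, sprintf("unknown override key: %s", nm))
      }
    }
  }
  problems <- c(problems, validate_run_config(cfg))
  if (length(problems)) {
    stop(structure(
      class = c("run_config_error", "error", "condition"),
      list(message = paste0("invalid configuration:\n",
                            paste0("  - ", problems, collapse = "\n")),
           call = NULL)))
  }
  structure(cfg, class = "run_config")
}

# returns a character vector of violations (empty when valid)
validate_run_config <- function(cfg) {
  p <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) p <<- c(p, msg)
  s <- cfg$schedule
  chk(is.numeric(s$timesteps) && length(s$timesteps) == 1 &&
        s$timesteps >= 1 && s$timesteps == round(s$timesteps),
      "schedule.timesteps must be a positive integer")
  chk(is.numeric(s$beta_start) && s$beta_start > 0 && s$beta_start < 1,
      "schedule.beta_start must lie in (0,1)")
  chk(is.numeric(s$beta_end) && s$beta_end > 0 && s$beta_end < 1,
      "schedule.beta_end must lie in (0,1)")
  if (is.numeric(s$beta_start) && is.numeric(s$beta_end)) {
    chk(s$beta_start <= s$beta_end,
        "schedule.beta_start must not exceed schedule.beta_end")
  }
  chk(s$sigma_variant %in% c("beta", "posterior"),
      "schedule.sigma_variant must be 'beta' or 'posterior'")
  m <- cfg$model
  spec_err <- tryCatch({
    do.call(denoiser_spec, m)
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(spec_err)) p <- c(p, paste0("model: ", spec_err))
  tr <- cfg$training
  for (nm in c("epochs", "steps_per_epoch", "batch_size")) {
    chk(is.numeric(tr[[nm]]) && length(tr[[nm]]) == 1 && tr[[nm]] >= 1 &&
          tr[[nm]] == round(tr[[nm]]),
        sprintf("training.%s must be a positive integer", nm))
  }
  chk(is.numeric(tr$learning_rate) && tr$learning_rate > 0,
      "training.learning_rate must be positive")
  chk(tolower(tr$loss_kind) %in% c("huber", "l1", "l2"),
      "training.loss_kind must be one of huber, l1, l2")
  chk(is.numeric(tr$huber_delta) && tr$huber_delta > 0,
      "training.huber_delta must be positive")
  sa <- cfg$sampling
  chk(is.numeric(sa$n_images) && sa$n_images >= 1,
      "sampling.n_images must be a positive integer")
  if (length(sa$snapshot_after) && is.numeric(s$timesteps)) {
    chk(all(sa$snapshot_after >= 1) &&
          all(sa$snapshot_after <= s$timesteps),
        sprintf("sampling.snapshot_after entries must lie in 1..%d",
                s$timesteps))
  }
  ev <- cfg$eval
  chk(ev$extractor %in% c("projection-pool"),
      "eval.extractor must be 'projection-pool'")
  chk(is.numeric(ev$dims) && all(ev$dims >= 1),
      "eval.dims must be positive integers")
  chk(is.numeric(ev$n_generate) && ev$n_generate >= 2,
      "eval.n_generate must be at least 2")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1 &&
        cfg$seed == round(cfg$seed),
      "seed must be an integer")
  p
}

#' Write a resolved configuration as YAML
#'
#' The written file reloads to an identical configuration via
#' [load_config()], so every run can archive the exact settings it used.
#'
#' @param cfg a `run_config`.
#' @param path output YAML file.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(drop_null(unclass(cfg)), path)
  invisible(path)
}

drop_null <- function(x) {
  if (!is.list(x)) return(x)
  x <- x[!vapply(x, is.null, logical(1))]
  lapply(x, drop_null)
}

# constructors from config sections
schedule_from_config <- function(cfg) {
  schedule_from_list(cfg$schedule)
}

model_from_config <- function(cfg, rng_seed = NULL) {
  spec <- do.call(denoiser_spec, cfg$model)
  build_denoiser(spec, rng_seed %||% derive_seed(cfg$seed, "model-init"))
}

training_config_from_config <- function(cfg, checkpoint_path = NULL) {
  tr <- cfg$training
  training_config(epochs = tr$epochs, steps_per_epoch = tr$steps_per_epoch,
                  batch_size = tr$batch_size,
                  learning_rate = tr$learning_rate,
                  loss_kind = tr$loss_kind, huber_delta = tr$huber_delta,
                  seed = derive_seed(cfg$seed, "training"),
                  drop_last = tr$drop_last,
                  checkpoint_path = checkpoint_path)
}
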