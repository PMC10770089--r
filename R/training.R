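# Loss construction, Adam optimization with plateau LR decay and early
# stopping, and MAE evaluation.  The combined loss follows the MD-dataset
# recipe: w_E * MSE(energy) + w_F * MSE(force), defaults 0.05 / 0.95.
# Because forces are themselves gradients, the parameter gradient of the
# force term is a second backward pass over the tape.

#' Training configuration
#'
#' @param loss_energy_weight weight of the energy MSE term (default 0.05).
#' @param loss_force_weight weight of the force MSE term (default 0.95).
#' @param batch_size frames per optimization step (default 10).
#' @param lr initial learning rate (default 1e-4).
#' @param lr_decay_factor multiplicative decay on plateau (default 0.8).
#' @param plateau_patience_epochs epochs without validation improvement that
#'   trigger one decay (default 30).
#' @param early_stop_patience epochs without improvement that stop training
#'   (default 3x the plateau patience).
#' @param max_epochs hard epoch cap (default 100).
#' @param min_improvement absolute validation-loss improvement that counts
#'   (default 1e-7).
#' @param seed RNG seed for batch shuffling.
#' @return object of class `train_config`.
#' @export
train_config <- function(loss_energy_weight = 0.05,
                         loss_force_weight = 0.95,
                         batch_size = 10L, lr = 1e-4,
                         lr_decay_factor = 0.8,
                         plateau_patience_epochs = 30L,
                         early_stop_patience = 3L * plateau_patience_epochs,
                         max_epochs = 100L, min_improvement = 1e-7,
                         seed = 1L) {
  stopifnot(loss_energy_weight >= 0, loss_force_weight >= 0,
            loss_energy_weight + loss_force_weight > 0,
            lr > 0, lr_decay_factor > 0, lr_decay_factor < 1,
            batch_size >= 1L, max_epochs >= 1L)
  structure(list(loss_energy_weight = loss_energy_weight,
                 loss_force_weight = loss_force_weight,
                 batch_size = as.integer(batch_size), lr = lr,
                 lr_decay_factor = lr_decay_factor,
                 plateau_patience_epochs = as.integer(plateau_patience_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 max_epochs = as.integer(max_epochs),
                 min_improvement = min_improvement,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Combined energy/force loss
#'
#' `w_E MSE(E) + w_F MSE(F)`, the force MSE averaged over all 3N components.
#'
#' @param pred_E,true_E numeric energy vectors (one value per frame).
#' @param pred_F,true_F stacked force matrices (total atoms x 3) or NULL when
#'   the force weight is zero.
#' @param cfg a [train_config()].
#' @return scalar loss.
#' @export
combined_loss <- function(pred_E, true_E, pred_F, true_F, cfg) {
  if (length(pred_E) != length(true_E))
    stop("energy shape mismatch")
  loss <- cfg$loss_energy_weight * mean((pred_E - true_E)^2)
  if (cfg$loss_force_weight > 0) {
    if (is.null(pred_F) || is.null(true_F) ||
        !identical(dim(pred_F), dim(true_F)))
      stop("force shape mismatch")
    loss <- loss + cfg$loss_force_weight * mean((pred_F - true_F)^2)
  }
  loss
}

# loss as a tape node over one batch
batch_loss_graph <- function(params, model_cfg, batch, true_E, true_F, cfg) {
  gr <- batch_energy_forces_graph(params, model_cfg, batch,
                                  need_forces = cfg$loss_force_weight > 0)
  dE <- ad_addc(gr$E_frames, -matrix(true_E, ncol = 1L))
  loss <- ad_scale(ad_sum(ad_mul(dE, dE)),
                   cfg$loss_energy_weight / length(true_E))
  if (cfg$loss_force_weight > 0) {
    dF <- ad_addc(gr$F_node, -true_F)
    loss <- ad_add(loss, ad_scale(ad_sum(ad_mul(dF, dF)),
                                  cfg$loss_force_weight / length(true_F)))
  }
  list(loss = loss, pn = gr$pn)
}

batch_labels <- function(configs) {
  list(E = vapply(configs, function(cf) cf$energy, 0),
       F = do.call(rbind, lapply(configs, function(cf) cf$forces)))
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = st)
}

dataset_loss <- function(params, model_cfg, configs, cfg) {
  lab <- batch_labels(configs)
  batch <- build_batch(configs, model_cfg$cutoff)
  bl <- batch_loss_graph(params, model_cfg, batch, lab$E, lab$F, cfg)
  ad_value(bl$loss)[1L]
}

#' Fit a model by combined energy/force matching
#'
#' Mini-batch Adam with plateau-triggered learning-rate decay (factor
#' `lr_decay_factor` whenever the validation loss has not improved by more
#' than `min_improvement` for `plateau_patience_epochs` consecutive epochs),
#' early stopping, and best-validation checkpointing.  Deterministic for a
#' fixed seed on a single device.
#'
#' @param model an [rgc_model()] (head "energy_forces").
#' @param dataset list of labeled [atomic_configuration()]s.
#' @param split a [dataset_split()] over `dataset`.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return list of class `train_report`: `model` (best checkpoint), `log`
#'   (data.frame epoch/lr/train_loss/val_loss), `best_val`, and `test_mae`
#'   (energy/force MAE on the split's test indices, when non-empty).
#' @export
fit <- function(model, dataset, split, cfg = train_config(),
                verbose = FALSE) {
  stopifnot(length(split$train) >= 1L)
  train_set <- dataset[split$train]
  val_set <- dataset[split$val]
  if (length(val_set) == 0L) stop("empty validation split")
  for (cf in c(train_set, val_set)) {
    if (is.null(cf$energy)) stop("dataset must carry energy labels")
    if (cfg$loss_force_weight > 0 && is.null(cf$forces))
      stop("force-weighted loss needs force labels")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)

  ## label standardization: the network learns O(1) quantities; the affine
  ## calibration (scale from the training force spread, shift from the mean
  ## training energy) is stored on the returned model
  tr_E <- vapply(train_set, function(cf) cf$energy, 0)
  shift <- mean(tr_E)
  scale <- if (cfg$loss_force_weight > 0) {
    stats::sd(unlist(lapply(train_set, function(cf) cf$forces)))
  } else {
    stats::sd(tr_E)
  }
  if (!is.finite(scale) || scale <= 0) scale <- 1
  standardize <- function(cfs) lapply(cfs, function(cf) {
    cf$energy <- (cf$energy - shift) / scale
    if (!is.null(cf$forces)) cf$forces <- cf$forces / scale
    cf
  })
  train_set <- standardize(train_set)
  val_set <- standardize(val_set)

  params <- model$params
  st <- adam_state(params)
  lr <- cfg$lr
  best_val <- Inf
  best_params <- params
  since_improve <- 0L
  since_decay <- 0L
  log <- data.frame()

  for (epoch in seq_len(cfg$max_epochs)) {
    idx <- sample(seq_along(train_set))
    batches <- split(idx, ceiling(seq_along(idx) / cfg$batch_size))
    tr_loss <- 0
    for (bidx in batches) {
      configs <- train_set[bidx]
      lab <- batch_labels(configs)
      batch <- build_batch(configs, model$config$cutoff)
      bl <- batch_loss_graph(params, model$config, batch, lab$E, lab$F, cfg)
      lval <- ad_value(bl$loss)[1L]
      if (!is.finite(lval)) stop("NaN/Inf loss at epoch ", epoch)
      gnodes <- ad_grad(bl$loss, bl$pn[names(params)])
      grads <- lapply(gnodes, ad_value)
      names(grads) <- names(params)
      upd <- adam_step(params, grads, st, lr)
      params <- upd$params; st <- upd$state
      tr_loss <- tr_loss + lval * length(bidx)
    }
    tr_loss <- tr_loss / length(train_set)
    val_loss <- dataset_loss(params, model$config, val_set, cfg)
    if (!is.finite(val_loss)) stop("NaN/Inf validation loss at epoch ", epoch)
    log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                 train_loss = tr_loss, val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %4d  lr %.3g  train %.6g  val %.6g",
                      epoch, lr, tr_loss, val_loss))
    if (val_loss < best_val - cfg$min_improvement) {
      best_val <- val_loss
      best_params <- params
      since_improve <- 0L
      since_decay <- 0L
    } else {
      since_improve <- since_improve + 1L
      since_decay <- since_decay + 1L
      if (since_decay >= cfg$plateau_patience_epochs) {
        lr <- lr * cfg$lr_decay_factor
        since_decay <- 0L
      }
      if (since_improve >= cfg$early_stop_patience) break
    }
  }

  best_model <- structure(list(config = model$config, params = best_params,
                               output_scale = scale, output_shift = shift),
                          class = "rgc_model")
  report <- list(model = best_model, log = log, best_val = best_val)
  if (length(split$test) > 0L) {
    report$test_mae <- evaluate_mae(best_model, dataset[split$test])
  }
  class(report) <- "train_report"
  report
}

#' @export
print.train_report <- function(x, ...) {
  cat(sprintf("<train_report: %d epochs, best validation loss %.6g>\n",
              nrow(x$log), x$best_val))
  invisible(x)
}

#' Mean absolute errors of energy and forces
#'
#' @param model an [rgc_model()].
#' @param configs labeled configurations.
#' @return named vector `c(energy_mae = ..., force_mae = ...)` in kcal/mol
#'   and kcal/mol/A (force MAE over all 3N components; NA when no force
#'   labels).
#' @export
evaluate_mae <- function(model, configs) {
  e_err <- numeric(0); f_err <- numeric(0)
  have_forces <- all(vapply(configs, function(cf) !is.null(cf$forces), TRUE))
  for (cf in configs) {
    if (have_forces) {
      ef <- predict_energy_forces(model, cf)
      f_err <- c(f_err, abs(ef$forces - cf$forces))
    } else {
      ef <- list(energy = predict_energy(model, cf))
    }
    e_err <- c(e_err, abs(ef$energy - cf$energy))
  }
  c(energy_mae = mean(e_err),
    force_mae = if (have_forces) mean(f_err) else NA_real_)
}

#' Run the frozen parameter-recovery experiment
#'
#' Trains the small reference model (2 blocks, 64 channels) on the frozen
#' 4-atom-chain fixture ([reference_fixture()]: 50 training + 10 validation
#' frames, 0.05 A displacements, seed 7) with the combined 0.05/0.95
#' energy/force loss, and reports the validation force MAE relative to the
#' standard deviation of the label forces.  This is the package's
#' learnability benchmark: a healthy implementation reaches a ratio well
#' below 0.05.
#'
#' @param max_epochs training length (default 500; smaller values give a
#'   cheaper, weaker check).
#' @param verbose print per-epoch progress.
#' @return list with `force_mae`, `force_sd`, `ratio`, `energy_mae`, and
#'   the full `report` from [fit()].
#' @export
reference_recovery <- function(max_epochs = 500L, verbose = FALSE) {
  fx <- reference_fixture()
  ds <- generate_dataset(fx$spec, fx$n_train + fx$n_val,
                         fx$displacement_scale, seed = fx$seed)
  sp <- structure(list(train = seq_len(fx$n_train),
                       val = fx$n_train + seq_len(fx$n_val),
                       test = integer(0), seed = fx$seed),
                  class = "dataset_split")
  mc <- model_config(n_blocks = fx$model_blocks,
                     hidden_dim = fx$model_dim, n_heads = 8L, cutoff = 5)
  model <- rgc_model(mc, seed = fx$seed)
  tc <- train_config(lr = 2e-3, batch_size = 25L,
                     max_epochs = as.integer(max_epochs),
                     plateau_patience_epochs = 12L,
                     early_stop_patience = 100L, seed = fx$seed)
  report <- fit(model, ds, sp, tc, verbose = verbose)
  mae <- evaluate_mae(report$model, ds[sp$val])
  force_sd <- stats::sd(unlist(lapply(ds[sp$train],
                                      function(cf) cf$forces)))
  list(force_mae = unname(mae["force_mae"]), force_sd = force_sd,
       ratio = unname(mae["force_mae"]) / force_sd,
       energy_mae = unname(mae["energy_mae"]), report = report)
}

#' Learning-rate sequence after plateau decays
#'
#' Pure schedule arithmetic: starting rate decayed `n_decays` times by the
#' configured factor.
#'
#' @param lr0 starting learning rate.
#' @param factor decay factor in (0, 1).
#' @param n_decays number of plateau events.
#' @return numeric vector of length `n_decays + 1`.
#' @export
lr_schedule <- function(lr0, factor, n_decays) lr0 * factor^(0:n_decays)
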