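# Masked cross-entropy training.  The objective is the mean negative
# log-probability of the true category over masked slots only (pooled across
# node properties and edges, so its scale does not depend on the masking
# rate); unmasked slots contribute nothing.  Optimized with Adam under a
# global gradient-norm clip; the checkpoint with the lowest validation loss
# (fixed alpha, fixed corruption seed) is returned.

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param beta1,beta2 Adam moment decays (defaults 0.9 / 0.98).
#' @param batch_size graphs per gradient step.
#' @param grad_accum number of micro-batches summed into one update; the
#'   combined gradient equals the single-large-batch gradient because
#'   normalization by the masked-slot count happens after accumulation.
#' @param clip maximum global gradient norm (default 10).
#' @param max_epochs epoch budget.
#' @param patience early-stopping patience on validation loss (default 10).
#' @param mask training/validation masking config (`mask_config()`).
#' @param seed RNG seed fixing shuffling, corruption, and initialization.
#' @return an object of class `mgm_train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, beta1 = 0.9, beta2 = 0.98,
                         batch_size = 32L, grad_accum = 1L, clip = 10,
                         max_epochs = 20L, patience = 10L,
                         mask = mask_config(), seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, grad_accum >= 1, clip > 0,
            max_epochs >= 1)
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 batch_size = as.integer(batch_size),
                 grad_accum = as.integer(grad_accum), clip = clip,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), mask = mask, seed = seed),
            class = "mgm_train_config")
}

#' Masked cross-entropy loss for one graph
#'
#' Mean over masked slots of `-log p(true category)`; an empty mask set gives
#' 0 by convention.
#'
#' @param predictions output of [mgm_forward()] on the corrupted graph.
#' @param original the uncorrupted `mgm_graph` supplying true categories.
#' @param mask the `mgm_mask_set` from the corruption call.
#' @return scalar loss (nats per masked slot).
#' @export
masked_ce_loss <- function(predictions, original, mask) {
  m <- n_masked_slots(mask)
  if (m == 0) return(0)
  total <- 0
  if (nrow(mask$nodes) > 0) {
    for (r in seq_len(nrow(mask$nodes))) {
      i <- mask$nodes[r, 1]; k <- mask$nodes[r, 2]
      pk <- predictions$node[[k]]
      if (i > nrow(pk) || i > nrow(original$nodes)) {
        stop("masked_ce_loss: mask references a slot with no prediction", call. = FALSE)
      }
      cls <- original$nodes[i, k]
      total <- total - log(pk[i, cls])
    }
  }
  if (length(mask$edges) > 0) {
    if (max(mask$edges) > nrow(predictions$edge)) {
      stop("masked_ce_loss: mask references a slot with no prediction", call. = FALSE)
    }
    cls <- original$edges[mask$edges]
    total <- total - sum(log(predictions$edge[cbind(mask$edges, cls)]))
  }
  total / m
}

# ---- internal batched loss/gradient ----------------------------------------

# Collect masked-slot targets of a batch in batch coordinates.
batch_targets <- function(originals, masks, n) {
  P <- (n * (n - 1L)) %/% 2L
  node <- lapply(1:6, function(k) list(rows = integer(0), cls = integer(0)))
  erows <- integer(0); ecls <- integer(0)
  for (b in seq_along(originals)) {
    mk <- masks[[b]]
    if (nrow(mk$nodes) > 0) {
      for (k in 1:6) {
        sel <- mk$nodes[, 2] == k
        if (any(sel)) {
          ii <- mk$nodes[sel, 1]
          node[[k]]$rows <- c(node[[k]]$rows, (b - 1L) * n + ii)
          node[[k]]$cls <- c(node[[k]]$cls, originals[[b]]$nodes[ii, k])
        }
      }
    }
    if (length(mk$edges) > 0) {
      erows <- c(erows, (b - 1L) * P + mk$edges)
      ecls <- c(ecls, originals[[b]]$edges[mk$edges])
    }
  }
  list(node = node, edge = list(rows = erows, cls = ecls))
}

# Sum-NLL loss over masked slots plus d(loss)/d(logits); caller normalizes.
loss_and_dlogits <- function(fw, targets) {
  loss <- 0
  per_prop <- numeric(7)  # 6 node properties + edge type
  d_node <- vector("list", 6L)
  for (k in 1:6) {
    lg <- fw$node_logits[[k]]
    dk <- matrix(0, nrow(lg), ncol(lg))
    tg <- targets$node[[k]]
    if (length(tg$rows) > 0) {
      sub <- lg[tg$rows, , drop = FALSE]
      lp <- row_log_softmax(sub)
      sel <- cbind(seq_along(tg$rows), tg$cls)
      lk <- -sum(lp[sel])
      loss <- loss + lk
      per_prop[k] <- lk
      dsub <- exp(lp)
      dsub[sel] <- dsub[sel] - 1
      dk[tg$rows, ] <- dsub
    }
    d_node[[k]] <- dk
  }
  d_edge <- NULL
  lg <- fw$edge_logits
  if (nrow(lg) > 0) {
    d_edge <- matrix(0, nrow(lg), ncol(lg))
    tg <- targets$edge
    if (length(tg$rows) > 0) {
      sub <- lg[tg$rows, , drop = FALSE]
      lp <- row_log_softmax(sub)
      sel <- cbind(seq_along(tg$rows), tg$cls)
      le <- -sum(lp[sel])
      loss <- loss + le
      per_prop[7] <- le
      dsub <- exp(lp)
      dsub[sel] <- dsub[sel] - 1
      d_edge[tg$rows, ] <- dsub
    }
  }
  list(loss = loss, per_prop = per_prop, d_node = d_node, d_edge = d_edge)
}

# One micro-batch: corrupt, forward, loss, backward.  alpha is drawn per
# graph.  Returns unnormalized (sum) loss/grads plus masked-slot count.
train_microbatch <- function(params, graphs, alphas, y_std = NULL) {
  vocab <- params$vocab
  n <- graphs[[1]]$n
  masked <- lapply(seq_along(graphs), function(b)
    mask_graph(graphs[[b]], alphas[b], vocab))
  corrupted <- lapply(masked, `[[`, "graph")
  masks <- lapply(masked, `[[`, "mask")
  m_tot <- sum(vapply(masks, n_masked_slots, numeric(1)))
  if (m_tot == 0) return(list(loss = 0, m = 0, grads = NULL, per_prop = numeric(7)))
  batch <- build_batch(corrupted, vocab)
  fw <- forward_batch(params, batch, y_std = y_std, want_cache = TRUE)
  tg <- batch_targets(graphs, masks, n)
  ld <- loss_and_dlogits(fw, tg)
  grads <- backward_batch(params, batch, fw, ld$d_node, ld$d_edge)
  list(loss = ld$loss, m = m_tot, grads = grads, per_prop = ld$per_prop)
}

adam_init <- function(par) list(m = par_zeros(par), v = par_zeros(par), t = 0L)

adam_update <- function(par, grads, state, lr, b1, b2, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    gg <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * gg
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * gg^2
    par[[nm]] <- par[[nm]] - lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(par = par, state = state)
}

clip_grads <- function(grads, clip) {
  nrm <- par_global_norm(grads)
  if (is.finite(nrm) && nrm > clip) grads <- lapply(grads, function(x) x * (clip / nrm))
  grads
}

# Deterministic validation loss: fixed alpha, fixed corruption seed.  On a
# tiny validation set the fixed draw can mask zero slots (loss undefined);
# retry with the next derived seed until something is masked.
validation_loss <- function(params, dataset, alpha = 0.1, seed = 97L,
                            y_all = NULL) {
  for (attempt in 0:99) {
    out <- .validation_loss_once(params, dataset, alpha, seed + attempt, y_all)
    if (!is.null(out)) return(out)
  }
  0
}

.validation_loss_once <- function(params, dataset, alpha, seed, y_all) {
  vocab <- params$vocab
  with_seed_opt(seed, {
    tot <- 0; m <- 0
    by_n <- split(seq_along(dataset$graphs),
                  vapply(dataset$graphs, `[[`, integer(1), "n"))
    for (ix in by_n) {
      graphs <- dataset$graphs[ix]
      mb <- lapply(graphs, mask_graph, alpha = alpha, vocab = vocab)
      corrupted <- lapply(mb, `[[`, "graph")
      masks <- lapply(mb, `[[`, "mask")
      mm <- sum(vapply(masks, n_masked_slots, numeric(1)))
      if (mm == 0) next
      batch <- build_batch(corrupted, vocab)
      y_std <- if (params$config$conditional) y_all[ix] else NULL
      fw <- forward_batch(params, batch, y_std = y_std)
      tg <- batch_targets(graphs, masks, graphs[[1]]$n)
      ld <- loss_and_dlogits(fw, tg)
      tot <- tot + ld$loss; m <- m + mm
    }
    if (m == 0) NULL else tot / m
  })
}

#' Train a masked graph model
#'
#' Each step draws one masking rate per graph uniformly from the training
#' range, corrupts, computes the pooled masked cross-entropy, and applies a
#' clipped Adam update (micro-batch accumulation when configured).  After
#' every epoch the validation loss is evaluated at the fixed validation rate
#' with a fixed corruption seed; the parameters minimizing it are returned.
#'
#' For a conditional model every graph must carry its ground-truth property
#' value in `$y`; standardization statistics come from the training split
#' only and are stored in the checkpoint metadata.
#'
#' @param dataset_train,dataset_valid `mgm_dataset` objects sharing one
#'   vocabulary (`dataset_train$vocab` is used).
#' @param mcfg an `mgm_model_config`.
#' @param tcfg an `mgm_train_config`.
#' @param verbose print one line per epoch.
#' @param log_file optional path; one JSON object per epoch is appended.
#' @param warm_start optional `mgm_params` to continue training from
#'   (e.g. a lower-learning-rate fine-tuning stage); must match `mcfg`.
#' @return list with `params` (best checkpoint), `history` (data.frame of
#'   epoch losses), and `best_epoch`.
#' @export
train_model <- function(dataset_train, dataset_valid, mcfg, tcfg,
                        verbose = FALSE, log_file = NULL, warm_start = NULL) {
  if (length(dataset_train$graphs) == 0) stop("train_model: empty training set",
                                              call. = FALSE)
  vocab <- dataset_train$vocab
  if (is.null(vocab)) stop("train_model: training dataset carries no vocabulary",
                           call. = FALSE)
  params <- if (is.null(warm_start)) {
    init_params(vocab, mcfg, seed = tcfg$seed)
  } else {
    stopifnot(inherits(warm_start, "mgm_params"),
              identical(warm_start$config$d0, mcfg$d0),
              identical(warm_start$config$L, mcfg$L))
    warm_start
  }
  y_tr <- y_va <- NULL
  if (mcfg$conditional) {
    raw_tr <- vapply(dataset_train$graphs, function(g) g$y %||% NA_real_, numeric(1))
    raw_va <- vapply(dataset_valid$graphs, function(g) g$y %||% NA_real_, numeric(1))
    if (anyNA(raw_tr) || anyNA(raw_va)) {
      stop("train_model: conditional mode requires $y on every graph", call. = FALSE)
    }
    params$meta$y_mean <- mean(raw_tr)
    params$meta$y_sd <- stats::sd(raw_tr)
    y_tr <- standardize_property(raw_tr, params$meta$y_mean, params$meta$y_sd)
    y_va <- standardize_property(raw_va, params$meta$y_mean, params$meta$y_sd)
  }

  state <- adam_init(params$par)
  best <- list(loss = Inf, par = params$par, epoch = 0L)
  hist <- list()
  wait <- 0L
  with_seed_opt(tcfg$seed, {
    for (epoch in seq_len(tcfg$max_epochs)) {
      ord <- sample.int(length(dataset_train$graphs))
      sizes <- vapply(dataset_train$graphs[ord], `[[`, integer(1), "n")
      groups <- split(ord, sizes)
      ep_loss <- 0; ep_m <- 0; ep_prop <- numeric(7)
      micro_cap <- max(1L, tcfg$batch_size %/% tcfg$grad_accum)
      for (grp in groups) {
        chunks <- split(grp, ceiling(seq_along(grp) / tcfg$batch_size))
        for (chunk in chunks) {
          micro <- split(chunk, ceiling(seq_along(chunk) / micro_cap))
          acc <- NULL; acc_loss <- 0; acc_m <- 0
          for (ix in micro) {
            alphas <- stats::runif(length(ix), tcfg$mask$training_rate_range[1],
                                   tcfg$mask$training_rate_range[2])
            res <- train_microbatch(params, dataset_train$graphs[ix], alphas,
                                    y_std = if (mcfg$conditional) y_tr[ix] else NULL)
            if (res$m == 0) next
            if (!is.finite(res$loss)) {
              stop(sprintf("train_model: non-finite loss at epoch %d (|batch|=%d)",
                           epoch, length(ix)), call. = FALSE)
            }
            acc_loss <- acc_loss + res$loss; acc_m <- acc_m + res$m
            ep_prop <- ep_prop + res$per_prop
            acc <- if (is.null(acc)) res$grads
                   else Map(`+`, acc, res$grads)
          }
          if (is.null(acc) || acc_m == 0) next
          grads <- lapply(acc, function(x) x / acc_m)
          grads <- clip_grads(grads, tcfg$clip)
          upd <- adam_update(params$par, grads, state, tcfg$learning_rate,
                             tcfg$beta1, tcfg$beta2)
          params$par <- upd$par; state <- upd$state
          ep_loss <- ep_loss + acc_loss; ep_m <- ep_m + acc_m
        }
      }
      tr_loss <- if (ep_m > 0) ep_loss / ep_m else NA_real_
      va_loss <- validation_loss(params, dataset_valid,
                                 alpha = tcfg$mask$validation_rate,
                                 seed = tcfg$seed + 9973L, y_all = y_va)
      rec <- list(epoch = epoch, train_loss = tr_loss, valid_loss = va_loss,
                  per_property = ep_prop / max(ep_m, 1))
      hist[[epoch]] <- rec
      if (!is.null(log_file)) {
        cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = 8), "\n",
            file = log_file, append = TRUE)
      }
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  valid %.4f", epoch, tr_loss, va_loss))
      }
      if (is.finite(va_loss) && va_loss < best$loss - 1e-12) {
        best <- list(loss = va_loss, par = params$par, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= tcfg$patience) break
      }
    }
  })
  params$par <- best$par
  params$meta$best_epoch <- best$epoch
  params$meta$best_valid_loss <- best$loss
  history <- data.frame(
    epoch = vapply(hist, `[[`, numeric(1), "epoch"),
    train_loss = vapply(hist, `[[`, numeric(1), "train_loss"),
    valid_loss = vapply(hist, `[[`, numeric(1), "valid_loss")
  )
  list(params = params, history = history, best_epoch = best$epoch)
}
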