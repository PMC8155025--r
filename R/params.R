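# Model parameterization: embedding tables, one tied MPNN layer (GRU update +
# LayerNorm + two-layer edge MLP), six node projection heads, one edge head,
# and an optional scalar-property conditioner.  Parameters live in a flat
# named list of base-R matrices/vectors so the optimizer and the gradient
# checker can iterate them uniformly.

#' Model configuration
#'
#' @param d0 embedding width (the full-scale default in the source setting is
#'   2048; desk-scale fixtures use 64-128).
#' @param L number of MPNN layers; parameters are tied across all `L`
#'   applications (4 for QM9-scale molecules, 6 for ChEMBL-scale).
#' @param conditional whether a scalar graph-level property conditions the
#'   model.
#' @param property_name label of the conditioning property (bookkeeping only).
#' @param product how Eq. "message = h_e . h_v" combines edge and node states:
#'   `"hadamard"` (elementwise product, the default interpretation) or
#'   `"inner"` (scaled inner product reweighting the neighbor state), kept as
#'   a sensitivity switch.
#' @return an object of class `mgm_model_config`.
#' @export
model_config <- function(d0 = 2048L, L = 4L, conditional = FALSE,
                         property_name = NULL, product = c("hadamard", "inner")) {
  product <- match.arg(product)
  stopifnot(d0 >= 1, L >= 1)
  structure(list(d0 = as.integer(d0), L = as.integer(L),
                 conditional = isTRUE(conditional),
                 property_name = property_name, product = product),
            class = "mgm_model_config")
}

# fan-in scaled Gaussian init
.rmat <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nr)), nr, nc)

#' Initialize model parameters
#'
#' Weight matrices use a fan-in-scaled Gaussian; LayerNorm gains start at 1,
#' all biases at 0.  Shapes are derived from the vocabulary: each embedding
#' table has one extra MASK row, while projection heads output only real
#' categories (MASK is never a predictable outcome).
#'
#' @param vocab an `mgm_vocab`.
#' @param config an `mgm_model_config`.
#' @param seed RNG seed for the initialization draw.
#' @return an object of class `mgm_params` holding `vocab`, `config`, the
#'   flat parameter list `par`, and training metadata `meta`.
#' @export
init_params <- function(vocab, config, seed = 1L) {
  d0 <- config$d0
  with_seed_opt(seed, {
    par <- list()
    for (k in 1:6) {
      tk <- vocab_n_categories(vocab, k)
      par[[paste0("emb_node_", k)]] <- .rmat(tk + 1L, d0)
    }
    par$emb_edge <- .rmat(length(vocab$edge$categories) + 1L, d0)
    for (nm in c("gru_Wr", "gru_Wz", "gru_Wn", "gru_Ur", "gru_Uz", "gru_Un")) {
      par[[nm]] <- .rmat(d0, d0)
    }
    par$gru_br <- numeric(d0); par$gru_bz <- numeric(d0)
    par$gru_bn1 <- numeric(d0); par$gru_bn2 <- numeric(d0)
    par$ln_g <- rep(1, d0); par$ln_b <- numeric(d0)
    par$edge_E1 <- .rmat(d0, d0); par$edge_b1 <- numeric(d0)
    par$edge_E2 <- .rmat(d0, d0); par$edge_b2 <- numeric(d0)
    for (k in 1:6) {
      tk <- vocab_n_categories(vocab, k)
      par[[paste0("head_n", k, "_W1")]] <- .rmat(d0, d0)
      par[[paste0("head_n", k, "_b1")]] <- numeric(d0)
      par[[paste0("head_n", k, "_W2")]] <- .rmat(d0, tk)
      par[[paste0("head_n", k, "_b2")]] <- numeric(tk)
    }
    par$head_e_W1 <- .rmat(d0, d0); par$head_e_b1 <- numeric(d0)
    par$head_e_W2 <- .rmat(d0, length(vocab$edge$categories))
    par$head_e_b2 <- numeric(length(vocab$edge$categories))
    if (config$conditional) {
      par$cond_W1 <- .rmat(1L, d0); par$cond_b1 <- numeric(d0)
      par$cond_W2 <- .rmat(d0, d0); par$cond_b2 <- numeric(d0)
    }
    structure(list(vocab = vocab, config = config, par = par,
                   meta = list(init_seed = seed, y_mean = NULL, y_sd = NULL)),
              class = "mgm_params")
  })
}

#' @export
print.mgm_params <- function(x, ...) {
  np <- sum(vapply(x$par, length, numeric(1)))
  cat(sprintf("<mgm_params: d0=%d, L=%d, %s, %d parameters>\n",
              x$config$d0, x$config$L,
              if (x$config$conditional) paste0("conditional on ", x$config$property_name)
              else "unconditional", np))
  invisible(x)
}

# zero gradient structure matching a parameter list
par_zeros <- function(par) {
  lapply(par, function(p) if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p)))
}

par_global_norm <- function(g) sqrt(sum(vapply(g, function(x) sum(x^2), numeric(1))))

#' Standardize a scalar property value
#'
#' @param y raw property value(s).
#' @param train_mean,train_sd mean and standard deviation computed on the
#'   training split only.
#' @return standardized value `(y - mean) / sd`.
#' @export
standardize_property <- function(y, train_mean, train_sd) {
  if (!is.finite(train_sd) || train_sd <= 0) {
    stop("standardize_property: training standard deviation must be > 0", call. = FALSE)
  }
  (y - train_mean) / train_sd
}

#' Save / load a model checkpoint
#'
#' The parameter blob is an RDS file; a JSON sidecar (`<path>.json`) records
#' the model config, vocabulary and training metadata so checkpoints are
#' self-describing.
#'
#' @param params an `mgm_params`.
#' @param path checkpoint file path.
#' @export
save_checkpoint <- function(params, path) {
  saveRDS(params, path)
  side <- list(config = unclass(params$config), meta = params$meta,
               vocab = unclass(params$vocab))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  p <- readRDS(path)
  stopifnot(inherits(p, "mgm_params"))
  p
}
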