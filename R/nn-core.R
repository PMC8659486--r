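# Minimal reverse-mode autodiff over the compiled 3D kernels. Tensors are
# (C, D, H, W) arrays; a "node" wraps a value with its parents and a backward
# closure. Nodes are appended to the active tape in creation order, which is
# a topological order, so backpropagation is a single reverse sweep.
#
# In prediction the same layer functions are called with plain arrays (no
# tape, no caches), so large volumes can be segmented without holding the
# whole activation history in memory.

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL

is_node <- function(x) inherits(x, "ag_node")
nd_val <- function(x) if (is_node(x)) x$value else x

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

tape_node <- function(value, parents = list(), backfn = NULL, pname = NULL) {
  tp <- .ag$tape
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  nd$pname <- pname
  class(nd) <- "ag_node"
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[tp$n]] <- nd
  nd
}

with_tape <- function(expr) {
  old <- .ag$tape
  .ag$tape <- new_tape()
  on.exit(.ag$tape <- old)
  res <- force(expr)
  list(result = res, tape = .ag$tape)
}

# Reverse sweep from `loss`; returns the named list of parameter gradients.
tape_backward <- function(tape, loss) {
  loss$grad <- 1
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd) || is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[[j]]
      if (!is_node(p) || is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
    nd$grad <- NULL  # free as we go
  }
  grads <- list()
  for (i in seq_len(tape$n)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd) || is.null(nd$pname) || is.null(nd$grad)) next
    grads[[nd$pname]] <- if (is.null(grads[[nd$pname]])) nd$grad
                         else grads[[nd$pname]] + nd$grad
  }
  grads
}

op_input <- function(x) {
  if (is.null(.ag$tape)) x else tape_node(x)
}

op_param <- function(params, name) {
  if (is.null(.ag$tape)) params[[name]] else tape_node(params[[name]], pname = name)
}

op_conv3 <- function(x, w, b, k = 3L) {
  pad <- (k - 1L) %/% 2L
  xv <- nd_val(x); wv <- nd_val(w); bv <- nd_val(b)
  y <- nn_conv3d_fw(xv, wv, bv, k, pad)
  if (!is_node(x) && !is_node(w)) return(y)
  tape_node(y, parents = list(x, w, b), backfn = function(g) {
    r <- nn_conv3d_bw(xv, wv, g, k, pad)
    list(r$gx, r$gw, r$gb)
  })
}

op_convt3 <- function(x, w, b, k, stride = 2L, pad = 0L, opad = 0L) {
  xv <- nd_val(x); wv <- nd_val(w); bv <- nd_val(b)
  y <- nn_convt3d_fw(xv, wv, bv, k, stride, pad, opad)
  if (!is_node(x) && !is_node(w)) return(y)
  tape_node(y, parents = list(x, w, b), backfn = function(g) {
    r <- nn_convt3d_bw(xv, wv, g, k, stride, pad, opad)
    list(r$gx, r$gw, r$gb)
  })
}

op_maxpool <- function(x) {
  xv <- nd_val(x)
  r <- nn_maxpool3d_fw(xv)
  if (!is_node(x)) return(r$y)
  xdim <- dim(xv)
  tape_node(r$y, parents = list(x), backfn = function(g) {
    list(nn_maxpool3d_bw(g, r$idx, xdim))
  })
}

op_scale <- function(x, s) {
  y <- nd_val(x) * s
  if (!is_node(x)) return(y)
  tape_node(y, parents = list(x), backfn = function(g) list(g * s))
}

op_relu <- function(x) {
  xv <- nd_val(x)
  y <- xv * (xv > 0)
  if (!is_node(x)) return(y)
  tape_node(y, parents = list(x), backfn = function(g) list(g * (xv > 0)))
}

op_add <- function(a, b) {
  y <- nd_val(a) + nd_val(b)
  if (!is_node(a) && !is_node(b)) return(y)
  tape_node(y, parents = list(a, b), backfn = function(g) list(g, g))
}

concat_channels <- function(vals) {
  Cs <- vapply(vals, function(v) dim(v)[1L], 0L)
  sp <- dim(vals[[1L]])[2:4]
  out <- array(0, c(sum(Cs), sp))
  at <- 0L
  for (v in vals) {
    out[at + seq_len(dim(v)[1L]), , , ] <- v
    at <- at + dim(v)[1L]
  }
  out
}

op_concat <- function(xs) {
  vals <- lapply(xs, nd_val)
  y <- concat_channels(vals)
  if (!any(vapply(xs, is_node, TRUE))) return(y)
  Cs <- vapply(vals, function(v) dim(v)[1L], 0L)
  tape_node(y, parents = xs, backfn = function(g) {
    out <- vector("list", length(Cs))
    at <- 0L
    for (j in seq_along(Cs)) {
      out[[j]] <- g[at + seq_len(Cs[j]), , , , drop = FALSE]
      at <- at + Cs[j]
    }
    out
  })
}

row_stat <- function(v, C, fn) fn(matrix(v, nrow = C))

# Channel normalisation with learned scale/shift: statistics are computed per
# input volume over its spatial extent (exact batch normalisation at batch
# size one; mini-batches use gradient accumulation).
op_chnorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- nd_val(x); gv <- nd_val(gamma); bv <- nd_val(beta)
  C <- dim(xv)[1L]
  mu <- row_stat(xv, C, rowMeans)
  va <- row_stat((xv - mu)^2, C, rowMeans)
  istd <- 1 / sqrt(va + eps)
  xhat <- (xv - mu) * istd
  y <- xhat * gv + bv
  if (!is_node(x) && !is_node(gamma)) return(y)
  tape_node(y, parents = list(x, gamma, beta), backfn = function(g) {
    dxhat <- g * gv
    m1 <- row_stat(dxhat, C, rowMeans)
    m2 <- row_stat(dxhat * xhat, C, rowMeans)
    dx <- istd * (dxhat - m1 - xhat * m2)
    dgamma <- row_stat(g * xhat, C, rowSums)
    dbeta <- row_stat(g, C, rowSums)
    list(dx, dgamma, dbeta)
  })
}

op_dropout <- function(x, rate, training) {
  if (!training || rate <= 0) return(x)
  xv <- nd_val(x)
  mask <- (runif(length(xv)) >= rate) / (1 - rate)
  y <- array(xv * mask, dim(xv))
  if (!is_node(x)) return(y)
  tape_node(y, parents = list(x), backfn = function(g) list(g * mask))
}

softmax_channels <- function(z) {
  C <- dim(z)[1L]
  zm <- matrix(z, nrow = C)
  mx <- do.call(pmax, c(asplit(zm, 1), list(na.rm = FALSE)))
  e <- exp(zm - rep(mx, each = C))
  s <- .colSums(e, C, ncol(e))
  array(e / rep(s, each = C), dim(z))
}

op_softmax <- function(x) {
  xv <- nd_val(x)
  p <- softmax_channels(xv)
  if (!is_node(x)) return(p)
  C <- dim(xv)[1L]
  tape_node(p, parents = list(x), backfn = function(g) {
    pg <- p * g
    s <- .colSums(matrix(pg, nrow = C), C, length(pg) / C)
    list(p * (g - rep(s, each = C)))
  })
}

wce_eps <- 1e-7

# Core of the weighted cross-entropy: p, onehot and w4 are (C,D,H,W) arrays,
# N the number of voxels in the volume.
wce_value <- function(p, onehot, w4, N) {
  pc <- pmin(pmax(p, wce_eps), 1 - wce_eps)
  -sum(w4 * (onehot * log(pc) + (1 - onehot) * log(1 - pc))) / N
}

op_wce <- function(p, onehot, w4, N) {
  pv <- nd_val(p)
  val <- wce_value(pv, onehot, w4, N)
  if (!is_node(p)) return(val)
  tape_node(val, parents = list(p), backfn = function(g) {
    pc <- pmin(pmax(pv, wce_eps), 1 - wce_eps)
    list(g * (-(w4 / N) * (onehot / pc - (1 - onehot) / (1 - pc))))
  })
}

onehot_channels <- function(labels, n_classes) {
  d <- dim(labels)
  oh <- array(0, c(n_classes, d))
  lv <- as.integer(labels)
  idx <- seq_along(lv)
  oh[lv + 1L + (idx - 1L) * n_classes] <- 1
  oh
}

#' Weighted cross-entropy loss
#'
#' The loss driving both networks:
#' `-(1/N) * sum_i w_i * [ y_i log p_i + (1 - y_i) log(1 - p_i) ]`, summed
#' over voxels and output channels, where `N` is the number of voxels in the
#' volume, `p_i` the predicted per-channel probability, `y_i` the one-hot
#' ground truth and `w_i` a per-voxel weight determined by the voxel's true
#' class. The weights compensate for class imbalance between background and
#' the (much smaller) kidney classes. Probabilities are clamped at 1e-7
#' before the logarithm.
#'
#' @param pred_probs `(C, D, H, W)` array of per-voxel class probabilities.
#' @param truth_labels 3D integer label array over `0..C-1`.
#' @param class_weights numeric vector of length `C`; `class_weights[k + 1]`
#'   multiplies every term of a voxel whose true class is `k`. See
#'   [class_weights_from_priors()].
#' @return Scalar loss (non-negative; 0 only in the perfect-prediction
#'   limit).
#' @export
weighted_cross_entropy <- function(pred_probs, truth_labels, class_weights) {
  C <- dim(pred_probs)[1L]
  if (length(class_weights) != C)
    stop("need one weight per class", call. = FALSE)
  oh <- onehot_channels(truth_labels, C)
  wv <- class_weights[as.integer(truth_labels) + 1L]
  w4 <- array(rep(wv, each = C), dim(pred_probs))
  wce_value(pred_probs, oh, w4, length(truth_labels))
}

#' Class weights inversely proportional to foreground priors
#'
#' Computes `w_k = prior(background) / prior(k)` from the voxel label counts
#' of a dataset, so the background weight is exactly 1 and rarer foreground
#' classes weigh proportionally more. Absent classes fall back to weight 1.
#'
#' @param labels_list list of 3D integer label arrays (class 0 = background).
#' @param n_classes number of classes.
#' @export
class_weights_from_priors <- function(labels_list, n_classes) {
  counts <- numeric(n_classes)
  for (l in labels_list) {
    tb <- tabulate(as.integer(l) + 1L, nbins = n_classes)
    counts <- counts + tb
  }
  pri <- counts / sum(counts)
  w <- ifelse(pri > 0, pri[1L] / pri, 1)
  w[1L] <- 1
  w
}

he_init <- function(K, Cout) {
  matrix(rnorm(K * Cout, sd = sqrt(2 / K)), K, Cout)
}

# --- shared parameter helpers -----------------------------------------------

conv_par <- function(params, name, Cin, Cout, k) {
  params[[paste0(name, ".w")]] <- he_init(Cin * k^3, Cout)
  params[[paste0(name, ".b")]] <- numeric(Cout)
  params
}

convt_par <- function(params, name, Cin, Cout, k) {
  params[[paste0(name, ".w")]] <- matrix(rnorm(Cin * Cout * k^3,
                                               sd = sqrt(2 / (Cin * k^3))),
                                         Cin, Cout * k^3)
  params[[paste0(name, ".b")]] <- numeric(Cout)
  params
}

norm_par <- function(params, name, C) {
  params[[paste0(name, ".g")]] <- rep(1, C)
  params[[paste0(name, ".be")]] <- numeric(C)
  params
}

# layer wrappers used by the network builders; pm(name) resolves a parameter
# to a node (training) or array (prediction)
ly_conv3 <- function(pm, name, x, k = 3L) op_conv3(x, pm(paste0(name, ".w")), pm(paste0(name, ".b")), k)
ly_convt <- function(pm, name, x, k, stride, pad, opad)
  op_convt3(x, pm(paste0(name, ".w")), pm(paste0(name, ".b")), k, stride, pad, opad)
ly_norm <- function(pm, name, x) op_chnorm(x, pm(paste0(name, ".g")), pm(paste0(name, ".be")))

#' @export
print.rs_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf("<rs_model:%s> %d classes, %s parameters\n",
              x$type, x$config$n_classes, format(np, big.mark = ",")))
  invisible(x)
}

#' Forward pass of a trained model
#'
#' Runs the network in prediction mode (no dropout, no gradient caches) on a
#' single `(channels, D, H, W)` input and returns per-voxel class
#' probabilities `(n_classes, D, H, W)`.
#'
#' @param model an `rs_model` from [build_rb_unet()] or
#'   [build_fc_densenet()].
#' @param x input array `(in_channels, D, H, W)`.
#' @export
net_forward <- function(model, x) {
  pm <- function(name) model$params[[name]]
  model$forward(pm, x, training = FALSE)
}

model_forward_train <- function(model, x, training = TRUE) {
  # assumes an active tape
  pm <- function(name) op_param(model$params, name)
  model$forward(pm, op_input(x), training = training)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Optimiser settings for network training
#'
#' Defaults follow the training protocol the pipeline was designed with:
#' Adam, initial learning rate 1e-4 halved every 50 epochs, weight decay
#' 1e-8, mini-batch 4, up to 400 epochs. Scale `epochs` (and phantom sizes)
#' down for desk-scale runs.
#' @keywords internal
optimizer_config <- function(lr = 1e-4, epochs = 400, batch_size = 4,
                             lr_drop_every = 50, lr_drop_factor = 0.5,
                             weight_decay = 1e-8, seed = 1L, verbose = FALSE) {
  list(lr = lr, epochs = epochs, batch_size = batch_size,
       lr_drop_every = lr_drop_every, lr_drop_factor = lr_drop_factor,
       weight_decay = weight_decay, seed = seed, verbose = verbose)
}

# Shared training loop: weighted cross-entropy on softmax outputs, Adam with
# a step learning-rate schedule, gradient accumulation over the mini-batch.
# Fully deterministic given `opt$seed`.
train_net <- function(model, dataset, opt) {
  if (length(dataset) == 0L) stop("empty training dataset", call. = FALSE)
  opt <- modifyList(optimizer_config(), opt)
  set.seed(opt$seed)
  n_classes <- model$config$n_classes
  cw <- class_weights_from_priors(lapply(dataset, `[[`, "y"), n_classes)
  state <- adam_init(model$params)
  history <- data.frame(epoch = integer(), loss = numeric(), lr = numeric())
  batches <- split(seq_along(dataset),
                   ceiling(seq_along(dataset) / opt$batch_size))
  for (epoch in seq_len(opt$epochs)) {
    lr_t <- opt$lr * opt$lr_drop_factor^((epoch - 1) %/% opt$lr_drop_every)
    losses <- numeric(0)
    for (bi in batches) {
      acc <- list()
      for (si in bi) {
        smp <- dataset[[si]]
        oh <- onehot_channels(smp$y, n_classes)
        wv <- cw[as.integer(smp$y) + 1L]
        run <- with_tape({
          probs <- model_forward_train(model, smp$x, training = TRUE)
          w4 <- array(rep(wv, each = n_classes), dim(nd_val(probs)))
          op_wce(probs, oh, w4, length(smp$y))
        })
        losses <- c(losses, nd_val(run$result))
        grads <- tape_backward(run$tape, run$result)
        for (nm in names(grads)) {
          acc[[nm]] <- if (is.null(acc[[nm]])) grads[[nm]] else acc[[nm]] + grads[[nm]]
        }
      }
      acc <- lapply(acc, function(g) g / length(bi))
      upd <- adam_step(model$params, acc, state, lr_t,
                       weight_decay = opt$weight_decay)
      model$params <- upd$params
      state <- upd$state
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, loss = mean(losses), lr = lr_t))
    if (isTRUE(opt$verbose))
      message(sprintf("epoch %d  loss %.5f  lr %.2g", epoch, mean(losses), lr_t))
  }
  model$history <- history
  model
}

#' Save / load a trained model checkpoint
#'
#' @param model an `rs_model`.
#' @param path checkpoint file (RDS).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
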