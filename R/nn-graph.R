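# A minimal directed-acyclic-graph network executor.
#
# A network is an ordered list of nodes; each node holds an op (a list
# with a $type and any parameter arrays) and the indices of its input
# nodes.  Forward evaluation walks the list in order caching what the
# backward pass needs; the backward pass walks it in reverse, summing
# gradients at fan-out points.  This is enough autograd for the
# encoder-decoder architectures in this package while keeping every
# numerical step explicit.

net_builder <- function() {
  nb <- new.env(parent = emptyenv())
  nb$nodes <- list()
  nb
}

nb_add <- function(nb, op, inputs = integer(0)) {
  nb$nodes[[length(nb$nodes) + 1L]] <- list(op = op,
                                            inputs = as.integer(inputs))
  length(nb$nodes)
}

nb_finish <- function(nb, input, output, stages = NULL) {
  structure(list(nodes = nb$nodes, input = as.integer(input),
                 output = as.integer(output), stages = stages),
            class = "sonnseg_net")
}

# ---- op constructors -------------------------------------------------------

op_input <- function() list(type = "input")

op_conv <- function(in_channels, out_channels, k, stride = 1L,
                    pad = (k - 1L) %/% 2L, bias = TRUE) {
  fan_in <- in_channels * k * k
  a <- sqrt(6 / fan_in)
  W <- matrix(stats::runif(fan_in * out_channels, -a, a),
              nrow = fan_in, ncol = out_channels)
  b <- if (bias) numeric(out_channels) else NULL
  list(type = "conv", W = W, b = b, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad))
}

op_selfonn <- function(in_channels, out_channels, k, q, stride = 1L,
                       pad = (k - 1L) %/% 2L, bias = TRUE) {
  spec <- selfonn_layer_spec(in_channels, out_channels, kernel_size = k,
                             q = q, stride = stride, padding = pad,
                             has_bias = bias)
  coef <- taylor_coefficients(spec)
  list(type = "selfonn", spec = spec,
       W = taylor_weight_matrix(coef, spec),
       b = coef$bias)
}

op_bn <- function(channels) {
  running <- new.env(parent = emptyenv())
  running$mean <- numeric(channels)
  running$var <- rep(1, channels)
  list(type = "bn", gamma = rep(1, channels), beta = numeric(channels),
       running = running)
}

op_relu <- function() list(type = "relu")
op_tanh <- function() list(type = "tanh")
op_identity <- function() list(type = "identity")
op_maxpool <- function(k = 2L, stride = k, pad = 0L)
  list(type = "maxpool", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad))
op_avgpool2 <- function() list(type = "avgpool2")
op_upsample <- function(factor = 2L)
  list(type = "upsample", factor = as.integer(factor))
op_concat <- function() list(type = "concat")
op_add <- function() list(type = "add")
op_softmax2 <- function() list(type = "softmax2")

op_activation <- function(name) {
  switch(name,
         relu = op_relu(),
         tanh = op_tanh(),
         identity = op_identity(),
         stop("unknown activation ", name, call. = FALSE))
}

# ---- forward / backward ----------------------------------------------------

net_forward <- function(net, x, training = FALSE, keep_cache = FALSE,
                        outputs = NULL) {
  n <- length(net$nodes)
  vals <- vector("list", n)
  caches <- if (keep_cache) vector("list", n) else NULL
  for (i in seq_len(n)) {
    nd <- net$nodes[[i]]
    op <- nd$op
    ins <- lapply(nd$inputs, function(j) vals[[j]])
    r <- switch(op$type,
      input = list(out = as_nchw(x), cache = NULL),
      conv = conv2d_forward(ins[[1L]], op$W, op$b, op$k, op$stride, op$pad),
      selfonn = selfonn_forward_train(ins[[1L]], op$spec, op$W, op$b),
      bn = {
        bf <- batchnorm_forward(ins[[1L]], op$gamma, op$beta,
                                as.list(op$running), training)
        if (training) {
          op$running$mean <- bf$running$mean
          op$running$var <- bf$running$var
        }
        bf
      },
      relu = {
        y <- pmax(ins[[1L]], 0)
        list(out = y, cache = ins[[1L]] > 0)
      },
      tanh = {
        y <- tanh(ins[[1L]])
        list(out = y, cache = y)
      },
      identity = list(out = ins[[1L]], cache = NULL),
      maxpool = maxpool_forward(ins[[1L]], op$k, op$stride, op$pad),
      avgpool2 = avgpool2_forward(ins[[1L]]),
      upsample = upsample_forward(ins[[1L]], op$factor),
      concat = {
        dims <- lapply(ins, dim)
        cs <- vapply(dims, `[`, integer(1), 1L)
        d1 <- dims[[1L]]
        out <- array(0, dim = c(sum(cs), d1[2L], d1[3L], d1[4L]))
        at <- 0L
        for (z in seq_along(ins)) {
          out[at + seq_len(cs[z]), , , ] <- ins[[z]]
          at <- at + cs[z]
        }
        list(out = out, cache = cs)
      },
      add = {
        out <- ins[[1L]]
        if (length(ins) > 1L) for (z in 2:length(ins)) out <- out + ins[[z]]
        list(out = out, cache = NULL)
      },
      softmax2 = softmax2_forward(ins[[1L]]),
      stop("unknown op type ", op$type, call. = FALSE)
    )
    vals[[i]] <- r$out
    if (keep_cache) caches[i] <- list(r$cache)
  }
  if (!is.null(outputs)) {
    return(list(out = lapply(outputs, function(j) vals[[j]]), vals = vals,
                caches = caches))
  }
  list(out = vals[[net$output]], vals = vals, caches = caches)
}

# Backward from a gradient at the output node.  Returns the named list of
# parameter gradients ("<node>.W", "<node>.b", "<node>.gamma", ...) and the
# gradient at the input node.
net_backward <- function(net, fw, dOut, from = net$output) {
  n <- length(net$nodes)
  dvals <- vector("list", n)
  dvals[[from]] <- dOut
  grads <- list()
  acc <- function(cur, add) if (is.null(cur)) add else cur + add
  for (i in seq(n, 1L)) {
    dY <- dvals[[i]]
    if (is.null(dY)) next
    nd <- net$nodes[[i]]
    op <- nd$op
    cache <- fw$caches[[i]]
    switch(op$type,
      input = NULL,
      conv = {
        cb <- conv2d_backward(dY, op$W, cache, has_bias = !is.null(op$b))
        grads[[paste0(i, ".W")]] <- cb$dW
        if (!is.null(op$b)) grads[[paste0(i, ".b")]] <- cb$db
        dvals[[nd$inputs]] <- acc(dvals[[nd$inputs]], cb$dx)
      },
      selfonn = {
        sb <- selfonn_backward_train(dY, op$spec, op$W, cache)
        grads[[paste0(i, ".W")]] <- sb$dW
        if (!is.null(op$b)) grads[[paste0(i, ".b")]] <- sb$db
        dvals[[nd$inputs]] <- acc(dvals[[nd$inputs]], sb$dx)
      },
      bn = {
        bb <- batchnorm_backward(dY, cache)
        grads[[paste0(i, ".gamma")]] <- bb$dgamma
        grads[[paste0(i, ".beta")]] <- bb$dbeta
        dvals[[nd$inputs]] <- acc(dvals[[nd$inputs]], bb$dx)
      },
      relu = dvals[[nd$inputs]] <- acc(dvals[[nd$inputs]], dY * cache),
      tanh = dvals[[nd$inputs]] <- acc(dvals[[nd$inputs]],
                                       dY * (1 - cache^2)),
      identity = dvals[[nd$inputs]] <- acc(dvals[[nd$inputs]], dY),
      maxpool = dvals[[nd$inputs]] <- acc(dvals[[nd$inputs]],
                                          maxpool_backward(dY, cache)),
      avgpool2 = dvals[[nd$inputs]] <- acc(dvals[[nd$inputs]],
                                           avgpool2_backward(dY, cache)),
      upsample = dvals[[nd$inputs]] <- acc(dvals[[nd$inputs]],
                                           upsample_backward(dY, cache)),
      concat = {
        at <- 0L
        for (z in seq_along(nd$inputs)) {
          j <- nd$inputs[z]
          dpart <- dY[at + seq_len(cache[z]), , , , drop = FALSE]
          dvals[[j]] <- acc(dvals[[j]], dpart)
          at <- at + cache[z]
        }
      },
      add = {
        for (j in nd$inputs) dvals[[j]] <- acc(dvals[[j]], dY)
      },
      softmax2 = dvals[[nd$inputs]] <- acc(dvals[[nd$inputs]],
                                           softmax2_backward(dY, cache)),
      stop("unknown op type ", op$type, call. = FALSE)
    )
    if (i != from) dvals[i] <- list(NULL)   # free memory, keep list length
  }
  list(grads = grads, dx = dvals[[net$input]])
}

# ---- parameter plumbing ----------------------------------------------------

net_params <- function(net) {
  out <- list()
  for (i in seq_along(net$nodes)) {
    op <- net$nodes[[i]]$op
    if (op$type %in% c("conv", "selfonn")) {
      out[[paste0(i, ".W")]] <- op$W
      if (!is.null(op$b)) out[[paste0(i, ".b")]] <- op$b
    } else if (op$type == "bn") {
      out[[paste0(i, ".gamma")]] <- op$gamma
      out[[paste0(i, ".beta")]] <- op$beta
    }
  }
  out
}

net_set_params <- function(net, params) {
  for (nm in names(params)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    i <- as.integer(parts[1L])
    field <- parts[2L]
    old <- net$nodes[[i]]$op[[field]]
    new <- params[[nm]]
    if (!is.null(dim(old))) dim(new) <- dim(old)
    net$nodes[[i]]$op[[field]] <- new
  }
  net
}

#' Count trainable parameters
#'
#' Sums the lengths of every trainable array (convolution and Self-ONN
#' kernels and biases, batch-normalisation scales and shifts) in a network
#' or assembled segmentation model.  Batch-norm running statistics are not
#' trainable and are not counted.
#'
#' @param network A network or model object from [build_encoder()],
#'   [build_decoder()] or [build_model()].
#' @return Non-negative integer count of trainable scalars.
#' @export
count_parameters <- function(network) {
  UseMethod("count_parameters")
}

#' @export
count_parameters.sonnseg_net <- function(network) {
  sum(vapply(net_params(network), length, numeric(1)))
}

#' @export
count_parameters.sonnseg_model <- function(network) {
  count_parameters(network$net)
}

#' @export
count_parameters.sonnseg_encoder <- function(network) {
  count_parameters(network$net)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, betas = c(0.9, 0.999),
                      eps = 1e-8) {
  state$t <- state$t + 1L
  b1 <- betas[1L]; b2 <- betas[2L]
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
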