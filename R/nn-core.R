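# Small neural-network kernel: seeded Glorot initialization and the two
# optimizers used by the training and feedback modules (Adam, SGD+momentum).
# Parameters live in a flat named list of numeric arrays; gradients mirror
# that structure, so optimizers are generic over parameter names.

.glorot <- function(nin, nout) {
  limit <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -limit, limit), nin, nout)
}

.zeros_like <- function(params) {
  lapply(params, function(p) {
    if (is.null(dim(p))) numeric(length(p)) else array(0, dim = dim(p))
  })
}

#' Create an Adam optimizer state
#' @param params named list of parameter arrays.
#' @param lr learning rate.
#' @param weight_decay L2 coefficient added to gradients.
#' @param beta1,beta2,eps Adam moment coefficients.
#' @return optimizer state list.
#' @keywords internal
adam_init <- function(params, lr = 1e-4, weight_decay = 1e-8,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(kind = "adam", lr = lr, wd = weight_decay, b1 = beta1, b2 = beta2,
       eps = eps, t = 0L, m = .zeros_like(params), v = .zeros_like(params))
}

#' Create an SGD-with-momentum optimizer state
#' @inheritParams adam_init
#' @param momentum momentum coefficient.
#' @keywords internal
sgd_init <- function(params, lr = 1e-4, momentum = 0.9, weight_decay = 1e-8) {
  list(kind = "sgd", lr = lr, mom = momentum, wd = weight_decay,
       buf = .zeros_like(params))
}

#' Apply one optimizer step
#' @param opt optimizer state from [adam_init()] or [sgd_init()].
#' @param params named list of parameters.
#' @param grads named list of gradients (same shapes).
#' @return list(params, opt) with updated values.
#' @keywords internal
optimizer_step <- function(opt, params, grads) {
  if (opt$kind == "adam") {
    opt$t <- opt$t + 1L
    bc1 <- 1 - opt$b1^opt$t
    bc2 <- 1 - opt$b2^opt$t
    for (nm in names(params)) {
      g <- grads[[nm]] + opt$wd * params[[nm]]
      opt$m[[nm]] <- opt$b1 * opt$m[[nm]] + (1 - opt$b1) * g
      opt$v[[nm]] <- opt$b2 * opt$v[[nm]] + (1 - opt$b2) * g * g
      mhat <- opt$m[[nm]] / bc1
      vhat <- opt$v[[nm]] / bc2
      params[[nm]] <- params[[nm]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
    }
  } else {
    for (nm in names(params)) {
      g <- grads[[nm]] + opt$wd * params[[nm]]
      opt$buf[[nm]] <- opt$mom * opt$buf[[nm]] + g
      params[[nm]] <- params[[nm]] - opt$lr * opt$buf[[nm]]
    }
  }
  list(params = params, opt = opt)
}

# elementwise accumulate b into a (same names/shapes); missing entries kept
.acc_grads <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}
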