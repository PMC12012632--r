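## Internal dense multilayer perceptron with manual backprop, plus the Adam
## optimizer shared by the autoencoder, transformer and LSTM training loops.

mlp_init <- function(widths, acts) {
  # widths: layer sizes incl. input/output; acts: activation per weight layer
  stopifnot(length(acts) == length(widths) - 1L)
  layers <- vector("list", length(acts))
  for (l in seq_along(acts)) {
    fan_in <- widths[l]
    layers[[l]] <- list(
      W = matrix(rnorm(fan_in * widths[l + 1], sd = sqrt(1 / fan_in)),
                 fan_in, widths[l + 1]),
      b = rep(0, widths[l + 1]), act = acts[l])
  }
  layers
}

.act_fwd <- function(z, act) switch(act, tanh = tanh(z), linear = z)
.act_grad <- function(a, z, act) switch(act, tanh = 1 - a^2, linear = 1)

mlp_forward <- function(layers, X) {
  caches <- vector("list", length(layers))
  A <- X
  for (l in seq_along(layers)) {
    Z <- sweep(A %*% layers[[l]]$W, 2, layers[[l]]$b, "+")
    caches[[l]] <- list(A_in = A, Z = Z)
    A <- .act_fwd(Z, layers[[l]]$act)
    caches[[l]]$A_out <- A
  }
  list(out = A, caches = caches)
}

# dOut: gradient of the loss wrt the network output
mlp_backward <- function(layers, caches, dOut) {
  grads <- vector("list", length(layers))
  dA <- dOut
  for (l in rev(seq_along(layers))) {
    cc <- caches[[l]]
    dZ <- dA * .act_grad(cc$A_out, cc$Z, layers[[l]]$act)
    grads[[l]] <- list(W = crossprod(cc$A_in, dZ), b = colSums(dZ))
    dA <- tcrossprod(dZ, layers[[l]]$W)
  }
  grads
}

## ---- Adam over an arbitrary named list of numeric arrays ----

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = NULL) {
  state$t <- state$t + 1L
  if (!is.null(clip)) {
    gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
    if (is.finite(gn) && gn > clip) grads <- lapply(grads, function(g) g * (clip / gn))
  }
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# flatten nested (layer, W/b) structures into a named flat list and back
flatten_layers <- function(layers, prefix = "l") {
  out <- list()
  for (l in seq_along(layers)) {
    out[[sprintf("%s%d_W", prefix, l)]] <- layers[[l]]$W
    out[[sprintf("%s%d_b", prefix, l)]] <- layers[[l]]$b
  }
  out
}

unflatten_layers <- function(flat, layers, prefix = "l") {
  for (l in seq_along(layers)) {
    layers[[l]]$W <- flat[[sprintf("%s%d_W", prefix, l)]]
    layers[[l]]$b <- flat[[sprintf("%s%d_b", prefix, l)]]
  }
  layers
}
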