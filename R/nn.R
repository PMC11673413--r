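# Minimal neural-network layer toolkit. Every layer has an explicit forward
# (returning output plus a cache) and backward (consuming the cache); the
# training loop wires them together by hand. Feature maps are [H, W, C]
# arrays, batch size is always 1. Compiled kernels do the heavy lifting.

he_conv <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

he_linear <- function(n_in, n_out) {
  matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
}

conv_fw <- function(x, w, b) {
  pad <- (dim(w)[1] - 1L) %/% 2L
  list(y = conv2d_fw(x, w, b, pad), x = x, w = w, pad = pad)
}

conv_bw <- function(cache, gy) {
  conv2d_bw(cache$x, cache$w, gy, cache$pad)
}

relu_fw <- function(x) list(y = pmax(x, 0), mask = x > 0)
relu_bw <- function(cache, gy) gy * cache$mask

linear_fw <- function(x, w, b) {
  list(y = x %*% w + matrix(b, nrow(x), length(b), byrow = TRUE),
       x = x, w = w)
}

linear_bw <- function(cache, gy) {
  list(gx = gy %*% t(cache$w), gw = crossprod(cache$x, gy), gb = colSums(gy))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# elementwise smooth L1 (Huber with beta = 1) and its derivative
smooth_l1 <- function(x) ifelse(abs(x) < 1, 0.5 * x^2, abs(x) - 0.5)
smooth_l1_grad <- function(x) ifelse(abs(x) < 1, x, sign(x))

# SGD with classical momentum and L2 weight decay; `opt` is an environment
# holding one velocity buffer per parameter.
sgd_init <- function(params) {
  opt <- new.env(parent = emptyenv())
  for (nm in names(params)) assign(nm, params[[nm]] * 0, envir = opt)
  opt
}

sgd_step <- function(params, grads, opt, lr, momentum, weight_decay) {
  for (nm in names(grads)) {
    g <- grads[[nm]] + weight_decay * params[[nm]]
    v <- momentum * get(nm, envir = opt) - lr * g
    assign(nm, v, envir = opt)
    params[[nm]] <- params[[nm]] + v
  }
  params
}

# rescale all gradients so the global L2 norm does not exceed max_norm
clip_grad_norm <- function(grads, max_norm) {
  if (is.null(max_norm) || !is.finite(max_norm)) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (total > max_norm)
    grads <- lapply(grads, function(g) g * (max_norm / total))
  grads
}

# gradient accumulator
grad_env <- function() new.env(parent = emptyenv())
grad_add <- function(ge, nm, g) {
  if (is.null(ge[[nm]])) ge[[nm]] <- g else ge[[nm]] <- ge[[nm]] + g
  invisible(NULL)
}
grad_list <- function(ge) as.list(ge)

zeros_like_map <- function(fmap) array(0, dim(fmap))

# deterministic row argmax, ties toward the lower index
row_argmax <- function(m) max.col(m, ties.method = "first")
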