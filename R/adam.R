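# Adam optimizer over arbitrarily nested parameter lists (beta1 = 0.9,
# beta2 = 0.999, eps = 1e-8). Parameter and gradient lists must share
# their structure; numeric leaves are updated in place.

adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like)
    else if (is.numeric(p)) p * 0
    else p
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  step <- function(p, g, m, v) {
    if (is.list(p)) {
      keys <- if (is.null(names(g))) seq_along(g) else names(g)
      for (nm in keys) {
        if (is.null(p[[nm]]) || is.null(g[[nm]])) next
        r <- step(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
      list(p = p, m = m, v = v)
    } else if (is.numeric(p) && !is.null(g)) {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
      list(p = p, m = m, v = v)
    } else list(p = p, m = m, v = v)
  }
  r <- step(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}
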