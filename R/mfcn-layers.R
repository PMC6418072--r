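# Layer primitives for the MFCN. All activations are numeric arrays in
# [H, W, C, N] layout. Convolutions run through the compiled im2col/GEMM
# kernels; batch-norm, the rectifier and softmax are thin array code here.

conv_init <- function(k, cin, cout) {
  # He initialisation, fan-in = k^2 * cin.
  w <- array(rnorm(k * k * cin * cout) * sqrt(2 / (k * k * cin)),
             dim = c(k, k, cin, cout))
  list(w = w, b = numeric(cout))
}

tconv_init <- function(cin, cout) {
  w <- array(rnorm(4 * cin * cout) * sqrt(2 / (4 * cin)),
             dim = c(2, 2, cin, cout))
  list(w = w, b = numeric(cout))
}

bn_init <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c))
}

# Batch normalisation and the fused rectifier live in compiled code
# (.bn_stats / .bn_act_fwd / .bn_act_bwd / .bn_eval_bwd): per-channel
# reductions over [H, W, C, N] arrays dominate the step time if done with
# R-level temporaries.

relu_fwd <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}

relu_bwd <- function(dy, x) {
  dy * (x > 0)
}

# Channel-wise softmax for the 2-class score map.
softmax2 <- function(x) {
  m <- pmax(x[, , 1, , drop = FALSE], x[, , 2, , drop = FALSE])
  e1 <- exp(x[, , 1, , drop = FALSE] - m)
  e2 <- exp(x[, , 2, , drop = FALSE] - m)
  s <- e1 + e2
  y <- x
  y[, , 1, ] <- e1 / s
  y[, , 2, ] <- e2 / s
  y
}
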