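## Minimal neural-network primitives: dense and 1-D convolutional layers with
## manual backpropagation and an Adam optimizer, all on base matrix algebra.
## Row convention for convolutional activations: "sample-major" 2-D matrices
## of shape (B*L, C) where row (b-1)*L + l holds sample b, timestep l.

nn_relu <- function(z) { z[z < 0] <- 0; z }
nn_relu_bwd <- function(dy, z) { dy[z <= 0] <- 0; dy }
nn_sigmoid <- function(z) 1 / (1 + exp(-z))

## He-normal initialisation.
nn_init <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out)
}

nn_dense_fwd <- function(x, W, b) sweep(x %*% W, 2, b, "+")

## Returns gradients and the input gradient.
nn_dense_bwd <- function(dy, x, W) {
  list(dW = crossprod(x, dy), db = colSums(dy), dx = tcrossprod(dy, W))
}

## Zero-padded ("same") im2col over sample-major rows. Returns (B*L, k*C).
nn_im2col <- function(x2, B, L, k) im2col_cpp(x2, B, L, k)

## Scatter the im2col gradient back onto the input rows.
nn_col2im <- function(dM, B, L, k, C) col2im_cpp(dM, B, L, k, C)

nn_conv_fwd <- function(x2, B, L, W, b, k) {
  M <- nn_im2col(x2, B, L, k)
  list(z = sweep(M %*% W, 2, b, "+"), M = M)
}

nn_conv_bwd <- function(dz, cache_M, B, L, k, C_in, W) {
  dW <- crossprod(cache_M, dz)
  db <- colSums(dz)
  dM <- tcrossprod(dz, W)
  list(dW = dW, db = db, dx = nn_col2im(dM, B, L, k, C_in))
}

## Reshape sample-major (B*L, F) activations to per-sample flat (B, L*F).
nn_flatten <- function(h, B, L) flatten_cpp(h, B, L)

nn_unflatten <- function(hf, B, L) unflatten_cpp(hf, B, L)

## Adam optimizer over a named list of parameter matrices.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

## One fused Adam step. Updates the parameter and moment buffers in place
## (the training loops own them exclusively) and returns the new state.
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    adam_update_inplace(params[[nm]], grads[[nm]],
                        state$m[[nm]], state$v[[nm]],
                        lr, beta1, beta2, eps, bc1, bc2)
  }
  state
}
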