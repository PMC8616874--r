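# A small volumetric encoder-decoder ("3D U-Net") with one pooling level,
# written directly over the conv/pool kernels in src/. This is deliberately
# tiny: the package's scaled-down training runs use networks in the
# 10^4-10^5 parameter range, trained on CPU in minutes. Activations travel
# as (channels x voxels) matrices in R's column-major voxel order.

relu_ <- function(m) { m[m < 0] <- 0; m }

#' Initialise a tiny 3D U-Net
#'
#' Topology: two 3x3x3 conv+ReLU blocks, 2x max-pool, two conv+ReLU blocks at
#' double width, nearest x2 upsampling, skip concatenation, two conv+ReLU
#' blocks, and a 1x1x1 linear head. He-normal initialisation, deterministic
#' given `seed`. Input grids must have even dimensions.
#'
#' @param in_ch,out_ch Input / output channel counts.
#' @param width Base feature-map count (doubled at the coarse level).
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `unet3d`.
#' @export
unet3d_init <- function(in_ch, out_ch, width = 8, seed = 1) {
  he <- function(o, fanin) matrix(stats::rnorm(o * fanin, 0, sqrt(2 / fanin)), o, fanin)
  fw <- width
  p <- with_seed(seed, list(
    W1a = he(fw, 27 * in_ch),      b1a = numeric(fw),
    W1b = he(fw, 27 * fw),         b1b = numeric(fw),
    W2a = he(2 * fw, 27 * fw),     b2a = numeric(2 * fw),
    W2b = he(2 * fw, 27 * 2 * fw), b2b = numeric(2 * fw),
    W3a = he(fw, 27 * 3 * fw),     b3a = numeric(fw),
    W3b = he(fw, 27 * fw),         b3b = numeric(fw),
    Wh  = he(out_ch, fw) * 0.1,    bh  = numeric(out_ch)))
  structure(list(params = p, in_ch = in_ch, out_ch = out_ch, width = fw),
            class = "unet3d")
}

#' Number of trainable parameters of a `unet3d`
#' @param net A `unet3d`.
#' @return Integer parameter count.
#' @export
unet3d_n_params <- function(net) sum(vapply(net$params, length, 1L))

unet3d_forward <- function(net, x, dims) {
  if (any(dims %% 2L != 0L)) stop("grid dimensions must be even")
  p <- net$params
  a1 <- cpp_conv3_fwd(x, dims, p$W1a, p$b1a);  r1 <- relu_(a1)
  a2 <- cpp_conv3_fwd(r1, dims, p$W1b, p$b1b); r2 <- relu_(a2)
  pl <- cpp_pool2_fwd(r2, dims)
  dh <- dims %/% 2L
  a3 <- cpp_conv3_fwd(pl$y, dh, p$W2a, p$b2a); r3 <- relu_(a3)
  a4 <- cpp_conv3_fwd(r3, dh, p$W2b, p$b2b);   r4 <- relu_(a4)
  up <- cpp_up2_fwd(r4, dh)
  ct <- rbind(r2, up)
  a5 <- cpp_conv3_fwd(ct, dims, p$W3a, p$b3a); r5 <- relu_(a5)
  a6 <- cpp_conv3_fwd(r5, dims, p$W3b, p$b3b); r6 <- relu_(a6)
  out <- p$Wh %*% r6 + p$bh
  list(out = out,
       cache = list(x = x, a1 = a1, r1 = r1, a2 = a2, r2 = r2, pl = pl,
                    a3 = a3, r3 = r3, a4 = a4, r4 = r4, ct = ct,
                    a5 = a5, r5 = r5, a6 = a6, r6 = r6, dims = dims))
}

unet3d_backward <- function(net, cache, gout) {
  p <- net$params
  dims <- cache$dims
  dh <- dims %/% 2L
  g <- list()
  g$Wh <- gout %*% t(cache$r6)
  g$bh <- rowSums(gout)
  gr6 <- t(p$Wh) %*% gout
  gr6[cache$a6 <= 0] <- 0
  b6 <- cpp_conv3_bwd(cache$r5, dims, p$W3b, gr6)
  g$W3b <- b6$gW; g$b3b <- as.numeric(b6$gb)
  gr5 <- b6$gx; gr5[cache$a5 <= 0] <- 0
  b5 <- cpp_conv3_bwd(cache$ct, dims, p$W3a, gr5)
  g$W3a <- b5$gW; g$b3a <- as.numeric(b5$gb)
  fw <- net$width
  gskip <- b5$gx[seq_len(fw), , drop = FALSE]
  gup <- b5$gx[(fw + 1):(3 * fw), , drop = FALSE]
  gr4 <- cpp_up2_bwd(gup, dh); gr4[cache$a4 <= 0] <- 0
  b4 <- cpp_conv3_bwd(cache$r3, dh, p$W2b, gr4)
  g$W2b <- b4$gW; g$b2b <- as.numeric(b4$gb)
  gr3 <- b4$gx; gr3[cache$a3 <= 0] <- 0
  b3 <- cpp_conv3_bwd(cache$pl$y, dh, p$W2a, gr3)
  g$W2a <- b3$gW; g$b2a <- as.numeric(b3$gb)
  gr2 <- gskip + cpp_pool2_bwd(b3$gx, cache$pl$idx, prod(dims))
  gr2[cache$a2 <= 0] <- 0
  b2 <- cpp_conv3_bwd(cache$r1, dims, p$W1b, gr2)
  g$W1b <- b2$gW; g$b1b <- as.numeric(b2$gb)
  gr1 <- b2$gx; gr1[cache$a1 <= 0] <- 0
  b1 <- cpp_conv3_bwd(cache$x, dims, p$W1a, gr1)
  g$W1a <- b1$gW; g$b1a <- as.numeric(b1$gb)
  g
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, st, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  for (k in names(params)) {
    st$m[[k]] <- beta1 * st$m[[k]] + (1 - beta1) * grads[[k]]
    st$v[[k]] <- beta2 * st$v[[k]] + (1 - beta2) * grads[[k]]^2
    params[[k]] <- params[[k]] -
      lr * (st$m[[k]] / c1) / (sqrt(st$v[[k]] / c2) + eps)
  }
  list(params = params, state = st)
}

zero_grads <- function(params) lapply(params, function(p) p * 0)

add_grads <- function(a, b) {
  for (k in names(a)) a[[k]] <- a[[k]] + b[[k]]
  a
}

scale_grads <- function(a, s) lapply(a, function(p) p * s)

# Generic early-stopped training loop shared by the localizer and the
# segmenters. `step_fun(net)` performs one optimisation step (mutating via
# return), `val_fun(net)` returns a scalar validation loss. The weights with
# the best validation loss are returned; `patience` = 0 returns the initial
# weights untrained.
train_loop <- function(net, epochs, steps_per_epoch, patience, step_fun,
                       val_fun, verbose = FALSE) {
  best <- net$params
  best_val <- val_fun(net)
  history <- data.frame(epoch = 0, val = best_val)
  if (patience <= 0)
    return(list(net = net, val = best_val, history = history))
  since_best <- 0L
  for (e in seq_len(epochs)) {
    for (s in seq_len(steps_per_epoch)) net <- step_fun(net)
    v <- val_fun(net)
    if (!is.finite(v)) stop("training diverged (non-finite validation loss)")
    history <- rbind(history, data.frame(epoch = e, val = v))
    if (verbose) message(sprintf("epoch %d: val %.5f", e, v))
    if (v < best_val - 1e-9) {
      best_val <- v
      best <- net$params
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best > patience) break
    }
  }
  net$params <- best
  list(net = net, val = best_val, history = history)
}
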