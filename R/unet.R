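#' 3D U-Net specification
#'
#' Architecture hyperparameters for the miniature dose-prediction network:
#' an encoder–decoder with skip connections, 3x3x3 convolutions everywhere
#' except the 1x1x1 output layer, max-pooling that halves the feature-map
#' size at each encoder stage, mean-square-error loss, Adam optimization and
#' He-normal weight initialization. Input channels are the density volume
#' plus one channel per ROI mask (body, PTV, bladder, both femoral heads).
#'
#' @param encoder_filters filters per encoder stage, length >= 2;
#'   default `c(32, 64, 128, 256, 512)`
#' @param in_channels input channels; default 6 (density + 5 ROI masks)
#' @param dose_scale_gy dose normalization applied to training targets and
#'   undone at prediction time; default 50 (the prescription)
#' @return a `unet_spec` list
#' @export
unet_spec <- function(encoder_filters = c(32L, 64L, 128L, 256L, 512L),
                      in_channels = 6L, dose_scale_gy = 50) {
  if (length(encoder_filters) < 2L || any(encoder_filters < 1)) {
    abort_argument("`encoder_filters` must list >= 2 positive filter counts")
  }
  structure(list(
    encoder_filters = as.integer(encoder_filters),
    conv_kernel = 3L, output_kernel = 1L, pool_factor = 2L,
    loss = "mse", optimizer_name = "adam", init_scheme = "he_normal",
    in_channels = as.integer(in_channels), dose_scale_gy = dose_scale_gy
  ), class = "unet_spec")
}

# ---- im2col machinery ------------------------------------------------------
# Feature maps are stored as (nvox x channels) matrices over a flat (z,y,x)
# column-major grid; a 3x3x3 convolution is one matrix multiply against a
# gathered (nvox x 27*channels) patch matrix.

voxel_coords <- function(shape) {
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  list(z = rep_len(seq_len(nz), nz * ny * nx),
       y = rep(rep(seq_len(ny), each = nz), nx),
       x = rep(seq_len(nx), each = nz * ny))
}

# (nvox x 27) map of neighbour flat indices; 0 = outside (zero padding).
conv3_index <- function(shape) {
  co <- voxel_coords(shape)
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  out <- matrix(0L, nrow = nz * ny * nx, ncol = 27L)
  o <- 0L
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    o <- o + 1L
    zz <- co$z + dz; yy <- co$y + dy; xx <- co$x + dx
    ok <- zz >= 1L & zz <= nz & yy >= 1L & yy <= ny & xx >= 1L & xx <= nx
    idx <- zz + nz * (yy - 1L) + nz * ny * (xx - 1L)
    idx[!ok] <- 0L
    out[, o] <- idx
  }
  out
}

# (nout x 8) map: flat input indices of the 2x2x2 children of each pooled voxel.
pool2_index <- function(shape) {
  os <- shape %/% 2L
  co <- voxel_coords(os)
  nz <- shape[1]; ny <- shape[2]
  out <- matrix(0L, nrow = prod(os), ncol = 8L)
  o <- 0L
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    o <- o + 1L
    zz <- 2L * co$z - 1L + dz; yy <- 2L * co$y - 1L + dy; xx <- 2L * co$x - 1L + dx
    out[, o] <- zz + nz * (yy - 1L) + nz * ny * (xx - 1L)
  }
  out
}

gather_patches <- function(V, idx) {
  C <- ncol(V)
  Vaug <- rbind(0, V)
  X <- matrix(0, nrow = nrow(idx), ncol = 27L * C)
  for (o in seq_len(27L)) {
    X[, (o - 1L) * C + seq_len(C)] <- Vaug[idx[, o] + 1L, , drop = FALSE]
  }
  X
}

scatter_patches <- function(dX, idx, nvox, C) {
  dV <- matrix(0, nrow = nvox + 1L, ncol = C)
  for (o in seq_len(27L)) {
    tgt <- idx[, o] + 1L
    keep <- tgt > 1L   # within each offset the map is injective
    dV[tgt[keep], ] <- dV[tgt[keep], , drop = FALSE] +
      dX[keep, (o - 1L) * C + seq_len(C), drop = FALSE]
  }
  dV[-1L, , drop = FALSE]
}

he_normal <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

#' Build a miniature 3D U-Net
#'
#' Constructs the encoder–decoder with one 3x3x3 convolution + ReLU per
#' stage, max-pool downsampling, nearest-neighbour upsampling with skip
#' concatenation, and a linear 1x1x1 output convolution to a single dose
#' channel. Weights are drawn from the He-normal distribution
#' (`sd = sqrt(2 / fan_in)`). A forward pass requires the spatial shape to
#' be divisible by `pool_factor^(depth - 1)`.
#'
#' @param spec a [unet_spec()]
#' @param seed seed for weight initialization
#' @return a `unet` network handle
#' @export
build_unet <- function(spec = unet_spec(), seed = 1L) {
  f <- spec$encoder_filters
  D <- length(f)
  layers <- with_seed(seed, {
    enc <- lapply(seq_len(D), function(k) {
      cin <- if (k == 1L) spec$in_channels else f[k - 1L]
      list(W = he_normal(27L * cin, f[k], 27L * cin), b = numeric(f[k]),
           cin = cin, cout = f[k])
    })
    dec <- lapply(rev(seq_len(D - 1L)), function(k) {
      cin <- f[k + 1L] + f[k]          # upsampled + skip
      list(W = he_normal(27L * cin, f[k], 27L * cin), b = numeric(f[k]),
           cin = cin, cout = f[k], level = k)
    })
    outl <- list(W = he_normal(f[1L], 1L, f[1L]), b = 0,
                 cin = f[1L], cout = 1L)
    list(enc = enc, dec = dec, out = outl)
  })
  structure(list(spec = spec, layers = layers, depth = D), class = "unet")
}

#' @exportS3Method base::print
print.unet <- function(x, ...) {
  cat(sprintf("<unet> depth %d, filters %s, %d parameters\n", x$depth,
              paste(x$spec$encoder_filters, collapse = "-"),
              unet_num_params(x)))
  invisible(x)
}

#' Number of trainable parameters of a network
#'
#' @param net a [build_unet()] handle
#' @return integer parameter count
#' @export
unet_num_params <- function(net) {
  n <- 0
  for (l in c(net$layers$enc, net$layers$dec, list(net$layers$out))) {
    n <- n + length(l$W) + length(l$b)
  }
  n
}

check_unet_shape <- function(net, shape) {
  div <- net$spec$pool_factor^(net$depth - 1L)
  if (any(shape %% div != 0)) {
    abort_shape(sprintf(
      "input shape (%s) must be divisible by %d in every axis for a depth-%d network",
      paste(shape, collapse = ","), div, net$depth))
  }
}

# Forward pass; returns the prediction and, if `keep = TRUE`, every cached
# intermediate needed for backpropagation.
unet_forward <- function(net, V, shape, keep = FALSE) {
  check_unet_shape(net, shape)
  D <- net$depth
  shapes <- vector("list", D); acts <- vector("list", D)
  cidx <- vector("list", D); pidx <- vector("list", D - 1L)
  Xs <- vector("list", D)
  argmax <- vector("list", D - 1L)
  cur <- V; cur_shape <- shape
  for (k in seq_len(D)) {
    shapes[[k]] <- cur_shape
    cidx[[k]] <- conv3_index(cur_shape)
    X <- gather_patches(cur, cidx[[k]])
    H <- X %*% net$layers$enc[[k]]$W
    H <- sweep(H, 2L, net$layers$enc[[k]]$b, `+`)
    H[H < 0] <- 0
    if (keep) { Xs[[k]] <- X }
    acts[[k]] <- H
    if (k < D) {
      pidx[[k]] <- pool2_index(cur_shape)
      ch <- pidx[[k]]
      pooled <- H[ch[, 1L], , drop = FALSE]
      am <- matrix(1L, nrow(ch), ncol(H))
      for (o in 2:8) {
        cand <- H[ch[, o], , drop = FALSE]
        upd <- cand > pooled
        pooled[upd] <- cand[upd]
        am[upd] <- o
      }
      argmax[[k]] <- am
      cur <- pooled
      cur_shape <- cur_shape %/% 2L
    }
  }
  # decoder
  dXs <- vector("list", D - 1L); dec_acts <- vector("list", D - 1L)
  cur <- acts[[D]]
  for (j in seq_len(D - 1L)) {
    k <- net$layers$dec[[j]]$level
    ch <- pidx[[k]]
    up <- matrix(0, nrow = prod(shapes[[k]]), ncol = ncol(cur))
    for (o in 1:8) up[ch[, o], ] <- cur
    cat_in <- cbind(up, acts[[k]])
    X <- gather_patches(cat_in, cidx[[k]])
    H <- X %*% net$layers$dec[[j]]$W
    H <- sweep(H, 2L, net$layers$dec[[j]]$b, `+`)
    H[H < 0] <- 0
    if (keep) { dXs[[j]] <- X; dec_acts[[j]] <- H }
    cur <- H
  }
  pred <- as.vector(cur %*% net$layers$out$W + net$layers$out$b)
  if (!keep) return(pred)
  list(pred = pred, acts = acts, Xs = Xs, dXs = dXs, dec_acts = dec_acts,
       dec_last = cur, cidx = cidx, pidx = pidx, argmax = argmax,
       shapes = shapes)
}

# Backpropagation of d(loss)/d(pred); returns gradients in layer order.
unet_backward <- function(net, cache, dpred) {
  D <- net$depth
  g <- list(enc = vector("list", D), dec = vector("list", D - 1L), out = NULL)
  dpred <- matrix(dpred, ncol = 1L)
  g$out <- list(W = crossprod(cache$dec_last, dpred), b = sum(dpred))
  dcur <- dpred %*% t(net$layers$out$W)
  skip_grads <- vector("list", D)
  for (j in rev(seq_len(D - 1L))) {
    k <- net$layers$dec[[j]]$level
    dcur[cache$dec_acts[[j]] <= 0] <- 0
    X <- cache$dXs[[j]]
    g$dec[[j]] <- list(W = crossprod(X, dcur), b = colSums(dcur))
    dX <- dcur %*% t(net$layers$dec[[j]]$W)
    cin <- net$layers$dec[[j]]$cin
    dcat_in <- scatter_patches(dX, cache$cidx[[k]], prod(cache$shapes[[k]]), cin)
    cup <- net$spec$encoder_filters[k + 1L]
    dup <- dcat_in[, seq_len(cup), drop = FALSE]
    skip_grads[[k]] <- dcat_in[, cup + seq_len(ncol(dcat_in) - cup), drop = FALSE]
    # nearest-upsample backward: sum the 8 children into the parent
    ch <- cache$pidx[[k]]
    dparent <- dup[ch[, 1L], , drop = FALSE]
    for (o in 2:8) dparent <- dparent + dup[ch[, o], , drop = FALSE]
    dcur <- dparent
  }
  # encoder, deepest to shallowest
  dH <- dcur   # gradient reaching the bottleneck activation
  for (k in rev(seq_len(D))) {
    if (k < D) {
      # maxpool backward then add the skip gradient
      ch <- cache$pidx[[k]]; am <- cache$argmax[[k]]
      dact <- matrix(0, nrow = nrow(cache$acts[[k]]), ncol = ncol(cache$acts[[k]]))
      for (o in 1:8) {
        hit <- am == o
        if (any(hit)) {
          rows <- ch[, o]
          idx <- cbind(rows[row(am)[hit]], col(am)[hit])
          dact[idx] <- dact[idx] + dH[hit]
        }
      }
      dH <- dact + skip_grads[[k]]
    }
    dH[cache$acts[[k]] <= 0] <- 0
    g$enc[[k]] <- list(W = crossprod(cache$Xs[[k]], dH), b = colSums(dH))
    if (k > 1L) {
      dX <- dH %*% t(net$layers$enc[[k]]$W)
      dH <- scatter_patches(dX, cache$cidx[[k]],
                            prod(cache$shapes[[k]]),
                            net$layers$enc[[k]]$cin)
    }
  }
  g
}

# Stack phantom channels into the (nvox x C) input matrix: standardized
# density then the five ROI masks.
unet_input <- function(p) {
  dz <- as.vector(p$density)
  sdd <- stats::sd(dz)
  dz <- (dz - mean(dz)) / if (sdd > 0) sdd else 1
  cbind(dz,
        as.numeric(p$masks$body), as.numeric(p$masks$ptv),
        as.numeric(p$masks$bladder),
        as.numeric(p$masks$femoral_head_l),
        as.numeric(p$masks$femoral_head_r))
}

#' Train a U-Net on (phantom, dose) cases
#'
#' Mean-square-error loss on prescription-normalized doses, minimized with
#' Adam; one parameter update per case per epoch, cases visited in order, so
#' training is deterministic given the seed. Raises a training error naming
#' the epoch if the loss becomes non-finite.
#'
#' @param net a [build_unet()] handle
#' @param cases list of `list(phantom = , dose = )` pairs
#' @param epochs number of epochs (0 returns the net unchanged, empty trace)
#' @param lr Adam learning rate
#' @param seed RNG seed (training itself is order-deterministic)
#' @return list with the trained `net` and the per-epoch `loss_trace`
#' @export
train_unet <- function(net, cases, epochs = 50, lr = 1e-3, seed = 1L) {
  if (length(cases) < 1L) abort_argument("`cases` must contain at least one case")
  prepped <- lapply(cases, function(cs) {
    list(V = unet_input(cs$phantom),
         target = as.vector(dose_values(cs$dose)) / net$spec$dose_scale_gy,
         shape = dim(cs$phantom$density))
  })
  for (cs in prepped) check_unet_shape(net, cs$shape)
  if (epochs == 0) return(list(net = net, loss_trace = numeric(0)))

  adam <- list(m = zero_like_params(net), v = zero_like_params(net), t = 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  trace <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      losses <- numeric(length(prepped))
      for (ci in seq_along(prepped)) {
        cs <- prepped[[ci]]
        cache <- unet_forward(net, cs$V, cs$shape, keep = TRUE)
        resid <- cache$pred - cs$target
        losses[ci] <- mean(resid^2)
        if (!is.finite(losses[ci])) {
          abort_training(sprintf("non-finite training loss at epoch %d", ep))
        }
        grads <- unet_backward(net, cache, 2 * resid / length(resid))
        adam$t <- adam$t + 1
        upd <- adam_update(net, grads, adam, lr, b1, b2, eps)
        net <- upd$net; adam <- upd$adam
      }
      trace[ep] <- mean(losses)
    }
  })
  list(net = net, loss_trace = trace)
}

zero_like_params <- function(net) {
  lapply(flatten_layers(net), function(l) list(W = l$W * 0, b = l$b * 0))
}

flatten_layers <- function(net) {
  c(net$layers$enc, net$layers$dec, list(net$layers$out))
}

unflatten_layers <- function(net, flat) {
  D <- net$depth
  net$layers$enc <- flat[seq_len(D)]
  net$layers$dec <- flat[D + seq_len(D - 1L)]
  net$layers$out <- flat[[2L * D]]
  net
}

adam_update <- function(net, grads, adam, lr, b1, b2, eps) {
  flat <- flatten_layers(net)
  gflat <- c(grads$enc, grads$dec, list(grads$out))
  for (i in seq_along(flat)) {
    for (fld in c("W", "b")) {
      gv <- gflat[[i]][[fld]]
      adam$m[[i]][[fld]] <- b1 * adam$m[[i]][[fld]] + (1 - b1) * gv
      adam$v[[i]][[fld]] <- b2 * adam$v[[i]][[fld]] + (1 - b2) * gv^2
      mhat <- adam$m[[i]][[fld]] / (1 - b1^adam$t)
      vhat <- adam$v[[i]][[fld]] / (1 - b2^adam$t)
      flat[[i]][[fld]] <- flat[[i]][[fld]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(net = unflatten_layers(net, flat), adam = adam)
}

#' Predict a dose distribution with a (trained) U-Net
#'
#' Runs the forward pass on the phantom's stacked channels, undoes the
#' prescription normalization, and clamps negative raw outputs to zero so
#' the result is a valid dose grid.
#'
#' @param net a [build_unet()] handle (typically after [train_unet()])
#' @param p a [phantom()] whose shape satisfies the network's divisibility
#' @return a [dose_grid()]
#' @export
predict_dose <- function(net, p) {
  V <- unet_input(p)
  pred <- unet_forward(net, V, dim(p$density)) * net$spec$dose_scale_gy
  pred[pred < 0] <- 0
  dose_grid(array(pred, dim = dim(p$density)), p$spacing, p$origin)
}
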