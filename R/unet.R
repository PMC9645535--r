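#' Configuration of the 3D attention U-Net
#'
#' The network is a standard 3D encoder-decoder: the contraction path halves
#' the resolution and doubles the channel count at each level, the expansion
#' path mirrors it, and each skip connection optionally passes through an
#' additive attention gate before concatenation. The final layer maps to
#' per-voxel class scores normalized to a probability simplex.
#'
#' @param depth number of resolution levels (>= 2).
#' @param base_channels channels at the highest resolution.
#' @param in_channels input channels (1 for CT).
#' @param out_classes number of classes (3 for background/lumen/WS-ILT on
#'   contrast, 2 for the non-contrast aorta and the ROI stage).
#' @param attention enable attention gates; with `FALSE` the architecture
#'   reduces to the plain 3D U-Net used as a baseline.
#' @param attention_per_channel if `TRUE` the gate emits one coefficient per
#'   voxel and channel; default is a single per-voxel coefficient.
#' @param convs_per_block 3x3x3 convolutions per resolution block.
#' @param patch_size training/inference patch, voxels; each dimension must
#'   be divisible by `2^(depth - 1)`.
#' @param learning_rate Adam step size.
#' @param epochs training epochs.
#' @param patches_per_case random patches drawn per case per epoch.
#' @param augment apply online random affine augmentation while training.
#' @param seed integer seed fixing initialization, patch draws and
#'   augmentation.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(depth = 3, base_channels = 8, in_channels = 1,
                        out_classes = 3, attention = TRUE,
                        attention_per_channel = FALSE,
                        convs_per_block = 2, patch_size = c(32, 32, 32),
                        learning_rate = 1e-3, epochs = 30,
                        patches_per_case = 2, augment = TRUE, seed = 1L) {
  if (depth < 2) stop("unet_config: depth must be >= 2", call. = FALSE)
  if (out_classes < 2) stop("unet_config: out_classes must be >= 2", call. = FALSE)
  patch_size <- as.integer(rep(patch_size, length.out = 3))
  div <- 2^(depth - 1)
  if (any(patch_size %% div != 0))
    stop("unet_config: patch_size must be divisible by 2^(depth-1) = ", div,
         call. = FALSE)
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 in_channels = as.integer(in_channels),
                 out_classes = as.integer(out_classes),
                 attention = isTRUE(attention),
                 attention_per_channel = isTRUE(attention_per_channel),
                 convs_per_block = as.integer(convs_per_block),
                 patch_size = patch_size,
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 patches_per_case = as.integer(patches_per_case),
                 augment = isTRUE(augment),
                 seed = as.integer(seed)),
            class = "unet_config")
}

level_channels <- function(cfg, l) cfg$base_channels * 2L^(l - 1L)

he_mat <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)

init_unet_params <- function(cfg) {
  p <- list()
  for (l in seq_len(cfg$depth)) {
    cl <- level_channels(cfg, l)
    ci <- if (l == 1) cfg$in_channels else level_channels(cfg, l - 1)
    for (k in seq_len(cfg$convs_per_block)) {
      cin <- if (k == 1) ci else cl
      p[[sprintf("enc%d.conv%d.W", l, k)]] <- he_mat(cin * 27L, cl)
      p[[sprintf("enc%d.conv%d.b", l, k)]] <- numeric(cl)
    }
  }
  for (l in seq_len(cfg$depth - 1)) {
    cl <- level_channels(cfg, l)
    cd <- level_channels(cfg, l + 1)
    p[[sprintf("dec%d.up.W", l)]] <- he_mat(cd, cl)
    p[[sprintf("dec%d.up.b", l)]] <- numeric(cl)
    if (cfg$attention) {
      Fc <- max(1L, cl %/% 2L)
      A <- if (cfg$attention_per_channel) cl else 1L
      p[[sprintf("dec%d.att.Wx", l)]] <- he_mat(cl, Fc)
      p[[sprintf("dec%d.att.Wg", l)]] <- he_mat(cl, Fc)
      p[[sprintf("dec%d.att.bg", l)]] <- numeric(Fc)
      p[[sprintf("dec%d.att.psi", l)]] <- he_mat(Fc, A) * 0.1
      p[[sprintf("dec%d.att.bpsi", l)]] <- rep(1, A)  # start nearly open
    }
    for (k in seq_len(cfg$convs_per_block)) {
      cin <- if (k == 1) 2L * cl else cl
      p[[sprintf("dec%d.conv%d.W", l, k)]] <- he_mat(cin * 27L, cl)
      p[[sprintf("dec%d.conv%d.b", l, k)]] <- numeric(cl)
    }
  }
  p[["final.W"]] <- he_mat(cfg$base_channels, cfg$out_classes)
  p[["final.b"]] <- numeric(cfg$out_classes)
  p
}

as_feature <- function(x, in_channels = 1L) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  stopifnot(dim(x)[4] == in_channels)
  x
}

conv1x1_fw <- function(x, W, b) {
  d <- dim(x)
  m <- matrix(x, ncol = d[4])
  y <- m %*% W
  y <- y + rep(b, each = nrow(y))
  array(y, c(d[1:3], ncol(W)))
}

conv1x1_bw <- function(x, W, gy) {
  d <- dim(x)
  m <- matrix(x, ncol = d[4])
  gm <- matrix(gy, ncol = ncol(W))
  list(gx = array(gm %*% t(W), d),
       gW = crossprod(m, gm),
       gb = colSums(gm))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

att_fw <- function(skip, u, Wx, Wg, bg, psi, bpsi) {
  d <- dim(skip)
  sm <- matrix(skip, ncol = d[4])
  um <- matrix(u, ncol = d[4])
  qpre <- sm %*% Wx + um %*% Wg
  qpre <- qpre + rep(bg, each = nrow(qpre))
  q <- pmax(qpre, 0)
  apre <- q %*% psi
  apre <- apre + rep(bpsi, each = nrow(apre))
  a <- sigmoid(apre)
  gated <- if (ncol(a) == 1L) skip * as.vector(a) else array(sm * a, d)
  list(gated = gated, alpha = a, q = q)
}

#' Additive attention gate on a skip connection
#'
#' Computes per-voxel attention coefficients `alpha` in \[0, 1\] by an
#' additive combination of linear projections of the skip features and the
#' (coarser-scale) gating signal, rectification, projection to a single
#' channel (or one per channel) and a logistic squash; the gating signal is
#' upsampled by factor 2 to the skip resolution. The output is the
#' element-wise product `alpha * skip`.
#'
#' @param skip skip-connection features, array `(nx, ny, nz, c)`.
#' @param gating gating features from the coarser scale,
#'   `(nx/2, ny/2, nz/2, c_g)`, already projected to `c` channels, or of the
#'   same spatial shape as `skip`.
#' @param weights list with `Wx` (c x f), `Wg` (c x f), `bg` (f),
#'   `psi` (f x a), `bpsi` (a).
#' @return List with `gated` (same shape as `skip`) and `alpha`
#'   (`(nx, ny, nz)` or `(nx, ny, nz, c)` array of coefficients).
#' @export
attention_gate <- function(skip, gating, weights) {
  ds <- dim(skip)
  dg <- dim(gating)
  if (!all(ds[1:3] == dg[1:3])) {
    if (all(ds[1:3] == 2L * dg[1:3])) gating <- upsample3d_fw(gating)
    else stop("attention_gate: gating shape not reconcilable with skip by ",
              "factor-2 upsampling", call. = FALSE)
  }
  if (dim(gating)[4] != ds[4])
    stop("attention_gate: gating must carry the same channel count as skip",
         call. = FALSE)
  o <- att_fw(skip, gating, weights$Wx, weights$Wg, weights$bg,
              weights$psi, weights$bpsi)
  adim <- if (ncol(o$alpha) == 1L) ds[1:3] else ds
  list(gated = o$gated, alpha = array(o$alpha, adim))
}

unet_forward <- function(params, cfg, x, keep_cache = FALSE) {
  x <- as_feature(x, cfg$in_channels)
  cache <- list(enc = vector("list", cfg$depth),
                pool = vector("list", cfg$depth),
                dec = vector("list", cfg$depth))
  enc_out <- vector("list", cfg$depth)
  h <- x
  for (l in seq_len(cfg$depth)) {
    if (l > 1) {
      pl <- maxpool3d_fw(h)
      cache$pool[[l]] <- list(idx = pl$idx, dims_in = dim(h))
      h <- pl$y
    }
    xin <- vector("list", cfg$convs_per_block)
    for (k in seq_len(cfg$convs_per_block)) {
      xin[[k]] <- h
      z <- conv3d_fw(h, params[[sprintf("enc%d.conv%d.W", l, k)]],
                     params[[sprintf("enc%d.conv%d.b", l, k)]])
      h <- pmax(z, 0)
    }
    cache$enc[[l]] <- list(xin = xin, out = h)
    enc_out[[l]] <- h
  }
  f <- enc_out[[cfg$depth]]
  for (l in rev(seq_len(cfg$depth - 1))) {
    upx <- upsample3d_fw(f)
    u <- conv1x1_fw(upx, params[[sprintf("dec%d.up.W", l)]],
                    params[[sprintf("dec%d.up.b", l)]])
    skip <- enc_out[[l]]
    if (cfg$attention) {
      at <- att_fw(skip, u,
                   params[[sprintf("dec%d.att.Wx", l)]],
                   params[[sprintf("dec%d.att.Wg", l)]],
                   params[[sprintf("dec%d.att.bg", l)]],
                   params[[sprintf("dec%d.att.psi", l)]],
                   params[[sprintf("dec%d.att.bpsi", l)]])
      skipg <- at$gated
    } else {
      at <- NULL
      skipg <- skip
    }
    d <- dim(skip)
    conc <- array(c(skipg, u), c(d[1:3], 2L * d[4]))
    h <- conc
    xin <- vector("list", cfg$convs_per_block)
    for (k in seq_len(cfg$convs_per_block)) {
      xin[[k]] <- h
      z <- conv3d_fw(h, params[[sprintf("dec%d.conv%d.W", l, k)]],
                     params[[sprintf("dec%d.conv%d.b", l, k)]])
      h <- pmax(z, 0)
    }
    cache$dec[[l]] <- list(upx = upx, u = u, skip = skip, att = at,
                           conc = conc, xin = xin, out = h)
    f <- h
  }
  cache$head_in <- f
  logits <- conv1x1_fw(f, params[["final.W"]], params[["final.b"]])
  d <- dim(logits)
  lm <- matrix(logits, ncol = d[4])
  lm <- lm - apply(lm, 1, max)
  em <- exp(lm)
  probs <- array(em / rowSums(em), d)
  if (keep_cache) list(probs = probs, cache = cache) else list(probs = probs)
}

# gz: gradient w.r.t. logits
unet_backward <- function(params, cfg, cache, gz) {
  g <- list()
  bw <- conv1x1_bw(cache$head_in, params[["final.W"]], gz)
  g[["final.W"]] <- bw$gW
  g[["final.b"]] <- bw$gb
  genc <- vector("list", cfg$depth)  # grads into enc_out[[l]]
  gf <- bw$gx
  for (l in seq_len(cfg$depth - 1)) {
    dc <- cache$dec[[l]]
    gh <- gf
    for (k in rev(seq_len(cfg$convs_per_block))) {
      out_k <- if (k == cfg$convs_per_block) dc$out else dc$xin[[k + 1]]
      gz_k <- gh * (out_k > 0)
      bwk <- conv3d_bw(dc$xin[[k]], params[[sprintf("dec%d.conv%d.W", l, k)]], gz_k)
      g[[sprintf("dec%d.conv%d.W", l, k)]] <- bwk$gW
      g[[sprintf("dec%d.conv%d.b", l, k)]] <- bwk$gb
      gh <- bwk$gx
    }
    d <- dim(dc$skip)
    nc <- d[4]
    gconc <- gh
    np <- prod(d[1:3])
    gm <- matrix(gconc, ncol = 2L * nc)
    gskipg <- gm[, seq_len(nc), drop = FALSE]
    gu <- gm[, nc + seq_len(nc), drop = FALSE]
    sm <- matrix(dc$skip, ncol = nc)
    um <- matrix(dc$u, ncol = nc)
    if (cfg$attention) {
      a <- dc$att$alpha
      qm <- dc$att$q
      psi <- params[[sprintf("dec%d.att.psi", l)]]
      if (ncol(a) == 1L) {
        gskip <- gskipg * as.vector(a)
        ga <- matrix(rowSums(gskipg * sm), ncol = 1)
      } else {
        gskip <- gskipg * a
        ga <- gskipg * sm
      }
      gapre <- ga * a * (1 - a)
      g[[sprintf("dec%d.att.psi", l)]] <- crossprod(qm, gapre)
      g[[sprintf("dec%d.att.bpsi", l)]] <- colSums(gapre)
      gq <- gapre %*% t(psi)
      gqpre <- gq * (qm > 0)
      g[[sprintf("dec%d.att.Wx", l)]] <- crossprod(sm, gqpre)
      g[[sprintf("dec%d.att.Wg", l)]] <- crossprod(um, gqpre)
      g[[sprintf("dec%d.att.bg", l)]] <- colSums(gqpre)
      gskip <- gskip + gqpre %*% t(params[[sprintf("dec%d.att.Wx", l)]])
      gu <- gu + gqpre %*% t(params[[sprintf("dec%d.att.Wg", l)]])
    } else {
      gskip <- gskipg
    }
    genc[[l]] <- array(gskip, d)
    bwu <- conv1x1_bw(dc$upx, params[[sprintf("dec%d.up.W", l)]], array(gu, d))
    g[[sprintf("dec%d.up.W", l)]] <- bwu$gW
    g[[sprintf("dec%d.up.b", l)]] <- bwu$gb
    ginput <- upsample3d_bw(bwu$gx)
    if (l + 1 == cfg$depth) genc[[cfg$depth]] <- ginput
    else gf <- ginput  # grad of decoder block l+1's output
  }
  for (l in rev(seq_len(cfg$depth))) {
    ec <- cache$enc[[l]]
    gh <- genc[[l]]
    for (k in rev(seq_len(cfg$convs_per_block))) {
      out_k <- if (k == cfg$convs_per_block) ec$out else ec$xin[[k + 1]]
      gz_k <- gh * (out_k > 0)
      bwk <- conv3d_bw(ec$xin[[k]], params[[sprintf("enc%d.conv%d.W", l, k)]], gz_k)
      g[[sprintf("enc%d.conv%d.W", l, k)]] <- bwk$gW
      g[[sprintf("enc%d.conv%d.b", l, k)]] <- bwk$gb
      gh <- bwk$gx
    }
    if (l > 1) {
      pl <- cache$pool[[l]]
      gpool <- maxpool3d_bw(gh, pl$idx, as.integer(pl$dims_in))
      genc[[l - 1]] <- genc[[l - 1]] + gpool
    }
  }
  g
}

one_hot <- function(target, n_classes) {
  d <- dim(target)
  m <- matrix(0, prod(d), n_classes)
  m[cbind(seq_len(prod(d)), as.vector(target) + 1L)] <- 1
  array(m, c(d, n_classes))
}

#' Soft Dice loss
#'
#' `1 - mean_c (2 sum(p_c g_c) + eps) / (sum(p_c) + sum(g_c) + eps)` over the
#' non-background classes; in the hard-prediction limit this equals one
#' minus the mean Dice score. When a class is absent from both prediction
#' and target its contribution is 0 (Dice 1 by the epsilon convention).
#'
#' @param pred_probs array `(nx, ny, nz, n_classes)` of per-voxel class
#'   probabilities.
#' @param target a [label_mask()] or integer array of class indices.
#' @param eps numerical stabilizer.
#' @return Scalar loss in \[0, 1\].
#' @export
soft_dice_loss <- function(pred_probs, target, eps = 1e-5) {
  soft_dice_grad(pred_probs, target, eps, want_grad = FALSE)$loss
}

soft_dice_grad <- function(pred_probs, target, eps = 1e-5, want_grad = TRUE) {
  if (inherits(target, "ct_volume")) target <- target$data
  d <- dim(pred_probs)
  C <- d[4]
  if (!all(dim(target) == d[1:3]))
    stop("soft_dice_loss: prediction and target shapes differ", call. = FALSE)
  pm <- matrix(pred_probs, ncol = C)
  tg <- as.vector(target)
  loss <- 0
  gp <- if (want_grad) matrix(0, nrow(pm), C) else NULL
  nfg <- C - 1L
  for (c in 2:C) {
    gcol <- as.numeric(tg == (c - 1L))
    A <- sum(pm[, c] * gcol)
    D <- sum(pm[, c]) + sum(gcol) + eps
    S <- (2 * A + eps) / D
    loss <- loss + (1 - S) / nfg
    if (want_grad)
      gp[, c] <- -(2 * gcol * D - (2 * A + eps)) / D^2 / nfg
  }
  list(loss = loss, gp = gp)
}

# combined softmax + soft-dice gradient w.r.t. logits
loss_grad_logits <- function(probs, target, eps = 1e-5) {
  sg <- soft_dice_grad(probs, target, eps)
  d <- dim(probs)
  pm <- matrix(probs, ncol = d[4])
  s <- rowSums(sg$gp * pm)
  gz <- pm * (sg$gp - s)
  list(loss = sg$loss, gz = array(gz, d))
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gnm <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gnm
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gnm^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

pad_to_patch <- function(arr, patch, fill = 0) {
  d <- dim(arr)[1:3]
  if (all(d >= patch)) return(arr)
  nd <- pmax(d, patch)
  out <- array(fill, nd)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- arr
  out
}

sample_patch <- function(img, mask, patch, fg_bias = 0.9) {
  di <- pad_to_patch(img$data, patch)
  dm <- pad_to_patch(mask$data, patch, 0L)
  d <- dim(di)
  fg <- which(dm > 0L)
  ctr <- if (length(fg) && stats::runif(1) < fg_bias) {
    v <- fg[sample.int(length(fg), 1)] - 1
    c(v %% d[1], (v %/% d[1]) %% d[2], v %/% (d[1] * d[2])) + 1
  } else {
    sapply(d, function(n) sample.int(n, 1))
  }
  lo <- pmin(pmax(ctr - patch %/% 2, 1), d - patch + 1)
  hi <- lo + patch - 1
  list(img = di[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
       mask = dm[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE])
}

normalize_training_case <- function(cs) {
  if (inherits(cs, "phantom_case"))
    list(img = cs$contrast, mask = cs$truth$label_mask)
  else list(img = cs$img, mask = cs$mask)
}

#' Fit the attention U-Net
#'
#' Trains by Adam on the soft Dice loss over randomly sampled patches, with
#' optional online random affine augmentation of each patch. Images are
#' expected on the normalized \[0, 1\] intensity scale (see
#' [normalize_intensity()]); masks must use class indices below
#' `config$out_classes`. Fully reproducible given `config$seed`.
#'
#' @param cases list of training cases, each a list with `img`
#'   ([ct_volume()]) and `mask` ([label_mask()]).
#' @param config a [unet_config()].
#' @param val_cases optional held-out cases, monitored with a fixed
#'   foreground-centred patch per case each epoch.
#' @param verbose print per-epoch losses.
#' @return An object of class `unet3d` with elements `params`, `config` and
#'   `history` (data frame of per-epoch training/validation soft Dice loss).
#' @export
fit_unet <- function(cases, config, val_cases = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "unet_config"))
  cases <- lapply(cases, normalize_training_case)
  if (length(cases) < 2 && config$epochs > 0)
    stop("fit_unet: need at least 2 training cases", call. = FALSE)
  if (!any(vapply(cases, function(cs) any(cs$mask$data > 0L), logical(1))))
    stop("fit_unet: no foreground voxels in any training case", call. = FALSE)
  if (!is.null(val_cases)) val_cases <- lapply(val_cases, normalize_training_case)
  set.seed(config$seed)
  params <- init_unet_params(config)
  state <- adam_init(params)
  patch <- config$patch_size
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  val_patches <- NULL
  if (!is.null(val_cases)) {
    val_patches <- lapply(val_cases, function(cs) {
      fg <- which(cs$mask$data > 0L)
      d <- dim(cs$mask$data)
      ctr <- if (length(fg)) {
        v <- fg[ceiling(length(fg) / 2)] - 1
        c(v %% d[1], (v %/% d[1]) %% d[2], v %/% (d[1] * d[2])) + 1
      } else d %/% 2
      di <- pad_to_patch(cs$img$data, patch)
      dm <- pad_to_patch(cs$mask$data, patch, 0L)
      d <- dim(di)
      lo <- pmin(pmax(ctr - patch %/% 2, 1), d - patch + 1)
      hi <- lo + patch - 1
      list(img = di[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
           mask = dm[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE])
    })
  }
  for (ep in seq_len(config$epochs)) {
    tr_losses <- numeric(0)
    for (ci in sample(seq_along(cases))) {
      cs <- cases[[ci]]
      for (pp in seq_len(config$patches_per_case)) {
        pt <- sample_patch(cs$img, cs$mask, patch)
        if (config$augment) {
          pv <- ct_volume(pt$img, cs$img$spacing)
          pmsk <- label_mask(pt$mask, cs$img$spacing)
          aug <- random_affine_3d(pv, pmsk)
          pt <- list(img = aug$img$data, mask = aug$mask$data)
        }
        fw <- unet_forward(params, config, pt$img, keep_cache = TRUE)
        lg <- loss_grad_logits(fw$probs, pt$mask)
        grads <- unet_backward(params, config, fw$cache, lg$gz)
        upd <- adam_step(params, grads, state, config$learning_rate)
        params <- upd$params
        state <- upd$state
        tr_losses <- c(tr_losses, lg$loss)
      }
    }
    vl <- NA_real_
    if (!is.null(val_patches)) {
      vl <- mean(vapply(val_patches, function(pt) {
        fw <- unet_forward(params, config, pt$img)
        soft_dice_loss(fw$probs, pt$mask)
      }, numeric(1)))
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(tr_losses),
                                   val_loss = vl))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %s", ep, mean(tr_losses),
                      ifelse(is.na(vl), "-", sprintf("%.4f", vl))))
  }
  structure(list(params = params, config = config, history = hist),
            class = "unet3d")
}

#' @export
print.unet3d <- function(x, ...) {
  cfg <- x$config
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<unet3d> depth %d, base %d channels, %d classes, %s\n",
              cfg$depth, cfg$base_channels, cfg$out_classes,
              if (cfg$attention) "attention-gated" else "plain"))
  cat(sprintf("  %d parameters, trained %d epochs", np, nrow(x$history)))
  if (nrow(x$history)) {
    cat(sprintf(", final train loss %.4f", utils::tail(x$history$train_loss, 1)))
    if (!is.na(utils::tail(x$history$val_loss, 1)))
      cat(sprintf(", val loss %.4f", utils::tail(x$history$val_loss, 1)))
  }
  cat("\n")
  invisible(x)
}

#' @export
summary.unet3d <- function(object, ...) {
  print(object)
  if (nrow(object$history)) {
    cat("\nTraining history (last 5 epochs):\n")
    print(utils::tail(object$history, 5), row.names = FALSE)
  }
  invisible(object$history)
}

#' @export
coef.unet3d <- function(object, ...) object$params

#' @export
plot.unet3d <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) stop("plot.unet3d: no training history", call. = FALSE)
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "soft Dice loss", ylim = range(c(h$train_loss, h$val_loss),
                                                       na.rm = TRUE), ...)
  if (any(!is.na(h$val_loss)))
    graphics::lines(h$epoch, h$val_loss, lty = 2)
  graphics::legend("topright", legend = c("train", "validation"),
                   lty = c(1, 2), bty = "n")
  invisible(h)
}

#' Sliding-window prediction of per-class probabilities
#'
#' Runs patch-wise inference with half-patch overlap and uniform averaging;
#' volumes smaller than the patch are zero-padded (and the padding cropped
#' from the output). Inference is deterministic.
#'
#' @param object a fitted [fit_unet()] model.
#' @param v a [ct_volume()] on the normalized intensity scale used in
#'   training.
#' @param stride stride between patches, voxels; defaults to half the patch.
#' @param ... unused.
#' @return A `prob_volume`: list with `probs` (4D array, classes last,
#'   summing to 1 per voxel), `spacing`, `origin`.
#' @export
predict.unet3d <- function(object, v, stride = NULL, ...) {
  stopifnot(inherits(v, "ct_volume"))
  cfg <- object$config
  patch <- cfg$patch_size
  if (is.null(stride)) stride <- pmax(patch %/% 2L, 1L)
  stride <- as.integer(rep(stride, length.out = 3))
  d0 <- dim(v$data)
  x <- pad_to_patch(v$data, patch)
  d <- dim(x)
  acc <- array(0, c(d, cfg$out_classes))
  cnt <- array(0, d)
  starts <- function(n, p, s) {
    if (n <= p) return(1L)
    st <- seq(1L, n - p, by = s)
    unique(c(st, n - p + 1L))
  }
  for (i in starts(d[1], patch[1], stride[1]))
    for (j in starts(d[2], patch[2], stride[2]))
      for (k in starts(d[3], patch[3], stride[3])) {
        ii <- i:(i + patch[1] - 1); jj <- j:(j + patch[2] - 1)
        kk <- k:(k + patch[3] - 1)
        fw <- unet_forward(object$params, cfg, x[ii, jj, kk, drop = FALSE])
        acc[ii, jj, kk, ] <- acc[ii, jj, kk, , drop = FALSE] + fw$probs
        cnt[ii, jj, kk] <- cnt[ii, jj, kk] + 1
      }
  probs <- acc / as.vector(cnt)
  probs <- probs[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3]), , drop = FALSE]
  structure(list(probs = probs, spacing = v$spacing, origin = v$origin),
            class = "prob_volume")
}

#' Hard segmentation from a probability volume
#'
#' Classes are mutually exclusive, so binarization is by per-voxel argmax
#' (not a fixed per-channel threshold).
#'
#' @param p a `prob_volume` from [predict.unet3d()].
#' @return A [label_mask()] of class indices.
#' @export
prob_argmax <- function(p) {
  d <- dim(p$probs)
  m <- matrix(p$probs, ncol = d[4])
  lab <- max.col(m, ties.method = "first") - 1L
  label_mask(array(lab, d[1:3]), p$spacing, p$origin)
}
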