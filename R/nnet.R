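# Internal mini-framework for the volumetric encoder-decoder segmenters:
# forward passes and analytic backpropagation over a fixed U-Net graph,
# with the compute-heavy convolutions in C++ (src/kernels.cpp).
# Tensors are (x, y, z, channel) arrays.

.convFwd <- function(x, w, b) {
  k <- dim(w)[1L]
  out <- conv3d_fwd_cpp(x, dim(x), w, b, k)
  array(out, c(dim(x)[1:3], length(b)))
}

.convBwd <- function(x, w, gy) {
  r <- conv3d_bwd_cpp(x, dim(x), w, gy, dim(w)[1L], dim(w)[5L])
  list(gx = array(r$gx, dim(x)), gw = array(r$gw, dim(w)), gb = r$gb)
}

.dwconvFwd <- function(x, w, b) {
  k <- dim(w)[1L]
  out <- dwconv3d_fwd_cpp(x, dim(x), w, b, k)
  array(out, dim(x))
}

.dwconvBwd <- function(x, w, gy) {
  r <- dwconv3d_bwd_cpp(x, dim(x), w, gy, dim(w)[1L])
  list(gx = array(r$gx, dim(x)), gw = array(r$gw, dim(w)), gb = r$gb)
}

.downFwd <- function(x, w, b) {
  out <- downconv3d_fwd_cpp(x, dim(x), w, b)
  array(out, c(dim(x)[1:3] %/% 2L, length(b)))
}

.downBwd <- function(x, w, gy) {
  r <- downconv3d_bwd_cpp(x, dim(x), w, gy, dim(w)[5L])
  list(gx = array(r$gx, dim(x)), gw = array(r$gw, dim(w)), gb = r$gb)
}

.upFwd <- function(x) {
  out <- upsample2_fwd_cpp(x, dim(x))
  array(out, c(dim(x)[1:3] * 2L, dim(x)[4L]))
}

.upBwd <- function(gy, indim) array(upsample2_bwd_cpp(gy, indim), indim)

.normFwd <- function(x, p, norm, eps = 1e-5) {
  if (norm == "none") return(list(y = x, cache = NULL))
  d <- dim(x); n <- prod(d[1:3]); C <- d[4L]
  xm <- matrix(x, n, C)
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = n)
  istd <- 1 / sqrt(colSums(xc * xc) / n + eps)
  xhat <- xc * rep(istd, each = n)
  y <- xhat * rep(p$g, each = n) + rep(p$b, each = n)
  list(y = array(y, d), cache = list(xhat = xhat, istd = istd, d = d))
}

.normBwd <- function(cache, p, norm, gy) {
  if (norm == "none") return(list(gx = gy, gg = NULL, gb = NULL))
  d <- cache$d; n <- prod(d[1:3])
  gym <- matrix(gy, n, length(p$g))
  gb <- colSums(gym)
  gg <- colSums(gym * cache$xhat)
  gxh <- gym * rep(p$g, each = n)
  gx <- (gxh - rep(colMeans(gxh), each = n) -
           cache$xhat * rep(colMeans(gxh * cache$xhat), each = n)) *
    rep(cache$istd, each = n)
  list(gx = array(gx, d), gg = gg, gb = gb)
}

.actFwd <- function(x, act) {
  if (act == "relu") {
    mask <- x > 0
    x[!mask] <- 0
    list(y = x, mask = mask)
  } else {                               # leakyrelu, slope 0.01
    mask <- x > 0
    x[!mask] <- 0.01 * x[!mask]
    list(y = x, mask = mask)
  }
}

.actBwd <- function(mask, act, gy) {
  if (act == "relu") gy * mask else gy * (mask + 0.01 * !mask)
}

# conv -> norm -> act unit
.cnaFwd <- function(x, p, norm, act) {
  a <- .convFwd(x, p$c$w, p$c$b)
  nf <- .normFwd(a, p$n, norm)
  af <- .actFwd(nf$y, act)
  list(y = af$y, cache = list(x = x, nc = nf$cache, mask = af$mask))
}

.cnaBwd <- function(cache, p, norm, act, gy) {
  g <- .actBwd(cache$mask, act, gy)
  nb <- .normBwd(cache$nc, p$n, norm, g)
  cb <- .convBwd(cache$x, p$c$w, nb$gx)
  list(gx = cb$gx,
       gp = list(c = list(w = cb$gw, b = cb$gb),
                 n = if (norm == "none") NULL else
                   list(g = nb$gg, b = nb$gb)))
}

# ---------------------------------------------------------------------------
# family-specific stage blocks (Cin -> Cout)

.blockFwd <- function(fam, p, x, norm, act) {
  if (fam == "dynamic_unet") {
    u1 <- .cnaFwd(x, p$u1, norm, act)
    u2 <- .cnaFwd(u1$y, p$u2, norm, act)
    list(y = u2$y, cache = list(u1 = u1$cache, u2 = u2$cache))
  } else if (fam == "residual_unet") {
    u1 <- .cnaFwd(x, p$u1, norm, act)
    a2 <- .convFwd(u1$y, p$c2$w, p$c2$b)
    n2 <- .normFwd(a2, p$n2, norm)
    skip <- if (is.null(p$proj)) x else .convFwd(x, p$proj$w, p$proj$b)
    af <- .actFwd(n2$y + skip, act)
    list(y = af$y,
         cache = list(u1 = u1$cache, x2 = u1$y, n2 = n2$cache, x = x,
                      mask = af$mask))
  } else {                               # large_kernel_unet
    h <- .convFwd(x, p$pw1$w, p$pw1$b)
    dwa <- .dwconvFwd(h, p$dw$w, p$dw$b)
    nf <- .normFwd(dwa, p$n1, norm)
    af <- .actFwd(nf$y, act)
    u <- .convFwd(af$y, p$pw2$w, p$pw2$b)
    af2 <- .actFwd(u + h, act)
    list(y = af2$y,
         cache = list(x = x, h = h, nc = nf$cache, mask1 = af$mask,
                      t = af$y, mask2 = af2$mask))
  }
}

.blockBwd <- function(fam, p, cache, norm, act, gy) {
  if (fam == "dynamic_unet") {
    b2 <- .cnaBwd(cache$u2, p$u2, norm, act, gy)
    b1 <- .cnaBwd(cache$u1, p$u1, norm, act, b2$gx)
    list(gx = b1$gx, gp = list(u1 = b1$gp, u2 = b2$gp))
  } else if (fam == "residual_unet") {
    gs <- .actBwd(cache$mask, act, gy)
    nb <- .normBwd(cache$n2, p$n2, norm, gs)
    cb <- .convBwd(cache$x2, p$c2$w, nb$gx)
    b1 <- .cnaBwd(cache$u1, p$u1, norm, act, cb$gx)
    gp <- list(u1 = b1$gp,
               c2 = list(w = cb$gw, b = cb$gb),
               n2 = if (norm == "none") NULL else
                 list(g = nb$gg, b = nb$gb))
    if (is.null(p$proj)) {
      gx <- b1$gx + gs
    } else {
      pb <- .convBwd(cache$x, p$proj$w, gs)
      gx <- b1$gx + pb$gx
      gp$proj <- list(w = pb$gw, b = pb$gb)
    }
    list(gx = gx, gp = gp)
  } else {
    gs <- .actBwd(cache$mask2, act, gy)
    ub <- .convBwd(cache$t, p$pw2$w, gs)       # grad into t, pw2
    gt <- .actBwd(cache$mask1, act, ub$gx)
    nb <- .normBwd(cache$nc, p$n1, norm, gt)
    db <- .dwconvBwd(cache$h, p$dw$w, nb$gx)
    gh <- db$gx + gs                           # residual join at h
    pb <- .convBwd(cache$x, p$pw1$w, gh)
    list(gx = pb$gx,
         gp = list(pw1 = list(w = pb$gw, b = pb$gb),
                   dw = list(w = db$gw, b = db$gb),
                   n1 = if (norm == "none") NULL else
                     list(g = nb$gg, b = nb$gb),
                   pw2 = list(w = ub$gw, b = ub$gb)))
  }
}

# ---------------------------------------------------------------------------
# parameter initialization

.heConv <- function(k, cin, cout) {
  array(rnorm(k^3 * cin * cout, 0, sqrt(2 / (k^3 * cin))),
        c(k, k, k, cin, cout))
}

.initCna <- function(k, cin, cout, norm) {
  list(c = list(w = .heConv(k, cin, cout), b = numeric(cout)),
       n = if (norm == "none") NULL else
         list(g = rep(1, cout), b = numeric(cout)))
}

.initBlock <- function(fam, cin, cout, norm, kLarge) {
  if (fam == "dynamic_unet") {
    list(u1 = .initCna(3L, cin, cout, norm),
         u2 = .initCna(3L, cout, cout, norm))
  } else if (fam == "residual_unet") {
    p <- list(u1 = .initCna(3L, cin, cout, norm),
              c2 = list(w = .heConv(3L, cout, cout), b = numeric(cout)),
              n2 = if (norm == "none") NULL else
                list(g = rep(1, cout), b = numeric(cout)),
              proj = NULL)
    if (cin != cout)
      p$proj <- list(w = .heConv(1L, cin, cout), b = numeric(cout))
    p
  } else {
    list(pw1 = list(w = .heConv(1L, cin, cout), b = numeric(cout)),
         dw = list(w = array(rnorm(kLarge^3 * cout, 0,
                                   sqrt(2 / kLarge^3)),
                             c(kLarge, kLarge, kLarge, cout)),
                   b = numeric(cout)),
         n1 = if (norm == "none") NULL else
           list(g = rep(1, cout), b = numeric(cout)),
         pw2 = list(w = .heConv(1L, cout, cout), b = numeric(cout)))
  }
}

# per-level channel widths: double per level, capped at 8x base width
# (the documented derivation rule of the dynamic family, shared by all
# families at desk scale)
.levelWidths <- function(baseWidth, depth) {
  pmin(baseWidth * 2^(seq_len(depth) - 1L), 8L * baseWidth)
}

.initParams <- function(config) {
  fam <- config@family
  norm <- config@normalization
  kL <- config@kernelSize
  W <- .levelWidths(config@baseWidth, config@depth)
  depth <- config@depth
  cin <- config@inChannels + 3L            # + 3 coordinate channels
  params <- list(stem = .initCna(3L, cin, W[1L], norm),
                 enc = vector("list", depth),
                 down = vector("list", depth - 1L),
                 dec = vector("list", depth - 1L),
                 heads = vector("list", length(config@nClasses)))
  for (l in seq_len(depth))
    params$enc[[l]] <- .initBlock(fam, W[l], W[l], norm, kL)
  for (l in seq_len(depth - 1L))
    params$down[[l]] <- list(
      c = list(w = array(rnorm(8 * W[l] * W[l + 1L], 0,
                               sqrt(2 / (8 * W[l]))),
                         c(2L, 2L, 2L, W[l], W[l + 1L])),
               b = numeric(W[l + 1L])),
      n = if (norm == "none") NULL else
        list(g = rep(1, W[l + 1L]), b = numeric(W[l + 1L])))
  for (l in seq_len(depth - 1L))           # dec[[l]] refines level l
    params$dec[[l]] <- list(
      up = .initCna(1L, W[l + 1L], W[l], norm),
      block = .initBlock(fam, 2L * W[l], W[l], norm, kL))
  # heads read the trunk features concatenated with the raw input
  # channels (full-resolution input skip): a per-voxel rule on intensity
  # and coordinates stays learnable whatever the trunk does
  for (h in seq_along(config@nClasses))
    params$heads[[h]] <- list(w = .heConv(1L, W[1L] + cin,
                                          config@nClasses[h]),
                              b = numeric(config@nClasses[h]))
  params
}

# ---------------------------------------------------------------------------
# whole-network forward / backward

.unetFwd <- function(config, params, x, keepCache = FALSE) {
  fam <- config@family; norm <- config@normalization
  act <- config@activation; depth <- config@depth
  stem <- .cnaFwd(x, params$stem, norm, act)
  f <- stem$y
  skips <- vector("list", depth)
  caches <- list(stem = stem$cache, enc = vector("list", depth),
                 down = vector("list", depth - 1L),
                 dec = vector("list", depth - 1L))
  for (l in seq_len(depth)) {
    bf <- .blockFwd(fam, params$enc[[l]], f, norm, act)
    skips[[l]] <- bf$y
    caches$enc[[l]] <- bf$cache
    if (l < depth) {
      dp <- params$down[[l]]
      a <- .downFwd(bf$y, dp$c$w, dp$c$b)
      nf <- .normFwd(a, dp$n, norm)
      af <- .actFwd(nf$y, act)
      caches$down[[l]] <- list(x = bf$y, nc = nf$cache, mask = af$mask,
                               indim = dim(bf$y))
      f <- af$y
    }
  }
  d <- skips[[depth]]
  for (l in rev(seq_len(depth - 1L))) {
    dp <- params$dec[[l]]
    u <- .upFwd(d)
    uc <- .cnaFwd(u, dp$up, norm, act)
    cat <- array(c(uc$y, skips[[l]]),
                 c(dim(uc$y)[1:3], dim(uc$y)[4L] + dim(skips[[l]])[4L]))
    bf <- .blockFwd(fam, dp$block, cat, norm, act)
    caches$dec[[l]] <- list(up = uc$cache, block = bf$cache,
                            updim = dim(d), nup = dim(uc$y)[4L])
    d <- bf$y
  }
  head_in <- array(c(d, x), c(dim(d)[1:3], dim(d)[4L] + dim(x)[4L]))
  logits <- lapply(params$heads, function(h) .convFwd(head_in, h$w, h$b))
  out <- list(logits = logits)
  if (keepCache) {
    caches$trunk <- head_in
    caches$ntrunk <- dim(d)[4L]
    out$cache <- caches
  }
  out
}

# gheads: list of gradients w.r.t. each head's logits
.unetBwd <- function(config, params, cache, gheads) {
  fam <- config@family; norm <- config@normalization
  act <- config@activation; depth <- config@depth
  gparams <- list(stem = NULL, enc = vector("list", depth),
                  down = vector("list", depth - 1L),
                  dec = vector("list", depth - 1L),
                  heads = vector("list", length(params$heads)))
  gtrunk <- NULL
  for (h in seq_along(params$heads)) {
    hb <- .convBwd(cache$trunk, params$heads[[h]]$w, gheads[[h]])
    gparams$heads[[h]] <- list(w = hb$gw, b = hb$gb)
    gtrunk <- if (is.null(gtrunk)) hb$gx else gtrunk + hb$gx
  }
  # drop the input-skip channels: no trainable parameters feed them
  gtrunk <- gtrunk[, , , seq_len(cache$ntrunk), drop = FALSE]
  gskips <- vector("list", depth)
  gd <- gtrunk
  for (l in seq_len(depth - 1L)) {
    dp <- params$dec[[l]]
    dc <- cache$dec[[l]]
    bb <- .blockBwd(fam, dp$block, dc$block, norm, act, gd)
    nup <- dc$nup
    d4 <- dim(bb$gx)[4L]
    gcat <- bb$gx
    gup <- gcat[, , , seq_len(nup), drop = FALSE]
    gskips[[l]] <- gcat[, , , (nup + 1L):d4, drop = FALSE]
    ub <- .cnaBwd(dc$up, dp$up, norm, act, gup)
    gd <- .upBwd(ub$gx, dc$updim)
    gparams$dec[[l]] <- list(up = ub$gp, block = bb$gp)
  }
  gskips[[depth]] <- gd
  gf <- NULL
  for (l in rev(seq_len(depth))) {
    gy <- gskips[[l]]
    if (l < depth) {
      dnc <- cache$down[[l]]
      dp <- params$down[[l]]
      g <- .actBwd(dnc$mask, act, gf)
      nb <- .normBwd(dnc$nc, dp$n, norm, g)
      db <- .downBwd(dnc$x, dp$c$w, nb$gx)
      gparams$down[[l]] <- list(
        c = list(w = db$gw, b = db$gb),
        n = if (norm == "none") NULL else list(g = nb$gg, b = nb$gb))
      gy <- gy + db$gx
    }
    bb <- .blockBwd(fam, params$enc[[l]], cache$enc[[l]], norm, act, gy)
    gparams$enc[[l]] <- bb$gp
    gf <- bb$gx
  }
  sb <- .cnaBwd(cache$stem, params$stem, norm, act, gf)
  gparams$stem <- sb$gp
  gparams
}

# ---------------------------------------------------------------------------
# parameter tree arithmetic (SGD with momentum)

.paramMap2 <- function(f, a, b) {
  if (is.numeric(a)) return(f(a, b))
  out <- a
  for (nm in seq_along(a))
    if (!is.null(a[[nm]]))
      out[[nm]] <- .paramMap2(f, a[[nm]], b[[nm]])
  out
}

.paramZeros <- function(a) {
  if (is.numeric(a)) return(a * 0)
  out <- a
  for (nm in seq_along(a))
    if (!is.null(a[[nm]])) out[[nm]] <- .paramZeros(a[[nm]])
  out
}

.paramMap3 <- function(f, a, b, c) {
  if (is.numeric(a)) return(f(a, b, c))
  out <- a
  for (nm in seq_along(a))
    if (!is.null(a[[nm]]))
      out[[nm]] <- .paramMap3(f, a[[nm]], b[[nm]], c[[nm]])
  out
}

.paramCount <- function(a) {
  if (is.numeric(a)) return(length(a))
  sum(vapply(a, function(e) if (is.null(e)) 0 else .paramCount(e), 0))
}

# normalized [-1, 1] coordinate channels of a patch within a full grid
.coordChannels <- function(fullShape, origin, patchShape) {
  ax <- lapply(1:3, function(i) {
    idx <- origin[i] + seq_len(patchShape[i]) - 1
    2 * (idx + 0.5) / fullShape[i] - 1
  })
  cx <- array(rep(ax[[1L]], times = prod(patchShape[2:3])), patchShape)
  cy <- array(rep(rep(ax[[2L]], each = patchShape[1L]),
                  times = patchShape[3L]), patchShape)
  cz <- array(rep(ax[[3L]], each = prod(patchShape[1:2])), patchShape)
  list(cx, cy, cz)
}

# assemble the network input: z-scored intensity + coordinate channels
.networkInput <- function(patch, mu, sigma, fullShape, origin) {
  ps <- dim(patch)
  cc <- .coordChannels(fullShape, origin, ps)
  array(c((patch - mu) / sigma, cc[[1L]], cc[[2L]], cc[[3L]]), c(ps, 4L))
}
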