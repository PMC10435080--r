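#' Video transformer configuration
#'
#' Architecture of the factorized spatio-temporal transformer. The input is
#' a `T' x H x W x C` sensing video; non-overlapping `t' x h x w` tubelets
#' are flattened and projected to `G`-dimensional tokens, giving
#' `n_t = T'/t'` temporal patches of `n_s = (H/h)(W/w)` spatial tokens.
#' Each of the `L` encoder blocks applies pre-LayerNorm multi-headed
#' self-attention over space (within a temporal index), then over time
#' (within a spatial index), then a GELU MLP, each with a residual
#' connection. A final LayerNorm, global average pooling over all tokens
#' (no classification token) and a two-layer GELU MLP head produce the four
#' regression outputs (X, Y, alpha, beta).
#'
#' @param T_prime,H,W,C video dimensions (frames, rows, cols, channels).
#' @param t_prime,h,w tubelet dimensions; must divide `T_prime`, `H`, `W`.
#' @param L encoder blocks.
#' @param G latent token width; must be divisible by `n_heads`.
#' @param n_heads attention heads.
#' @param mlp_ratio MLP hidden width as a multiple of `G`.
#' @param n_out regression outputs.
#' @return An object of class `vt_config`.
#' @export
vt_config <- function(T_prime = 80, H = 9, W = 22, C = 4,
                      t_prime = 8, h = 1, w = 1,
                      L = 4, G = 96, n_heads = 4, mlp_ratio = 4,
                      n_out = 4) {
  if (T_prime %% t_prime) stop("T_prime must be divisible by t_prime")
  if (H %% h) stop("H must be divisible by h")
  if (W %% w) stop("W must be divisible by w")
  if (G %% n_heads) stop("G must be divisible by n_heads")
  cfg <- list(T_prime = T_prime, H = H, W = W, C = C,
              t_prime = t_prime, h = h, w = w,
              L = L, G = G, n_heads = n_heads, mlp_ratio = mlp_ratio,
              n_out = n_out,
              n_t = T_prime %/% t_prime, n_h = H %/% h, n_w = W %/% w)
  cfg$n_s <- cfg$n_h * cfg$n_w
  cfg$n_tok <- cfg$n_s * cfg$n_t
  cfg$g <- t_prime * h * w * C
  structure(cfg, class = "vt_config")
}

.trunc_normal <- function(n, sd = 0.02) {
  qnorm(runif(n, pnorm(-2), pnorm(2))) * sd
}

#' Initialize video-transformer parameters
#'
#' Truncated-normal (sd 0.02) projections and positional embeddings, zero
#' biases, unit LayerNorm gains. The output projection of every residual
#' branch (attention output and second MLP layer) starts at zero, so each
#' encoder block is the identity at initialization and the residual
#' branches grow as training demands them — this markedly speeds up
#' optimization on the short schedules used at desk scale. Uses the
#' current RNG state; seed it for reproducible initializations.
#'
#' @param cfg a [vt_config()].
#' @return Named list of parameter arrays.
#' @export
vt_init <- function(cfg) {
  G <- cfg$G
  tn <- function(nr, nc) matrix(.trunc_normal(nr * nc), nr, nc)
  zz <- function(nr, nc) matrix(0, nr, nc)
  p <- list(emb_W = tn(cfg$g, G), emb_b = numeric(G),
            pos = tn(cfg$n_tok, G))
  for (l in seq_len(cfg$L)) {
    pre <- paste0("b", l, ".")
    blk <- list(ln1_g = rep(1, G), ln1_b = numeric(G),
                sa_Wq = tn(G, G), sa_bq = numeric(G),
                sa_Wk = tn(G, G), sa_bk = numeric(G),
                sa_Wv = tn(G, G), sa_bv = numeric(G),
                sa_Wo = zz(G, G), sa_bo = numeric(G),
                ln2_g = rep(1, G), ln2_b = numeric(G),
                ta_Wq = tn(G, G), ta_bq = numeric(G),
                ta_Wk = tn(G, G), ta_bk = numeric(G),
                ta_Wv = tn(G, G), ta_bv = numeric(G),
                ta_Wo = zz(G, G), ta_bo = numeric(G),
                ln3_g = rep(1, G), ln3_b = numeric(G),
                mlp_W1 = tn(G, cfg$mlp_ratio * G), mlp_b1 = numeric(cfg$mlp_ratio * G),
                mlp_W2 = zz(cfg$mlp_ratio * G, G), mlp_b2 = numeric(G))
    names(blk) <- paste0(pre, names(blk))
    p <- c(p, blk)
  }
  c(p, list(lnf_g = rep(1, G), lnf_b = numeric(G),
            head_W1 = tn(G, G), head_b1 = numeric(G),
            head_W2 = tn(G, cfg$n_out), head_b2 = numeric(cfg$n_out)))
}

#' Number of trainable parameters
#' @param params a [vt_init()] result.
#' @return Integer parameter count.
#' @export
vt_n_params <- function(params) sum(vapply(params, length, 1L))

#' Extract tubelet tokens from a batch of videos
#'
#' Partitions each video into non-overlapping `t' x h x w x C` tubes and
#' flattens them, returning the raw token matrix (before projection).
#' Tokens are ordered spatial-index fastest (rows, then columns), then
#' temporal patch, then sample.
#'
#' @param videos array `B x T' x H x W x C` (a single video may omit the
#'   batch dimension).
#' @param cfg a [vt_config()].
#' @return Matrix `(n_s n_t B) x g`.
#' @export
tubelet_tokens <- function(videos, cfg) {
  if (length(dim(videos)) == 4) dim(videos) <- c(1, dim(videos))
  d <- dim(videos)
  if (!all(d[-1] == c(cfg$T_prime, cfg$H, cfg$W, cfg$C)))
    stop("video dimensions do not match the configuration")
  B <- d[1]
  Vp <- aperm(videos, c(2, 3, 4, 5, 1))
  dim(Vp) <- c(cfg$t_prime, cfg$n_t, cfg$h, cfg$n_h, cfg$w, cfg$n_w, cfg$C, B)
  Vp <- aperm(Vp, c(1, 3, 5, 7, 4, 6, 2, 8))
  dim(Vp) <- c(cfg$g, cfg$n_s * cfg$n_t * B)
  t(Vp)
}

# ---- primitive layers (forward caches what the backward pass needs) ----

# thin wrappers over the single-pass compiled primitives
.addb <- function(M, b) .addb_cpp(M, b)
.ln_fwd <- function(X, g, b, eps = 1e-6) .ln_fwd_cpp(X, g, b, eps)
.ln_bwd <- function(dY, cache, g) .ln_bwd_cpp(dY, cache$xhat, cache$inv, g)
.gelu_fwd <- function(x) .gelu_fwd_cpp(x)

.msa_fwd <- function(Zin, p, pre, cfg, B, spatial) {
  d <- cfg$G %/% cfg$n_heads
  Qm <- .addb(Zin %*% p[[paste0(pre, "Wq")]], p[[paste0(pre, "bq")]])
  Km <- .addb(Zin %*% p[[paste0(pre, "Wk")]], p[[paste0(pre, "bk")]])
  Vm <- .addb(Zin %*% p[[paste0(pre, "Wv")]], p[[paste0(pre, "bv")]])
  at <- .attn_fwd_cpp(Qm, Km, Vm, cfg$n_s, cfg$n_t, B, cfg$n_heads,
                      spatial, 1 / sqrt(d))
  Y <- .addb(at$O %*% p[[paste0(pre, "Wo")]], p[[paste0(pre, "bo")]])
  list(Y = Y, cache = list(Zin = Zin, Q = Qm, K = Km, V = Vm, A = at$A,
                           Om = at$O, spatial = spatial, B = B))
}

.msa_bwd <- function(dY, cache, p, pre, cfg) {
  d <- cfg$G %/% cfg$n_heads
  g <- list()
  g[[paste0(pre, "Wo")]] <- crossprod(cache$Om, dY)
  g[[paste0(pre, "bo")]] <- colSums(dY)
  dOm <- tcrossprod(dY, p[[paste0(pre, "Wo")]])
  bk <- .attn_bwd_cpp(cache$Q, cache$K, cache$V, cache$A, dOm,
                      cfg$n_s, cfg$n_t, cache$B, cfg$n_heads,
                      cache$spatial, 1 / sqrt(d))
  g[[paste0(pre, "Wq")]] <- crossprod(cache$Zin, bk$dQ)
  g[[paste0(pre, "bq")]] <- colSums(bk$dQ)
  g[[paste0(pre, "Wk")]] <- crossprod(cache$Zin, bk$dK)
  g[[paste0(pre, "bk")]] <- colSums(bk$dK)
  g[[paste0(pre, "Wv")]] <- crossprod(cache$Zin, bk$dV)
  g[[paste0(pre, "bv")]] <- colSums(bk$dV)
  dZin <- tcrossprod(bk$dQ, p[[paste0(pre, "Wq")]]) +
    tcrossprod(bk$dK, p[[paste0(pre, "Wk")]]) +
    tcrossprod(bk$dV, p[[paste0(pre, "Wv")]])
  list(dZin = dZin, grads = g)
}

# forward from a precomputed token matrix (training avoids re-extracting
# tubelets every epoch)
.vt_forward_tokens <- function(params, cfg, X, B, cache = FALSE) {
  Z <- .addb(X %*% params$emb_W, params$emb_b) +
    params$pos[rep(seq_len(cfg$n_tok), B), , drop = FALSE]
  cc <- if (cache) list(X = X, B = B) else NULL
  for (l in seq_len(cfg$L)) {
    pre <- paste0("b", l, ".")
    ln1 <- .ln_fwd(Z, params[[paste0(pre, "ln1_g")]], params[[paste0(pre, "ln1_b")]])
    sa <- .msa_fwd(ln1$Y, params, paste0(pre, "sa_"), cfg, B, TRUE)
    Z1 <- Z + sa$Y
    ln2 <- .ln_fwd(Z1, params[[paste0(pre, "ln2_g")]], params[[paste0(pre, "ln2_b")]])
    ta <- .msa_fwd(ln2$Y, params, paste0(pre, "ta_"), cfg, B, FALSE)
    Z2 <- Z1 + ta$Y
    ln3 <- .ln_fwd(Z2, params[[paste0(pre, "ln3_g")]], params[[paste0(pre, "ln3_b")]])
    H1 <- .addb(ln3$Y %*% params[[paste0(pre, "mlp_W1")]],
                params[[paste0(pre, "mlp_b1")]])
    gl <- .gelu_fwd(H1)
    Z3 <- Z2 + .addb(gl$Y %*% params[[paste0(pre, "mlp_W2")]],
                     params[[paste0(pre, "mlp_b2")]])
    if (cache) cc[[paste0("l", l)]] <-
        list(ln1 = ln1[-1], sa = sa$cache, ln2 = ln2[-1], ta = ta$cache,
             ln3 = ln3, H1 = H1, T1 = gl$Tn, Hg = gl$Y)
    Z <- Z3
  }
  lnf <- .ln_fwd(Z, params$lnf_g, params$lnf_b)
  Pool <- colMeans(array(lnf$Y, c(cfg$n_tok, B, cfg$G)), dims = 1)
  if (B == 1) Pool <- matrix(Pool, 1)
  Hh <- .addb(Pool %*% params$head_W1, params$head_b1)
  glh <- .gelu_fwd(Hh)
  out <- .addb(glh$Y %*% params$head_W2, params$head_b2)
  if (cache) {
    cc$lnf <- lnf[-1]
    cc$Pool <- Pool; cc$Hh <- Hh; cc$Th <- glh$Tn; cc$Hhg <- glh$Y
  }
  list(out = out, cache = cc)
}

#' Forward pass of the video transformer
#'
#' @param params parameter list from [vt_init()].
#' @param cfg a [vt_config()].
#' @param videos array `B x T' x H x W x C` (standardized input), or a
#'   single video without the batch dimension.
#' @param cache keep the intermediate activations needed by
#'   [vt_backward()] and by attention rollout.
#' @return List with `out` (`B x n_out` matrix of standardized predictions)
#'   and, if requested, `cache`.
#' @export
vt_forward <- function(params, cfg, videos, cache = FALSE) {
  if (length(dim(videos)) == 4) dim(videos) <- c(1, dim(videos))
  B <- dim(videos)[1]
  .vt_forward_tokens(params, cfg, tubelet_tokens(videos, cfg), B, cache)
}

#' Backward pass of the video transformer
#'
#' Analytic gradients of all parameters (and optionally of the raw input
#' tokens) given the gradient of a scalar loss with respect to the model
#' output.
#'
#' @param params,cfg as in [vt_forward()].
#' @param cache the cache returned by `vt_forward(..., cache = TRUE)`.
#' @param dOut `B x n_out` upstream gradient.
#' @param input_grad also return the gradient w.r.t. the raw tokens.
#' @return List `grads` (same names as `params`) and optionally `dX`.
#' @export
vt_backward <- function(params, cfg, cache, dOut, input_grad = FALSE) {
  B <- cache$B
  g <- list()
  g$head_W2 <- crossprod(cache$Hhg, dOut)
  g$head_b2 <- colSums(dOut)
  dHhg <- tcrossprod(dOut, params$head_W2)
  dHh <- .gelu_bwd_cpp(dHhg, cache$Hh, cache$Th)
  g$head_W1 <- crossprod(cache$Pool, dHh)
  g$head_b1 <- colSums(dHh)
  dPool <- tcrossprod(dHh, params$head_W1)
  # pooling: every token of sample b receives dPool[b, ] / n_tok
  dLnf <- dPool[rep(seq_len(B), each = cfg$n_tok), , drop = FALSE] / cfg$n_tok
  lb <- .ln_bwd(dLnf, cache$lnf, params$lnf_g)
  g$lnf_g <- lb$dg; g$lnf_b <- lb$db
  dZ <- lb$dX
  for (l in rev(seq_len(cfg$L))) {
    pre <- paste0("b", l, ".")
    cl <- cache[[paste0("l", l)]]
    # MLP sublayer
    dHg <- tcrossprod(dZ, params[[paste0(pre, "mlp_W2")]])
    g[[paste0(pre, "mlp_W2")]] <- crossprod(cl$Hg, dZ)
    g[[paste0(pre, "mlp_b2")]] <- colSums(dZ)
    dH1 <- .gelu_bwd_cpp(dHg, cl$H1, cl$T1)
    g[[paste0(pre, "mlp_W1")]] <- crossprod(cl$ln3$Y, dH1)
    g[[paste0(pre, "mlp_b1")]] <- colSums(dH1)
    dLn3 <- tcrossprod(dH1, params[[paste0(pre, "mlp_W1")]])
    lb <- .ln_bwd(dLn3, cl$ln3, params[[paste0(pre, "ln3_g")]])
    g[[paste0(pre, "ln3_g")]] <- lb$dg
    g[[paste0(pre, "ln3_b")]] <- lb$db
    dZ <- dZ + lb$dX
    # temporal attention sublayer
    mb <- .msa_bwd(dZ, cl$ta, params, paste0(pre, "ta_"), cfg)
    g <- c(g, mb$grads)
    lb <- .ln_bwd(mb$dZin, cl$ln2, params[[paste0(pre, "ln2_g")]])
    g[[paste0(pre, "ln2_g")]] <- lb$dg
    g[[paste0(pre, "ln2_b")]] <- lb$db
    dZ <- dZ + lb$dX
    # spatial attention sublayer
    mb <- .msa_bwd(dZ, cl$sa, params, paste0(pre, "sa_"), cfg)
    g <- c(g, mb$grads)
    lb <- .ln_bwd(mb$dZin, cl$ln1, params[[paste0(pre, "ln1_g")]])
    g[[paste0(pre, "ln1_g")]] <- lb$dg
    g[[paste0(pre, "ln1_b")]] <- lb$db
    dZ <- dZ + lb$dX
  }
  g$emb_W <- crossprod(cache$X, dZ)
  g$emb_b <- colSums(dZ)
  dpos <- colSums(aperm(array(dZ, c(cfg$n_tok, B, cfg$G)), c(2, 1, 3)), dims = 1)
  g$pos <- matrix(dpos, cfg$n_tok, cfg$G)
  out <- list(grads = g[names(params)])
  if (input_grad) out$dX <- tcrossprod(dZ, params$emb_W)
  out
}

# ---- importance maps ----

# head-averaged, identity-augmented, row-normalized attention matrices of
# one layer, for a single-sample cache (B = 1).
# A: n x n x (groups * heads), slice = g + groups * (h - 1)
.rollout_mats <- function(A, n, groups) {
  S <- dim(A)[3]
  heads <- S %/% groups
  out <- vector("list", groups)
  for (gi in seq_len(groups)) {
    Ab <- A[, , gi + groups * (seq_len(heads) - 1), drop = FALSE]
    M <- apply(Ab, c(1, 2), mean) + diag(n)
    out[[gi]] <- M / rowSums(M)
  }
  out
}

#' Temporal and spatial importance maps
#'
#' Attention-rollout attribution of the model output to the input tokens.
#' Per encoder block the head-averaged attention is augmented with the
#' identity (the residual path), row-normalized, and composed across the
#' `L` blocks; the column mass received, averaged over the pooled output
#' tokens, scores each source token. Temporal importance (TI) composes the
#' temporal attention blocks (averaged over spatial groups); spatial
#' importance (SI) composes the spatial blocks per temporal patch. Both are
#' nonnegative and normalized to sum to one (per patch for SI). The
#' `"saliency"` backend instead uses gradient-times-input magnitudes from
#' the analytic backward pass; it satisfies the same normalization
#' contract. Maps from an untrained model are valid but carry no signal.
#'
#' @param params,cfg model parameters and configuration.
#' @param video one standardized video `T' x H x W x C`.
#' @param backend `"rollout"` (default) or `"saliency"`.
#' @return An object of class `importance_maps`: `TI` (length `n_t`), `SI`
#'   (`n_t x n_h x n_w`), and `SI_pixel` (`n_t x H x W`; tubelet values
#'   spread uniformly over their pixels, each temporal slice summing to 1).
#' @export
vt_importance <- function(params, cfg, video,
                          backend = c("rollout", "saliency"),
                          null_video = NULL) {
  backend <- match.arg(backend)
  fw <- vt_forward(params, cfg, video, cache = TRUE)
  if (backend == "rollout") {
    Rt <- diag(cfg$n_t)
    Rs <- rep(list(diag(cfg$n_s)), cfg$n_t)
    for (l in seq_len(cfg$L)) {
      cl <- fw$cache[[paste0("l", l)]]
      # temporal rollout pools attention over spatial groups and heads
      At <- .rollout_mats(cl$ta$A, cfg$n_t, 1)[[1]]
      Rt <- At %*% Rt
      As <- .rollout_mats(cl$sa$A, cfg$n_s, cfg$n_t)
      for (tt in seq_len(cfg$n_t)) Rs[[tt]] <- As[[tt]] %*% Rs[[tt]]
    }
    TI <- colMeans(Rt)
    SI <- t(vapply(Rs, colMeans, numeric(cfg$n_s)))
  } else {
    bw <- vt_backward(params, cfg, fw$cache, matrix(1, 1, cfg$n_out),
                      input_grad = TRUE)
    ref <- if (is.null(null_video)) 0 else tubelet_tokens(null_video, cfg)
    contrib <- abs(bw$dX * (fw$cache$X - ref))
    score <- rowSums(contrib)
    sc <- matrix(score, cfg$n_s, cfg$n_t)
    TI <- colSums(sc)
    SI <- t(sc)
    # gradient-times-input attributes within tubelets as well: fold each
    # token's feature contributions back onto its member pixels
    SIp <- array(0, c(cfg$n_t, cfg$H, cfg$W))
    for (i in seq_len(nrow(contrib))) {
      s <- (i - 1) %% cfg$n_s
      tt <- (i - 1) %/% cfg$n_s + 1
      rh <- s %% cfg$n_h + 1
      rw <- s %/% cfg$n_h + 1
      block <- array(contrib[i, ], c(cfg$t_prime, cfg$h, cfg$w, cfg$C))
      px <- apply(block, c(2, 3), sum)
      SIp[tt, (rh - 1) * cfg$h + seq_len(cfg$h),
          (rw - 1) * cfg$w + seq_len(cfg$w)] <-
        SIp[tt, (rh - 1) * cfg$h + seq_len(cfg$h),
            (rw - 1) * cfg$w + seq_len(cfg$w)] + px
    }
    SIp <- SIp / apply(SIp, 1, sum)
  }
  TI <- TI / sum(TI)
  SI <- SI / rowSums(SI)
  dim(SI) <- c(cfg$n_t, cfg$n_h, cfg$n_w)
  if (backend == "rollout") {
    # rollout resolves tokens only: spread each tubelet's mass uniformly
    # over its pixels
    SIp <- array(0, c(cfg$n_t, cfg$H, cfg$W))
    for (r in seq_len(cfg$H)) for (cc in seq_len(cfg$W)) {
      SIp[, r, cc] <- SI[, (r - 1) %/% cfg$h + 1, (cc - 1) %/% cfg$w + 1] /
        (cfg$h * cfg$w)
    }
  }
  structure(list(TI = TI, SI = SI, SI_pixel = SIp, backend = backend),
            class = "importance_maps")
}

#' @export
print.importance_maps <- function(x, ...) {
  cat("Importance maps (", x$backend, "): TI over ", length(x$TI),
      " temporal patches, SI ", paste(dim(x$SI), collapse = " x "), "\n",
      sep = "")
  cat("TI:", paste(sprintf("%.3f", x$TI), collapse = " "), "\n")
  invisible(x)
}

#' Most important whiskers in a temporal patch
#'
#' Ranks the mapped (non-null) pixels of the sensing grid by pixel-level
#' spatial importance in the given temporal patch; null pixels are never
#' returned and ties are broken by whisker id.
#'
#' @param imp a [vt_importance()] result.
#' @param grid_map the [map_to_grid()] used to build the video.
#' @param k how many whiskers.
#' @param patch temporal patch index.
#' @return Data frame (id, row, col, SI) in decreasing importance.
#' @export
top_whiskers <- function(imp, grid_map, k = 5, patch = 1) {
  stopifnot(inherits(imp, "importance_maps"))
  if (patch < 1 || patch > dim(imp$SI_pixel)[1]) stop("patch out of range")
  asg <- grid_map$assignment
  if (k > nrow(asg)) stop("k exceeds the number of mapped whiskers")
  si <- imp$SI_pixel[patch, , ][cbind(asg$row, asg$col)]
  ord <- order(-si, asg$id)
  out <- data.frame(id = asg$id[ord], row = asg$row[ord], col = asg$col[ord],
                    SI = si[ord])
  head(out, k)
}

# shape contract of the unfactorized (joint-attention) baseline: all
# spatio-temporal tokens attend jointly, so one group of n_tok tokens per
# sample; used as a reference in unit tests only
.joint_attention_shapes <- function(cfg, B = 1) {
  list(tokens = cfg$n_tok * B, groups = B,
       attention_dim = c(cfg$n_tok, cfg$n_tok, B * cfg$n_heads))
}
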