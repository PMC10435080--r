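tiny_cfg <- function(L = 2, G = 8, heads = 2)
  vt_config(T_prime = 4, H = 2, W = 3, C = 2, t_prime = 2, h = 1, w = 1,
            L = L, G = G, n_heads = heads, mlp_ratio = 2)

test_that("tubelet arithmetic matches the configuration contract", {
  cfg <- vt_config()  # full-scale defaults
  expect_equal(cfg$n_t, 10)    # 80 frames / 8 per tubelet
  expect_equal(cfg$n_s, 198)   # 9 x 22 with 1 x 1 spatial tubelets
  expect_equal(cfg$g, 32)      # 8 * 1 * 1 * 4
  expect_error(vt_config(T_prime = 81), "divisible")
  expect_error(vt_config(G = 95), "divisible")
})

test_that("tubelet extraction flattens tubes losslessly", {
  cfg <- tiny_cfg()
  set.seed(1)
  vid <- array(rnorm(4 * 2 * 3 * 2), c(4, 2, 3, 2))
  X <- tubelet_tokens(vid, cfg)
  expect_equal(dim(X), c(cfg$n_tok, cfg$g))
  # token for spatial (r=2, c=3), temporal patch 2 holds frames 3:4 there
  s <- 2 + 2 * (3 - 1)           # row-fastest spatial index
  tok <- X[s + cfg$n_s * (2 - 1), ]
  expect_setequal(tok, as.vector(vid[3:4, 2, 3, ]))
  expect_equal(max(abs(tubelet_tokens(vid * 0, cfg))), 0)
})

test_that("forward pass is deterministic with the contracted output shape", {
  cfg <- tiny_cfg()
  set.seed(2)
  params <- vt_init(cfg)
  vids <- array(rnorm(3 * prod(c(4, 2, 3, 2))), c(3, 4, 2, 3, 2))
  o1 <- vt_forward(params, cfg, vids)$out
  o2 <- vt_forward(params, cfg, vids)$out
  expect_identical(o1, o2)
  expect_equal(dim(o1), c(3, 4))
})

test_that("attention rows are a probability distribution", {
  set.seed(3)
  n_s <- 5; n_t <- 3; B <- 2; heads <- 2; G <- 8
  N <- n_s * n_t * B
  Q <- matrix(rnorm(N * G), N, G)
  K <- matrix(rnorm(N * G), N, G)
  V <- matrix(rnorm(N * G), N, G)
  for (spatial in c(TRUE, FALSE)) {
    at <- whiskerVT:::.attn_fwd_cpp(Q, K, V, n_s, n_t, B, heads, spatial, 0.5)
    sums <- apply(at$A, 3, rowSums)
    expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-12)
    expect_true(all(at$A >= 0))
  }
})

test_that("spatial blocks never mix across time; temporal never across space", {
  cfg <- tiny_cfg(L = 1)
  set.seed(4)
  params <- vt_init(cfg)
  # move off the identity-block initialization so the mixing is visible
  params <- lapply(params, function(p) p + rnorm(length(p), sd = 0.05))
  N <- cfg$n_tok
  Z <- matrix(rnorm(N * cfg$G), N, cfg$G)
  Z2 <- Z
  # perturb all tokens of temporal patch 2
  rows_t2 <- cfg$n_s * (2 - 1) + seq_len(cfg$n_s)
  Z2[rows_t2, ] <- Z2[rows_t2, ] + 1
  o1 <- whiskerVT:::.msa_fwd(Z, params, "b1.sa_", cfg, 1, TRUE)$Y
  o2 <- whiskerVT:::.msa_fwd(Z2, params, "b1.sa_", cfg, 1, TRUE)$Y
  expect_equal(o1[-rows_t2, ], o2[-rows_t2, ], tolerance = 1e-12)
  expect_gt(max(abs(o1[rows_t2, ] - o2[rows_t2, ])), 0)
  # perturb one spatial index across all times
  Z3 <- Z
  rows_s3 <- 3 + cfg$n_s * (seq_len(cfg$n_t) - 1)
  Z3[rows_s3, ] <- Z3[rows_s3, ] + 1
  o1t <- whiskerVT:::.msa_fwd(Z, params, "b1.ta_", cfg, 1, FALSE)$Y
  o3t <- whiskerVT:::.msa_fwd(Z3, params, "b1.ta_", cfg, 1, FALSE)$Y
  expect_equal(o1t[-rows_s3, ], o3t[-rows_s3, ], tolerance = 1e-12)
})

test_that("single-token groups reduce attention to the identity mixing", {
  # one spatial token: the softmax over a single entry is 1
  cfg1 <- vt_config(T_prime = 4, H = 2, W = 3, C = 2, t_prime = 2,
                    h = 2, w = 3, L = 1, G = 8, n_heads = 2, mlp_ratio = 2)
  expect_equal(cfg1$n_s, 1)
  set.seed(5)
  params <- vt_init(cfg1)
  Z <- matrix(rnorm(cfg1$n_tok * 8), cfg1$n_tok, 8)
  sa <- whiskerVT:::.msa_fwd(Z, params, "b1.sa_", cfg1, 1, TRUE)
  expect_equal(max(abs(sa$cache$A - 1)), 0, tolerance = 1e-12)
  expect_equal(sa$cache$Om, sa$cache$V, tolerance = 1e-12)
  # one temporal patch: TI is trivially [1]
  cfgt <- vt_config(T_prime = 4, H = 2, W = 3, C = 2, t_prime = 4,
                    h = 1, w = 1, L = 1, G = 8, n_heads = 2, mlp_ratio = 2)
  vid <- array(rnorm(4 * 2 * 3 * 2), c(4, 2, 3, 2))
  imp <- vt_importance(vt_init(cfgt), cfgt, vid)
  expect_equal(imp$TI, 1)
})

test_that("analytic gradients match central differences", {
  cfg <- tiny_cfg()
  set.seed(42)
  params <- vt_init(cfg)
  # perturb away from the identity-block initialization so every gradient
  # path (including through the zero-initialized output projections) is
  # exercised
  params <- lapply(params, function(p) p + rnorm(length(p), sd = 0.05))
  B <- 2
  vids <- array(rnorm(B * prod(c(4, 2, 3, 2))), c(B, 4, 2, 3, 2))
  y <- matrix(rnorm(B * 4), B, 4)
  lossfn <- function(p) mean((vt_forward(p, cfg, vids)$out - y)^2)
  fw <- vt_forward(params, cfg, vids, cache = TRUE)
  dOut <- 2 * (fw$out - y) / length(y)
  bw <- vt_backward(params, cfg, fw$cache, dOut)
  set.seed(7)
  eps <- 1e-4
  for (nm in names(params)) {
    idx <- sample(length(params[[nm]]), min(2, length(params[[nm]])))
    for (ii in idx) {
      p2 <- params; p2[[nm]][ii] <- p2[[nm]][ii] + eps
      p3 <- params; p3[[nm]][ii] <- p3[[nm]][ii] - eps
      num <- (lossfn(p2) - lossfn(p3)) / (2 * eps)
      ana <- bw$grads[[nm]][ii]
      expect_lt(abs(num - ana) / max(abs(num) + abs(ana), 1e-6), 1e-4)
    }
  }
})

test_that("token count is conserved and parameters are config-determined", {
  cfg <- tiny_cfg()
  set.seed(6)
  p1 <- vt_init(cfg)
  p2 <- vt_init(cfg)
  expect_equal(vt_n_params(p1), vt_n_params(p2))
  # longer videos only add positional embeddings
  cfg2 <- vt_config(T_prime = 8, H = 2, W = 3, C = 2, t_prime = 2,
                    h = 1, w = 1, L = 2, G = 8, n_heads = 2, mlp_ratio = 2)
  p3 <- vt_init(cfg2)
  expect_equal(vt_n_params(p3) - vt_n_params(p1),
               (cfg2$n_tok - cfg$n_tok) * cfg$G)
  # every block preserves the token count
  fw <- vt_forward(p1, cfg, array(rnorm(48), c(4, 2, 3, 2)), cache = TRUE)
  expect_equal(nrow(fw$cache$l1$sa$Zin), cfg$n_tok)
  expect_equal(nrow(fw$cache$l2$ta$Zin), cfg$n_tok)
})

test_that("uniform attention yields uniform rollout importance", {
  cfg <- tiny_cfg()
  set.seed(8)
  params <- vt_init(cfg)
  for (l in 1:2) for (at in c("sa_", "ta_")) {
    params[[paste0("b", l, ".", at, "Wq")]][] <- 0
    params[[paste0("b", l, ".", at, "Wk")]][] <- 0
    params[[paste0("b", l, ".", at, "bq")]][] <- 0
    params[[paste0("b", l, ".", at, "bk")]][] <- 0
  }
  vid <- array(rnorm(48), c(4, 2, 3, 2))
  imp <- vt_importance(params, cfg, vid)
  expect_equal(imp$TI, rep(1 / cfg$n_t, cfg$n_t), tolerance = 1e-12)
  expect_equal(as.vector(imp$SI), rep(1 / cfg$n_s, cfg$n_t * cfg$n_s),
               tolerance = 1e-12)
})

test_that("importance maps are normalized for both backends", {
  cfg <- tiny_cfg()
  set.seed(9)
  params <- vt_init(cfg)
  vid <- array(rnorm(48), c(4, 2, 3, 2))
  for (be in c("rollout", "saliency")) {
    imp <- vt_importance(params, cfg, vid, backend = be)
    expect_true(all(imp$TI >= 0))
    expect_true(all(imp$SI >= 0))
    expect_equal(sum(imp$TI), 1, tolerance = 1e-6)
    expect_equal(rowSums(matrix(imp$SI, cfg$n_t)), rep(1, cfg$n_t),
                 tolerance = 1e-6)
    expect_equal(apply(imp$SI_pixel, 1, sum), rep(1, cfg$n_t),
                 tolerance = 1e-6)
  }
})

test_that("saliency importance localizes a single informative patch", {
  # labels depend only on the content of temporal patch 2: a model trained
  # on such data must attribute its output there
  cfg <- vt_config(T_prime = 8, H = 2, W = 2, C = 1, t_prime = 2, h = 1,
                   w = 1, L = 2, G = 8, n_heads = 2, mlp_ratio = 2)
  set.seed(10)
  n <- 48
  vids <- array(0, c(n, 8, 2, 2, 1))
  lab <- runif(n, -1, 1)
  vids[, 3:4, , , ] <- array(rep(lab, 8), c(n, 2, 2, 2, 1))  # patch 2 only
  ds <- structure(list(videos = vids,
                       labels = data.frame(X = lab * 120, Y = 100 + 0 * lab,
                                           alpha = 0 * lab, beta = 0 * lab),
                       grid_map = NULL, meta = list()),
                  class = "wvt_dataset")
  ctl <- vt_control(epochs = 60, batch_size = 16, lr = 3e-3, seed = 1)
  fit <- wvt_fit(ds, cfg, ctl)
  expect_lt(tail(fit$history$train_mse, 1), fit$history$train_mse[1] / 5)
  imp <- importance(fit, array(vids[1, , , , ], c(8, 2, 2, 1)),
                    backend = "saliency")
  expect_equal(which.max(imp$TI), 2)
})

test_that("top whiskers respect the null-pixel mask and tie-break order", {
  gm <- fx_grid_map()
  n_t <- 3
  SIp <- array(1, c(n_t, 9, 22))
  SIp <- SIp / sum(SIp[1, , ])
  imp <- structure(list(TI = rep(1 / n_t, n_t), SI = NULL, SI_pixel = SIp,
                        backend = "rollout"), class = "importance_maps")
  top <- top_whiskers(imp, gm, k = 5, patch = 1)
  expect_equal(top$id, sort(gm$assignment$id)[1:5])  # pure tie-break
  # mass concentrated on one mapped whisker wins
  asg <- gm$assignment
  SIp2 <- array(0, c(n_t, 9, 22))
  SIp2[, asg$row[10], asg$col[10]] <- 1
  imp2 <- imp; imp2$SI_pixel <- SIp2
  expect_equal(top_whiskers(imp2, gm, 1, 2)$id, asg$id[10])
  # a hot null pixel must never be returned
  occupied <- matrix(FALSE, 9, 22)
  occupied[cbind(asg$row, asg$col)] <- TRUE
  null_rc <- which(!occupied, arr.ind = TRUE)[1, ]
  SIp3 <- SIp
  SIp3[, null_rc[1], null_rc[2]] <- 100
  imp3 <- imp; imp3$SI_pixel <- SIp3
  expect_false(any(is.na(match(top_whiskers(imp3, gm, 88, 1)$id, asg$id))))
  expect_error(top_whiskers(imp, gm, 5, patch = 99), "out of range")
  expect_error(top_whiskers(imp, gm, 89, 1), "exceeds")
})

test_that("the joint-attention reference would use one global token group", {
  cfg <- tiny_cfg()
  ref <- whiskerVT:::.joint_attention_shapes(cfg)
  expect_equal(ref$tokens, cfg$n_tok)
  expect_equal(ref$groups, 1)
  expect_equal(ref$attention_dim[1:2], rep(cfg$n_tok, 2))
})
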