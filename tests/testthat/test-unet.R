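test_that("configuration contracts are enforced", {
  expect_error(unet_config(depth = 1), "depth")
  expect_error(unet_config(out_classes = 1), "out_classes")
  expect_error(unet_config(depth = 3, patch_size = c(30, 32, 32)), "divisible")
  cfg <- unet_config(depth = 3, patch_size = 32)
  expect_identical(cfg$patch_size, c(32L, 32L, 32L))
})

test_that("forward pass emits a probability simplex and survives zero input", {
  cfg <- unet_config(depth = 3, base_channels = 4, out_classes = 3,
                     patch_size = c(16, 16, 16), seed = 1)
  set.seed(1)
  params <- aortaseg:::init_unet_params(cfg)
  fw <- aortaseg:::unet_forward(params, cfg, array(rnorm(16^3), c(16, 16, 16)))
  expect_equal(dim(fw$probs), c(16L, 16L, 16L, 3L))
  expect_lt(max(abs(apply(fw$probs, 1:3, sum) - 1)), 1e-12)
  fw0 <- aortaseg:::unet_forward(params, cfg, array(0, c(16, 16, 16)))
  expect_true(all(is.finite(fw0$probs)))
  # deterministic forward
  fw2 <- aortaseg:::unet_forward(params, cfg, array(0, c(16, 16, 16)))
  expect_identical(fw0$probs, fw2$probs)
})

test_that("attention gate coefficients lie in [0,1] with identity/zero limits", {
  set.seed(2)
  skip <- array(rnorm(8 * 8 * 8 * 4), c(8, 8, 8, 4))
  gating <- array(rnorm(4 * 4 * 4 * 4), c(4, 4, 4, 4))
  w <- list(Wx = matrix(rnorm(8), 4, 2), Wg = matrix(rnorm(8), 4, 2),
            bg = rnorm(2), psi = matrix(rnorm(2), 2, 1), bpsi = 0)
  g <- attention_gate(skip, gating, w)
  expect_true(all(g$alpha >= 0 & g$alpha <= 1))
  expect_equal(dim(g$gated), dim(skip))
  # bias override: alpha forced to ~1 reproduces the skip input
  w1 <- modifyList(w, list(psi = matrix(0, 2, 1), bpsi = 30))
  g1 <- attention_gate(skip, gating, w1)
  expect_equal(g1$gated, skip, tolerance = 1e-9)
  # alpha forced to ~0 zeroes the output
  w0 <- modifyList(w, list(psi = matrix(0, 2, 1), bpsi = -30))
  g0 <- attention_gate(skip, gating, w0)
  expect_lt(max(abs(g0$gated)), 1e-9)
  # irreconcilable shapes rejected
  expect_error(attention_gate(skip, array(0, c(3, 3, 3, 4)), w), "shape")
})

test_that("soft Dice loss identities and a hand computation hold", {
  tg <- array(c(0L, 1L, 2L, 0L, 1L, 2L, 0L, 1L), c(2, 2, 2))
  oh <- aortaseg:::one_hot(tg, 3L)
  expect_lt(soft_dice_loss(oh, tg), 1e-4)
  # uniform 1/3 prediction, evaluated by hand on the 8 voxels:
  # class 1: A = 3/3 = 1, D = 8/3 + 3; class 2: A = 2/3, D = 8/3 + 2
  unif <- array(1 / 3, c(2, 2, 2, 3))
  s1 <- (2 * 1 + 1e-5) / (8 / 3 + 3 + 1e-5)
  s2 <- (2 * 2 / 3 + 1e-5) / (8 / 3 + 2 + 1e-5)
  expect_equal(soft_dice_loss(unif, tg), 1 - (s1 + s2) / 2, tolerance = 1e-12)
  # disjoint hard prediction
  wrong <- aortaseg:::one_hot(array(2L - tg, c(2, 2, 2)) * 0L +
                                ifelse(tg == 1L, 2L, 1L), 3L)
  expect_gt(soft_dice_loss(wrong, tg), 0.999)
  # empty class in both prediction and target contributes 0 (Dice 1)
  bg <- array(0L, c(2, 2, 2))
  none <- aortaseg:::one_hot(bg, 3L)
  expect_equal(soft_dice_loss(none, bg), 0)
})

test_that("soft Dice on hard predictions equals 1 - mean dice_score", {
  set.seed(4)
  for (rep in 1:5) {
    a <- array(sample(0:2, 6^3, TRUE), c(6, 6, 6))
    b <- array(sample(0:2, 6^3, TRUE), c(6, 6, 6))
    soft <- soft_dice_loss(aortaseg:::one_hot(a, 3L), b)
    ma <- label_mask(a); mb <- label_mask(b)
    hard <- 1 - mean(c(dice_score(ma, mb, 1L), dice_score(ma, mb, 2L)))
    expect_equal(soft, hard, tolerance = 1e-4)
  }
})

test_that("analytic gradients match finite differences on a tiny network", {
  cfg <- unet_config(depth = 2, base_channels = 2, out_classes = 3,
                     patch_size = c(8, 8, 8), seed = 42)
  set.seed(42)
  params <- aortaseg:::init_unet_params(cfg)
  x <- array(rnorm(8^3), c(8, 8, 8))
  tg <- array(sample(0:2, 512, TRUE), c(8, 8, 8))
  fw <- aortaseg:::unet_forward(params, cfg, x, keep_cache = TRUE)
  lg <- aortaseg:::loss_grad_logits(fw$probs, tg)
  gr <- aortaseg:::unet_backward(params, cfg, fw$cache, lg$gz)
  lossf <- function(p)
    soft_dice_loss(aortaseg:::unet_forward(p, cfg, x)$probs, tg)
  h <- 1e-5
  for (nm in names(params)) {
    q <- sample(length(params[[nm]]), 1)
    p2 <- params
    p2[[nm]][q] <- p2[[nm]][q] + h; up <- lossf(p2)
    p2[[nm]][q] <- p2[[nm]][q] - 2 * h; dn <- lossf(p2)
    num <- (up - dn) / (2 * h)
    expect_lt(abs(num - gr[[nm]][q]) / max(1e-6, abs(num) + abs(gr[[nm]][q])),
              5e-3)
  }
})

test_that("with the gate held open the attention net matches the plain U-Net", {
  cfg_a <- unet_config(depth = 2, base_channels = 2, out_classes = 2,
                       patch_size = c(8, 8, 8), attention = TRUE, seed = 3)
  cfg_p <- unet_config(depth = 2, base_channels = 2, out_classes = 2,
                       patch_size = c(8, 8, 8), attention = FALSE, seed = 3)
  set.seed(3)
  pa <- aortaseg:::init_unet_params(cfg_a)
  # force alpha = 1 everywhere
  pa[["dec1.att.psi"]][] <- 0
  pa[["dec1.att.bpsi"]][] <- 50
  pp <- pa[setdiff(names(pa), grep("att", names(pa), value = TRUE))]
  x <- array(rnorm(8^3), c(8, 8, 8))
  fa <- aortaseg:::unet_forward(pa, cfg_a, x)
  fp <- aortaseg:::unet_forward(pp, cfg_p, x)
  expect_equal(fa$probs, fp$probs, tolerance = 1e-9)
})

test_that("training is reproducible and prediction deterministic", {
  set.seed(10)
  mk <- function() {
    img <- array(rnorm(12^3, 0.2, 0.05), c(12, 12, 12))
    lab <- array(0L, c(12, 12, 12)); lab[5:8, 5:8, 5:8] <- 1L
    img[lab == 1L] <- img[lab == 1L] + 0.6
    list(img = ct_volume(img), mask = label_mask(lab))
  }
  cases <- list(mk(), mk())
  cfg <- unet_config(depth = 2, base_channels = 2, out_classes = 2,
                     patch_size = c(8, 8, 8), epochs = 2,
                     patches_per_case = 1, seed = 11)
  f1 <- fit_unet(cases, cfg)
  f2 <- fit_unet(cases, cfg)
  expect_equal(f1$history$train_loss, f2$history$train_loss, tolerance = 1e-12)
  expect_identical(coef(f1)[["final.W"]], coef(f2)[["final.W"]])
  p1 <- predict(f1, cases[[1]]$img)
  p2 <- predict(f1, cases[[1]]$img)
  expect_identical(p1$probs, p2$probs)
  expect_lt(max(abs(apply(p1$probs, 1:3, sum) - 1)), 1e-9)
  expect_s3_class(prob_argmax(p1), "label_mask")
  expect_error(fit_unet(list(list(img = cases[[1]]$img,
                                  mask = label_mask(array(0L, c(12, 12, 12))))),
                        cfg), "at least 2|foreground")
})
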