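makeTwoGroupExpr <- function(n_per = 10, p = 200, n_signal = 10, effect = 3,
                             seed = 50) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per * p), 2 * n_per, p,
              dimnames = list(NULL, sprintf("g%04d", 1:p)))
  lab <- factor(rep(c("HFE", "LFE"), each = n_per))
  X[lab == "LFE", seq_len(n_signal)] <- X[lab == "LFE", seq_len(n_signal)] + effect
  list(X = X, labels = lab, signal = colnames(X)[seq_len(n_signal)])
}

test_that("keepX = p reproduces dense PLS-DA loadings", {
  d <- makeTwoGroupExpr(p = 60)
  p <- ncol(d$X)
  sparse <- splsdaFit(d$X, d$labels, ncomp = 2, keepX = c(p, p))
  # dense oracle: the same NIPALS construction with no thresholding, written
  # out directly
  Xc <- scale(d$X)
  Y <- scale(model.matrix(~ 0 + d$labels), scale = FALSE)
  dense <- matrix(0, p, 2)
  Xd <- Xc; Yd <- Y
  for (h in 1:2) {
    sv <- svd(crossprod(Xd, Yd), nu = 1, nv = 1)
    u <- sv$u[, 1]
    tt <- Xd %*% u
    if (sum(tt * ifelse(d$labels == "HFE", 1, -1)) < 0) { u <- -u; tt <- -tt }
    cl <- crossprod(Xd, tt) / sum(tt^2)
    Xd <- Xd - tt %*% t(cl)
    Yd <- Yd - tt %*% t(crossprod(Yd, tt) / sum(tt^2))
    dense[, h] <- u
  }
  expect_equal(unname(sparse$loadings), dense, tolerance = 1e-6)
})

test_that("sPLS-DA agrees with the reference mixOmics implementation", {
  skip_if_not_installed("mixOmics")
  d <- makeTwoGroupExpr(p = 80)
  fit <- splsdaFit(d$X, d$labels, ncomp = 2, keepX = c(10, 10))
  mo <- mixOmics::splsda(d$X, d$labels, ncomp = 2, keepX = c(10, 10))
  mo_sel <- rownames(mo$loadings$X)[mo$loadings$X[, 1] != 0]
  expect_setequal(fit$selected[[1]], mo_sel)
  common <- fit$selected[[1]]
  expect_gt(abs(cor(fit$loadings[common, 1], mo$loadings$X[common, 1])), 0.999)
})

test_that("selected gene counts equal keepX exactly", {
  d <- makeTwoGroupExpr()
  fit <- splsdaFit(d$X, d$labels, ncomp = 2, keepX = c(7, 13))
  expect_length(fit$selected[[1]], 7)
  expect_length(fit$selected[[2]], 13)
  expect_error(splsdaFit(d$X, d$labels, keepX = ncol(d$X) + 1), "exceed")
})

test_that("planted discriminating genes are recovered with low BER", {
  hits <- ber1 <- numeric(8)
  for (i in 1:8) {
    d <- makeTwoGroupExpr(p = 400, n_signal = 10, effect = 3, seed = 60 + i)
    fit <- splsdaFit(d$X, d$labels, ncomp = 1, keepX = 10, reps = 3,
                     seed = 60 + i)
    hits[i] <- length(intersect(fit$selected[[1]], d$signal))
    ber1[i] <- fit$ber[1]
  }
  expect_gte(mean(hits), 8)
  expect_lte(mean(ber1), 0.15)
})

test_that("permuted labels give chance-level cross-validated BER", {
  set.seed(70)
  d <- makeTwoGroupExpr(p = 100, n_signal = 0)
  bers <- sapply(1:5, function(i) {
    lab <- sample(d$labels)
    splsdaFit(d$X, lab, ncomp = 1, keepX = 10, reps = 2, seed = i)$ber[1]
  })
  expect_lt(abs(mean(bers) - 0.5), 0.12)
})

test_that("rCCA reduces to the multiple correlation for one unpenalized trait", {
  set.seed(71)
  n <- 30; p <- 12
  Y <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("g%02d", 1:p)))
  x <- matrix(Y[, 1] + rnorm(n), n, 1, dimnames = list(NULL, "RFI"))
  rc <- rccaFit(Y, x, lambda1 = 0, lambda2 = 0)
  R2 <- summary(lm(scale(x) ~ scale(Y)))$r.squared
  expect_equal(rc$cancor[1], sqrt(R2), tolerance = 1e-8)
})

test_that("rCCA satisfies its structural invariants", {
  set.seed(72)
  n <- 40; p <- 30; q <- 4
  Y <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("g%02d", 1:p)))
  X <- matrix(rnorm(n * q), n, q,
              dimnames = list(NULL, c("RFI", "FCR", "ADG", "ADFI")))
  rc <- rccaFit(Y, X)
  expect_true(all(rc$cancor >= 0 & rc$cancor <= 1))
  expect_true(all(diff(rc$cancor) <= 1e-10))
  # canonical correlations invariant to gene reordering
  perm <- sample(p)
  rc2 <- rccaFit(Y[, perm], X, lambda1 = rc$lambda1, lambda2 = rc$lambda2)
  expect_equal(rc$cancor, rc2$cancor, tolerance = 1e-8)
  # duplicating X as Y gives perfect correlation at lambda = 0
  rc3 <- rccaFit(X, X, lambda1 = 0, lambda2 = 0)
  expect_equal(rc3$cancor, rep(1, 4), tolerance = 1e-8)
  expect_error(rccaFit(Y, X, lambda1 = -1), "non-negative")
  expect_error(rccaFit(Y[1:2, ], X[1:2, ]), "at least 3")
})

test_that("rCCA canonical correlations match the reference implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(73)
  n <- 25; p <- 40; q <- 3
  Y <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("g%02d", 1:p)))
  X <- matrix(rnorm(n * q), n, q)
  rc <- rccaFit(Y, X, lambda1 = 0.15, lambda2 = 0.2, ncomp = 3)
  mo <- mixOmics::rcc(scale(X), scale(Y), lambda1 = 0.15, lambda2 = 0.2,
                      ncomp = 3)
  expect_equal(rc$cancor, unname(mo$cor[1:3]), tolerance = 1e-6)
})

test_that("genes correlated with the efficiency traits pass median + 2SD selection", {
  recovered <- sapply(1:6, function(i) {
    set.seed(80 + i)
    n <- 60; p <- 500
    planted <- sprintf("g%04d", 1:30)
    Y <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("g%04d", 1:p)))
    rfi <- rnorm(n)
    Y[, planted] <- sqrt(0.5) * matrix(rfi, n, 30) + sqrt(0.5) * Y[, planted]
    X <- cbind(RFI = rfi, FCR = 0.7 * rfi + rnorm(n, 0, 0.7),
               ADG = rnorm(n), ADFI = rnorm(n))
    rc <- rccaFit(Y, X, select_pop = "all")
    mean(planted %in% rc$selected)
  })
  expect_gte(mean(recovered), 0.7)
})

test_that("candidate integration flags method overlaps and loading concordance", {
  de <- data.frame(gene = c("g1", "g2", "g3", "g4", "g5"),
                   de = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  L <- matrix(0.1, 5, 1, dimnames = list(de$gene, "comp1"))
  spls <- list(loadings = L, selected = list(c("g2", "g3", "g4")))
  B <- matrix(0.2, 5, 1, dimnames = list(de$gene, "CC1"))
  rcca <- list(trait_cor = B, ycoef = B, selected = c("g3", "g5"))
  out <- integrateCandidates(de, spls, rcca, min_methods = 2)
  expect_setequal(out$candidates, c("g2", "g3"))
  expect_setequal(out$table$gene[out$table$n_methods == 3], "g3")
  # identical loading vectors over common genes give concordance 1 when
  # there are enough genes
  spls2 <- list(loadings = L, selected = list(de$gene))
  set.seed(90)
  B2 <- matrix(rnorm(5), 5, 1, dimnames = list(de$gene, "CC1"))
  rcca2 <- list(trait_cor = B2, ycoef = B2, selected = de$gene)
  spls2$loadings <- B2
  out2 <- integrateCandidates(de, spls2, rcca2)
  expect_equal(out2$concordance, 1)
})

test_that("sPLS-DA and rCCA loadings concord on planted-signal data", {
  pos <- sapply(1:5, function(i) {
    # plant both up- and down-regulated genes so loadings span both signs
    d <- makeTwoGroupExpr(p = 150, n_signal = 15, effect = 2, seed = 200 + i)
    down <- d$signal[1:7]
    d$X[d$labels == "LFE", down] <- d$X[d$labels == "LFE", down] - 4
    fit <- splsdaFit(d$X, d$labels, ncomp = 1, keepX = 30, reps = 2,
                     seed = 200 + i)
    rfi <- ifelse(d$labels == "LFE", 1, -1) + rnorm(length(d$labels), 0, 0.5)
    X <- cbind(RFI = rfi, FCR = rfi + rnorm(length(rfi), 0, 0.7))
    rc <- rccaFit(d$X, X, select_pop = "all")
    common <- intersect(fit$selected[[1]], rc$selected)
    if (length(common) < 3) return(NA)
    cor(fit$loadings[common, 1], rc$ycoef[common, 1])
  })
  expect_gte(mean(pos > 0, na.rm = TRUE), 0.9)
})

test_that("up-in-LFE genes carry negative component-1 loadings", {
  d <- makeTwoGroupExpr(p = 100, n_signal = 10, effect = 3)
  fit <- splsdaFit(d$X, d$labels, ncomp = 1, keepX = 10)
  sel <- intersect(fit$selected[[1]], d$signal)
  expect_true(all(fit$loadings[sel, 1] < 0))
})
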