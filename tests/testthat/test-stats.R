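# ---------------------------------------------------------------------------

test_that("BH step-up matches hand enumeration on the worked examples", {
  r1 <- bh_fdr(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_true(all(r1$reject))
  r2 <- bh_fdr(rep(1, 5), q = 0.05)
  expect_false(any(r2$reject))
  expect_equal(r2$adjusted, rep(1, 5))
  r3 <- bh_fdr(c(0.001, 0.8, 0.9), q = 0.05)
  expect_equal(r3$reject, c(TRUE, FALSE, FALSE))
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
  expect_error(bh_fdr(c(0.1, 0.2), q = 1.5), "0, 1")
})

test_that("BH rejection set equals the step-up definition on random vectors", {
  withr::with_seed(31, {
    for (r in 1:200) {
      m <- sample(1:10, 1)
      p <- round(runif(m)^sample(1:3, 1), 3)
      q <- sample(c(0.01, 0.05, 0.1, 0.2), 1)
      got <- bh_fdr(p, q)
      expect_identical(got$reject, stepup_bh_reject(p, q))
      # adjusted p monotone in raw-p order and >= raw p
      o <- order(p)
      expect_true(all(diff(got$adjusted[o]) >= -1e-15))
      expect_true(all(got$adjusted >= p - 1e-15))
    }
  })
})

test_that("Spearman rho equals the midrank closed form, ties included", {
  expect_equal(spearman_assoc(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_assoc(1:10, -(1:10))$rho, -1)
  withr::with_seed(32, {
    for (r in 1:200) {
      n <- sample(5:30, 1)
      x <- sample(1:6, n, replace = TRUE)   # heavy ties
      y <- x + rpois(n, 2) - rnorm(n)
      expect_equal(spearman_assoc(x, y)$rho, midrank_rho(x, y), tolerance = 1e-12)
    }
  })
  expect_error(spearman_assoc(rep(1, 5), 1:5), "constant")
  expect_error(spearman_assoc(1:4, 1:5), "equal length")
})

test_that("exact permutation p-value is valid at small n", {
  # n = 4: all 24 permutations enumerable by hand
  perms <- betatrack:::permutations_of(4)
  expect_equal(nrow(perms), 24)
  expect_equal(nrow(unique(perms)), 24)
  sp <- spearman_assoc(1:4, c(2, 1, 4, 3))
  expect_equal(sp$method, "exact permutation")
  # oracle: count permutations with |rho| >= observed
  rx <- rank(1:4)
  ry <- rank(c(2, 1, 4, 3))
  rhos <- apply(perms, 1, function(p) cor(rx, ry[p]))
  expect_equal(sp$p, mean(abs(rhos) >= abs(sp$rho) - 1e-12))
})

test_that("inverse Gaussian sampler has the right moments", {
  withr::with_seed(33, {
    x <- rinvgauss(2e5, mean = 0.2, shape = 1.5)
    expect_true(all(x > 0))
    expect_equal(mean(x), 0.2, tolerance = 0.01)
    expect_equal(var(x), 0.2^3 / 1.5, tolerance = 0.05)
  })
})

test_that("model specs enforce term hierarchy", {
  expect_error(model_spec("y", c("a", "a:b")), "marginal")
  sp <- model_spec("y", c("a", "b", "a:b"))
  expect_s3_class(sp, "model_spec")
  # neither a nor b is removable while a:b is present
  expect_identical(betatrack:::removable_terms(sp$fixed), "a:b")
})

test_that("intercept-only Gaussian fit on constant data recovers the constant", {
  d <- data.frame(participant = rep(c("A", "B"), each = 5), y = rep(3.5, 10))
  f <- fit_model(model_spec("y", character(0)), d)
  expect_equal(f$coefficients$estimate[1], 3.5, tolerance = 1e-8)
  expect_true(is.finite(f$aic))
})

test_that("positive-support families reject non-positive responses", {
  d <- data.frame(participant = "A", y = c(0.1, -0.2, 0.3))
  expect_error(fit_model(model_spec("y", character(0), family = "INVERSE_GAUSSIAN"), d),
               "positive")
})

test_that("GLMM recovers a simulated group effect with calibrated CIs", {
  crit <- qt(0.975, df = 37)
  cover <- vapply(1:150, function(r) {
    d <- sim_ig_data(r)
    f <- fit_model(model_spec("tracking_error", "group",
                              family = "INVERSE_GAUSSIAN", link = "IDENTITY"),
                   d, nAGQ = 9)
    est <- f$coefficients[f$coefficients$term == "groupOLDER", ]
    abs(est$estimate - 0.12) <= crit * est$se
  }, logical(1))
  expect_gte(mean(cover), 0.90)
})

test_that("a null group effect rejects at roughly the nominal rate", {
  # u_sd is kept small relative to the within-participant information:
  # when the random-intercept variance dominates, glmer Wald tests are
  # anticonservative (a documented limitation)
  rej <- vapply(1:60, function(r) {
    d <- sim_ig_data(r + 500, b = 0, u_sd = 0.015)
    f <- fit_model(model_spec("tracking_error", "group",
                              family = "INVERSE_GAUSSIAN", link = "IDENTITY"), d)
    f$term_tests$p[f$term_tests$term == "group"] < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.15)
})

test_that("family selection by AIC finds the generating family", {
  wins <- vapply(1:20, function(r) {
    d <- sim_ig_data(r + 900, nt = 40)
    sel <- select_family(model_spec("tracking_error", "group"), d)
    sel$best_spec$family == "INVERSE_GAUSSIAN" && sel$best_spec$link == "IDENTITY"
  }, logical(1))
  expect_gte(mean(wins), 0.6)

  # single candidate is returned unconditionally
  d <- sim_ig_data(1)
  one <- select_family(model_spec("tracking_error", "group"), d,
                       candidates = data.frame(family = "GAMMA", link = "IDENTITY"))
  expect_equal(one$best_spec$family, "GAMMA")
})

test_that("stepwise reduction drops null terms and keeps strong ones", {
  spec <- model_spec("y", c("x", "z"))
  dropped_null <- logical(60)
  kept_strong <- logical(60)
  for (r in 1:60) {
    d <- sim_lmm_data(r)
    res <- stepwise_backward(spec, d)
    dropped_null[r] <- !("z" %in% res$spec$fixed)
    kept_strong[r] <- "x" %in% res$spec$fixed
  }
  expect_gte(mean(dropped_null), 0.90)
  expect_gte(mean(kept_strong), 0.95)
})

test_that("stepwise trace is reproducible and hierarchy-respecting", {
  d <- sim_lmm_data(77)
  d$g <- factor(rep(c("u", "v"), length.out = nrow(d)))
  spec <- model_spec("y", c("x", "g", "x:g"))
  r1 <- stepwise_backward(spec, d)
  r2 <- stepwise_backward(spec, d)
  expect_identical(r1$trace, r2$trace)
  # while x:g is present, neither x nor g may be dropped first
  if (nrow(r1$trace) > 0) expect_equal(r1$trace$term[1], "x:g")
})

test_that("pairwise contrasts enumerate all level pairs with BH adjustment", {
  withr::with_seed(35, {
    d <- data.frame(
      participant = rep(sprintf("P%02d", 1:12), each = 6),
      a = factor(rep(rep(c("l1", "l2", "l3"), 2), 12)),
      b = factor(rep(rep(c("m1", "m2"), each = 3), 12))
    )
    d$y <- rnorm(nrow(d)) + (d$a == "l3") * 1.5
    f <- fit_model(model_spec("y", c("a", "b", "a:b")), d)
    c3 <- pairwise_contrasts(f, "a")
    expect_equal(nrow(c3), choose(3, 2))
    c15 <- pairwise_contrasts(f, c("a", "b"))
    expect_equal(nrow(c15), choose(6, 2))
    expect_true(all(c15$p_adj >= c15$p_raw - 1e-15))
    d$one <- factor("only")
    f2 <- fit_model(model_spec("y", c("a")), d)
    expect_error(pairwise_contrasts(f2, "one"), "levels")
  })
})

test_that("null pairwise contrasts reject at about the raw level, fewer after BH", {
  withr::with_seed(36, {
    raw <- 0L
    adj <- 0L
    total <- 0L
    for (r in 1:40) {
      d <- data.frame(
        participant = rep(sprintf("P%02d", 1:15), each = 3),
        a = factor(rep(c("l1", "l2", "l3"), 15)),
        y = rnorm(45)
      )
      f <- fit_model(model_spec("y", "a"), d)
      cc <- pairwise_contrasts(f, "a")
      raw <- raw + sum(cc$p_raw < 0.05)
      adj <- adj + sum(cc$reject)
      total <- total + nrow(cc)
    }
    expect_lte(raw / total, 0.12)
    expect_lte(adj, raw)
  })
})

test_that("association model recovers a planted MRBD-performance link", {
  make_assoc_data <- function(seed, b = 0.03) {
    withr::with_seed(seed, {
      np <- 39
      grp <- rep(c("YOUNGER", "OLDER"), length.out = np)
      preds <- expand.grid(stage = c("planning", "execution"),
                          region = c("frontal", "central", "parietal"),
                          hemisphere = c("left", "right"),
                          stringsAsFactors = FALSE)
      rows <- list()
      for (i in seq_len(np)) {
        u <- rnorm(1, 0, 0.02)
        for (cond in names(btt_conditions())) {
          mr <- rnorm(nrow(preds), mean = -2, sd = 1)
          names(mr) <- paste(preds$stage, preds$region, preds$hemisphere, sep = "_")
          err <- 0.15 + b * (mr[["planning_central_right"]] + 2) + u + rnorm(1, 0, 0.02)
          for (k in seq_len(nrow(preds))) {
            rows[[length(rows) + 1L]] <- data.frame(
              participant = sprintf("P%02d", i), group = grp[i],
              electrode = "XX", region = preds$region[k],
              hemisphere = preds$hemisphere[k], condition = cond,
              stage = preds$stage[k], mrbd_db = mr[[k]],
              tracking_error = err, stringsAsFactors = FALSE)
          }
        }
      }
      do.call(rbind, rows)
    })
  }
  kept_pos <- vapply(1:8, function(r) {
    d <- make_assoc_data(r)
    mrbd <- d[, c("participant", "group", "electrode", "region", "hemisphere",
                  "condition", "stage", "mrbd_db")]
    beh <- unique(d[, c("participant", "group", "condition", "tracking_error")])
    beh$block <- 1L
    beh$trial <- 1L
    res <- association_model(mrbd, beh, interactions = character(0))
    if (!"planning_central_right" %in% res$spec$fixed) return(FALSE)
    cf <- res$fit$coefficients
    cf$estimate[cf$term == "planning_central_right"] > 0
  }, logical(1))
  expect_gte(mean(kept_pos), 0.9)
})

test_that("generator's configured association reproduces the target correlation", {
  # ground-truth right-central planning depth vs simulated tracking error,
  # older group; replicate-averaged rho should sit near the calibrated
  # target of 0.56
  rhos <- vapply(1:6, function(r) {
    coh <- make_cohort(10, 10, seed = 400 + r)
    cfg <- neural_config()
    gt <- assign_depths(coh, cfg, seed = 500 + r)
    beh <- simulate_cohort_behavior(coh, seed = 600 + r)
    err <- tapply(beh$tracking_error, beh$participant, mean)
    d <- gt[gt$electrode == "C4" & gt$group == "OLDER", ]
    dp <- tapply(d$depth_plan_db, d$participant, mean)
    ids <- intersect(names(dp), names(err))
    spearman_assoc(dp[ids], err[ids])$rho
  }, numeric(1))
  expect_equal(mean(rhos), 0.56, tolerance = 0.15)
  expect_true(all(rhos > 0))
})
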