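# build a full-grid dB "grand average" matrix directly
make_grand <- function(power) {
  g <- default_grid()
  flat_tfr(power, g$freqs, g$times, scale = "DB")
}

test_that("grand averaging equals the brute-force loop", {
  withr::with_seed(21, {
    g <- default_grid()
    nt <- length(g$times)
    tfrs <- lapply(1:9, function(i) flat_tfr(matrix(rnorm(33 * nt), 33, nt),
                                             g$freqs, g$times))
    ga <- grand_average(tfrs)
    manual <- Reduce(`+`, lapply(tfrs, `[[`, "power")) / 9
    expect_equal(ga$power, manual, tolerance = 1e-12)
    expect_equal(grand_average(tfrs[3])$power, tfrs[[3]]$power)
    neg <- tfrs[[1]]
    neg$power <- -tfrs[[1]]$power
    expect_equal(grand_average(list(tfrs[[1]], neg))$power,
                 matrix(0, 33, nt))
    bad <- tfrs[[1]]
    bad$times <- bad$times + 1
    expect_error(grand_average(list(tfrs[[1]], bad)), "grid")
  })
})

test_that("grand average is blind to input order and labels", {
  withr::with_seed(22, {
    g <- default_grid()
    nt <- length(g$times)
    tfrs <- lapply(1:8, function(i) {
      flat_tfr(matrix(rnorm(33 * nt), 33, nt), g$freqs, g$times,
               group = sample(c("YOUNGER", "OLDER"), 1))
    })
    ga1 <- grand_average(tfrs)
    shuffled <- tfrs[sample(8)]
    for (i in seq_along(shuffled)) shuffled[[i]]$group <- "OLDER"  # permute labels
    ga2 <- grand_average(shuffled)
    expect_equal(ga1$power, ga2$power, tolerance = 1e-12)
    m1 <- build_mask(ga1, "execution")
    m2 <- build_mask(ga2, "execution")
    expect_identical(m1$include, m2$include)
  })
})

test_that("stationary null yields essentially no mask inclusions", {
  withr::with_seed(23, {
    g <- default_grid()
    nt <- length(g$times)
    total_cells <- 0
    total_incl <- 0
    for (r in 1:50) {
      grand <- make_grand(matrix(rnorm(33 * nt, mean = -1, sd = 0.3), 33, nt))
      for (stage in c("planning", "execution")) {
        mk <- build_mask(grand, stage)
        total_incl <- total_incl + sum(mk$include)
        total_cells <- total_cells + length(mk$include)
      }
    }
    # the per-cell null level is exactly alpha / (full grid), so ~2340
    # candidate cells per cohort give < 0.02 expected inclusions per
    # cohort (fraction ~ 0); over 50 cohorts the Poisson mean is ~0.85
    expect_lte(total_incl, 5)
    expect_lt(total_incl / 100, 0.05)  # mean inclusions per mask build
    expect_gt(total_cells, 1e5)
  })
})

test_that("a -10 rest-SD shift forces 100% inclusion", {
  withr::with_seed(24, {
    g <- default_grid()
    nt <- length(g$times)
    tl <- trial_timeline()
    power <- matrix(rnorm(33 * nt, 0, 0.3), 33, nt)
    exec_cols <- g$times >= tl$exec_window[1] & g$times <= tl$exec_window[2]
    rest_cols <- g$times >= tl$rest_window[1] & g$times <= tl$rest_window[2]
    for (i in 1:33) {
      power[i, exec_cols] <- mean(power[i, rest_cols]) -
        10 * sd(power[i, rest_cols])
    }
    mk <- build_mask(make_grand(power), "execution")
    expect_equal(mk$included_fraction, 100)
  })
})

test_that("mask threshold uses the full decomposition grid and nests in alpha", {
  withr::with_seed(25, {
    g <- default_grid()
    nt <- length(g$times)
    power <- matrix(rnorm(33 * nt, 0, 0.3), 33, nt)
    tl <- trial_timeline()
    exec_cols <- g$times >= 1 & g$times <= 3
    power[, exec_cols] <- power[, exec_cols] - 2  # moderate shift
    m05 <- build_mask(make_grand(power), "execution", alpha = 0.05)
    m10 <- build_mask(make_grand(power), "execution", alpha = 0.10)
    expect_equal(m05$threshold, 0.05 / (33 * nt))
    # loosening alpha never removes cells
    expect_true(all(m10$include[m05$include]))
  })
})

test_that("constant grand matrix raises a degenerate-test error", {
  g <- default_grid()
  grand <- make_grand(matrix(1, 33, length(g$times)))
  expect_error(build_mask(grand, "planning"), "degenerate")
})

test_that("masked extraction averages exactly the masked cells", {
  withr::with_seed(26, {
    g <- default_grid()
    nt <- length(g$times)
    tl <- trial_timeline()
    power <- matrix(rnorm(33 * nt, 0, 0.2), 33, nt)
    exec_cols <- g$times >= 1 & g$times <= 3
    power[, exec_cols] <- power[, exec_cols] - 5
    mk <- build_mask(make_grand(power), "execution")
    expect_gt(sum(mk$include), 0)

    # constant matrix at -3 dB: any mask extracts exactly -3
    const <- flat_tfr(matrix(-3, 33, nt), g$freqs, g$times,
                      participant = "P01", group = "OLDER",
                      electrode = "C4", condition = "ONE_ONE")
    tab <- extract_mrbd(list(const), mk)
    expect_equal(tab$mrbd_db, -3)
    expect_equal(tab$region, "central")
    expect_equal(tab$hemisphere, "right")

    # single-cell mask extracts that cell
    one <- mk
    keep <- which(one$include, arr.ind = TRUE)[1, ]
    one$include[] <- FALSE
    one$include[keep[1], keep[2]] <- TRUE
    tf <- flat_tfr(power, g$freqs, g$times, participant = "P01",
                   group = "OLDER", electrode = "F3", condition = "ONE_ONE")
    row_idx <- match(one$freqs[keep[1]], g$freqs)
    col_idx <- match(one$times[keep[2]], g$times)
    expect_equal(extract_mrbd(list(tf), one)$mrbd_db,
                 power[row_idx, col_idx])

    # empty mask is an explicit error
    empty <- mk
    empty$include[] <- FALSE
    expect_error(extract_mrbd(list(tf), empty), "empty")
  })
})
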