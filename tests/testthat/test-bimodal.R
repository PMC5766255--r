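test_that("fit_gmm2 recovers planted mixture parameters", {
  set.seed(4)
  x <- c(rnorm(500, 0, 1), rnorm(500, 6, 1))
  f <- fit_gmm2(x, seed = 1)
  expect_gt(f$delta_bic, 2)
  expect_lt(abs(f$mu_high - 6), 0.2)
  expect_lt(abs(f$mu_low - 0), 0.2)
  expect_lt(abs(f$pi_high - 0.5), 0.05)
  expect_true(f$mu_low <= f$mu_high)
  expect_equal(f$delta_bic, f$bic1 - f$bic2)
  # posteriors aligned with input, NA propagated
  x2 <- x; x2[c(3, 10)] <- NA
  f2 <- fit_gmm2(x2, seed = 1)
  expect_identical(which(is.na(f2$posteriors)), c(3L, 10L))
  expect_equal(f2$n_used, 998L)
})

test_that("fit_gmm2 rejects degenerate input and is seed-stable", {
  expect_error(fit_gmm2(rep(1, 50)), "degenerate")
  expect_error(fit_gmm2(c(1, 2, 3)), "degenerate")
  set.seed(8); x <- rnorm(200)
  f1 <- fit_gmm2(x, seed = 5); f2 <- fit_gmm2(x, seed = 5)
  expect_identical(f1[names(f1) != "analyte_id"],
                   f2[names(f2) != "analyte_id"])
})

test_that("C++ EM core agrees with the plain-R reference implementation", {
  set.seed(21)
  v <- c(rnorm(300), rnorm(200, 3))
  z <- as.numeric(v > median(v))
  fv <- 1e-3 * var(v)
  a <- switchmix:::em_gmm2(v, z, fv, 1000, 1e-8)
  b <- switchmix:::.em_gmm2_cpp(v, z, fv, 1000L, 1e-8)
  expect_equal(a$loglik, b$loglik, tolerance = 1e-10)
  expect_equal(a$mu, b$mu, tolerance = 1e-10)
  expect_equal(a$post, b$post, tolerance = 1e-10)
})

test_that("is_bimodal is a strict > 2 threshold on delta_bic", {
  f <- structure(list(delta_bic = 2), class = "mixture_fit")
  expect_false(is_bimodal(f))
  f$delta_bic <- 2.01
  expect_true(is_bimodal(f))
  f$delta_bic <- -5
  expect_false(is_bimodal(f))
})

test_that("posterior_high matches the closed-form Bayes ratio", {
  f <- structure(list(mu_low = 0, mu_high = 6, sigma_low = 1,
                      sigma_high = 1, pi_high = 0.5),
                 class = "mixture_fit")
  # independent oracle: direct density evaluation
  want <- 0.5 * dnorm(3.5, 6, 1) / (0.5 * dnorm(3.5, 0, 1) +
                                      0.5 * dnorm(3.5, 6, 1))
  expect_equal(posterior_high(f, 3.5), want, tolerance = 1e-12)
  # symmetry: midpoint of the means -> exactly 1/2
  expect_equal(posterior_high(f, 3), 0.5, tolerance = 1e-12)
  # monotone in x for equal SDs
  grid <- posterior_high(f, seq(-5, 11, length.out = 200))
  expect_true(all(diff(grid) >= 0))
  expect_true(all(grid >= 0 & grid <= 1))
})

test_that("EM stationarity: mean posterior equals pi_high on converged fits", {
  set.seed(12)
  for (rep in 1:4) {
    x <- c(rnorm(400, 0, 1), rnorm(200 + 50 * rep, 5, 1.3))
    f <- fit_gmm2(x, seed = rep)
    expect_true(f$converged)
    expect_lt(abs(mean(f$posteriors) - f$pi_high), 1e-6)
  }
})

test_that("negating the data swaps components and reflects posteriors", {
  set.seed(13)
  x <- c(rnorm(300, 0, 1), rnorm(300, 4, 1))
  f <- fit_gmm2(x, seed = 2)
  g <- fit_gmm2(-x, seed = 2)
  expect_equal(g$mu_low, -f$mu_high, tolerance = 1e-8)
  expect_equal(g$mu_high, -f$mu_low, tolerance = 1e-8)
  expect_equal(g$pi_high, 1 - f$pi_high, tolerance = 1e-8)
  expect_equal(g$posteriors, 1 - f$posteriors, tolerance = 1e-8)
})

test_that("tissue_entropy matches hand computation and edge cases", {
  # one group from a single tissue -> entropy 0
  p <- c(0.9, 0.95, 0.1, 0.2)
  tis <- c("a", "a", "b", "c")
  e <- tissue_entropy(p, tis)
  expect_equal(unname(e["entropy_high"]), 0)
  expect_equal(unname(e["entropy_low"]), log(2), tolerance = 1e-12)

  # uniform over 4 tissues -> ln 4 (and the empty low group warns)
  expect_warning(e2 <- tissue_entropy(rep(0.9, 4), c("a", "b", "c", "d")),
                 "empty low")
  expect_equal(unname(e2["entropy_high"]), log(4), tolerance = 1e-12)

  # counts {A:2, B:1, C:1}: -(0.5 ln 0.5 + 2 * 0.25 ln 0.25)
  e3 <- suppressWarnings(tissue_entropy(rep(0.7, 4), c("A", "A", "B", "C")))
  expect_equal(unname(e3["entropy_high"]),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)), tolerance = 1e-12)

  expect_error(tissue_entropy(c(NA, NA), c("a", "b")), "missing")
  # cells with missing posterior are excluded
  e4 <- tissue_entropy(c(0.9, NA, 0.8, 0.1), c("a", "b", "b", "c"))
  expect_equal(unname(e4["entropy_high"]), log(2), tolerance = 1e-12)
})

test_that("classify_switches: tertiles, common/rare and the 1/4 boundary", {
  # 9 synthetic 'fits' with controlled min_entropy and pi_high
  mkfit <- function(id, post, pi_high, dbic = 10) {
    structure(list(analyte_id = id, posteriors = post, pi_high = pi_high,
                   delta_bic = dbic), class = "mixture_fit")
  }
  tis <- rep(letters[1:4], each = 5)
  # entropy controlled by how many tissues populate the high group
  posts <- lapply(1:9, function(k) {
    p <- rep(0.1, 20)
    p[seq_len(2 * k)] <- 0.9 # high group spans ceiling(2k/5) tissues
    p
  })
  fits <- c(
    mapply(mkfit, paste0("B", 1:9), posts,
           pi_high = c(0.3, 0.9, 0.5, 0.75, 0.24, 0.26, 0.5, 0.5, 0.5),
           SIMPLIFY = FALSE),
    list(mkfit("U1", rep(0.5, 20), 0.5, dbic = -3)))
  cls <- classify_switches(fits, tis)

  expect_identical(cls$switch_class[cls$analyte == "U1"], "none")
  expect_true(is.na(cls$diversity_tertile[cls$analyte == "U1"]))
  # pi_high 0.3 -> minor 0.3 > 1/4 -> common; 0.9 -> minor 0.1 -> rare
  expect_identical(cls$switch_class[cls$analyte == "B1"], "common")
  expect_identical(cls$switch_class[cls$analyte == "B2"], "rare")
  # boundary exactly 1/4 -> rare (strict), just above -> common
  expect_identical(cls$switch_class[cls$analyte == "B5"], "rare")
  expect_identical(cls$switch_class[cls$analyte == "B6"], "common")

  # tertile recount oracle over the bimodal analytes
  me <- cls$min_entropy[cls$is_bimodal]
  br <- quantile(me, c(1, 2) / 3)
  want <- ifelse(me <= br[1], "low", ifelse(me <= br[2], "medium", "high"))
  expect_identical(cls$diversity_tertile[cls$is_bimodal], unname(want))
})

test_that("tertile labels follow the 1..9 quantile oracle", {
  mkfit <- function(id, post, pi_high = 0.5, dbic = 10) {
    structure(list(analyte_id = id, posteriors = post, pi_high = pi_high,
                   delta_bic = dbic), class = "mixture_fit")
  }
  # 24 tissues x 4 cells; fit k's high group is uniform over k+1 tissues,
  # so min_entropy = ln(k+1) (the low side spans >= 14 tissues, always
  # more), giving 9 strictly increasing values
  tis <- rep(sprintf("t%02d", 1:24), each = 4)
  fits <- lapply(1:9, function(k) {
    p <- rep(0.1, 96)
    p[seq_len(4 * (k + 1))] <- 0.9
    mkfit(paste0("B", k), p)
  })
  cls <- classify_switches(fits, tis)
  expect_equal(cls$min_entropy, log(2:10), tolerance = 1e-12)
  expect_identical(cls$diversity_tertile,
                   rep(c("low", "medium", "high"), each = 3))
})

test_that("fit_layer skips low-coverage analytes and is order-independent", {
  set.seed(31)
  v <- rbind(S1 = c(rnorm(60), rnorm(60, 5)),
             LOW = c(rnorm(30), rep(NA, 90)),
             FLAT = rep(1, 120))
  colnames(v) <- paste0("c", 1:120)
  m <- expr_matrix(v, "protein")
  fits <- suppressMessages(fit_layer(m, seed = 1, min_cells = 40))
  expect_identical(names(fits), "S1")
  pm <- posterior_matrix(fits)
  expect_equal(dim(pm), c(1L, 120L))
  tab <- fits_table(fits)
  expect_true(tab$is_bimodal[1])
})
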