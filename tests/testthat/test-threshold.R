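test_that("instance maxima take elementwise maxima inside action windows", {
  X <- rbind(c(1, 1, 50, 50), c(5, 2, 60, 55), c(3, 9, 55, 70))
  track <- manual_track(X, stride = 0.1, t0 = 10.25)
  w <- data.frame(start = 10, end = 10.5, label = "SR")
  mx <- instance_maxima(track, w)
  expect_equal(nrow(mx), 1L)
  expect_equal(unlist(mx[1, -1], use.names = FALSE), c(5, 9, 60, 70))
  # single-vector window is that vector
  w1 <- data.frame(start = 10, end = 10.2, label = "SR")
  mx1 <- instance_maxima(track, w1)
  expect_equal(unlist(mx1[1, -1], use.names = FALSE), c(1, 1, 50, 50))
  # window outside the track span excluded with a warning
  w2 <- rbind(w, data.frame(start = 99, end = 100, label = "SR"))
  expect_warning(mx2 <- instance_maxima(track, w2), "excluded")
  expect_equal(nrow(mx2), 1L)
})

test_that("thresholds are medians and linear-interpolation third quartiles", {
  # independent quantile oracle: linear interpolation between order stats
  lin_q <- function(v, p) {
    v <- sort(v)
    h <- (length(v) - 1) * p + 1
    lo <- floor(h)
    v[lo] + (h - lo) * (v[min(lo + 1, length(v))] - v[lo])
  }
  vals <- c(1, 2, 3, 4, 5)
  mx <- data.frame(label = "A", total_power = vals, psd_peak = vals,
                   mnf_hz = vals, mdf_hz = vals)
  m <- fit_thresholds(mx, "multiclass")
  expect_equal(unname(m$lower["A", "total_power"]), lin_q(vals, 0.5))
  expect_equal(unname(m$lower["A", "total_power"]), 3)
  expect_equal(unname(m$upper["A", "total_power"]), lin_q(vals, 0.75))
  expect_equal(unname(m$upper["A", "total_power"]), 4)
  same <- data.frame(label = "A", total_power = rep(2, 4),
                     psd_peak = rep(2, 4), mnf_hz = rep(2, 4),
                     mdf_hz = rep(2, 4))
  ms <- fit_thresholds(same, "multiclass")
  expect_equal(unname(ms$lower["A", ]), rep(2, 4))
  expect_equal(unname(ms$upper["A", ]), rep(2, 4))
  expect_warning(fit_thresholds(mx[1, ], "binary"), "single occurrence")
})

test_that("classes are ordered by ascending median band power", {
  mx <- data.frame(label = rep(c("hi", "lo"), each = 4),
                   total_power = c(101:104, 1:4), psd_peak = rep(1, 8),
                   mnf_hz = rep(1, 8), mdf_hz = rep(1, 8))
  m <- fit_thresholds(mx, "multiclass")
  expect_equal(m$class_order, c("lo", "hi"))
  expect_true(all(m$lower <= m$upper))
})

test_that("binary prediction needs all four thresholds satisfied", {
  mx <- data.frame(label = "SR", total_power = c(2, 3, 4),
                   psd_peak = c(2, 3, 4), mnf_hz = c(2, 3, 4),
                   mdf_hz = c(2, 3, 4))
  m <- fit_thresholds(mx, "binary")   # lower = (3,3,3,3)
  expect_equal(predict_threshold(m, rbind(c(4, 4, 4, 4))), "SR")
  expect_equal(predict_threshold(m, rbind(c(4, 4, 4, 2))), "no_action")
  expect_equal(predict_threshold(m, rbind(c(3, 3, 3, 3))), "SR")  # ties pass
})

test_that("multi-class bands assign the highest satisfied class", {
  mk <- function(v) c(v, v, v, v)
  mx <- data.frame(label = rep(c("SR", "PC"), each = 5),
                   total_power = c(1:5, 11:15), psd_peak = c(1:5, 11:15),
                   mnf_hz = c(1:5, 11:15), mdf_hz = c(1:5, 11:15))
  m <- fit_thresholds(mx, "multiclass")  # SR band [3,4], PC lower 13
  expect_equal(predict_threshold(m, rbind(mk(13.5))), "PC")
  expect_equal(predict_threshold(m, rbind(mk(3.5))), "SR")
  # above SR's Q3 cap but below PC's median: conservative no-action
  expect_equal(predict_threshold(m, rbind(mk(7))), "no_action")
  expect_equal(predict_threshold(m, rbind(mk(0.5))), "no_action")
  # flagged vectors are never actions
  tr <- manual_track(rbind(mk(13.5)))
  tr$flag <- TRUE
  expect_equal(predict_threshold(m, tr), "no_action")
})

test_that("threshold classification is scale-equivariant", {
  set.seed(31)
  X <- matrix(runif(200, 1, 100), 50, 4)
  mx <- data.frame(label = rep(c("a", "b"), each = 6),
                   total_power = c(runif(6, 5, 10), runif(6, 50, 80)),
                   psd_peak = c(runif(6, 1, 2), runif(6, 8, 12)),
                   mnf_hz = c(runif(6, 40, 50), runif(6, 90, 110)),
                   mdf_hz = c(runif(6, 40, 50), runif(6, 90, 110)))
  m <- fit_thresholds(mx, "multiclass")
  # scaling the signal by k scales power features by k^2, spectral ones not
  k2 <- 7.3
  mx_k <- mx
  mx_k$total_power <- mx$total_power * k2
  mx_k$psd_peak <- mx$psd_peak * k2
  m_k <- fit_thresholds(mx_k, "multiclass")
  Xk <- X
  Xk[, 1:2] <- X[, 1:2] * k2
  expect_identical(predict_threshold(m, X), predict_threshold(m_k, Xk))
})

test_that("fitting is invariant to the order of occurrences", {
  set.seed(32)
  mx <- data.frame(label = sample(rep(c("a", "b"), each = 7)),
                   total_power = runif(14, 1, 100),
                   psd_peak = runif(14, 1, 10),
                   mnf_hz = runif(14, 30, 120), mdf_hz = runif(14, 30, 120))
  m1 <- fit_thresholds(mx, "multiclass")
  m2 <- fit_thresholds(mx[sample(nrow(mx)), ], "multiclass")
  expect_equal(m1$lower, m2$lower)
  expect_equal(m1$upper, m2$upper)
  expect_identical(m1$class_order, m2$class_order)
})
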