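test_that("learning stores pairs verbatim and guards its state", {
  m <- encoding_model(1L, mark_dim = 2, n_bins = 4)
  add_spike(m, c(100, 110), 0)
  expect_equal(m$n, 1L)
  expect_error(add_spike(m, c(1, 2, 3), 0), "dimension mismatch")
  freeze(m, mean_rate = 1)
  expect_error(add_spike(m, c(1, 2), 1), "state error")
  expect_silent(freeze(m, mean_rate = 1))        # idempotent
  expect_error(freeze(encoding_model(1, 2, 4)), "empty")
  expect_error(encoding_model(1, 2, 4, sigma = 0), "configuration error")
})

test_that("the spike-position distribution is the normalised bin histogram", {
  set.seed(21)
  m <- encoding_model(1L, 1, n_bins = 6)
  bins <- sample(0:5, 500, replace = TRUE)
  add_spikes(m, matrix(rnorm(500), ncol = 1), bins)
  freeze(m, mean_rate = 1)
  expect_equal(m$ground, tabulate(bins + 1, 6) / 500)
  expect_equal(sum(m$ground), 1)
})

test_that("kernel weights follow the Gaussian kernel exactly", {
  m <- toy_model(matrix(c(0, 0), 1), 0, sigma = 1)
  expect_equal(kernel_weights(m, c(0, 0)), 1 / sqrt(2 * pi), tolerance = 1e-6)

  m <- toy_model(matrix(100, 1, 1), 0, sigma = 20)
  # squared distance 400: exp(-400/800) / (20 sqrt(2 pi))
  expect_equal(kernel_weights(m, 120), 0.012099, tolerance = 1e-4)
  expect_equal(kernel_weights(m, 120),
               exp(-0.5) / (20 * sqrt(2 * pi)), tolerance = 1e-12)
})

test_that("weights decrease with distance, peak at 1/(sigma sqrt(2 pi)), and are shift-invariant", {
  set.seed(4)
  M <- matrix(rnorm(60), ncol = 3)
  m <- toy_model(M, rep(0, 20), sigma = 1.7)
  q <- rnorm(3)
  w <- kernel_weights(m, q)
  a2 <- colSums((t(M) - q)^2)
  expect_equal(order(w), order(-a2))
  expect_lte(max(w), 1 / (1.7 * sqrt(2 * pi)) + 1e-12)

  m2 <- toy_model(M + 5, rep(0, 20), sigma = 1.7)  # same shift on both sides
  expect_equal(kernel_weights(m2, q + 5), w, tolerance = 1e-12)
})

test_that("joint mark density is the weighted histogram / count", {
  # two stored spikes equidistant from the query: equal weights w
  m <- toy_model(rbind(c(-1, 0), c(1, 0)), c(0, 1), n_bins = 4, sigma = 1)
  w <- kernel_weights(m, c(0, 0))[1]
  expect_equal(joint_mark_density(m, c(0, 0)), c(w / 2, w / 2, 0, 0))

  m <- toy_model(matrix(c(5, 5), 1), 2, n_bins = 4, sigma = 1)
  d <- joint_mark_density(m, c(5, 5))
  expect_equal(which(d > 0), 3L)                  # all mass at its bin
})

test_that("joint mark density matches a brute-force KDE oracle", {
  set.seed(33)
  n <- 1000; D <- 4; nb <- 41; sigma <- 20
  M <- matrix(runif(n * D, 0, 300), ncol = D)
  bins <- sample(0:(nb - 1), n, replace = TRUE)
  m <- toy_model(M, bins, n_bins = nb, sigma = sigma)
  for (k in 1:20) {
    q <- runif(D, 0, 300)
    # naive double loop: per stored mark, accumulate into its bin
    dens <- numeric(nb)
    for (o in seq_len(n)) {
      a2 <- sum((M[o, ] - q)^2)
      dens[bins[o] + 1] <- dens[bins[o] + 1] +
        exp(-a2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
    }
    dens <- dens / n
    got <- joint_mark_density(m, q)
    expect_lt(max(abs(got - dens)) / max(dens), 1e-10)
  }
})

test_that("intensities implement mu * p / occupancy with the floor", {
  set.seed(9)
  nb <- 7
  M <- matrix(rnorm(40), ncol = 2)
  bins <- sample(0:(nb - 1), 20, replace = TRUE)
  occ <- runif(nb, 0.5, 2); occ <- occ / sum(occ)
  m <- toy_model(M, bins, n_bins = nb, sigma = 1.3, mu = 4.2, occupancy = occ)
  q <- rnorm(2)
  r <- intensities(m, q)
  expect_equal(r$jmi, 4.2 * joint_mark_density(m, q) / (occ + 1e-12),
               tolerance = 1e-12)
  expect_equal(r$ground, 4.2 * (tabulate(bins + 1, nb) / 20) / (occ + 1e-12),
               tolerance = 1e-12)
  expect_true(all(r$jmi >= 0) && all(is.finite(r$jmi)))

  # uniform occupancy and uniform spike distribution: ground == mu everywhere
  mu_model <- toy_model(matrix(rnorm(nb * 3), ncol = 3), 0:(nb - 1),
                        n_bins = nb, mu = 3)
  expect_equal(ground_intensity(mu_model), rep(3, nb), tolerance = 1e-9)
})

test_that("queries agree before and after freezing the same stored set", {
  set.seed(14)
  m <- encoding_model(1L, 2, 10, sigma = 2)
  add_spikes(m, matrix(rnorm(100), ncol = 2), sample(0:9, 50, TRUE))
  q <- rnorm(2)
  before <- joint_mark_density(m, q)
  freeze(m, mean_rate = 1)
  expect_identical(joint_mark_density(m, q), before)
})

test_that("identical marks with cyclic positions give a uniform spike distribution", {
  # deterministic latency-test inputs: constant marks, positions i mod n_bins
  nb <- 10; n <- 500; D <- 4
  m <- encoding_model(1L, D, nb)
  add_spikes(m, matrix(1, n, D), (seq_len(n) - 1) %% nb)
  freeze(m, mean_rate = 1)
  expect_equal(m$ground, rep(1 / nb, nb))
  d <- joint_mark_density(m, rep(1, D))
  expect_equal(d / sum(d), rep(1 / nb, nb), tolerance = 1e-12)
})

test_that("query cost grows sub-linearly in mark dimensionality", {
  nb <- 41; n <- 4000; reps <- 200
  t_for <- function(D) {
    m <- encoding_model(1L, D, nb)
    add_spikes(m, matrix(1, n, D), (seq_len(n) - 1) %% nb)
    freeze(m, mean_rate = 1)
    q <- rep(1, D)
    joint_mark_density(m, q)   # warm up
    median(vapply(1:5, function(i) {
      system.time(for (r in seq_len(reps)) joint_mark_density(m, q))[["elapsed"]]
    }, numeric(1)))
  }
  ratio <- t_for(16) / max(t_for(1), 1e-3)
  expect_lt(ratio, 16)
})

test_that("models persist and reload losslessly", {
  set.seed(2)
  m <- encoding_model(3L, 2, 8, sigma = 5)
  add_spikes(m, matrix(rnorm(30), ncol = 2), sample(0:7, 15, TRUE))
  observe_position(m, sample(0:7, 100, TRUE), 1 / 30)
  freeze(m)
  f <- tempfile(fileext = ".json")
  write_encoding_model(m, f)
  m2 <- read_encoding_model(f)
  q <- rnorm(2)
  expect_equal(intensities(m2, q), intensities(m, q), tolerance = 1e-12)
  expect_equal(m2$mu, m$mu)
  expect_true(m2$frozen)
})
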