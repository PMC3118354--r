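test_that("grid planning follows the eigenvalue side-ratio rule", {
  expect_equal(plan_grid(100, iso_data()), c(10, 10))
  # lambda1/lambda2 = 4 gives side ratio 2 (enumeration oracle: among factor
  # pairs the ratio-2 pair closest to 100 neurons is 14 x 7)
  aniso <- rbind(c(2, 0), c(-2, 0), c(0, 1), c(0, -1))
  dims <- plan_grid(100, aniso)
  expect_equal(dims, c(14, 7))
  # prime sizes resolve to a balanced pair, not a strip
  small <- suppressWarnings(plan_grid(5, iso_data()))
  expect_true(all(small >= 2))
  expect_lte(abs(prod(small) - 5), 2)
  # rank-deficient data falls back to a square grid with a warning
  line <- outer(1:10, c(1, 2))
  expect_warning(dims_line <- plan_grid(100, line), "rank-deficient")
  expect_equal(dims_line, c(10, 10))
})

test_that("initialization is seeded and range-respecting", {
  set.seed(1)
  data <- matrix(rnorm(200, mean = 5, sd = 2), 50, 4)
  cfg <- test_config(map_size = 25)
  s1 <- som_init(cfg, data)
  s2 <- som_init(cfg, data)
  expect_identical(s1$prototypes, s2$prototypes)
  s3 <- som_init(cfg, data, seed = 99)
  expect_false(identical(s1$prototypes, s3$prototypes))
  lo <- apply(data, 2, min); hi <- apply(data, 2, max)
  for (j in 1:4) {
    expect_true(all(s1$prototypes[, j] >= lo[j]))
    expect_true(all(s1$prototypes[, j] <= hi[j]))
  }
})

test_that("BMU matches exhaustive search and breaks ties low", {
  set.seed(2)
  som <- som_init(test_config(map_size = 16), matrix(rnorm(100), 25, 4))
  expect_equal(bmu(som, som$prototypes[7, ]), 7)
  # equidistant prototypes: the lower index wins
  som$prototypes[3, ] <- c(1, 0, 0, 0)
  som$prototypes[9, ] <- c(-1, 0, 0, 0)
  expect_equal(bmu(som, c(0, 0, 0, 0)), 3)
  # brute-force oracle on random queries
  queries <- matrix(rnorm(80), 20, 4)
  oracle <- apply(queries, 1, function(q)
    which.min(sqrt(rowSums(sweep(som$prototypes, 2, q)^2))))
  expect_equal(bmu(som, queries), unname(oracle))
  expect_error(bmu(som, c(NA, 0, 0, 0)), "finite")
})

test_that("neighbourhood kernels have the textbook shapes", {
  for (kind in c("gaussian", "bubble", "ep"))
    expect_equal(neighbourhood_weight(kind, 0, 2), 1)
  expect_equal(neighbourhood_weight("bubble", 2, 2), 1)
  expect_equal(neighbourhood_weight("bubble", 2.001, 2), 0)
  expect_equal(neighbourhood_weight("ep", 2, 2), 0)
  expect_equal(neighbourhood_weight("gaussian", 2, 2), exp(-0.5))
  expect_error(neighbourhood_weight("triangle", 1, 1), "arg")
})

test_that("learning-rate schedules start at alpha0 and decrease", {
  for (kind in c("inverse", "linear", "power"))
    expect_equal(alpha_schedule(kind, 0.05, 0, 1000), 0.05)
  expect_equal(alpha_schedule("linear", 0.08, 500, 1000), 0.04)
  tgrid <- seq(0, 999)
  for (kind in c("inverse", "linear", "power")) {
    vals <- alpha_schedule(kind, 0.05, tgrid, 1000)
    expect_true(all(diff(vals) <= 0))
    expect_true(all(vals > 0 | kind == "linear"))
    expect_true(all(vals <= 0.05))
  }
  expect_error(alpha_schedule("linear", 0, 1, 10), "alpha0")
})

test_that("lattice distances honour geometry and wrapping", {
  data <- rbind(diag(4), -diag(4))  # exactly isotropic: 10 x 10 grid
  rect <- som_init(test_config(map_size = 100, lattice = "rectangular"), data)
  expect_equal(lattice_distance(rect, 1, 2), 1.0)
  hex <- som_init(test_config(map_size = 100, lattice = "hexagonal"), data)
  expect_equal(lattice_distance(hex, 1, 2), 1.0)          # same row
  # offset-row neighbours of an even-row cell are also at distance 1
  expect_equal(lattice_distance(hex, 1, hex$grid_cols + 1), 1.0)
  expect_equal(lattice_distance(hex, 2, hex$grid_cols + 1), 1.0)
  tor <- som_init(test_config(map_size = 100, lattice = "rectangular",
                              shape = "toroid"), data)
  expect_equal(tor$grid_cols, 10)
  expect_equal(lattice_distance(tor, 1, 10), 1.0)         # columns 0 and 9 wrap
  cyl <- som_init(test_config(map_size = 100, lattice = "rectangular",
                              shape = "cylinder"), data)
  expect_equal(lattice_distance(cyl, 1, 10), 1.0)
  # sheet does not wrap
  sheet <- som_init(test_config(map_size = 100, lattice = "rectangular"), data)
  expect_equal(lattice_distance(sheet, 1, 10), 9.0)
})

test_that("training converges to a single repeated input", {
  x <- matrix(rep(c(3, -2, 1), 10), 10, 3, byrow = TRUE)
  cfg <- test_config(map_size = 9, radius = 2, training_length = 50)
  som <- som_train(som_init(cfg, x + matrix(rnorm(30, sd = 1e-3), 10, 3)), x)
  d_win <- sqrt(sum((som$prototypes[bmu(som, x[1, ]), ] - x[1, ])^2))
  expect_lt(d_win, 1e-6)
})

test_that("batch training separates two blobs like a 2-means step", {
  bl <- blob_data(n_per = 40, d = 4, sep = 15, sigma = 1, seed = 3)
  cfg <- test_config(map_size = 4, radius = 1, training_length = 40)
  som <- som_train(som_init(cfg, bl$x), bl$x)
  # every blob mean is matched by some prototype within 0.1 blob sigma... the
  # k-means oracle: per-blob means of the data
  m1 <- colMeans(bl$x[bl$labels == 1, ])
  m2 <- colMeans(bl$x[bl$labels == 2, ])
  d1 <- min(sqrt(rowSums(sweep(som$prototypes, 2, m1)^2)))
  d2 <- min(sqrt(rowSums(sweep(som$prototypes, 2, m2)^2)))
  expect_lt(d1, 0.5)
  expect_lt(d2, 0.5)
})

test_that("radius-0 batch update equals the per-cell mean of won vectors", {
  set.seed(4)
  data <- matrix(rnorm(120), 30, 4)
  cfg <- test_config(map_size = 9, radius = 0, training_length = 1)
  som0 <- som_init(cfg, data)
  trained <- som_train(som0, data)
  win <- bmu(som0, data)
  for (n in seq_len(nrow(som0$prototypes))) {
    won <- which(win == n)
    expected <- if (length(won)) colMeans(data[won, , drop = FALSE])
                else som0$prototypes[n, ]
    expect_equal(trained$prototypes[n, ], expected, tolerance = 1e-12)
  }
})

test_that("hit counts match brute force and always conserve totals", {
  set.seed(5)
  data <- matrix(rnorm(200), 50, 4)
  cfg <- test_config(map_size = 16, training_length = 20)
  som <- som_train(som_init(cfg, data), data)
  h <- som_hits(som, data)
  expect_equal(sum(h$counts), 50)
  expect_equal(h$total, 50)
  oracle <- tabulate(apply(data, 1, function(q)
    which.min(rowSums(sweep(som$prototypes, 2, q)^2))), nrow(som$prototypes))
  expect_equal(h$counts, oracle)
  # prototypes as data: one hit each
  hp <- som_hits(som, som$prototypes)
  expect_equal(hp$counts, rep(1L, nrow(som$prototypes)))
})

test_that("training is bitwise deterministic given data, config and seed", {
  set.seed(6)
  data <- matrix(rnorm(300), 60, 5)
  for (alg in c("batch", "sequential")) {
    cfg <- test_config(map_size = 12, algorithm = alg, training_length = 10,
                       seed = 7)
    a <- som_train(som_init(cfg, data), data)
    b <- som_train(som_init(cfg, data), data)
    expect_identical(a$prototypes, b$prototypes)
  }
})

test_that("batch training reduces quantization error", {
  ok <- 0
  for (s in 1:10) {
    set.seed(s)
    data <- matrix(rnorm(400), 80, 5)
    cfg <- test_config(map_size = 16, training_length = 30, seed = s)
    init <- som_init(cfg, data)
    trained <- som_train(init, data)
    if (som_quantization_error(trained, data) <
        som_quantization_error(init, data)) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("a planted 1-D manifold maps monotonically onto the grid", {
  set.seed(8)
  t <- seq(0, 1, length.out = 300)
  dirvec <- c(5, 1, 0, 0, 0)
  data <- outer(t, dirvec) * 10 + matrix(rnorm(1500, sd = 0.3), 300, 5)
  cfg <- test_config(map_size = 24, radius = 3, training_length = 100)
  som <- som_train(som_init(cfg, data), data)
  pos_along <- som$positions[bmu(som, data), which.max(apply(som$positions, 2, max))]
  rho <- cor(seq_along(t), pos_along, method = "spearman")
  expect_gt(abs(rho), 0.8)
})

test_that("the clustering-efficiency index behaves as specified", {
  data <- matrix(rnorm(60), 12, 5)
  som <- som_init(test_config(map_size = 4, radius = 1), data)
  # perfect tightness: prototypes exactly at their cluster centroids
  som2 <- som
  som2$prototypes <- rbind(c(0, 0), c(0, 0), c(4, 0), c(4, 0))
  labels <- c(1, 1, 2, 2)
  expect_equal(performance_index(som2, labels), 0)
  # random instance: scale invariance
  set.seed(9)
  som3 <- som
  som3$prototypes <- matrix(rnorm(20), 4, 5)
  labels3 <- c(1, 2, 1, 2)
  p1 <- performance_index(som3, labels3)
  som3b <- som3
  som3b$prototypes <- som3$prototypes * 2
  expect_equal(performance_index(som3b, labels3), p1, tolerance = 1e-12)
  expect_gt(p1, 0)
  # degenerate centroids
  som4 <- som
  som4$prototypes <- matrix(1, 4, 5)
  expect_error(performance_index(som4, labels3), "coincide")
  expect_error(performance_index(som3, rep(1, 4)), "at least 2")
})

test_that("maps serialize through JSON and reload", {
  set.seed(10)
  data <- matrix(rnorm(100), 25, 4)
  cfg <- test_config(map_size = 9, training_length = 5)
  som <- som_train(som_init(cfg, data), data)
  path <- withr::local_tempfile(fileext = ".json")
  write_som(som, path, hits = som_hits(som, data))
  back <- read_som(path)
  expect_equal(back$prototypes, som$prototypes, tolerance = 1e-12)
  expect_equal(back$grid_rows, som$grid_rows)
  expect_true(back$trained)
  expect_equal(bmu(back, data), bmu(som, data))
})
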