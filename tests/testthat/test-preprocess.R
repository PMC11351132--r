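make_toy_collection <- function() {
  ## 3 experiments x 4 timesteps, small hand-checkable values
  time <- c(0, 1, 2, 3)
  mk <- function(id, base) {
    data <- outer(seq(0, 3), rep(1, 7)) + base
    colnames(data) <- ferm_channels()
    ferm_experiment(time, data, id = id)
  }
  ferm_collection(list(mk("a", 0), mk("b", 10), mk("c", 20)))
}

test_that("KNN imputation matches an exhaustive nearest-neighbour search", {
  coll <- make_toy_collection()
  broken <- coll
  broken$experiments[[2]] <-
    inject_fault(coll[[2]], fault_spec("missing_channel", "redox"))

  imp <- impute_missing_channels(broken, k = 1L)

  ## brute-force oracle: scan all complete rows, distance over observed
  donors <- do.call(rbind, lapply(list(coll[[1]], coll[[3]]),
                                  `[[`, "data"))
  for (r in 1:4) {
    row <- broken[[2]]$data[r, ]
    obs <- !is.na(row)
    d2 <- apply(donors[, obs, drop = FALSE], 1,
                function(d) sum((d - row[obs])^2))
    expected <- donors[which.min(d2), "redox"]
    expect_equal(unname(imp[[2]]$data[r, "redox"]), unname(expected))
  }

  ## observed entries bit-identical; imputed within observed range
  expect_identical(imp[[1]]$data, coll[[1]]$data)
  expect_identical(imp[[2]]$data[, "pH"], broken[[2]]$data[, "pH"])
  rng <- range(donors[, "redox"])
  expect_true(all(imp[[2]]$data[, "redox"] >= rng[1] &
                    imp[[2]]$data[, "redox"] <= rng[2]))

  ## idempotence and identity on complete data
  expect_identical(impute_missing_channels(imp, k = 1L), imp)
  expect_identical(impute_missing_channels(coll, k = 2L)$experiments,
                   coll$experiments)
  expect_error(impute_missing_channels(broken, k = 100L), "complete samples")
})

test_that("normalizers round-trip and compute the stated statistics", {
  imp <- small_imputed()
  mm <- fit_normalizer(imp, "minmax")
  normed <- apply_normalizer(imp, mm)
  pooled <- do.call(rbind, lapply(normed$experiments, `[[`, "data"))
  expect_true(all(pooled >= 0 & pooled <= 1))
  back <- invert_normalizer(normed, mm)
  for (i in seq_len(length(imp))) {
    expect_equal(back[[i]]$data, imp[[i]]$data, tolerance = 1e-10)
  }

  zs <- fit_normalizer(imp, "zscore")
  znormed <- apply_normalizer(imp, zs)
  zpooled <- do.call(rbind, lapply(znormed$experiments, `[[`, "data"))
  expect_equal(unname(colMeans(zpooled)), rep(0, 7), tolerance = 1e-10)
  expect_equal(unname(apply(zpooled, 2, sd)), rep(1, 7), tolerance = 1e-10)

  ## manual affine check on a tiny hand-built channel
  toy <- make_toy_collection()
  n <- fit_normalizer(toy, "minmax")
  v <- apply_normalizer(toy, n)[[1]]$data[, "pH"]
  expect_equal(unname(v), (c(0, 1, 2, 3) - 0) / (23 - 0))
})

test_that("normalizer statistics come from the fitting collection only", {
  imp <- small_imputed()
  sub <- imp[1:4]
  n <- fit_normalizer(sub, "minmax")
  pooled_sub <- do.call(rbind, lapply(sub$experiments, `[[`, "data"))
  expect_equal(n$center, apply(pooled_sub, 2, min))
  expect_equal(n$scale, apply(pooled_sub, 2, max) - apply(pooled_sub, 2, min))
  ## held-out experiments may fall outside [0, 1]; the fit must not move
  full <- fit_normalizer(imp, "minmax")
  expect_false(isTRUE(all.equal(n$center, full$center)))
})

test_that("constant channels are rejected by name", {
  toy <- make_toy_collection()
  for (i in 1:3) toy$experiments[[i]]$data[, "temperature"] <- 34
  expect_error(fit_normalizer(toy), "temperature")
})

test_that("regridding preserves lines exactly and sines to second order", {
  time <- seq(0, 10, length.out = 600L)
  data <- matrix(rep(2 * time + 1, 7), ncol = 7,
                 dimnames = list(NULL, ferm_channels()))
  data[, "ethanol"] <- sin(time)
  e <- ferm_experiment(time, data, id = "grid")

  same <- regrid(e, 600L)
  expect_equal(same$data, e$data, tolerance = 1e-12)

  r <- regrid(e, 500L)
  expect_equal(r$time[1], 0)
  expect_equal(r$time[500], 10)
  expect_equal(unname(r$data[, "pH"]), 2 * r$time + 1, tolerance = 1e-10)
  h <- 10 / 599
  expect_lt(max(abs(r$data[, "ethanol"] - sin(r$time))), h^2)
  expect_error(regrid(e, 1L), "n_points")
})

test_that("tensor and regression arrays have the protocol shapes and round-trip", {
  imp <- small_imputed()
  nrm <- fit_normalizer(imp)
  normed <- apply_normalizer(imp, nrm)
  tens <- to_vae_tensor(normed)
  expect_equal(dim(tens), c(11L, 60L, 7L))

  arr <- to_regression_arrays(normed)
  expect_equal(dim(arr$features), c(11L * 60L, 4L))
  expect_equal(dim(arr$targets), c(11L * 60L, 1L))
  expect_equal(colnames(arr$features),
               c("pH", "redox", "capacitance", "temperature"))

  one <- to_regression_arrays(normed[1])
  expect_equal(dim(one$features), c(60L, 4L))

  back <- tensor_to_collection(tens)
  expect_equal(to_vae_tensor(back), tens)
  ## slicing the tensor on channels 1:4 agrees with the feature matrix
  expect_equal(unname(arr$features[1:60, ]), unname(tens[1, , 1:4]))
  expect_equal(unname(arr$targets[61:120, 1]), unname(tens[2, , 5]))
})
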