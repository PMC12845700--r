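test_that("bank initialization is deterministic, Kaiming-scaled, and counts parameters", {
  b1 <- init_conv_bank(seed = 42)
  b2 <- init_conv_bank(seed = 42)
  expect_identical(b1, b2)
  b3 <- init_conv_bank(seed = 43)
  expect_false(identical(b1$raw[[1]]$weights, b3$raw[[1]]$weights))
  # branches share architecture, not weights
  expect_false(identical(b1$raw[[1]]$weights, b1$imf[[1]]$weights))

  # sample SD of the (3,1) module's 7680 draws near sqrt(2/(10*3))
  expect_equal(sd(b1$raw[[1]]$weights), sqrt(2 / 30), tolerance = 0.05 * sqrt(2 / 30))
  expect_true(all(b1$raw[[1]]$biases == 0))

  # per-module frozen parameter counts: n_filters * (C_in * k + 1)
  counts <- sapply(b1$raw, n_params)
  expect_equal(counts, c(7936, 13056, 28416))
  expect_equal(sum(sapply(b1$raw, n_params)) + sum(sapply(b1$imf, n_params)),
               98816)
  expect_error(init_conv_bank(configs = list(c(4, 1))), "odd")
})

test_that("convolution forward pass matches the brute-force loop oracle", {
  set.seed(5)
  spec <- conv_module_spec(5, 3, n_filters = 8, in_channels = 10)
  seg <- matrix(rnorm(10 * 64), nrow = 10)
  expect_equal(conv_forward(spec, seg), conv_oracle(spec, seg),
               tolerance = 1e-9)
  # all three study kernel configurations
  for (cf in list(c(3, 1), c(5, 3), c(11, 8))) {
    sp <- conv_module_spec(cf[1], cf[2], n_filters = 4, in_channels = 3)
    sg <- matrix(rnorm(3 * 50), nrow = 3)
    expect_equal(conv_forward(sp, sg), conv_oracle(sp, sg), tolerance = 1e-9)
  }
})

test_that("delta kernel passes its channel through; zero input maps to zero", {
  spec <- conv_module_spec(3, 1, n_filters = 1, in_channels = 2)
  spec$weights[] <- 0
  spec$weights[1, 1 * 2 + 1] <- 1        # center tap (j = 2), channel 1
  seg <- rbind(abs(rnorm(30)), rnorm(30))
  expect_equal(as.numeric(conv_forward(spec, seg)), seg[1, ])

  z <- conv_forward(conv_module_spec(5, 3, 4, 2), matrix(0, 2, 40))
  expect_true(all(z == 0))
  expect_error(conv_forward(spec, matrix(0, 3, 10)), "channels")
})

test_that("GAP/PPV statistics follow their definitions", {
  A <- matrix(0, 2, 4)
  st <- gap_ppv(A)
  expect_equal(st$gap, c(0, 0)); expect_equal(st$ppv, c(0, 0))
  st <- gap_ppv(matrix(1, 3, 5))
  expect_equal(st$gap, rep(1, 3)); expect_equal(st$ppv, rep(1, 3))
  st <- gap_ppv(matrix(c(0, 2, 0, 2), nrow = 1))
  expect_equal(st$gap, 1.0); expect_equal(st$ppv, 0.5)
})

test_that("fused feature vector has the documented layout and dimensions", {
  bank <- init_conv_bank(n_filters = 16, in_channels = 4, seed = 7)
  raw <- matrix(rnorm(4 * 80), nrow = 4)
  imf <- matrix(rnorm(4 * 80), nrow = 4)
  v <- extract_features(bank, raw, imf)
  expect_length(v, 2 * 3 * 2 * 16)
  expect_true(all(v[grepl("_ppv_", names(v))] >= 0 &
                  v[grepl("_ppv_", names(v))] <= 1))
  expect_true(all(v[grepl("_gap_", names(v))] >= 0))

  # repeated extraction is bit-identical (no state mutation)
  expect_identical(v, extract_features(bank, raw, imf))

  # layout contract: with tied branch weights, swapping the input segments
  # swaps exactly the two branch halves of the vector
  tied <- bank; tied$imf <- tied$raw
  v_t <- extract_features(tied, raw, imf)
  w_t <- extract_features(tied, imf, raw)
  half <- length(v_t) / 2
  expect_equal(unname(v_t[1:half]), unname(w_t[(half + 1):(2 * half)]))
  expect_equal(unname(v_t[(half + 1):(2 * half)]), unname(w_t[1:half]))
  # with independent branch weights the halves differ
  w <- extract_features(bank, imf, raw)
  expect_false(isTRUE(all.equal(unname(v[1:half]),
                                unname(w[(half + 1):(2 * half)]))))

  # zero inputs give an all-zero vector
  z <- extract_features(bank, matrix(0, 4, 80), matrix(0, 4, 80))
  expect_true(all(z == 0))

  expect_error(extract_features(bank, matrix(0, 3, 80), imf), "channel")
})

test_that("default bank reproduces the published dimension accounting", {
  bank <- init_conv_bank(seed = 42)       # C_in = 10, 256 filters
  raw <- matrix(rnorm(10 * 1100, 0, 0.1), nrow = 10)
  imf <- matrix(rnorm(10 * 1100, 0, 0.1), nrow = 10)
  v <- extract_features(bank, raw, imf)
  expect_length(v, 3072)
  expect_equal(sum(grepl("^raw_", names(v))), 1536)
  expect_equal(sum(grepl("^raw_k3d1_", names(v))), 512)
  expect_equal(length(feature_subset(v, "gap")), 1536)
  expect_equal(length(feature_subset(v, "ppv")), 1536)
})
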