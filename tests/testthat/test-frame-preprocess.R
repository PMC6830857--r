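test_that("channel separation is a bit-exact inverse of recombination", {
  set.seed(1)
  frames <- lapply(1:7, function(i)
    array(sample(0:255, 12 * 10 * 3, replace = TRUE), c(12, 10, 3)))
  frames[[1]][1, 1, ] <- c(10L, 20L, 30L)
  seq <- frame_sequence(frames, channel = "RGB")
  ch <- split_channels(seq)
  expect_length(ch$R, 7L)
  expect_length(ch$G, 7L)
  expect_length(ch$B, 7L)
  expect_identical(ch$R$frames[[1]][1, 1], 10L)
  expect_identical(ch$G$frames[[1]][1, 1], 20L)
  expect_identical(ch$B$frames[[1]][1, 1], 30L)
  rebuilt <- array(0L, dim(frames[[3]]))
  rebuilt[, , 1] <- ch$R$frames[[3]]
  rebuilt[, , 2] <- ch$G$frames[[3]]
  rebuilt[, , 3] <- ch$B$frames[[3]]
  expect_identical(rebuilt, frames[[3]])
  expect_error(split_channels(ch$R), "RGB")
})

test_that("difference ratio counts differing pixels exactly", {
  a <- noise_frame(100, 100, seed = 2)
  expect_identical(difference_ratio(a, a), 0)
  expect_identical(difference_ratio(a, (a + 1L) %% 256L), 1)

  b <- perturb_pixels(a, 4000L, seed = 3)
  expect_identical(difference_ratio(a, b), 0.4)
  expect_identical(difference_ratio(b, a), difference_ratio(a, b))

  expect_error(difference_ratio(a, a[1:50, ]), "dimensions")

  # tolerance masks small intensity jitter
  c1 <- a
  c1[1:10, 1] <- pmin(c1[1:10, 1] + 2L, 255L)
  expect_identical(difference_ratio(a, c1, zero_tolerance = 2L), 0)

  # a multi-channel pixel differs when ANY channel differs
  x <- array(0L, c(4, 4, 3))
  y <- x
  y[1, 1, 2] <- 5L
  expect_identical(difference_ratio(x, y), 1 / 16)
})

test_that("duplicate removal follows the reference-advance loop", {
  base <- noise_frame(100, 100, seed = 4)
  seq5 <- frame_sequence(rep(list(base), 5), channel = "R")
  dd <- remove_duplicates(seq5, phi = 0.6)
  expect_identical(dd$report$kept_indices, 1L)
  expect_identical(dd$report$removed_indices, 2:5)

  # constructed ratios vs the running reference: (1,2)=0.5 drop,
  # (1,3)=0.7 keep -> new reference 3, (3,4)=0.5 drop
  f1 <- base
  f2 <- perturb_pixels(f1, 5000L, seed = 5)
  f3 <- perturb_pixels(f1, 7000L, seed = 6)
  f4 <- perturb_pixels(f3, 5000L, seed = 7)
  seq <- frame_sequence(list(f1, f2, f3, f4), channel = "R")
  dd2 <- remove_duplicates(seq, phi = 0.6)
  expect_identical(dd2$report$kept_indices, c(1L, 3L))
  expect_identical(dd2$report$removed_indices, c(2L, 4L))
  expect_equal(dd2$report$ratios, c(0.5, 0.7, 0.5))

  # phi = 0: a ratio below 0 is impossible, everything is kept
  dd3 <- remove_duplicates(seq5, phi = 0)
  expect_identical(dd3$report$kept_indices, 1:5)

  # empty input
  dd4 <- remove_duplicates(frame_sequence(list(), channel = "R"), phi = 0.6)
  expect_length(dd4$sequence, 0L)
})

test_that("duplicate removal is idempotent and never grows the sequence", {
  fs <- make_frame_sequence(40L, list(c(2L, 3L), c(11L, 2L), c(30L, 5L)),
                            seed = 8L)
  once <- remove_duplicates(fs$sequence, phi = 0.6)
  twice <- remove_duplicates(once$sequence, phi = 0.6)
  expect_identical(twice$sequence$frames, once$sequence$frames)
  expect_identical(twice$report$removed_indices, integer(0))
  expect_lte(length(once$sequence), length(fs$sequence))

  # kept set partitions the input
  rep <- once$report
  expect_setequal(c(rep$kept_indices, rep$removed_indices),
                  seq_along(fs$sequence$frames))
})
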