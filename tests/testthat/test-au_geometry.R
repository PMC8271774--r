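test_that("au_centroid returns exact thirds and matches a loop oracle", {
  expect_equal(au_centroid(c(0, 0), c(3, 0), c(0, 3)), c(1, 1))
  expect_equal(au_centroid(c(5, 5), c(5, 5), c(5, 5)), c(5, 5))
  set.seed(11)
  for (i in 1:100) {
    p <- matrix(rnorm(6, sd = 50), 3, 2)
    expect_equal(au_centroid(p[1, ], p[2, ], p[3, ]),
                 oracle_centroid(p[1, ], p[2, ], p[3, ]))
  }
  expect_error(au_centroid(c(0, NA), c(1, 1), c(2, 2)), "finite")
})

test_that("centroid is translation- and scale-equivariant", {
  set.seed(12)
  for (i in 1:25) {
    p <- matrix(rnorm(6), 3, 2)
    t_off <- rnorm(2)
    c_scale <- runif(1, 0.1, 10)
    moved <- p * c_scale + matrix(t_off, 3, 2, byrow = TRUE)
    expect_equal(au_centroid(moved[1, ], moved[2, ], moved[3, ]),
                 c_scale * au_centroid(p[1, ], p[2, ], p[3, ]) + t_off,
                 tolerance = 1e-12)
  }
})

test_that("the AU table has the 11 documented landmark triples", {
  d <- au_definitions()
  expect_equal(nrow(d), 11L)
  expected <- list(
    AU4_M = c(21L, 22L, 27L), AU5_L = c(23L, 25L, 44L),
    AU5_R = c(18L, 20L, 37L), AU6_L = c(15L, 26L, 45L),
    AU6_R = c(1L, 17L, 36L), AU12_L = c(14L, 35L, 54L),
    AU12_R = c(2L, 31L, 48L), AU15_L = c(10L, 11L, 54L),
    AU15_R = c(5L, 6L, 48L), AU23_L = c(52L, 53L, 63L),
    AU23_R = c(49L, 50L, 61L))
  expect_setequal(d$au, names(expected))
  for (au in d$au) {
    expect_identical(d$landmarks[[which(d$au == au)]], expected[[au]])
  }
  expect_equal(sum(d$side == "left"), 5L)
  expect_equal(sum(d$side == "right"), 5L)
  expect_equal(sum(d$side == "middle"), 1L)
  expect_true(all(unlist(d$landmarks) >= 0 & unlist(d$landmarks) <= 67))
})

test_that("landmark_stream validates its invariants", {
  expect_error(landmark_stream(matrix(0, 5, 100), fps = 30), "136")
  m <- matrix(0, 5, 136)
  m[3, 7] <- NA
  expect_error(landmark_stream(m, fps = 30), "finite")
  expect_error(landmark_stream(matrix(0, 5, 136), fps = 0), "positive")
  expect_error(landmark_stream(matrix(0, 5, 136), fps = 30,
                               frame_index = c(0, 1, 2, 4, 5)), "gap")
  expect_error(constant_stream(emotion = "boredom"), "arg")
})

test_that("AU trajectories equal a naive per-frame oracle", {
  set.seed(13)
  n <- 50
  coords <- matrix(rnorm(n * 136, mean = 500, sd = 40), n, 136)
  s <- landmark_stream(coords, fps = 30)
  trajs <- extract_au_trajectories(s)
  expect_length(trajs, 11L)
  d <- au_definitions()
  for (i in seq_len(11)) {
    idx <- d$landmarks[[i]]
    for (fr in seq_len(n)) {
      pts <- lapply(idx, function(l) coords[fr, c(2 * l + 1, 2 * l + 2)])
      expect_equal(unname(trajs[[i]]$positions[fr, ]),
                   unname(oracle_centroid(pts[[1]], pts[[2]], pts[[3]])))
    }
    expect_equal(nrow(trajs[[i]]$positions), n)
  }
})

test_that("a whole-face translation at one frame moves every centroid equally", {
  s <- constant_stream(n_frames = 20)
  coords <- s$coords
  coords[7, seq(1, 135, 2)] <- coords[7, seq(1, 135, 2)] + 10
  coords[7, seq(2, 136, 2)] <- coords[7, seq(2, 136, 2)] - 4
  s2 <- landmark_stream(coords, fps = 30)
  t1 <- extract_au_trajectories(s)
  t2 <- extract_au_trajectories(s2)
  for (i in seq_len(11)) {
    diff <- t2[[i]]$positions - t1[[i]]$positions
    expect_equal(unname(diff[7, ]), c(10, -4))
    expect_true(all(diff[-7, ] == 0))
  }
})

test_that("analysis window extraction keeps the trailing frames", {
  s <- constant_stream(n_frames = 6300, fps = 30)
  w <- extract_analysis_window(s, 30)
  expect_equal(nrow(w$coords), 900L)
  expect_equal(w$frame_index[1], 5400L)

  s30 <- constant_stream(n_frames = 900, fps = 30)
  w30 <- extract_analysis_window(s30, 30)
  expect_equal(w30$coords, s30$coords)

  s31 <- constant_stream(n_frames = 310, fps = 10)
  w31 <- extract_analysis_window(s31, 30)
  expect_equal(nrow(w31$coords), 300L)
  expect_equal(w31$frame_index[1], 10L)

  expect_error(extract_analysis_window(constant_stream(n_frames = 100), 30),
               "30.00 s required")
})

test_that("metadata survives windowing", {
  s <- constant_stream(n_frames = 1200, fps = 30, subject = "s9",
                       emotion = "anger", authenticity = "fake")
  w <- extract_analysis_window(s, 30)
  expect_identical(w$meta, s$meta)
})

test_that("landmark CSV and JSON round-trips preserve the stream", {
  s <- constant_stream(n_frames = 12, fps = 30, subject = "s1",
                       emotion = "happiness", authenticity = "real")
  s$coords <- s$coords + matrix(rnorm(12 * 136), 12, 136)
  s <- landmark_stream(s$coords, 30, "s1", "happiness", "real")

  csv <- withr::local_tempfile(fileext = ".csv")
  write_landmark_csv(s, csv)
  r <- read_landmark_csv(csv)
  expect_equal(r$coords, s$coords, ignore_attr = TRUE)
  expect_identical(r$meta, s$meta)
  expect_equal(r$fps, 30)

  js <- withr::local_tempfile(fileext = ".json")
  write_landmark_json(s, js)
  r2 <- read_landmark_json(js)
  expect_equal(r2$coords, s$coords, ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(r2$meta, s$meta)
})
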