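make_run <- function(temps, seed = 1, ramp = quick_ramp(), stride = 200) {
  fx <- make_fixture_complex(demo_spec(temps = temps, seed = seed))
  run_titration(fx$model, fx$reference_frame, ramp, synth_backend(fx),
                stride_ps = stride, seed = seed)
}

test_that("titration profiles carry the anchor and one point per window", {
  run <- make_run(rep(2000, 4), seed = 1)
  prof <- titration_profile(run)
  expect_equal(nrow(prof$points), 16)
  expect_equal(unname(prof$anchor), c(300, -1))
  run2 <- make_run(rep(100, 4), seed = 1)
  prof2 <- titration_profile(run2)
  expect_equal(nrow(prof2$points), 1)
  expect_equal(prof2$points$mean_ifpcs[1], 0)
})

test_that("the MS coefficient follows the increment-unit slope convention", {
  ramp <- build_ramp(300, 450, 10, 10)
  mk_prof <- function(temps, means) structure(
    list(points = data.frame(temperature = temps, mean_ifpcs = means),
         anchor = c(temperature = 300, mean_ifpcs = -1)), class = "ttmd_profile")
  # full retention through 450 K
  full <- mk_prof(seq(300, 450, 10), rep(-1, 16))
  expect_equal(ms_coefficient(full, ramp)$ms, 0)
  # complete loss during the first window
  first <- mk_prof(300, 0)
  ms1 <- ms_coefficient(first, ramp)
  expect_equal(ms1$ms, 1)
  expect_true(is.na(ms1$ms_per_kelvin))
  # full ramp ending at mean -0.25: (1 - 0.25) / 15
  part <- mk_prof(seq(300, 450, 10), c(rep(-1, 15), -0.25))
  msp <- ms_coefficient(part, ramp)
  expect_equal(msp$ms, 0.75 / 15)
  expect_equal(msp$ms, 0.05)
  expect_equal(msp$ms_per_kelvin, 0.75 / 150)
  expect_equal(msp$t_end_used, 450)
  expect_equal(msp$mean_ifpcs_at_end, -0.25)
})

test_that("MS stays in [0, 1] and is 0 iff the final window mean is -1", {
  ramp <- build_ramp(300, 450, 10, 10)
  set.seed(42)
  for (k in 1:50) {
    n <- sample(1:16, 1)
    means <- sort(runif(n, -1, 0))
    if (n < 16) means[n] <- 0   # early termination implies a null final mean
    prof <- structure(list(points = data.frame(
      temperature = seq(300, by = 10, length.out = n), mean_ifpcs = means),
      anchor = c(temperature = 300, mean_ifpcs = -1)), class = "ttmd_profile")
    ms <- ms_coefficient(prof, ramp)$ms
    expect_gte(ms, 0); expect_lte(ms, 1)
    expect_equal(ms == 0, means[n] == -1)
  }
})

test_that("MS is monotone in the unbinding temperature", {
  ramp <- quick_ramp()
  for (seed in 1:5) {
    low <- make_run(rep(330, 4), seed = seed, stride = 500)
    high <- make_run(rep(400, 4), seed = seed, stride = 500)
    ms_low <- ms_coefficient(titration_profile(low), ramp)$ms
    ms_high <- ms_coefficient(titration_profile(high), ramp)$ms
    expect_gte(ms_low, ms_high)
  }
})

test_that("replicate trimming drops exactly one maximum and one minimum", {
  agg <- aggregate_replicates(c(0.10, 0.20, 0.30, 0.40, 0.90))
  expect_equal(sort(agg$retained), c(0.20, 0.30, 0.40))
  expect_equal(agg$aggregated_ms, 0.30)
  expect_equal(aggregate_replicates(rep(0.37, 5))$aggregated_ms, 0.37)
  ties <- aggregate_replicates(c(0.1, 0.1, 0.2, 0.3, 0.3))
  expect_equal(sort(ties$retained), c(0.1, 0.2, 0.3))
  expect_equal(ties$aggregated_ms, 0.2)
  expect_error(aggregate_replicates(c(0.1, 0.2)), "at least 3")
  # brute-force oracle on random 5-vectors
  set.seed(11)
  for (k in 1:100) {
    v <- runif(5)
    s <- sort(v)
    expect_equal(aggregate_replicates(v)$aggregated_ms, mean(s[2:4]))
  }
})

test_that("pose ranking sorts ascending MS with lexicographic tie-break", {
  rk <- rank_poses(list(p2 = 0.30, p1 = 0.05, p3 = 0.41))
  expect_equal(rk$pose, c("p1", "p2", "p3"))
  expect_equal(rk$rank, 1:3)
  expect_false(any(rk$tied))
  one <- rank_poses(list(only = aggregate_replicates(c(0.1, 0.2, 0.3))))
  expect_equal(one$rank, 1)
  tie <- rank_poses(list(b = 0.30, a = 0.30, c = 0.5))
  expect_equal(tie$pose, c("a", "b", "c"))
  expect_equal(tie$tied, c(TRUE, TRUE, FALSE))
  expect_error(rank_poses(list()), "no poses")
})

test_that("Kabsch superposition recovers rigid motions", {
  set.seed(3)
  X <- matrix(rnorm(30), ncol = 3)
  fit0 <- superpose_kabsch(X, X)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-8)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Y <- X %*% t(R) + matrix(c(1, -2, 3), nrow(X), 3, byrow = TRUE)
  fit <- superpose_kabsch(Y, X)
  expect_equal(fit$rmsd, 0, tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
  # one atom of four displaced by 2 A after fitting frame: RMSD = 2 / sqrt(4)
  A <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 1, 1, 0), ncol = 3, byrow = TRUE)
  B <- A; B[4, 3] <- 2
  expect_equal(sqrt(mean(rowSums((B - A)^2))), 1.0)
  expect_error(superpose_kabsch(A[1:2, ], A[1:2, ]), "at least 3")
  line <- cbind(0:4, 0, 0)
  expect_error(superpose_kabsch(line, line), "collinear")
})

test_that("RMSD series is zero for identity, exact for pure ligand translation", {
  fx <- make_fixture_complex(demo_spec(temps = rep(2000, 4), seed = 71))
  ramp <- build_ramp(300, 310, 10, 0.5)
  run <- run_titration(fx$model, fx$reference_frame, ramp, synth_backend(fx),
                       stride_ps = 100, seed = 2)
  # replace frames with exact copies / translated / rotated variants
  ref <- fx$reference_frame
  rot <- function(fr, R) new_frame(fr$protein_xyz %*% t(R) + 5,
                                   fr$ligand_xyz %*% t(R) + 5,
                                   temperature = fr$temperature)
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  shift <- new_frame(ref$protein_xyz, ref$ligand_xyz +
                       matrix(c(3, 0, 0), nrow(ref$ligand_xyz), 3, byrow = TRUE),
                     temperature = 300)
  run$windows <- list(list(temperature = 300, duration = 1,
                           frames = list(ref, shift, rot(ref, R)),
                           frame_scores = list(list(ifp_cs = -1, frame = 0L),
                                               list(ifp_cs = 0, frame = 1L),
                                               list(ifp_cs = -1, frame = 2L)),
                           mean_ifpcs = -2 / 3, terminated_here = FALSE))
  ts <- rmsd_series(run)
  expect_equal(ts$backbone_rmsd, rep(0, 3), tolerance = 1e-7)
  expect_equal(ts$ligand_rmsd, c(0, 3, 0), tolerance = 1e-7)
})

test_that("contact frequencies count frames within the cutoff", {
  fx <- make_fixture_complex(demo_spec(temps = rep(2000, 4), seed = 81))
  ramp <- build_ramp(300, 300, 10, 1)
  run <- run_titration(fx$model, fx$reference_frame, ramp, synth_backend(fx),
                       stride_ps = 100, seed = 3)
  cf <- contact_frequency_report(run)
  # every interaction site is within 4.5 A in every frame of a stable run
  expect_equal(nrow(cf), 4)
  expect_equal(cf$frequency, rep(1, 4))
  # a residue in contact in half the frames reports frequency 0.5
  ref <- fx$reference_frame
  far <- new_frame(ref$protein_xyz, ref$ligand_xyz + 50, temperature = 300)
  run$windows[[1]]$frames <- c(run$windows[[1]]$frames[1:5], replicate(5, far, simplify = FALSE))
  cf2 <- contact_frequency_report(run)
  expect_equal(cf2$frequency, rep(0.5, 4))
  expect_error(contact_frequency_report(run, cutoff = -1), "positive")
})

test_that("contact report caps at top_n without padding", {
  n_sites <- 30
  spec <- synthetic_ligand_spec(classes = rep("hydrophobic", n_sites),
                                characteristic_temperatures = rep(2000, n_sites),
                                seed = 91)
  fx <- make_fixture_complex(spec)
  ramp <- build_ramp(300, 300, 10, 0.5)
  run <- run_titration(fx$model, fx$reference_frame, ramp, synth_backend(fx),
                       stride_ps = 100, seed = 4)
  expect_equal(nrow(contact_frequency_report(run)), 25)
  expect_equal(nrow(contact_frequency_report(run, top_n = 40)), n_sites)
})

test_that("export writes deterministic tables and the three analysis plots", {
  fx <- make_fixture_complex(demo_spec(temps = rep(330, 4), seed = 99))
  ramp <- build_ramp(300, 340, 10, 0.5)
  run <- run_titration(fx$model, fx$reference_frame, ramp, synth_backend(fx),
                       stride_ps = 100, seed = 6)
  dir <- withr::local_tempdir()
  ranking <- rank_poses(list(poseA = 0.2, poseB = 0.6))
  paths <- export_report(run, dir, ranking = ranking)
  expect_true(all(file.exists(paths)))
  expect_length(grep("\\.png$", paths), 3)
  expect_length(grep("\\.csv$", paths), 4)
  prof <- titration_profile(run)
  re <- utils::read.csv(paths["profile_csv"])
  expect_equal(re$mean_ifpcs[-1], prof$points$mean_ifpcs)
  expect_equal(re$mean_ifpcs[1], -1)
  # identical inputs give identical data files
  dir2 <- withr::local_tempdir()
  paths2 <- export_report(run, dir2, ranking = ranking)
  for (f in grep("csv|json", names(paths), value = TRUE))
    expect_identical(readLines(paths[f]), readLines(paths2[f]))
})
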