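test_that("neutral clones keep their frequencies in deterministic mode", {
  counts <- c(a = 5000, b = 15000)
  eta <- c(0.5, 0.5)
  for (i in 1:5) {
    st <- simulate_passage(counts, eta, passage_days = 7,
                           bottleneck = 2e4, mode = "deterministic")
    counts <- st$counts
  }
  expect_equal(unname(counts), c(5000, 15000))
  expect_equal(st$growth_rate, 0.5, tolerance = 1e-12)
})

test_that("deterministic passaging follows the closed-form sweep", {
  # focal clone with per-generation fitness w over a doubling background
  w <- 2.23
  eta_bg <- 4 / 7                       # 4 generations per 7-day passage
  eta_focal <- eta_from_fitness(w, eta_bg)
  p0 <- 0.01
  counts <- c(focal = p0 * 1e6, bg = (1 - p0) * 1e6)
  sp <- selection_params(p0, w)
  for (k in 1:6) {
    st <- simulate_passage(counts, c(eta_focal, eta_bg), passage_days = 7,
                           bottleneck = 1e6, mode = "deterministic")
    counts <- st$counts
    expect_equal(counts[["focal"]] / sum(counts),
                 clone_frequency(sp, 4 * k), tolerance = 1e-4)
  }
})

test_that("stochastic bottlenecks are exact in size and unbiased", {
  set.seed(81)
  n_clones <- 200
  counts <- rep(100, n_clones)
  eta <- rep(0.5, n_clones)
  draws <- matrix(NA_real_, nrow = 1000, ncol = n_clones)
  for (s in 1:1000) {
    st <- simulate_passage(counts, eta, passage_days = 7,
                           bottleneck = 2e4, mode = "stochastic")
    expect_equal(sum(st$counts), 2e4)
    draws[s, ] <- st$counts
  }
  expect_equal(mean(colMeans(draws)), 100, tolerance = 0.01)
  # per-clone variance ~ multinomial: n p (1-p) with p = 1/200
  v_expected <- 2e4 * (1 / 200) * (1 - 1 / 200)
  expect_equal(mean(apply(draws, 2, var)), v_expected, tolerance = 0.05)
})

test_that("extinction is an error, not silent nonsense", {
  expect_error(simulate_passage(c(0, 0), c(0.5, 0.5)), "extinct")
})

test_that("experiment streams are seed-reproducible and independent", {
  clones <- clone_roster(random_barcodes(10), n0 = rep(100, 10),
                         soft = rep(0.5, 10))
  cfg1 <- experiment_config(clones, n_passages = 3, replicates = 2,
                            seed = 5, bottleneck = 1000)
  sim_a <- simulate_experiment(cfg1)
  sim_b <- simulate_experiment(cfg1)
  expect_identical(sim_a$trajectories, sim_b$trajectories)
  expect_identical(sim_a$final_counts, sim_b$final_counts)
  cfg2 <- experiment_config(clones, n_passages = 3, replicates = 2,
                            seed = 6, bottleneck = 1000)
  sim_c <- simulate_experiment(cfg2)
  expect_false(identical(sim_a$final_counts, sim_c$final_counts))
  # deterministic mode ignores the seed entirely
  cfg_d1 <- experiment_config(clones, n_passages = 3, replicates = 2,
                              seed = 5, bottleneck = 1000,
                              mode = "deterministic")
  cfg_d2 <- experiment_config(clones, n_passages = 3, replicates = 2,
                              seed = 99, bottleneck = 1000,
                              mode = "deterministic")
  expect_identical(simulate_experiment(cfg_d1)$final_counts,
                   simulate_experiment(cfg_d2)$final_counts)
})

test_that("a single clone realizes its own growth rate every passage", {
  clones <- clone_roster("A", n0 = 1000, soft = 0.37)
  cfg <- experiment_config(clones, n_passages = 4, replicates = 1,
                           seed = 1, bottleneck = 1000)
  sim <- simulate_experiment(cfg)
  expect_equal(sim$trajectories$growth_rate_per_day, rep(0.37, 4),
               tolerance = 1e-12)
})

test_that("simulated growth rates track the selection-model curve", {
  # 1% focal clone with a 2x growth-rate advantage on soft ECM
  n <- 100
  eta_bg <- 0.25; eta_f <- 0.5
  clones <- clone_roster(random_barcodes(n),
                         n0 = c(200, rep(19800 / (n - 1), n - 1)),
                         soft = c(eta_f, rep(eta_bg, n - 1)))
  cfg <- experiment_config(clones, n_passages = 12, replicates = 1,
                           mode = "deterministic", eta_ref = eta_bg)
  sim <- simulate_experiment(cfg)
  # model on the background-generation axis: w = 2^((eta_f-eta_bg)/eta_bg)
  w <- 2^((eta_f - eta_bg) / eta_bg)
  sp <- selection_params(0.01, w, eta_anc = eta_bg, eta_sel = eta_f)
  pred <- predicted_growth_rate(sp, sim$trajectories$generation -
                                  cfg$eta_ref * cfg$passage_days / 2)
  # realized per-passage rate is an average over the passage; compare at
  # the passage midpoint and require a small sup-norm
  expect_lt(max(abs(sim$trajectories$growth_rate_per_day - pred)), 0.02)
  # rises sigmoidally to the focal rate
  expect_true(all(diff(sim$trajectories$growth_rate_per_day) > -1e-9))
  expect_equal(tail(sim$trajectories$growth_rate_per_day, 1), eta_f,
               tolerance = 1e-3)
})

test_that("read generation respects frequencies, errors and qualities", {
  set.seed(82)
  bcs <- random_barcodes(5, min_dist = 3)
  freqs <- stats::setNames(rep(0.2, 5), bcs)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  truth <- generate_reads(freqs, 500, f1, f2, error_rate = 0, seed = 83)
  expect_equal(sum(truth$reads), 500)
  r1 <- read_fastq(f1)
  expect_length(r1$seq, 500)
  expect_true(all(nchar(r1$seq) == 75))
  # mates overlap: merged reads contain flank5+barcode+flank3
  fl <- barcode_flanks()
  expect_true(all(grepl(fl["flank5"], r1$seq, fixed = TRUE)))
  expect_error(generate_reads(freqs, 0, f1, f2), "positive")
})

test_that("clustered pipeline counts match the generator truth", {
  set.seed(84)
  bcs <- random_barcodes(8, min_dist = 3)
  freqs <- stats::setNames(rep(1 / 8, 8), bcs)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  truth <- generate_reads(freqs, 2000, f1, f2, error_rate = 0.005,
                          seed = 85)
  raw <- count_sample_barcodes(f1, f2)
  clustered <- cluster_barcodes(raw)
  # all true barcodes present; clustered counts near the multinomial truth
  expect_true(all(bcs %in% names(clustered)))
  got <- clustered[truth$barcode]
  expect_true(all(abs(got - truth$reads) <= 0.02 * truth$reads + 5))
  expect_equal(sum(raw), sum(clustered))
})

test_that("methylation generator encodes the condition effect truthfully", {
  gm <- generate_methylation_dataset(200, effect = 2, frac_affected = 0.25,
                                     coverage = 50, seed = 86)
  tr <- gm$truth
  expect_equal(stats::qlogis(tr$pi_A[tr$affected]) -
                 stats::qlogis(tr$pi_B[tr$affected]),
               rep(2, sum(tr$affected)), tolerance = 1e-12)
  expect_equal(tr$pi_A[!tr$affected], tr$pi_B[!tr$affected])
  # observed methylation fractions track truth
  loci <- gm$loci
  frac_A <- rowMeans(loci$M[, loci$condition == "A"] /
                       (loci$M + loci$U)[, loci$condition == "A"])
  region_id <- rep(seq_len(200), each = 5)
  est <- as.numeric(tapply(frac_A, region_id, mean))
  expect_equal(est, tr$pi_A, tolerance = 0.1)
})

test_that("image generator is exact at zero noise and stable under noise", {
  img0 <- generate_cell_image(noise_sd = 0)
  m0 <- measure_nc_from_image(img0$image, img0$nuc_mask, img0$cell_mask)
  expect_equal(m0$ratio, img0$truth$ratio)
  set.seed(87)
  ratios <- replicate(40, {
    im <- generate_cell_image(noise_sd = 25)  # 5% of the 500-unit signal
    measure_nc_from_image(im$image, im$nuc_mask, im$cell_mask)$ratio
  })
  expect_equal(mean(ratios), img0$truth$ratio, tolerance = 0.01)
  expect_error(generate_cell_image(cell_radius = 10, nuc_radius = 10),
               "smaller")
})

test_that("trajectory generator round-trips through the fitter", {
  sp <- selection_params(0.0103, 2.23, eta_anc = 0.25, eta_sel = 0.5)
  gen <- make_growth_trajectory(sp, 0:40, noise_sd = 0)
  expect_equal(gen$trajectory$gr, predicted_growth_rate(sp, 0:40))
  fit <- fit_selection_model(gen$trajectory, n_restarts = 5)
  expect_equal(fit$params$p0, 0.0103, tolerance = 1e-4)
  expect_equal(fit$params$w_star, 2.23, tolerance = 1e-4)
  # two seeds differ but share the mean curve
  g1 <- make_growth_trajectory(sp, 0:10, noise_sd = 0.05, replicates = 3,
                               seed = 88)
  g2 <- make_growth_trajectory(sp, 0:10, noise_sd = 0.05, replicates = 3,
                               seed = 89)
  expect_false(identical(g1$trajectory$gr, g2$trajectory$gr))
})
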