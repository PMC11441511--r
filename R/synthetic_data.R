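#' Random 20-bp barcodes
#'
#' Draws distinct barcodes over {A,C,G,T}; with `min_dist` > 0, rejection
#' sampling enforces a minimum pairwise Hamming distance (adequate for the
#' small sets used in simulations).
#'
#' @param n Number of barcodes.
#' @param len Barcode length (default 20).
#' @param min_dist Minimum pairwise Hamming distance (default 0 = distinct
#'   only).
#' @return Character vector of barcodes.
#' @export
random_barcodes <- function(n, len = 20L, min_dist = 0L) {
  out <- character(0)
  while (length(out) < n) {
    bc <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                collapse = "")
    ok <- if (!length(out)) TRUE
          else if (min_dist <= 0L) !(bc %in% out)
          else all(dist_to_set(bc, out, Inf) >= min_dist)
    if (ok) out <- c(out, bc)
  }
  out
}

#' Clone roster for the serial-passage simulator
#'
#' @param barcode Barcode per clone (unique).
#' @param n0 Founder cell count per clone.
#' @param ... Named numeric vectors of growth rates (doublings/day), one
#'   per condition, e.g. `soft =`, `stiff =`.
#' @return data.frame with columns `barcode`, `n0` and one `eta_<cond>`
#'   column per condition.
#' @export
clone_roster <- function(barcode, n0, ...) {
  fitness <- list(...)
  if (!length(fitness)) stop("at least one condition's fitness is required")
  stopifnot(!anyDuplicated(barcode), all(n0 >= 0))
  out <- data.frame(barcode = barcode, n0 = n0)
  for (cc in names(fitness))
    out[[paste0("eta_", cc)]] <- rep_len(fitness[[cc]], length(barcode))
  out
}

#' Growth rate of a clone with per-generation relative fitness w
#'
#' If the background multiplies 2-fold per generation at `eta_bg`
#' doublings/day, a clone with per-generation fitness ratio `w` multiplies
#' `2 w`-fold per generation, i.e. grows at
#' `eta_bg * (1 + log2(w))` doublings/day.
#'
#' @param w Per-generation relative fitness (> 0).
#' @param eta_bg Background growth rate, doublings/day.
#' @return Clone growth rate, doublings/day.
#' @export
eta_from_fitness <- function(w, eta_bg) {
  stopifnot(all(w > 0), eta_bg > 0)
  eta_bg * (1 + log2(w))
}

#' Serial-passage experiment configuration
#'
#' @param clones A [clone_roster()].
#' @param bottleneck Cells re-seeded each passage (default 2e4).
#' @param passage_days Days of growth per passage (default 7).
#' @param n_passages Number of passages (default 10).
#' @param conditions Condition labels; must match the roster's
#'   `eta_<cond>` columns (default: all in the roster).
#' @param replicates Replicates per condition (default 5).
#' @param seed Base seed; mandatory in stochastic mode.
#' @param mode `"stochastic"` (multinomial bottleneck) or
#'   `"deterministic"` (largest-remainder proportional bottleneck).
#' @param eta_ref Reference growth rate used to convert passages to
#'   generations (default: the fastest clone across conditions).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(clones, bottleneck = 2e4, passage_days = 7,
                              n_passages = 10, conditions = NULL,
                              replicates = 5, seed = NULL,
                              mode = c("stochastic", "deterministic"),
                              eta_ref = NULL) {
  mode <- match.arg(mode)
  stopifnot(bottleneck >= 1, passage_days > 0, n_passages >= 1,
            replicates >= 1)
  eta_cols <- grep("^eta_", names(clones), value = TRUE)
  if (is.null(conditions)) conditions <- sub("^eta_", "", eta_cols)
  missing_cols <- setdiff(paste0("eta_", conditions), names(clones))
  if (length(missing_cols))
    stop("roster lacks fitness column(s): ",
         paste(missing_cols, collapse = ", "))
  if (mode == "stochastic" && is.null(seed))
    stop("stochastic mode requires a seed")
  if (is.null(eta_ref))
    eta_ref <- max(unlist(clones[paste0("eta_", conditions)]))
  structure(list(clones = clones, bottleneck = bottleneck,
                 passage_days = passage_days, n_passages = n_passages,
                 conditions = conditions, replicates = replicates,
                 seed = seed, mode = mode, eta_ref = eta_ref),
            class = "experiment_config")
}

#' Default simulated experiment mirroring the study design
#'
#' 220 uniformly seeded lineages in a 2e4-cell founder population; on soft
#' ECM one focal clone carries per-generation fitness 2.23 over a
#' background growing at 0.25 doublings/day; on stiff ECM all clones are
#' neutral at 0.5 doublings/day. Five replicates per condition, 7-day
#' passages, 10 passages, multinomial bottlenecks of 2e4 cells.
#'
#' @param n_lineages Number of barcoded lineages (default 220).
#' @param focal_frac Founder frequency of the focal clone (default 0.01).
#' @param w_focal Per-generation fitness of the focal clone on soft ECM
#'   (default 2.23).
#' @param seed Base seed.
#' @return An `experiment_config`.
#' @export
default_experiment_config <- function(n_lineages = 220, focal_frac = 0.01,
                                      w_focal = 2.23, seed = 1) {
  set.seed(seed)
  barcodes <- random_barcodes(n_lineages, min_dist = 3L)
  n_total <- 2e4
  n_focal <- round(focal_frac * n_total)
  n0 <- c(n_focal, rep(round((n_total - n_focal) / (n_lineages - 1)),
                       n_lineages - 1))
  eta_bg_soft <- 0.25
  soft <- c(eta_from_fitness(w_focal, eta_bg_soft),
            rep(eta_bg_soft, n_lineages - 1))
  stiff <- rep(0.5, n_lineages)
  clones <- clone_roster(barcodes, n0, soft = soft, stiff = stiff)
  experiment_config(clones, seed = seed)
}

largest_remainder <- function(weights, total) {
  if (sum(weights) <= 0) stop("all clones extinct")
  q <- total * weights / sum(weights)
  base <- floor(q)
  rem <- as.integer(round(total - sum(base)))
  out <- base
  if (rem > 0) {
    frac <- q - base
    top <- order(-frac, seq_along(frac))[seq_len(rem)]
    out[top] <- out[top] + 1
  }
  out
}

#' Grow one passage and re-seed through the bottleneck
#'
#' Each clone grows deterministically as `N_i * 2^(eta_i * passage_days)`;
#' the realized population growth rate is
#' `log2(sum N_end / sum N_start) / passage_days`. The bottleneck then
#' draws exactly `bottleneck` cells — multinomially with probabilities
#' proportional to `N_end` in stochastic mode, or by largest-remainder
#' proportional rounding in deterministic mode.
#'
#' @param counts Cells per clone at seeding (non-negative; some > 0).
#' @param eta Growth rate per clone, doublings/day.
#' @param passage_days Days of growth.
#' @param bottleneck Cells re-seeded.
#' @param mode `"stochastic"` or `"deterministic"`.
#' @return List: `counts` (post-bottleneck), `growth_rate`
#'   (doublings/day), `n_end` (pre-bottleneck sizes).
#' @export
simulate_passage <- function(counts, eta, passage_days = 7,
                             bottleneck = 2e4,
                             mode = c("stochastic", "deterministic")) {
  mode <- match.arg(mode)
  stopifnot(length(counts) == length(eta), all(counts >= 0))
  if (sum(counts) <= 0) stop("all clones extinct")
  n_end <- counts * 2^(eta * passage_days)
  gr <- log2(sum(n_end) / sum(counts)) / passage_days
  new_counts <- if (mode == "stochastic") {
    as.numeric(stats::rmultinom(1, size = bottleneck, prob = n_end))
  } else {
    largest_remainder(n_end, bottleneck)
  }
  list(counts = new_counts, growth_rate = gr, n_end = n_end)
}

#' Run the full serial-passage experiment
#'
#' Each condition x replicate is an independent stream seeded from the base
#' seed. Growth rates are recorded per passage; generation indices use the
#' reference growth rate (`generation = eta_ref * passage_days * passage`).
#'
#' @param config An [experiment_config()].
#' @return A `sim_output` list: `trajectories` (data.frame `condition,
#'   replicate, passage, generation, growth_rate_per_day`), `frequencies`
#'   (long data.frame of true clone frequencies per passage),
#'   `final_counts` (named list sample -> named cell-count vector, plus
#'   `"ancestral"` = founder counts), and `config`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  clones <- config$clones
  gens_per_passage <- config$eta_ref * config$passage_days
  traj <- list(); freqs <- list(); finals <- list()
  finals[["ancestral"]] <- stats::setNames(clones$n0, clones$barcode)
  stream <- 0L
  for (cond in config$conditions) {
    eta <- clones[[paste0("eta_", cond)]]
    for (rep_i in seq_len(config$replicates)) {
      stream <- stream + 1L
      if (config$mode == "stochastic")
        set.seed((config$seed + 7919L * stream) %% .Machine$integer.max)
      counts <- as.numeric(clones$n0)
      for (k in seq_len(config$n_passages)) {
        st <- simulate_passage(counts, eta, config$passage_days,
                               config$bottleneck, config$mode)
        counts <- st$counts
        traj[[length(traj) + 1L]] <- data.frame(
          condition = cond, replicate = rep_i, passage = k,
          generation = k * gens_per_passage,
          growth_rate_per_day = st$growth_rate)
        freqs[[length(freqs) + 1L]] <- data.frame(
          condition = cond, replicate = rep_i, passage = k,
          barcode = clones$barcode,
          frequency = counts / sum(counts))
      }
      finals[[paste0(cond, "_rep", rep_i)]] <-
        stats::setNames(counts, clones$barcode)
    }
  }
  structure(list(trajectories = do.call(rbind, traj),
                 frequencies = do.call(rbind, freqs),
                 final_counts = finals,
                 config = config),
            class = "sim_output")
}

#' Simulated endpoint abundances as a barcode count table
#'
#' @param sim A `sim_output`.
#' @param drop_zero Drop clones absent everywhere (default TRUE).
#' @return A [barcode_count_table()] of cell counts (ancestral founder
#'   sample plus one sample per condition x replicate).
#' @export
sim_count_table <- function(sim, drop_zero = TRUE) {
  samples <- names(sim$final_counts)
  groups <- ifelse(samples == "ancestral", "ancestral",
                   sub("_rep[0-9]+$", "", samples))
  counts <- lapply(sim$final_counts, function(x) x[x > 0 | !drop_zero])
  barcode_count_table(counts, groups)
}

#' Write one condition's simulated growth-rate trajectory as TSV
#'
#' Columns `replicate, generation, growth_rate_per_day`, the format
#' [read_trajectory()] consumes.
#'
#' @param sim A `sim_output`.
#' @param condition Condition to export.
#' @param path Output path.
#' @export
write_sim_trajectory <- function(sim, condition, path) {
  tr <- sim$trajectories
  tr <- tr[tr$condition == condition,
           c("replicate", "generation", "growth_rate_per_day")]
  data.table::fwrite(tr, path, sep = "\t")
  invisible(path)
}

#' Generate paired-end barcode amplicon reads
#'
#' Reads are drawn multinomially from the lineage frequencies. Each
#' template is `pad5 + flank5 + barcode + flank3 + pad3`; mate 1 is its
#' first `read_len` bases, mate 2 the reverse complement of its last
#' `read_len` bases (so mates overlap by `2 * read_len - template length`).
#' Substitution errors hit each mate base independently at `error_rate`.
#' A fraction `frac_low` of read pairs carries the low Phred value on
#' every base to exercise the quality filter; the rest carry the high one.
#'
#' @param frequencies Named numeric vector (barcode -> frequency, sums
#'   to 1).
#' @param n_reads Number of read pairs (> 0).
#' @param fastq1,fastq2 Output FASTQ paths.
#' @param error_rate Per-base substitution probability in `[0, 0.1]`.
#' @param read_len Mate length (default 75, as in 2 x 75 sequencing).
#' @param phred_high,phred_low,frac_low Quality mixture (defaults 37, 20,
#'   0).
#' @param flank5,flank3 Flank sequences.
#' @param seed Optional seed.
#' @return Truth data.frame `barcode, reads`, invisibly alongside the
#'   written files.
#' @export
generate_reads <- function(frequencies, n_reads, fastq1, fastq2,
                           error_rate = 0, read_len = 75L,
                           phred_high = 37L, phred_low = 20L, frac_low = 0,
                           flank5 = barcode_flanks()[["flank5"]],
                           flank3 = barcode_flanks()[["flank3"]],
                           seed = NULL) {
  if (n_reads <= 0) stop("n_reads must be positive")
  stopifnot(abs(sum(frequencies) - 1) < 1e-8,
            error_rate >= 0, error_rate <= 0.1)
  if (!is.null(seed)) set.seed(seed)
  pad5 <- "TCGATTCACGCGTAACGCTAG"
  core_len <- nchar(pad5) + nchar(flank5) + 20L + nchar(flank3)
  template_len <- max(2L * read_len - 50L, core_len + 10L)
  pad3 <- paste(rep("CATG", ceiling((template_len - core_len) / 4)),
                collapse = "")
  pad3 <- substr(pad3, 1L, template_len - core_len)

  counts <- as.numeric(stats::rmultinom(1, n_reads, frequencies))
  truth <- data.frame(barcode = names(frequencies), reads = counts)
  bc_of_read <- rep(names(frequencies), counts)
  bc_of_read <- sample(bc_of_read)  # shuffle read order

  templates <- paste0(pad5, flank5, bc_of_read, flank3, pad3)
  m1 <- substr(templates, 1L, read_len)
  m2 <- revcomp(substr(templates, nchar(templates) - read_len + 1L,
                       nchar(templates)))
  if (error_rate > 0) {
    m1 <- vapply(m1, mutate_seq, character(1), rate = error_rate,
                 USE.NAMES = FALSE)
    m2 <- vapply(m2, mutate_seq, character(1), rate = error_rate,
                 USE.NAMES = FALSE)
  }
  low <- stats::runif(length(m1)) < frac_low
  qv <- ifelse(low, phred_low, phred_high)
  ids <- sprintf("read_%06d", seq_along(m1))
  write_fastq(fastq1, ids, m1, lapply(qv, rep, read_len))
  write_fastq(fastq2, ids, m2, lapply(qv, rep, read_len))
  invisible(truth)
}

# substitution errors on one sequence at per-base probability `rate`
mutate_seq <- function(seq, rate) {
  n <- nchar(seq)
  k <- stats::rbinom(1, n, rate)
  if (k == 0) return(seq)
  pos <- sample.int(n, k)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

#' Generate a synthetic RRBS-style methylation dataset with truth
#'
#' Regions are laid out well apart (gap > 200 bp between regions, members
#' within 50 bp) on one synthetic chromosome. Each region draws a true
#' methylation level `pi` uniformly on `pi_range`; in condition B a random
#' `frac_affected` subset is shifted by `-effect` on the log-odds scale.
#' Per-locus methylated counts are binomial in the per-locus coverage.
#'
#' @param n_regions Number of regions.
#' @param loci_per_region CpG loci per region (default 5).
#' @param coverage Per-locus coverage: a constant or a `function(n)`
#'   returning integer coverages (default constant 50).
#' @param effect Log-odds condition effect on affected regions (default 2).
#' @param frac_affected Fraction of regions carrying the effect
#'   (default 0.2).
#' @param replicates Integer vector `c(A =, B =)` (default 4 and 4).
#' @param pi_range True methylation-level range (default `c(0.55, 0.95)`,
#'   inside the region-methylation filter).
#' @param dir Optional directory: coverage files and a `samples.tsv` sheet
#'   are written there.
#' @param seed Optional seed.
#' @return List: `loci` (a `cpg_matrix`), `truth` (data.frame `region,
#'   start, end, affected, pi_A, pi_B`), and `sheet` when `dir` is given.
#' @export
generate_methylation_dataset <- function(n_regions, loci_per_region = 5L,
                                         coverage = 50, effect = 2,
                                         frac_affected = 0.2,
                                         replicates = c(A = 4L, B = 4L),
                                         pi_range = c(0.55, 0.95),
                                         dir = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_samp <- sum(replicates)
  condition <- rep(names(replicates), replicates)
  samples <- paste0(condition, "_rep", unlist(lapply(replicates, seq_len)))
  names(condition) <- samples

  region_start <- 1000L + (seq_len(n_regions) - 1L) * 1500L
  pos <- as.integer(outer(seq(0L, by = 50L,
                              length.out = loci_per_region),
                          region_start, "+"))
  region_id <- rep(seq_len(n_regions), each = loci_per_region)

  pi_A <- stats::runif(n_regions, pi_range[1], pi_range[2])
  affected <- stats::runif(n_regions) < frac_affected
  pi_B <- stats::plogis(stats::qlogis(pi_A) - effect * affected)

  cov_fun <- if (is.function(coverage)) coverage else {
    function(n) rep(as.integer(coverage), n)
  }
  n_loci <- length(pos)
  M <- matrix(0L, n_loci, n_samp, dimnames = list(NULL, samples))
  Tt <- matrix(0L, n_loci, n_samp, dimnames = list(NULL, samples))
  for (j in seq_len(n_samp)) {
    pi_j <- if (condition[j] == "A") pi_A else pi_B
    Tt[, j] <- cov_fun(n_loci)
    M[, j] <- stats::rbinom(n_loci, Tt[, j], pi_j[region_id])
  }
  loci <- cpg_matrix(rep("chrS", n_loci), pos, M, Tt - M, condition)

  truth <- data.frame(region = seq_len(n_regions),
                      start = region_start,
                      end = region_start + (loci_per_region - 1L) * 50L,
                      affected = affected, pi_A = pi_A, pi_B = pi_B)
  out <- list(loci = loci, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(dir, paste0(samples, ".cov"))
    for (j in seq_len(n_samp)) {
      cov <- M[, j] + (Tt - M)[, j]
      pct <- ifelse(cov > 0, 100 * M[, j] / cov, 0)
      writeLines(sprintf("chrS\t%d\t%d\t%s\t%d\t%d", pos, pos,
                         formatC(pct, format = "f", digits = 6),
                         M[, j], cov - M[, j]),
                 paths[j])
    }
    sheet <- data.frame(sample = samples, condition = unname(condition),
                        path = paths)
    data.table::fwrite(sheet, file.path(dir, "samples.tsv"), sep = "\t")
    out$sheet <- sheet
  }
  out
}

#' Generate a synthetic cell image with masks and truth
#'
#' A disk nucleus inside a disk cell on a uniform background, with optional
#' Gaussian noise; intensities are configured means so the analytic
#' N/C ratio is known.
#'
#' @param size Image side length, pixels (default 128).
#' @param cell_radius,nuc_radius Disk radii, pixels (nucleus < cell).
#' @param intensity_nuc,intensity_cyto,background Mean intensities.
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @param seed Optional seed.
#' @return List: `image`, `nuc_mask`, `cell_mask`, and `truth`
#'   (`ratio` = configured N/C ratio, `area_px` = cell mask pixel count).
#' @export
generate_cell_image <- function(size = 128L, cell_radius = 40,
                                nuc_radius = 15, intensity_nuc = 1000,
                                intensity_cyto = 500, background = 100,
                                noise_sd = 0, seed = NULL) {
  if (nuc_radius >= cell_radius)
    stop("nucleus radius must be smaller than cell radius")
  if (!is.null(seed)) set.seed(seed)
  ctr <- (size + 1) / 2
  d2 <- outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, "+")
  cell_mask <- d2 <= cell_radius^2
  nuc_mask <- d2 <= nuc_radius^2
  img <- matrix(background, size, size)
  img[cell_mask] <- intensity_cyto
  img[nuc_mask] <- intensity_nuc
  if (noise_sd > 0)
    img <- img + matrix(stats::rnorm(size^2, 0, noise_sd), size, size)
  list(image = img, nuc_mask = nuc_mask, cell_mask = cell_mask,
       truth = list(
         ratio = (intensity_nuc - background) /
           (intensity_cyto - background),
         area_px = sum(cell_mask)))
}

#' Generate a noisy growth-rate trajectory from the selection model
#'
#' Evaluates [predicted_growth_rate()] on the generation grid and adds
#' i.i.d. Gaussian noise per replicate; replicates are aggregated to mean,
#' SEM and n.
#'
#' @param params A [selection_params()] with growth-rate endpoints.
#' @param generations Generation grid (default 0:40).
#' @param noise_sd Per-observation noise, doublings/day (default 0).
#' @param replicates Replicates per generation (default 1).
#' @param seed Optional seed.
#' @return List: `trajectory` (a [growth_trajectory()]) and `replicates`
#'   (long data.frame `replicate, generation, growth_rate_per_day`).
#' @export
make_growth_trajectory <- function(params, generations = 0:40,
                                   noise_sd = 0, replicates = 1L,
                                   seed = NULL) {
  stopifnot(noise_sd >= 0, replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  mu <- predicted_growth_rate(params, generations)
  long <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    data.frame(replicate = r, generation = generations,
               growth_rate_per_day = mu +
                 stats::rnorm(length(mu), 0, noise_sd))
  }))
  agg <- stats::aggregate(growth_rate_per_day ~ generation, long, mean)
  sem <- stats::aggregate(growth_rate_per_day ~ generation, long,
                          function(x) stats::sd(x) / sqrt(length(x)))
  traj <- growth_trajectory(agg$generation, agg$growth_rate_per_day,
                            sem = if (replicates > 1)
                              sem$growth_rate_per_day else NA_real_,
                            n = replicates)
  list(trajectory = traj, replicates = long)
}
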