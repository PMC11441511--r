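#' Read a Bismark-style CpG coverage file
#'
#' Six tab-separated columns: `chrom, start, end, methylation_pct,
#' count_methylated, count_unmethylated`. The percentage column is
#' recomputed from the counts and must agree within 0.1.
#'
#' @param path Coverage file path.
#' @param sample Sample label attached to the result (default: file stem).
#' @return data.table with columns `chrom, pos, m, u, sample`.
#' @export
read_coverage <- function(path, sample = NULL) {
  if (is.null(sample))
    sample <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.table::data.table(chrom = character(0), pos = integer(0),
                                  m = integer(0), u = integer(0),
                                  sample = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 6L))
    stop("malformed coverage line ", which(nf != 6L)[1], " in ", path,
         ": expected 6 tab-separated fields")
  mat <- matrix(unlist(parts), ncol = 6L, byrow = TRUE)
  pos <- suppressWarnings(as.integer(mat[, 2]))
  pct <- suppressWarnings(as.numeric(mat[, 4]))
  m <- suppressWarnings(as.integer(mat[, 5]))
  u <- suppressWarnings(as.integer(mat[, 6]))
  bad <- which(is.na(pos) | is.na(pct) | is.na(m) | is.na(u) |
                 pos <= 0L | m < 0L | u < 0L)
  if (length(bad))
    stop("malformed coverage line ", bad[1], " in ", path)
  recomputed <- ifelse(m + u > 0, 100 * m / (m + u), 0)
  off <- which(abs(recomputed - pct) > 0.1)
  if (length(off))
    stop("inconsistent methylation percentage at line ", off[1], " in ",
         path, " (stated ", pct[off[1]], ", counts give ",
         round(recomputed[off[1]], 3), ")")
  data.table::data.table(chrom = mat[, 1], pos = pos, m = m, u = u,
                         sample = sample)
}

#' Load a methylation sample sheet and its coverage files
#'
#' @param sheet data.frame (or TSV path) with columns
#'   `sample, condition, path`.
#' @return A `cpg_matrix`: list with `chrom`, `pos`, per-sample count
#'   matrices `M` and `U` (loci x samples), and `condition` (named by
#'   sample). Only loci present in every sample are kept.
#' @export
read_methylation_samples <- function(sheet) {
  if (is.character(sheet)) sheet <- data.table::fread(sheet, sep = "\t")
  stopifnot(all(c("sample", "condition", "path") %in% names(sheet)))
  covs <- Map(read_coverage, sheet$path, sheet$sample)
  keys <- lapply(covs, function(d) paste(d$chrom, d$pos))
  common <- Reduce(intersect, keys)
  first <- covs[[1]][match(common, keys[[1]]), ]
  ord <- order(first$chrom, first$pos)
  common <- common[ord]
  M <- sapply(seq_along(covs), function(i)
    covs[[i]]$m[match(common, keys[[i]])])
  U <- sapply(seq_along(covs), function(i)
    covs[[i]]$u[match(common, keys[[i]])])
  M <- matrix(M, ncol = length(covs),
              dimnames = list(NULL, sheet$sample))
  U <- matrix(U, ncol = length(covs),
              dimnames = list(NULL, sheet$sample))
  structure(list(chrom = first$chrom[ord], pos = first$pos[ord],
                 M = M, U = U,
                 condition = stats::setNames(sheet$condition, sheet$sample)),
            class = "cpg_matrix")
}

#' Build a `cpg_matrix` from in-memory count matrices
#'
#' @param chrom,pos Locus coordinates (1-based).
#' @param M,U Methylated / unmethylated count matrices (loci x samples).
#' @param condition Named condition labels, one per sample column.
#' @return A `cpg_matrix`.
#' @export
cpg_matrix <- function(chrom, pos, M, U, condition) {
  stopifnot(length(chrom) == length(pos), nrow(M) == length(pos),
            all(dim(M) == dim(U)), ncol(M) == length(condition))
  if (is.null(colnames(M))) colnames(M) <- names(condition)
  if (is.null(colnames(U))) colnames(U) <- names(condition)
  ord <- order(chrom, pos)
  structure(list(chrom = chrom[ord], pos = pos[ord],
                 M = M[ord, , drop = FALSE], U = U[ord, , drop = FALSE],
                 condition = condition),
            class = "cpg_matrix")
}

#' Drop low-coverage CpG loci
#'
#' Default scope `"each"` keeps a locus only when its coverage `m + u`
#' reaches `min_cov` in every sample (strictest reading, avoids condition
#' imbalance); `"pooled"` tests the summed coverage across samples.
#'
#' @param loci A `cpg_matrix`.
#' @param min_cov Minimum read coverage (default 25).
#' @param scope `"each"` or `"pooled"`.
#' @return Filtered `cpg_matrix`.
#' @export
filter_low_coverage <- function(loci, min_cov = 25, scope = c("each", "pooled")) {
  scope <- match.arg(scope)
  stopifnot(min_cov >= 0)
  cov <- loci$M + loci$U
  keep <- if (scope == "each") {
    rowSums(cov >= min_cov) == ncol(cov)
  } else {
    rowSums(cov) >= min_cov
  }
  cpg_matrix(loci$chrom[keep], loci$pos[keep],
             loci$M[keep, , drop = FALSE], loci$U[keep, , drop = FALSE],
             loci$condition)
}

#' Chain CpG loci into methylation regions
#'
#' Greedy chaining along each chromosome: a locus joins the current region
#' iff the gap to the previous member position is at most `max_gap` bases
#' (default 200). Region counts are the sums over member loci.
#'
#' @param loci A `cpg_matrix` (sorted internally by chrom, pos).
#' @param max_gap Maximum gap between consecutive members, bases.
#' @return A `methyl_regions`: data.frame with `chrom, start, end, n_loci`
#'   plus matrices `M`, `T` (regions x samples) and `condition` as
#'   attributes.
#' @export
aggregate_regions <- function(loci, max_gap = 200) {
  n <- length(loci$pos)
  if (n == 0L) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_loci = integer(0))
    attr(out, "M") <- loci$M; attr(out, "T") <- loci$M + loci$U
    attr(out, "condition") <- loci$condition
    class(out) <- c("methyl_regions", "data.frame")
    return(out)
  }
  new_region <- c(TRUE, loci$chrom[-1] != loci$chrom[-n] |
                    diff(loci$pos) > max_gap)
  rid <- cumsum(new_region)
  Tm <- loci$M + loci$U
  M <- rowsum(loci$M, rid)
  Tt <- rowsum(Tm, rid)
  out <- data.frame(
    chrom = tapply(loci$chrom, rid, `[`, 1),
    start = as.integer(tapply(loci$pos, rid, min)),
    end = as.integer(tapply(loci$pos, rid, max)),
    n_loci = as.integer(tabulate(rid)),
    row.names = NULL)
  attr(out, "M") <- M
  attr(out, "T") <- Tt
  attr(out, "condition") <- loci$condition
  class(out) <- c("methyl_regions", "data.frame")
  out
}

region_meth_fraction <- function(regions) {
  attr(regions, "M") / attr(regions, "T")
}

subset_regions <- function(regions, keep) {
  M <- attr(regions, "M"); Tt <- attr(regions, "T")
  cond <- attr(regions, "condition")
  out <- as.data.frame(regions)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "M") <- M[keep, , drop = FALSE]
  attr(out, "T") <- Tt[keep, , drop = FALSE]
  attr(out, "condition") <- cond
  class(out) <- c("methyl_regions", "data.frame")
  out
}

#' Keep regions methylated in most replicates of some condition
#'
#' A region is retained iff there is a condition in which the fraction of
#' replicates with region-level methylation `M/T >= min_meth` exceeds
#' `min_rep_frac`.
#'
#' @param regions A `methyl_regions` from [aggregate_regions()].
#' @param min_meth Methylation-level threshold (default 0.5).
#' @param min_rep_frac Replicate-fraction threshold, strict (default 0.75).
#' @return Filtered `methyl_regions`.
#' @export
filter_regions_by_methylation <- function(regions, min_meth = 0.5,
                                          min_rep_frac = 0.75) {
  cond <- attr(regions, "condition")
  frac <- region_meth_fraction(regions)
  keep <- rep(FALSE, nrow(regions))
  for (cc in unique(cond)) {
    idx <- which(cond == cc)
    if (!length(idx)) stop("condition with zero replicates: ", cc)
    hit <- rowMeans(frac[, idx, drop = FALSE] >= min_meth, na.rm = FALSE)
    keep <- keep | (hit > min_rep_frac)
  }
  subset_regions(regions, keep)
}

# binomial-logistic IRLS for a design matrix X on grouped counts (m, t);
# returns coefficients and deviance
binom_irls <- function(m, t, X, tol = 1e-8, maxit = 50L) {
  # clamp proportions away from 0/1 so separated groups stay finite
  y <- pmin(pmax(m / t, 0.5 / t), 1 - 0.5 / t)
  beta <- rep(0, ncol(X))
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- t * mu * (1 - mu)
    z <- eta + (y - mu) / (mu * (1 - mu))
    fit <- stats::lm.wfit(X, z, w)
    beta <- fit$coefficients
    mu <- stats::plogis(drop(X %*% beta))
    dev <- 2 * sum(t * (xlogy(y, y / mu) + xlogy(1 - y, (1 - y) / (1 - mu))))
    if (abs(dev - dev_old) < tol) { converged <- TRUE; break }
    dev_old <- dev
  }
  list(beta = beta, deviance = dev, converged = converged)
}

xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))

#' Likelihood-ratio test for a condition effect on region methylation
#'
#' Fits the binomial-logistic model `logit(pi_j) = beta0 + beta1 * cond_j`
#' to the per-sample region counts by iteratively reweighted least squares
#' and compares it with the intercept-only null; the likelihood-ratio
#' statistic `deviance(null) - deviance(full)` is referred to chi-square
#' with 1 degree of freedom.
#'
#' @param m,t Methylated and total counts per sample (t > 0 everywhere).
#' @param condition Two-level factor/character of condition labels.
#' @return List: `beta0`, `beta1` (log-odds, effect of the second condition
#'   level), `lrt`, `p`, `converged`.
#' @export
binomial_glm_lrt <- function(m, t, condition) {
  condition <- as.factor(condition)
  if (nlevels(condition) != 2L)
    stop("exactly two conditions required, got ", nlevels(condition))
  if (any(t <= 0)) stop("every sample needs positive region coverage")
  X1 <- cbind(1, as.numeric(condition) - 1)
  X0 <- X1[, 1, drop = FALSE]
  full <- binom_irls(m, t, X1)
  null <- binom_irls(m, t, X0)
  lrt <- max(0, null$deviance - full$deviance)
  list(beta0 = unname(full$beta[1]), beta1 = unname(full$beta[2]),
       lrt = lrt, p = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
       converged = full$converged && null$converged)
}

#' Benjamini-Hochberg adjustment
#'
#' @param pvals P-values in `[0, 1]`.
#' @param method Only `"BH"` is offered.
#' @return Adjusted p-values, same order as the input.
#' @export
adjust_pvalues <- function(pvals, method = "BH") {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = method)
}

#' Test all regions and call DMRs
#'
#' Runs [binomial_glm_lrt()] per region, BH-adjusts, and flags
#' differentially methylated regions at `p_adjust <= max_p_adjust` and
#' `p <= max_p` (both thresholds applied, as stated — under BH the raw-p
#' condition is implied by the adjusted one, but it is kept literal).
#'
#' @param regions A `methyl_regions`.
#' @param max_p_adjust Adjusted-p threshold (default 0.01).
#' @param max_p Raw-p threshold (default 0.05).
#' @return data.frame: region coordinates, per-condition mean methylation,
#'   `beta0`, `beta1`, `lrt`, `p`, `p_adjust`, `is_dmr`.
#' @export
test_regions <- function(regions, max_p_adjust = 0.01, max_p = 0.05) {
  M <- attr(regions, "M"); Tt <- attr(regions, "T")
  cond <- attr(regions, "condition")
  lv <- unique(cond)
  if (length(lv) != 2L) stop("exactly two conditions required")
  res <- lapply(seq_len(nrow(regions)), function(i)
    binomial_glm_lrt(M[i, ], Tt[i, ], cond))
  frac <- M / Tt
  out <- data.frame(
    regions[, c("chrom", "start", "end", "n_loci")],
    meth_A = rowMeans(frac[, cond == lv[1], drop = FALSE]),
    meth_B = rowMeans(frac[, cond == lv[2], drop = FALSE]),
    beta0 = vapply(res, `[[`, numeric(1), "beta0"),
    beta1 = vapply(res, `[[`, numeric(1), "beta1"),
    lrt = vapply(res, `[[`, numeric(1), "lrt"),
    p = vapply(res, `[[`, numeric(1), "p"),
    converged = vapply(res, `[[`, logical(1), "converged"))
  out$p_adjust <- adjust_pvalues(out$p)
  out$is_dmr <- call_dmrs(out$p, out$p_adjust, max_p_adjust, max_p)
  attr(out, "conditions") <- lv
  out
}

#' DMR decision rule
#'
#' @param p,p_adjust Raw and BH-adjusted p-values.
#' @param max_p_adjust,max_p Thresholds (defaults 0.01 and 0.05).
#' @return Logical DMR calls.
#' @export
call_dmrs <- function(p, p_adjust, max_p_adjust = 0.01, max_p = 0.05) {
  p_adjust <= max_p_adjust & p <= max_p
}

#' Write DMR results as TSV and optionally BED
#'
#' The BED export converts the 1-based inclusive region coordinates to
#' 0-based half-open (`start - 1`, `end`).
#'
#' @param results Output of [test_regions()].
#' @param tsv Output TSV path.
#' @param bed Optional BED path for the `is_dmr` rows.
#' @export
write_dmr_results <- function(results, tsv, bed = NULL) {
  data.table::fwrite(results, tsv, sep = "\t")
  if (!is.null(bed)) {
    d <- results[results$is_dmr, ]
    data.table::fwrite(
      data.frame(chrom = d$chrom, start = d$start - 1L, end = d$end,
                 name = sprintf("DMR_%d", seq_len(nrow(d))),
                 score = round(pmin(1000, d$lrt)),
                 strand = "."),
      bed, sep = "\t", col.names = FALSE)
  }
  invisible(tsv)
}

#' Full region-level methylation analysis
#'
#' Coverage filter (>= `min_cov` in every sample), 200-bp chaining,
#' methylation-level region filter, per-region binomial GLM LRT, BH
#' adjustment and DMR calls.
#'
#' @param loci A `cpg_matrix` (e.g. from [read_methylation_samples()]).
#' @param min_cov,max_gap,min_meth,min_rep_frac,max_p_adjust,max_p
#'   Stage parameters; defaults 25, 200, 0.5, 0.75, 0.01, 0.05.
#' @return The [test_regions()] data.frame.
#' @export
methylation_pipeline <- function(loci, min_cov = 25, max_gap = 200,
                                 min_meth = 0.5, min_rep_frac = 0.75,
                                 max_p_adjust = 0.01, max_p = 0.05) {
  loci <- filter_low_coverage(loci, min_cov = min_cov)
  regions <- aggregate_regions(loci, max_gap = max_gap)
  regions <- filter_regions_by_methylation(regions, min_meth = min_meth,
                                           min_rep_frac = min_rep_frac)
  test_regions(regions, max_p_adjust = max_p_adjust, max_p = max_p)
}
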