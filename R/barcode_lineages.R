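#' Build a barcode count table across samples
#'
#' @param counts Named list, one element per sample: a named numeric vector
#'   of read counts per barcode.
#' @param groups Character vector (one per sample) of group labels from
#'   `ancestral`, `soft`, `stiff`.
#' @return A `barcode_count_table`: integer matrix (barcodes x samples) with
#'   a `groups` attribute.
#' @export
barcode_count_table <- function(counts, groups) {
  stopifnot(is.list(counts), length(counts) == length(groups),
            !is.null(names(counts)))
  bad <- setdiff(unique(groups), c("ancestral", "soft", "stiff"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  barcodes <- sort(unique(unlist(lapply(counts, names))))
  mat <- matrix(0, nrow = length(barcodes), ncol = length(counts),
                dimnames = list(barcodes, names(counts)))
  for (s in names(counts)) mat[names(counts[[s]]), s] <- counts[[s]]
  if (any(mat < 0)) stop("counts must be non-negative")
  structure(mat, groups = stats::setNames(as.character(groups),
                                          names(counts)),
            class = c("barcode_count_table", class(mat)))
}

#' @export
print.barcode_count_table <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf("barcode_count_table: %d barcodes x %d samples (%s)\n",
              nrow(x), ncol(x),
              paste(sprintf("%s: %d", names(table(g)), table(g)),
                    collapse = ", ")))
  invisible(x)
}

table_groups <- function(table) attr(table, "groups")

#' Per-sample barcode frequencies
#'
#' @param table A [barcode_count_table()].
#' @return Matrix of the same shape with columns summing to 1 (columns with
#'   zero reads stay zero).
#' @export
barcode_frequencies <- function(table) {
  tot <- colSums(table)
  tot[tot == 0] <- 1
  sweep(unclass(table), 2, tot, "/")
}

# Levenshtein distances from one barcode to a set; Hamming fast path is
# exact for equal-length strings when max_dist <= 1 (a single edit keeps
# length only if it is a substitution).
dist_to_set <- function(bc, set, max_dist) {
  if (max_dist <= 1L && all(nchar(set) == nchar(bc))) {
    r <- charToRaw(bc)
    m <- matrix(unlist(lapply(set, charToRaw)), nrow = length(r))
    colSums(m != r)
  } else {
    drop(utils::adist(bc, set))
  }
}

#' Cluster barcodes by Levenshtein distance
#'
#' Greedy abundance-ordered clustering emulating starcode's message
#' passing: barcodes are processed in decreasing count order (ties broken
#' lexicographically); each attaches to the most abundant earlier barcode
#' within `max_dist` edits whose own count is at least `min_ratio` times
#' its own, inheriting that parent's cluster root (so sequencing-error
#' chains — a two-error read one edit from a one-error read — collapse
#' transitively onto the true barcode). A barcode with no qualifying parent
#' founds its own cluster. Total reads are conserved.
#'
#' @param raw Named numeric vector: read count per raw barcode.
#' @param max_dist Maximum Levenshtein distance for absorption (default 1).
#' @param min_ratio Minimum parent/child count ratio (default 3).
#' @return Named numeric vector of clustered counts per root barcode,
#'   decreasing.
#' @export
cluster_barcodes <- function(raw, max_dist = 1L, min_ratio = 3) {
  stopifnot(max_dist >= 0, min_ratio >= 1)
  if (!length(raw)) return(stats::setNames(numeric(0), character(0)))
  if (is.null(names(raw)) || anyDuplicated(names(raw)))
    stop("raw must be a named vector with unique barcode names")
  ord <- order(-raw, names(raw))
  bcs <- names(raw)[ord]
  cnt <- unname(raw[ord])
  n <- length(bcs)

  same_len <- length(unique(nchar(bcs))) == 1L
  fast <- same_len && max_dist <= 1L
  if (fast) {
    # Hamming equals Levenshtein at distance <= 1 for equal lengths
    chmat <- matrix(utf8ToInt(paste(bcs, collapse = "")),
                    nrow = nchar(bcs[1]))
  }

  root <- seq_len(n)
  for (i in seq_len(n)[-1]) {
    # counts are non-increasing, so qualifying parents form a prefix
    j_max <- min(i - 1L, findInterval(-min_ratio * cnt[i], -cnt))
    if (j_max < 1L) next
    d <- if (fast) {
      colSums(chmat[, seq_len(j_max), drop = FALSE] != chmat[, i])
    } else {
      drop(utils::adist(bcs[i], bcs[seq_len(j_max)]))
    }
    hit <- which(d <= max_dist)
    if (length(hit)) root[i] <- root[hit[1]]  # most abundant qualifying
  }
  out <- tapply(cnt, root, sum)
  out <- stats::setNames(as.numeric(out), bcs[as.integer(names(out))])
  out[order(-out, names(out))]
}

selected_samples <- function(table) {
  g <- table_groups(table)
  names(g)[g %in% c("soft", "stiff")]
}

#' Lineage-retention filters
#'
#' A lineage is retained iff it satisfies at least one of:
#' 1. frequency > `min_freq_any` (default 0.1%) in at least one sample AND
#'    detected in the ancestral population;
#' 2. detected in at least one soft- AND one stiff-selected sample, OR in
#'    more than `max_single_group` (default 2) samples of a single selected
#'    group;
#' 3. frequency > `min_freq_gel` (default 0.5%) in at least one
#'    gel-selected sample.
#'
#' @param table A [barcode_count_table()] with an ancestral sample and at
#'   least one sample per selected group.
#' @param min_freq_any Rule-1 frequency threshold (fraction, default 0.001).
#' @param min_freq_gel Rule-3 frequency threshold (fraction, default 0.005).
#' @param max_single_group Rule-2 single-group sample count above which a
#'   lineage is retained (default 2).
#' @param detect_min Minimum read count for "detected" (default 1).
#' @return data.frame: `barcode`, logical `rule1`..`rule3`, `retained`.
#' @export
apply_lineage_filters <- function(table, min_freq_any = 0.001,
                                  min_freq_gel = 0.005,
                                  max_single_group = 2, detect_min = 1) {
  g <- table_groups(table)
  anc <- names(g)[g == "ancestral"]
  if (!length(anc)) stop("table has no ancestral sample")
  soft <- names(g)[g == "soft"]
  stiff <- names(g)[g == "stiff"]
  if (!length(soft) || !length(stiff))
    stop("table needs at least one sample per selected group")

  freq <- barcode_frequencies(table)
  det <- unclass(table) >= detect_min
  gel <- c(soft, stiff)

  in_anc <- rowSums(det[, anc, drop = FALSE]) > 0
  rule1 <- apply(freq, 1, max) > min_freq_any & in_anc
  n_soft <- rowSums(det[, soft, drop = FALSE])
  n_stiff <- rowSums(det[, stiff, drop = FALSE])
  rule2 <- (n_soft > 0 & n_stiff > 0) |
    n_soft > max_single_group | n_stiff > max_single_group
  rule3 <- apply(freq[, gel, drop = FALSE], 1, max) > min_freq_gel

  data.frame(barcode = rownames(table),
             rule1 = unname(rule1), rule2 = unname(rule2),
             rule3 = unname(rule3),
             retained = unname(rule1 | rule2 | rule3),
             row.names = NULL)
}

#' Log2 fold change between frequencies
#'
#' `log2((freq_sel + pseudo) / (freq_anc + pseudo))`; the pseudocount keeps
#' lineages absent from one sample finite.
#'
#' @param freq_sel,freq_anc Frequencies (fractions), vectorized.
#' @param pseudo Pseudocount fraction, > 0.
#' @return Dimensionless log2 fold changes.
#' @export
log2_fold_change <- function(freq_sel, freq_anc, pseudo = 1e-6) {
  stopifnot(pseudo > 0)
  log2((freq_sel + pseudo) / (freq_anc + pseudo))
}

default_pseudo <- function(table) {
  tot <- colSums(table)
  1 / min(tot[tot > 0])
}

#' Stiffness-preference score of lineages
#'
#' Mean log2 fold change (vs the ancestral frequency) across soft-selected
#' replicates minus the mean across stiff-selected replicates. Positive
#' values mark soft-preferring lineages.
#'
#' @param table A [barcode_count_table()].
#' @param pseudo Pseudocount for [log2_fold_change()]; default is the
#'   reciprocal of the smallest library size.
#' @return Named numeric vector, one score per barcode.
#' @export
preference_score <- function(table, pseudo = NULL) {
  if (is.null(pseudo)) pseudo <- default_pseudo(table)
  g <- table_groups(table)
  freq <- barcode_frequencies(table)
  anc <- rowMeans(freq[, g == "ancestral", drop = FALSE])
  l2fc_group <- function(grp) {
    f <- freq[, g == grp, drop = FALSE]
    rowMeans(log2_fold_change(f, anc, pseudo))
  }
  l2fc_group("soft") - l2fc_group("stiff")
}

#' Per-lineage summary table
#'
#' Percent abundance per sample, number of stiffness-selected samples each
#' lineage is detected in, group-mean log2 fold changes vs ancestral, the
#' soft-vs-stiff preference score, and the retention flag with the rules
#' that fired.
#'
#' @inheritParams preference_score
#' @param ... Passed to [apply_lineage_filters()].
#' @return data.frame, one row per barcode, ordered by decreasing ancestral
#'   abundance.
#' @export
lineage_table <- function(table, pseudo = NULL, ...) {
  if (is.null(pseudo)) pseudo <- default_pseudo(table)
  g <- table_groups(table)
  freq <- barcode_frequencies(table)
  anc <- rowMeans(freq[, g == "ancestral", drop = FALSE])
  det <- unclass(table) >= 1
  filters <- apply_lineage_filters(table, ...)
  l2 <- function(grp) rowMeans(log2_fold_change(
    freq[, g == grp, drop = FALSE], anc, pseudo))
  pct <- 100 * freq
  colnames(pct) <- paste0("pct_", colnames(pct))
  out <- data.frame(barcode = rownames(table),
                    pct,
                    n_samples_detected = rowSums(
                      det[, selected_samples(table), drop = FALSE]),
                    log2fc_soft = unname(l2("soft")),
                    log2fc_stiff = unname(l2("stiff")),
                    preference_score = unname(l2("soft") - l2("stiff")),
                    row.names = NULL, check.names = FALSE)
  out <- cbind(out, filters[match(out$barcode, filters$barcode),
                            c("rule1", "rule2", "rule3", "retained")])
  rownames(out) <- NULL
  out[order(-anc, out$barcode), ]
}

#' Display form of a barcode
#'
#' Truncates to the first 8 bases plus an ellipsis, the convention used in
#' abundance plots; stored barcodes stay full-length.
#' @param barcode Character vector of barcodes.
#' @param n Bases to keep (default 8).
#' @return Character vector.
#' @export
short_barcode <- function(barcode, n = 8L) {
  ifelse(nchar(barcode) > n,
         paste0(substr(barcode, 1L, n), "…"), barcode)
}

#' Unique-lineage diversity summary
#'
#' Counts distinct detected lineages per sample and per group (union over
#' the group's replicates), and the percent decrease of each selected
#' group's union — and of all selected samples pooled — relative to the
#' ancestral count.
#'
#' @param table A [barcode_count_table()].
#' @param detect_min Minimum read count for "detected" (default 1).
#' @return List with `per_sample` (named integer vector), `per_group`
#'   (named integer vector of union counts) and `percent_decrease` (named:
#'   one entry per selected group plus `"selected"` for the pooled union).
#' @export
diversity_summary <- function(table, detect_min = 1) {
  g <- table_groups(table)
  det <- unclass(table) >= detect_min
  per_sample <- colSums(det)
  anc_n <- sum(rowSums(det[, g == "ancestral", drop = FALSE]) > 0)
  if (anc_n == 0) stop("no lineages detected in the ancestral sample")
  union_n <- function(samples)
    sum(rowSums(det[, samples, drop = FALSE]) > 0)
  groups <- unique(g)
  per_group <- stats::setNames(
    vapply(groups, function(gr) union_n(names(g)[g == gr]), numeric(1)),
    groups)
  sel_groups <- setdiff(groups, "ancestral")
  pd <- vapply(sel_groups,
               function(gr) 100 * (1 - per_group[[gr]] / anc_n), numeric(1))
  pd <- c(pd, selected = 100 * (1 - union_n(selected_samples(table)) / anc_n))
  list(per_sample = per_sample, per_group = per_group,
       percent_decrease = pd, ancestral_lineages = anc_n)
}

#' Write a long-format counts TSV (`barcode, sample, count`)
#'
#' @param table A [barcode_count_table()].
#' @param path Output path.
#' @export
write_counts_tsv <- function(table, path) {
  long <- data.table::as.data.table(as.table(unclass(table)))
  data.table::setnames(long, c("barcode", "sample", "count"))
  data.table::fwrite(long[long$count > 0, ], path, sep = "\t")
  invisible(path)
}

#' Read a long-format counts TSV back into a count table
#'
#' @param path TSV with columns `barcode, sample, count`.
#' @param groups Named character vector mapping sample -> group.
#' @return A [barcode_count_table()].
#' @export
read_counts_tsv <- function(path, groups) {
  dt <- data.table::fread(path, sep = "\t")
  stopifnot(all(c("barcode", "sample", "count") %in% names(dt)))
  samples <- names(groups)
  counts <- lapply(samples, function(s) {
    sub <- dt[dt$sample == s, ]
    stats::setNames(sub$count, sub$barcode)
  })
  names(counts) <- samples
  barcode_count_table(counts, unname(groups))
}
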