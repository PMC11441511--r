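# independent oracles and shared fixtures

# iterative per-generation frequency update: multiply focal abundance by w,
# renormalize; independent of the closed form under test
iterate_frequency <- function(p0, w, t) {
  p <- p0
  for (i in seq_len(t)) p <- p * w / (p * w + (1 - p))
  p
}

# G-test statistic on a pooled 2x2 table (methylated/unmethylated x group)
g_test_2x2 <- function(m1, t1, m2, t2) {
  obs <- c(m1, t1 - m1, m2, t2 - m2)
  row_tot <- c(t1, t2)
  col_tot <- c(m1 + m2, t1 + t2 - m1 - m2)
  exp_ <- outer(row_tot, col_tot) / sum(row_tot)
  exp_ <- as.vector(t(exp_))  # order: m1, u1, m2, u2
  2 * sum(ifelse(obs == 0, 0, obs * log(obs / exp_)))
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
mw_enum_p <- function(a, b) {
  vals <- c(a, b)
  na <- length(a)
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_stat(a, b)
  combs <- utils::combn(length(vals), na)
  u_all <- apply(combs, 2, function(idx)
    u_stat(vals[idx], vals[-idx]))
  mu <- na * length(b) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# toy count table spanning the three lineage-retention rules
toy_count_table <- function() {
  total <- 10000
  counts <- list(
    anc = c(L_anc_only = 20, L_everywhere = 500, L_rich_gel = 5,
            L_bg1 = total - 20 - 500 - 5),
    soft_rep1 = c(L_everywhere = 400, L_both_rare = 1, L_single_low = 5,
                  L_tri = 10, L_bg2 = total - 416),
    soft_rep2 = c(L_everywhere = 400, L_tri = 10, L_bg2 = total - 410),
    soft_rep3 = c(L_tri = 10, L_bg2 = total - 10),
    stiff_rep1 = c(L_everywhere = 450, L_both_rare = 1, L_rich_gel = 60,
                   L_bg3 = total - 511),
    stiff_rep2 = c(L_everywhere = 450, L_bg3 = total - 450))
  barcode_count_table(counts,
                      c("ancestral", "soft", "soft", "soft",
                        "stiff", "stiff"))
}

phred_template_pair <- function(seed = 1, n = 120, overlap = 40) {
  set.seed(seed)
  tmpl <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  s1 <- substr(tmpl, 1, 80)
  s2_fwd <- substr(tmpl, 41, 120)
  s2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s2_fwd)))
  list(template = tmpl, seq1 = s1, seq2 = s2,
       qual1 = rep(35L, nchar(s1)), qual2 = rep(35L, nchar(s2)))
}
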