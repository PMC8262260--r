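# Independent oracles, written without reference to the implementation.

# brute-force VDJ doublet truth: literal transcription of rules (a)-(e)
# from chain counts and a label, evaluated case by case
brute_force_vdj <- function(n_igh, n_light, n_tra, n_trb, type,
                            b_types = "B", t_types = "T",
                            count_dual_tra = FALSE) {
  bcr <- n_igh + n_light > 0
  tcr <- n_tra + n_trb > 0
  fired <- character(0)
  if (bcr && tcr) fired <- c(fired, "a")
  if (n_igh >= 2 || n_light >= 2) fired <- c(fired, "b")
  if (n_trb >= 2 || (count_dual_tra && n_tra >= 2)) fired <- c(fired, "c")
  if (!is.na(type)) {
    if (bcr && !(type %in% b_types)) fired <- c(fired, "d")
    if (tcr && !(type %in% t_types)) fired <- c(fired, "e")
  }
  subtype <- if (!length(fired)) "none"
  else if (any(c("a", "d", "e") %in% fired)) "heterotypic"
  else if (identical(fired, "b")) "homotypic_BCR"
  else "homotypic_TCR"
  list(flag = length(fired) > 0, rules = fired, subtype = subtype)
}

# build a contig table holding the given chain multiset on one barcode,
# with distinct CDR3s so nothing collapses
contig_fixture <- function(chains, barcode = "BC1", umis = 10) {
  if (!length(chains))
    return(as_contig_df(data.frame(barcode = character(0),
                                   chain = character(0),
                                   productive = logical(0),
                                   umis = integer(0),
                                   v_gene = character(0),
                                   cdr3 = character(0))))
  as_contig_df(data.frame(
    barcode = barcode, chain = chains, productive = TRUE,
    umis = as.integer(umis),
    v_gene = paste0(chains, "V1"),
    cdr3 = sprintf("CDR%02d", seq_along(chains)),
    stringsAsFactors = FALSE))
}

as_contig_df <- function(df) {
  df$usable <- df$chain %in% c("IGH", "IGK", "IGL", "TRA", "TRB")
  df
}

# brute-force 1-D two-class threshold: grid minimiser of balanced
# misclassification (mean of the two class error rates); the empirical
# objective plateaus near the optimum, so the plateau centre is returned
grid_threshold <- function(pos, neg, n_grid = 4000) {
  grid <- seq(min(c(pos, neg)), max(c(pos, neg)), length.out = n_grid)
  err <- vapply(grid, function(t)
    (mean(pos <= t) + mean(neg > t)) / 2, numeric(1))
  mean(grid[err <= min(err) + 1e-3])
}

# analytic intersection of two equal-variance weighted normal densities
gaussian_intersection <- function(w1, m1, w2, m2, sd) {
  (m1 + m2) / 2 + sd^2 * log(w1 / w2) / (m2 - m1)
}

# adjusted Rand index between two partitions (contingency-table formula)
rand_index_adj <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
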