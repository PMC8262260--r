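# Shared fixtures, generated in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small three-type multi-omic dataset shared across test files
small_sim <- function() {
  cached("small_sim", generate_synthetic(
    synth_config(n_cells = c("B cell" = 450, "T cell" = 750,
                             "Monocyte" = 300),
                 seed = 42)))
}

# the same dataset, cleaned and spiked with 5% doublets
small_spiked <- function() {
  cached("small_spiked", spike_doublets(clean_base(small_sim()),
                                        proportion = 0.05, seed = 7))
}

# QC settings matched to the synthetic gene panel (a few hundred genes, so
# the whole-transcriptome min_genes default would empty it)
sim_qc <- list(min_genes = 100, min_umi = 1000, max_pct_mito = 25)

sim_pipeline_config <- function(dataset, ...) {
  modifyList(list(expr = dataset$expr, adt = dataset$adt,
                  contigs = dataset$contigs,
                  marker_sets = small_sim()$marker_sets, qc = sim_qc),
             list(...))
}

# an expression_matrix with prescribed per-droplet (n_genes, n_umi, pct_mito)
make_qc_matrix <- function(n_genes, n_umi, pct_mito) {
  stopifnot(length(n_genes) == length(n_umi),
            length(n_umi) == length(pct_mito))
  total_genes <- max(n_genes) + 1L
  genes <- c("MT-CO1", sprintf("G%04d", seq_len(total_genes - 1L)))
  counts <- matrix(0L, total_genes, length(n_genes),
                   dimnames = list(genes,
                                   sprintf("BC%03d", seq_along(n_genes))))
  for (i in seq_along(n_genes)) {
    mito <- round(n_umi[i] * pct_mito[i] / 100)
    rest <- n_umi[i] - mito
    k <- n_genes[i] - (mito > 0)   # non-mito genes detected
    base <- rep(1L, k)
    base[1] <- base[1] + rest - k  # dump the remainder on one gene
    if (mito > 0) counts["MT-CO1", i] <- mito
    counts[1L + seq_len(k), i] <- base
  }
  expression_matrix(counts)
}
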