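# Shared simulated fixtures, built once per test run and cached.
.fixture_env <- new.env(parent = emptyenv())

default_sim <- function(seed = 11) {
  key <- paste0("sim", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- simulate_annotation(sim_config(seed = seed))
  .fixture_env[[key]]
}

# larger gene panel (no heavy TE load) for expression-level experiments
expr_sim <- function(seed = 11, n_genes = 300) {
  key <- paste0("esim", seed, "_", n_genes)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- simulate_annotation(sim_config(
      seed = seed, n_genes = n_genes, n_chroms = 4, chrom_length = 500000,
      n_te_copies = c(DNA = 5, SINE = 5, LINE = 5, LTR = 5)))
  .fixture_env[[key]]
}

# single-gene toy annotation used by hand-computable examples
toy_gene <- function(strand = "+") {
  gene_models("gX", "chr1", strand,
              exon_starts = list(c(100L, 300L)),
              exon_ends = list(c(200L, 500L)),
              cds_start = 150L, cds_end = 450L)
}

toy_genome <- function() genome_table("chr1", 10000)
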