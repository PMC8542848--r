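# Shared fixture builders; everything is generated in code.

tiny_genotypes <- function(n = 6, m = 4, seed = 101, n_chromosomes = 2) {
  set.seed(seed)
  genotype_matrix(matrix(rbinom(n * m, 2, 0.4), n, m),
                  snp_ids = paste0("s", seq_len(m)),
                  chromosomes = rep(seq_len(n_chromosomes), length.out = m),
                  positions = seq_len(m) * 100L,
                  individual_ids = paste0("i", seq_len(n)))
}

# A small simulated dataset shared by sampler tests.
toy_dataset <- function(n = 80, m = 60, h2 = 0.5, seed = 77) {
  cfg <- sim_config(n_individuals = n, n_snps = m,
                    n_qtl_enriched = max(1L, m %/% 10L),
                    n_qtl_genomewide = max(1L, m %/% 30L),
                    heritabilities = h2, seed = seed)
  g <- simulate_genotypes(cfg)
  alloc <- assign_annotation_classes(cfg, g)
  sim <- simulate_traits(cfg, g, alloc)
  list(cfg = cfg, g = g, alloc = alloc, ph = sim$phenotypes, truth = sim$truth)
}

one_class <- function(m) class_allocation(list(all = seq_len(m)), m)

expect_partition <- function(alloc, m) {
  ix <- sort(unlist(alloc$members, use.names = FALSE))
  expect_identical(ix, seq_len(m))
}
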