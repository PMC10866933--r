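# Shared simulation configurations for tests.

# single CSR phenotype, flat signatures
csr_config <- function(cells_per_roi = 1000, n_rois = c(A = 1L),
                       roi = 700, n_markers = 4) {
  sim_config(
    phenotypes = list(phenotype_spec("P1", 1, rep(2, n_markers), 0.5,
                                     mean_cell_area = 80)),
    roi_width = roi, roi_height = roi, n_rois = n_rois,
    cells_per_roi = cells_per_roi)
}

# k equal phenotypes, block signatures separated by `sep` sd, optional
# attraction of B towards A
blocks_config <- function(n_pheno = 6, cells_per_roi = 1500,
                          n_rois = c(ICI = 12L), sep = 4, sdv = 0.6,
                          attraction = list(), markers_per_block = 4,
                          seed = 1L) {
  nm <- n_pheno * markers_per_block
  phenos <- lapply(seq_len(n_pheno), function(p) {
    mu <- rep(2, nm)
    mu[((p - 1) * markers_per_block + 1):(p * markers_per_block)] <- 2 + sep * sdv
    phenotype_spec(paste0("P", p), 1 / n_pheno, mu, sdv, mean_cell_area = 80)
  })
  sim_config(phenotypes = phenos, n_rois = n_rois,
             cells_per_roi = cells_per_roi, attraction = attraction,
             seed = seed)
}

attracted_config <- function(radius = 20, fraction = 0.5, n_pheno = 6,
                             cells_per_roi = 1500, n_rois = c(ICI = 12L),
                             seed = 1L) {
  blocks_config(n_pheno = n_pheno, cells_per_roi = cells_per_roi,
                n_rois = n_rois, seed = seed,
                attraction = list(attraction_spec("P1", "P2", radius,
                                                  fraction)))
}
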