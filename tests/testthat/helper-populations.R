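# hand-built multi-genotype populations for bottleneck/proliferation tests
make_pop <- function(c, p, abundance, cycle = 0L) {
  pop <- new_population(c[1], p[1], abundance[1], cycle = cycle)
  k <- length(c)
  pop$genotypes <- tibble::tibble(
    id = seq_len(k), parent_id = c(NA_integer_, rep(1L, k - 1L)),
    c = c, p = p, abundance = as.numeric(abundance),
    mut_id = c(NA_integer_, seq_len(k - 1L) + 0L)[seq_len(k)]
  )
  pop$pedigree <- tibble::tibble(
    id = seq_len(k), parent_id = c(NA_integer_, rep(1L, k - 1L)),
    mut_id = pop$genotypes$mut_id
  )
  if (k > 1L) {
    pop$mutations <- tibble::tibble(
      mut_id = seq_len(k - 1L), cycle_of_origin = 0L,
      c_factor = c[-1] / c[1], p_factor = p[-1] / p[1]
    )
  }
  pop$next_genotype_id <- k + 1L
  pop$next_mut_id <- k
  pop
}
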