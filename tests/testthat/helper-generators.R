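# Random, always-valid fixtures built in code. Tests that depend on the
# draws fix the seed at the call site.

randomRecords <- function(n = 1L, with_gs = TRUE, with_somo = TRUE) {
  h <- runif(n, -10, -4)
  l <- runif(n, -3, 2)
  e_n <- -500 - runif(n, 0, 500)
  energyRecords(
    id = sprintf("r%03d", seq_len(n)),
    eps_homo = h, eps_lumo = l,
    eps_somo_anion = if (with_somo) l + rnorm(n, 0, 0.05) else NA_real_,
    e_gs_nm1 = if (with_gs) e_n - h + rnorm(n, 0, 0.1) else NA_real_,
    e_gs_n = if (with_gs) e_n else NA_real_,
    e_gs_np1 = if (with_gs) e_n + l - rnorm(n, 0, 0.1) else NA_real_
  )
}

randomField <- function(counts = c(3L, 4L, 5L)) {
  axes <- diag(runif(3, 0.3, 1.2))
  atoms <- data.frame(number = c(6L, 8L), charge = c(6, 8),
                      x = runif(2), y = runif(2), z = runif(2))
  scalarField(array(rnorm(prod(counts)), dim = counts),
              origin = runif(3, -1, 1), axes = axes, atoms = atoms)
}
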