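#' @include local-fields.R
NULL

#' Specification for the synthetic-data generator
#'
#' Bundles every knob of the deterministic generator with validation.
#' The generator emulates the outputs of an upstream quantum-chemistry run
#' (frontier-orbital energies, ground-state total energies of the three
#' charge states, log texts, density grids) with known ground truth, so
#' that every pipeline stage can be exercised and recovery-tested without
#' electronic-structure software.
#'
#' Koopmans residuals are injected additively into the N-1 and N+1 total
#' energies, so the KID descriptors of a generated record equal the injected
#' residuals exactly (sharp recovery tests). Identical specs produce
#' identical outputs: the generator seeds R's Mersenne-Twister stream with
#' fixed \code{normal.kind}/\code{sample.kind} so results are stable across
#' platforms and R versions.
#'
#' @param seed Integer RNG seed.
#' @param n_molecules Number of molecules to generate.
#' @param homo_range,lumo_range HOMO/LUMO sampling intervals (eV);
#'   \code{max(homo_range)} must stay below \code{min(lumo_range)} so that
#'   every draw satisfies \code{eps_homo < eps_lumo}.
#' @param koopmans_residual_sd Standard deviation (eV) of the injected
#'   ionization/affinity residuals.
#' @param somo_offset_sd Standard deviation (eV) of the anion-SOMO offset
#'   from the neutral LUMO.
#' @param grid_counts Integer length-3 voxel counts of generated density
#'   grids.
#' @param n_atoms Number of density centers (atoms) per molecule.
#' @param electron_count Electron count N of the neutral state; generated
#'   densities integrate to N-1, N, N+1 exactly on the grid quadrature.
#' @param box_length Edge length (bohr) of the cubic grid box.
#' @return A validated \code{SyntheticSpec} list.
#' @export
syntheticSpec <- function(seed = 1L, n_molecules = 10L,
                          homo_range = c(-9, -5), lumo_range = c(-3, -0.5),
                          koopmans_residual_sd = 0.05,
                          somo_offset_sd = 0.02,
                          grid_counts = c(32L, 32L, 32L), n_atoms = 5L,
                          electron_count = 10L, box_length = 10) {
  spec <- list(seed = as.integer(seed),
               n_molecules = as.integer(n_molecules),
               homo_range = as.numeric(homo_range),
               lumo_range = as.numeric(lumo_range),
               koopmans_residual_sd = as.numeric(koopmans_residual_sd),
               somo_offset_sd = as.numeric(somo_offset_sd),
               grid_counts = as.integer(grid_counts),
               n_atoms = as.integer(n_atoms),
               electron_count = as.integer(electron_count),
               box_length = as.numeric(box_length))
  if (spec$n_molecules < 1L) stop("spec error: n_molecules must be >= 1")
  for (rng in c("homo_range", "lumo_range"))
    if (length(spec[[rng]]) != 2L || diff(spec[[rng]]) <= 0)
      stop("spec error: ", rng, " must be a non-degenerate interval")
  if (max(spec$homo_range) >= min(spec$lumo_range))
    stop("spec error: homo_range must lie strictly below lumo_range")
  if (spec$koopmans_residual_sd < 0 || spec$somo_offset_sd < 0)
    stop("spec error: residual scales must be non-negative")
  if (length(spec$grid_counts) != 3L || any(spec$grid_counts < 1L))
    stop("spec error: grid_counts must be three positive integers")
  if (spec$n_atoms < 1L || spec$electron_count < 2L)
    stop("spec error: need n_atoms >= 1 and electron_count >= 2")
  if (spec$box_length <= 0) stop("spec error: box_length must be positive")
  class(spec) <- "SyntheticSpec"
  spec
}

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

#' Generate synthetic molecule energy records with known ground truth
#'
#' Draws HOMO/LUMO pairs from the spec's intervals, assigns an arbitrary
#' neutral ground-state energy, and constructs
#' \code{e_gs_nm1 = e_gs_n - eps_homo + r_I} and
#' \code{e_gs_np1 = e_gs_n + eps_lumo - r_A} with residuals
#' \eqn{r_I, r_A \sim Normal(0, \sigma)}, so that the KID descriptors of
#' each record are exactly the injected residuals. The anion SOMO is the
#' LUMO plus a Normal offset.
#'
#' @param spec A [syntheticSpec()].
#' @return List with elements \code{records} (an [EnergyRecordSet-class])
#'   and \code{truth} (data.frame of the injected \code{residual_ji},
#'   \code{residual_ja} and \code{somo_offset} per molecule).
#' @export
generateEnergyRecords <- function(spec = syntheticSpec()) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  .withSeed(spec$seed, {
    n <- spec$n_molecules
    h <- stats::runif(n, spec$homo_range[1], spec$homo_range[2])
    l <- stats::runif(n, spec$lumo_range[1], spec$lumo_range[2])
    e_gs_n <- -1000 - stats::runif(n, 0, 100)
    r_i <- stats::rnorm(n, 0, spec$koopmans_residual_sd)
    r_a <- stats::rnorm(n, 0, spec$koopmans_residual_sd)
    somo_off <- stats::rnorm(n, 0, spec$somo_offset_sd)
    ids <- sprintf("mol%03d", seq_len(n))
    e_gs_nm1 <- e_gs_n - h + r_i
    e_gs_np1 <- e_gs_n + l - r_a
    somo <- l + somo_off
    records <- energyRecords(
      id = ids, eps_homo = h, eps_lumo = l,
      eps_somo_anion = somo,
      e_gs_nm1 = e_gs_nm1, e_gs_n = e_gs_n, e_gs_np1 = e_gs_np1,
      label = sprintf("synthetic molecule %d", seq_len(n)),
      source = sprintf("synthetic(seed=%d)", spec$seed))
    # ground truth is the *realized* residual, evaluated with the same
    # floating-point expressions the KID operations use, so recovery is
    # bit-for-bit (the drawn and realized residuals differ by ~1e-13 eV)
    list(records = records,
         truth = data.frame(id = ids,
                            residual_ji = h + e_gs_nm1 - e_gs_n,
                            residual_ja = l + e_gs_n - e_gs_np1,
                            somo_offset = somo - l,
                            stringsAsFactors = FALSE))
  })
}

#' Generate a synthetic electron-density triplet
#'
#' Places \code{n_atoms} random centers in a cubic box and builds each
#' charge state's density as a sum of isotropic Gaussian bells with
#' per-state random weights (so the three states differ spatially), then
#' rescales each state numerically so that its grid quadrature equals
#' exactly N-1, N and N+1 electrons. The normalization is performed on the
#' same quadrature used by [fieldIntegral()], so the integral identities of
#' the Fukui functions and dual descriptor hold to rounding error.
#'
#' @param spec A [syntheticSpec()].
#' @return A [DensityTriplet-class].
#' @export
generateDensityTriplet <- function(spec = syntheticSpec()) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  .withSeed(spec$seed, {
    counts <- spec$grid_counts
    L <- spec$box_length
    step <- L / counts
    axes <- diag(step, 3, 3)
    centers <- matrix(stats::runif(3 * spec$n_atoms, 0.25 * L, 0.75 * L),
                      ncol = 3)
    sigma <- stats::runif(spec$n_atoms, 0.06 * L, 0.12 * L)
    coords <- lapply(1:3, function(a) (seq_len(counts[a]) - 1L) * step[a])
    atoms <- data.frame(number = 6L, charge = 6,
                        x = centers[, 1], y = centers[, 2], z = centers[, 3])
    oneState <- function(target) {
      w <- stats::runif(spec$n_atoms, 0.5, 1.5)
      raw <- array(0, dim = counts)
      for (k in seq_len(spec$n_atoms)) {
        dx2 <- (coords[[1]] - centers[k, 1])^2
        dy2 <- (coords[[2]] - centers[k, 2])^2
        dz2 <- (coords[[3]] - centers[k, 3])^2
        raw <- raw + w[k] *
          exp(-outer(outer(dx2, dy2, "+"), dz2, "+") / (2 * sigma[k]^2))
      }
      total <- sum(raw) * prod(step)
      if (total < 1e-8)
        stop("generation error: grid too coarse to normalize the density")
      scalarField(raw * (target / total), origin = c(0, 0, 0), axes = axes,
                  atoms = atoms)
    }
    N <- spec$electron_count
    densityTriplet(oneState(N - 1), oneState(N), oneState(N + 1))
  })
}

#' Emit the minimal quantum-chemistry log dialect
#'
#' Writes a record as a small log text that [parseSimpleLog()] inverts
#' exactly on every populated field. Energies appear in hartree with 12
#' decimals; the occupied block ends at the HOMO, the virtual block starts
#' at the LUMO, and optional cation/anion sections carry the remaining
#' ground-state energies and the anion SOMO.
#'
#' @param records A one-record [EnergyRecordSet-class].
#' @return Character vector of log lines.
#' @export
generateLogText <- function(records) {
  stopifnot(is(records, "EnergyRecordSet"), length(records) == 1L)
  r <- records@data[1, ]
  hart <- function(x) sprintf("%.12f", evToHartree(x))
  out <- c(paste("MOLECULE", r$id, r$label),
           "SCF CONVERGED")
  if (!is.na(r$e_gs_n))
    out <- c(out, paste0("TOTAL ENERGY (HARTREE) = ", hart(r$e_gs_n)))
  occ <- c(r$eps_homo - 2, r$eps_homo - 1, r$eps_homo)
  virt <- c(r$eps_lumo, r$eps_lumo + 1, r$eps_lumo + 2)
  out <- c(out,
           "OCC EIGENVALUES (HARTREE):",
           paste0("  ", paste(hart(occ), collapse = "  ")),
           "VIRT EIGENVALUES (HARTREE):",
           paste0("  ", paste(hart(virt), collapse = "  ")))
  if (!is.na(r$e_gs_nm1))
    out <- c(out, paste0("CATION TOTAL ENERGY (HARTREE) = ", hart(r$e_gs_nm1)))
  if (!is.na(r$e_gs_np1))
    out <- c(out, paste0("ANION TOTAL ENERGY (HARTREE) = ", hart(r$e_gs_np1)))
  if (!is.na(r$eps_somo_anion))
    out <- c(out, paste0("ANION SOMO EIGENVALUE (HARTREE) = ",
                         hart(r$eps_somo_anion)))
  out
}
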