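#' @include energy-records.R
NULL

.requireGroundState <- function(df, cols, op) {
  miss <- Reduce(`|`, lapply(cols, function(c) is.na(df[[c]])))
  if (any(miss))
    stop("precondition error in ", op, ": fields ",
         paste(cols, collapse = ", "), " must all be present; missing for ",
         "record(s): ", paste(df$id[miss], collapse = ", "))
}

#' KID (Koopmans-in-DFT) compliance descriptors
#'
#' For a density functional that behaves according to the ionization-energy
#' and Janak theorems, the HOMO energy approximates minus the vertical
#' ionization energy and the LUMO energy minus the vertical electron
#' affinity. The KID diagnostics measure the residuals of these relations
#' from quantities computed at a single fixed geometry:
#' \deqn{J_I = \epsilon_H + E_{gs}(N-1) - E_{gs}(N)}
#' \deqn{J_A = \epsilon_L + E_{gs}(N) - E_{gs}(N+1)}
#' \deqn{J_{HL} = \sqrt{J_I^2 + J_A^2}}
#' and the extra descriptor \eqn{\Delta SL}, the anion SOMO energy minus the
#' neutral LUMO energy. All quantities are in eV; small magnitudes indicate
#' that the model chemistry is Koopmans-compliant and that frontier-orbital
#' descriptors can be trusted.
#'
#' \code{computeJI}/\code{computeJA} require the full ground-state energy
#' trio (N-1, N, N+1) to be present; \code{computeDeltaSL} requires the
#' anion SOMO.
#'
#' @param records An [EnergyRecordSet-class].
#' @return Named numeric vector (eV), one value per record.
#' @seealso [kidAssess()], [computeJHL()]
#' @export
setMethod("computeJI", "EnergyRecordSet", function(records) {
  df <- records@data
  .requireGroundState(df, c("e_gs_nm1", "e_gs_n", "e_gs_np1"), "computeJI")
  stats::setNames(df$eps_homo + df$e_gs_nm1 - df$e_gs_n, df$id)
})

#' @rdname computeJI-EnergyRecordSet-method
#' @export
setMethod("computeJA", "EnergyRecordSet", function(records) {
  df <- records@data
  .requireGroundState(df, c("e_gs_nm1", "e_gs_n", "e_gs_np1"), "computeJA")
  stats::setNames(df$eps_lumo + df$e_gs_n - df$e_gs_np1, df$id)
})

#' @rdname computeJI-EnergyRecordSet-method
#' @export
setMethod("computeDeltaSL", "EnergyRecordSet", function(records) {
  df <- records@data
  miss <- is.na(df$eps_somo_anion)
  if (any(miss))
    stop("precondition error in computeDeltaSL: eps_somo_anion missing for ",
         "record(s): ", paste(df$id[miss], collapse = ", "))
  stats::setNames(df$eps_somo_anion - df$eps_lumo, df$id)
})

#' Combined Koopmans residual
#'
#' Root-sum-of-squares of the ionization (\eqn{J_I}) and affinity
#' (\eqn{J_A}) residuals: \eqn{J_{HL} = \sqrt{J_I^2 + J_A^2}}. Even and
#' symmetric in both arguments; \code{computeJHL(a, 0) == abs(a)} exactly.
#'
#' @param ji,ja Koopmans residuals (eV), recycled to a common length.
#' @return Non-negative numeric vector (eV).
#' @export
computeJHL <- function(ji, ja) {
  stopifnot(is.finite(ji), is.finite(ja))
  sqrt(ji^2 + ja^2)
}

#' Assess Koopmans compliance per molecule
#'
#' Aggregates the KID descriptors and applies a pass rule: a molecule passes
#' when every available diagnostic is within tolerance, i.e.
#' \eqn{J_{HL} \le} \code{tolerance} (when the ground-state trio is present)
#' and \eqn{|\Delta SL| \le} \code{tolerance} (when the anion SOMO is
#' present). Records carrying neither kind of input get \code{passed = NA}.
#' Molecules are never dropped: unavailable descriptors are reported as
#' \code{NA}.
#'
#' @param records An [EnergyRecordSet-class].
#' @param tolerance Pass threshold in eV, applied independently to
#'   \eqn{J_{HL}} and \eqn{|\Delta SL|}. The default 0.15 eV is a pragmatic
#'   compliance band for well-behaved range-separated functionals.
#' @return A \code{data.frame} with columns \code{id}, \code{ji}, \code{ja},
#'   \code{jhl}, \code{delta_sl}, \code{tolerance}, \code{passed}; the
#'   tolerance is also attached as attribute \code{"tolerance"}.
#' @examples
#' kidAssess(apratoxinFixture())
#' @export
setMethod("kidAssess", "EnergyRecordSet", function(records, tolerance = 0.15) {
  stopifnot(is.numeric(tolerance), length(tolerance) == 1L, tolerance >= 0)
  df <- records@data
  has_gs <- !is.na(df$e_gs_nm1) & !is.na(df$e_gs_n) & !is.na(df$e_gs_np1)
  ji <- ifelse(has_gs, df$eps_homo + df$e_gs_nm1 - df$e_gs_n, NA_real_)
  ja <- ifelse(has_gs, df$eps_lumo + df$e_gs_n - df$e_gs_np1, NA_real_)
  jhl <- sqrt(ji^2 + ja^2)
  delta_sl <- df$eps_somo_anion - df$eps_lumo
  any_avail <- has_gs | !is.na(delta_sl)
  ok_jhl <- is.na(jhl) | jhl <= tolerance
  ok_sl <- is.na(delta_sl) | abs(delta_sl) <= tolerance
  passed <- ifelse(any_avail, ok_jhl & ok_sl, NA)
  out <- data.frame(id = df$id, ji = ji, ja = ja, jhl = jhl,
                    delta_sl = delta_sl,
                    tolerance = rep(tolerance, nrow(df)),
                    passed = passed, stringsAsFactors = FALSE)
  attr(out, "tolerance") <- tolerance
  out
})
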