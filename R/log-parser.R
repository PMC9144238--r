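#' @include energy-records.R
NULL

## The minimal quantum-chemistry log dialect understood here is the one
## emitted by generateLogText(): headers are anchored at column 1, all
## energies are in hartree, eigenvalue blocks run until a blank line or the
## next header. Full production-code logs are expected to be pre-converted.

.logBlock <- function(lines, header) {
  start <- which(lines == header)
  if (!length(start)) return(NULL)
  start <- start[[length(start)]] + 1L
  vals <- numeric(0)
  i <- start
  while (i <= length(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln) || grepl("^[A-Z]", lines[[i]])) break
    vals <- c(vals, suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]])))
    i <- i + 1L
  }
  if (anyNA(vals))
    stop("parse error: non-numeric eigenvalue under '", header, "'")
  vals
}

.logScalar <- function(lines, pattern) {
  hits <- grep(pattern, lines, value = TRUE)
  if (!length(hits)) return(NA_real_)
  # last occurrence wins (e.g. repeated SCF total-energy lines)
  as.numeric(sub(".*=\\s*", "", hits[[length(hits)]]))
}

#' Parse a minimal quantum-chemistry log
#'
#' Extracts a [EnergyRecordSet-class] record from text in the minimal log
#' dialect written by [generateLogText()]: \code{eps_homo} is the highest
#' occupied eigenvalue, \code{eps_lumo} the lowest virtual eigenvalue, and
#' \code{e_gs_n} the last neutral total-energy line. Optional cation/anion
#' total-energy lines and an anion-SOMO line populate the remaining fields.
#' All log energies are in hartree and are converted to eV.
#'
#' @param text Character vector of log lines (or a single string with
#'   embedded newlines).
#' @return An [EnergyRecordSet-class] with one record.
#' @seealso [generateLogText()]
#' @export
parseSimpleLog <- function(text) {
  lines <- unlist(strsplit(as.character(text), "\n", fixed = TRUE))
  occ <- .logBlock(lines, "OCC EIGENVALUES (HARTREE):")
  if (is.null(occ)) stop("parse error: no occupied-eigenvalue block")
  if (!length(occ)) stop("parse error: occupied-eigenvalue block is empty")
  virt <- .logBlock(lines, "VIRT EIGENVALUES (HARTREE):")
  if (is.null(virt) || !length(virt))
    stop("parse error: no virtual-eigenvalue block")
  mol <- grep("^MOLECULE ", lines, value = TRUE)
  id <- "unknown"; label <- ""
  if (length(mol)) {
    toks <- strsplit(sub("^MOLECULE\\s+", "", mol[[1]]), "\\s+")[[1]]
    id <- toks[[1]]
    if (length(toks) > 1) label <- paste(toks[-1], collapse = " ")
  }
  e_gs_n <- .logScalar(lines, "^TOTAL ENERGY \\(HARTREE\\) =")
  e_gs_nm1 <- .logScalar(lines, "^CATION TOTAL ENERGY \\(HARTREE\\) =")
  e_gs_np1 <- .logScalar(lines, "^ANION TOTAL ENERGY \\(HARTREE\\) =")
  somo <- .logScalar(lines, "^ANION SOMO EIGENVALUE \\(HARTREE\\) =")
  energyRecords(id = id, label = label,
                eps_homo = hartreeToEV(max(occ)),
                eps_lumo = hartreeToEV(min(virt)),
                eps_somo_anion = hartreeToEV(somo),
                e_gs_nm1 = hartreeToEV(e_gs_nm1),
                e_gs_n = hartreeToEV(e_gs_n),
                e_gs_np1 = hartreeToEV(e_gs_np1),
                source = "parsed log")
}
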