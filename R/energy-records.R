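#' @include AllGenerics.R
NULL

#' Construct an EnergyRecordSet
#'
#' Build a validated [EnergyRecordSet-class] from per-molecule energies given
#' in eV. Vectors are recycled to the length of \code{id}.
#'
#' @param id Character vector of unique molecule identifiers.
#' @param eps_homo,eps_lumo Neutral-system HOMO and LUMO energies (eV);
#'   mandatory, with \code{eps_homo < eps_lumo} strictly.
#' @param eps_somo_anion Optional SOMO energy of the radical anion (eV).
#' @param e_gs_nm1,e_gs_n,e_gs_np1 Optional ground-state total energies of
#'   the N-1, N and N+1 electron systems (eV).
#' @param label Free-text molecule names.
#' @param source Provenance string recorded per row.
#' @return An [EnergyRecordSet-class].
#' @examples
#' energyRecords(id = "A", eps_homo = -6.24, eps_lumo = -1.22,
#'               eps_somo_anion = -1.18)
#' @export
energyRecords <- function(id, eps_homo, eps_lumo,
                          eps_somo_anion = NA_real_,
                          e_gs_nm1 = NA_real_, e_gs_n = NA_real_,
                          e_gs_np1 = NA_real_,
                          label = "", source = "constructed") {
  n <- length(id)
  df <- data.frame(
    id = as.character(id),
    label = rep_len(as.character(label), n),
    eps_homo = rep_len(as.numeric(eps_homo), n),
    eps_lumo = rep_len(as.numeric(eps_lumo), n),
    eps_somo_anion = rep_len(as.numeric(eps_somo_anion), n),
    e_gs_nm1 = rep_len(as.numeric(e_gs_nm1), n),
    e_gs_n = rep_len(as.numeric(e_gs_n), n),
    e_gs_np1 = rep_len(as.numeric(e_gs_np1), n),
    source = rep_len(as.character(source), n),
    stringsAsFactors = FALSE
  )
  new("EnergyRecordSet", data = df)
}

#' @describeIn energyRecords Underlying data.frame (all energies in eV).
#' @param x An \code{EnergyRecordSet}.
#' @export
setMethod("recordData", "EnergyRecordSet", function(x) x@data)

#' @describeIn energyRecords Molecule identifiers.
#' @export
setMethod("recordIds", "EnergyRecordSet", function(x) x@data$id)

#' @describeIn energyRecords Named vector of HOMO energies (eV).
#' @export
setMethod("epsHOMO", "EnergyRecordSet", function(x)
  stats::setNames(x@data$eps_homo, x@data$id))

#' @describeIn energyRecords Named vector of LUMO energies (eV).
#' @export
setMethod("epsLUMO", "EnergyRecordSet", function(x)
  stats::setNames(x@data$eps_lumo, x@data$id))

#' @describeIn energyRecords Named vector of anion SOMO energies (eV, NA when
#'   unavailable).
#' @export
setMethod("epsSOMOAnion", "EnergyRecordSet", function(x)
  stats::setNames(x@data$eps_somo_anion, x@data$id))

#' @describeIn energyRecords Data.frame of the N-1/N/N+1 ground-state total
#'   energies (eV).
#' @export
setMethod("groundStateEnergies", "EnergyRecordSet", function(x)
  x@data[, c("id", "e_gs_nm1", "e_gs_n", "e_gs_np1")])

#' @export
setMethod("length", "EnergyRecordSet", function(x) nrow(x@data))

#' @export
setMethod("[", "EnergyRecordSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    idx <- match(i, x@data$id)
    if (anyNA(idx))
      stop("unknown record id(s): ", paste(i[is.na(idx)], collapse = ", "))
    i <- idx
  }
  new("EnergyRecordSet", data = x@data[i, , drop = FALSE])
})

#' @export
setMethod("show", "EnergyRecordSet", function(object) {
  df <- object@data
  cat("EnergyRecordSet with", nrow(df), "record(s) [energies in eV]\n")
  if (nrow(df)) {
    has_gs <- sum(stats::complete.cases(
      df[, c("e_gs_nm1", "e_gs_n", "e_gs_np1")]))
    cat("  HOMO range: [", format(min(df$eps_homo)), ",",
        format(max(df$eps_homo)), "]  LUMO range: [",
        format(min(df$eps_lumo)), ",", format(max(df$eps_lumo)), "]\n")
    cat("  anion SOMO present:", sum(!is.na(df$eps_somo_anion)),
        " ground-state trio present:", has_gs, "\n")
    print(utils::head(df[, c("id", "label", "eps_homo", "eps_lumo",
                             "eps_somo_anion")], 5), row.names = FALSE)
    if (nrow(df) > 5) cat("  ... and", nrow(df) - 5, "more\n")
  }
  invisible(NULL)
})

#' @export
setMethod("as.data.frame", "EnergyRecordSet",
          function(x, row.names = NULL, optional = FALSE, ...) x@data)

## ---------------------------------------------------------------------------
## Delimited-file I/O
## ---------------------------------------------------------------------------

.MANDATORY_FILE_COLUMNS <- c("id", "eps_homo", "eps_lumo")

#' Read molecule energy records from a delimited file
#'
#' Reads a CSV/TSV table with header columns \code{id}, \code{label},
#' \code{eps_homo}, \code{eps_lumo}, \code{eps_somo_anion}, \code{e_gs_nm1},
#' \code{e_gs_n}, \code{e_gs_np1}, \code{unit}. Only \code{id},
#' \code{eps_homo} and \code{eps_lumo} are mandatory; blank cells mean
#' "absent". The \code{unit} column (or the \code{unit} argument when the
#' column is missing) must be \code{"eV"} or \code{"hartree"}; hartree rows
#' are converted so that the returned records are always in eV.
#'
#' @param source Path to a delimited file, or a character vector of lines.
#' @param sep Field separator; by default inferred from the header line
#'   (tab when present, comma otherwise).
#' @param unit Default unit applied when the file has no \code{unit} column.
#' @return An [EnergyRecordSet-class] (empty for a header-only file).
#' @seealso [writeEnergyRecords()]
#' @export
readEnergyRecords <- function(source, sep = NULL, unit = "eV") {
  lines <- if (length(source) == 1L && file.exists(source))
    readLines(source) else as.character(source)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty input: no header line found")
  if (is.null(sep)) sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  df <- utils::read.table(text = lines, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE,
                          colClasses = NA)
  missing_cols <- setdiff(.MANDATORY_FILE_COLUMNS, names(df))
  if (length(missing_cols))
    stop("schema error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in setdiff(.RECORD_COLUMNS, names(df)))
    df[[col]] <- if (col == "label") rep("", nrow(df))
                 else rep(NA_real_, nrow(df))
  units <- if ("unit" %in% names(df)) tolower(trimws(df$unit))
           else rep(tolower(unit), nrow(df))
  bad_unit <- !units %in% c("ev", "hartree")
  if (any(bad_unit))
    stop("unknown energy unit(s): ", paste(unique(units[bad_unit]),
                                           collapse = ", "))
  energy_cols <- setdiff(.RECORD_COLUMNS, c("id", "label"))
  for (col in energy_cols) {
    raw <- df[[col]]
    if (is.character(raw)) raw[!nzchar(trimws(raw))] <- NA
    val <- suppressWarnings(as.numeric(raw))
    coerced <- is.na(val) & !is.na(raw)
    if (any(coerced))
      stop("non-numeric value in column '", col, "': ",
           paste(unique(raw[coerced]), collapse = ", "))
    df[[col]] <- val
    hr <- units == "hartree" & !is.na(df[[col]])
    df[[col]][hr] <- hartreeToEV(df[[col]][hr])
  }
  if (nrow(df)) {
    bad <- df$eps_homo >= df$eps_lumo
    bad[is.na(bad)] <- FALSE
    if (any(bad))
      stop("validation error: eps_homo >= eps_lumo for record(s): ",
           paste(df$id[bad], collapse = ", "))
  }
  src <- if (length(source) == 1L && file.exists(source)) source else "text"
  energyRecords(id = df$id, eps_homo = df$eps_homo, eps_lumo = df$eps_lumo,
                eps_somo_anion = df$eps_somo_anion, e_gs_nm1 = df$e_gs_nm1,
                e_gs_n = df$e_gs_n, e_gs_np1 = df$e_gs_np1,
                label = df$label, source = src)
}

#' Write molecule energy records to a delimited file
#'
#' Emits the documented column schema in eV (a \code{unit} column with value
#' \code{"eV"} is included so the file round-trips through
#' [readEnergyRecords()]).
#'
#' @param records An [EnergyRecordSet-class].
#' @param path Output file path; \code{NULL} returns the lines invisibly
#'   without writing.
#' @param sep Field separator (default comma).
#' @return Invisibly, the character vector of emitted lines.
#' @export
writeEnergyRecords <- function(records, path = NULL, sep = ",") {
  stopifnot(is(records, "EnergyRecordSet"))
  df <- records@data[, .RECORD_COLUMNS]
  df$unit <- rep("eV", nrow(df))
  con <- textConnection("out", "w", local = TRUE)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  close(con)
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}
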