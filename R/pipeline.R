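#' @include fixtures.R
NULL

#' Pipeline configuration
#'
#' Collects every knob of [runPipeline()] with validation. A configuration
#' can also be read from a YAML or JSON file with
#' [readPipelineConfig()]; fields are the argument names below.
#'
#' @param input Path to a delimited energy-record file (see
#'   [readEnergyRecords()]), or \code{NULL} when \code{records} are passed
#'   to [runPipeline()] directly.
#' @param kid_tolerance KID pass tolerance (eV), see [kidAssess()].
#' @param nucleophilicity_reference Numeric reference HOMO energy (eV) or
#'   the string \code{"calibrate"} for the packaged calibrated default.
#' @param decimals_kid,decimals_descriptors Display rounding (decimal
#'   places) of the KID and descriptor/pKa report tables; machine-readable
#'   outputs always carry full precision.
#' @param pka_intercept,pka_slope Coefficients of the hardness pKa QSAR.
#' @param output_dir Directory for report files; \code{NULL} disables
#'   writing.
#' @param formats Subset of \code{c("delimited", "structured", "markdown")}
#'   (CSV, JSON, Markdown).
#' @param seed Seed forwarded to any synthetic stage.
#' @return A validated \code{PipelineConfig} list.
#' @export
pipelineConfig <- function(input = NULL, kid_tolerance = 0.15,
                           nucleophilicity_reference = "calibrate",
                           decimals_kid = 3L, decimals_descriptors = 2L,
                           pka_intercept = 16.3088, pka_slope = 0.8268,
                           output_dir = NULL,
                           formats = c("delimited", "structured", "markdown"),
                           seed = 1L) {
  formats <- match.arg(formats, c("delimited", "structured", "markdown"),
                       several.ok = TRUE)
  stopifnot(kid_tolerance >= 0, decimals_kid >= 0, decimals_descriptors >= 0)
  if (!identical(nucleophilicity_reference, "calibrate"))
    stopifnot(is.numeric(nucleophilicity_reference),
              is.finite(nucleophilicity_reference))
  structure(list(input = input, kid_tolerance = kid_tolerance,
                 nucleophilicity_reference = nucleophilicity_reference,
                 decimals_kid = as.integer(decimals_kid),
                 decimals_descriptors = as.integer(decimals_descriptors),
                 pka_intercept = pka_intercept, pka_slope = pka_slope,
                 output_dir = output_dir, formats = formats,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' @rdname pipelineConfig
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json}
#'   configuration file.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("I/O error: cannot read config: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::fromJSON(path)
  do.call(pipelineConfig, cfg)
}

.roundCols <- function(df, digits, skip = "id") {
  for (col in setdiff(names(df), skip))
    if (is.numeric(df[[col]])) df[[col]] <- round(df[[col]], digits)
  df
}

.markdownTable <- function(df) {
  if (!nrow(df)) return(paste0("| ", paste(names(df), collapse = " | "), " |"))
  cells <- vapply(df, function(col) format(col, trim = TRUE), character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  c(paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
}

.writeTable <- function(df, display, stem, dir, formats) {
  if ("delimited" %in% formats)
    utils::write.csv(df, file.path(dir, paste0(stem, ".csv")),
                     row.names = FALSE, quote = FALSE)
  if ("structured" %in% formats)
    jsonlite::write_json(df, file.path(dir, paste0(stem, ".json")),
                         dataframe = "rows", digits = NA, na = "null")
  if ("markdown" %in% formats)
    writeLines(.markdownTable(display), file.path(dir, paste0(stem, ".md")))
}

#' Summarize electrophile/nucleophile class assignments
#'
#' @param descriptors Result of [computeGlobalDescriptors()].
#' @return List with named count vectors \code{electrophile} and
#'   \code{nucleophile} (always covering all three classes) and a
#'   \code{labels} data.frame of the per-molecule assignments.
#' @export
summarizeClasses <- function(descriptors) {
  count <- function(f) {
    f <- factor(f, levels = .CLASS_LEVELS)
    stats::setNames(as.integer(table(f)), .CLASS_LEVELS)
  }
  list(electrophile = count(descriptors$electrophile_class),
       nucleophile = count(descriptors$nucleophile_class),
       labels = descriptors[, c("id", "electrophile_class",
                                "nucleophile_class")])
}

#' Run the full reactivity-prospection pipeline
#'
#' Loads or accepts molecule energy records, assesses Koopmans compliance
#' ([kidAssess()]; molecules failing or lacking KID inputs are flagged, not
#' dropped), computes the global descriptor panel and class labels
#' ([computeGlobalDescriptors()]), predicts pKa from hardness
#' ([pkaFromHardness()]), and assembles the report bundle. When
#' \code{output_dir} is set, each table is written in every requested
#' format (full-precision CSV/JSON plus display-rounded Markdown) along
#' with a \code{run_metadata.json}; the table files are byte-deterministic
#' for identical inputs.
#'
#' @param config A [pipelineConfig()] (or path to a YAML/JSON config file).
#' @param records Optional [EnergyRecordSet-class] overriding
#'   \code{config$input}.
#' @return A \code{ReportBundle} list with elements \code{kid},
#'   \code{descriptors}, \code{pka} (full precision), \code{display}
#'   (rounded tables), \code{class_summary} and \code{metadata}.
#' @examples
#' bundle <- runPipeline(records = apratoxinFixture())
#' bundle$display$descriptors
#' @export
runPipeline <- function(config = pipelineConfig(), records = NULL) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "PipelineConfig"))
  if (is.null(records)) {
    if (is.null(config$input))
      stop("I/O error: no records given and config$input is NULL")
    if (!file.exists(config$input))
      stop("I/O error: cannot read input: ", config$input)
    records <- readEnergyRecords(config$input)
  }
  stopifnot(is(records, "EnergyRecordSet"))
  if (!length(records))
    warning("empty record list: the report tables will be empty")

  ref <- if (identical(config$nucleophilicity_reference, "calibrate"))
    defaultNucleophilicityReference()
  else nucleophilicityReference(config$nucleophilicity_reference,
                                provenance = "pipeline config")
  kid <- kidAssess(records, tolerance = config$kid_tolerance)
  desc <- computeGlobalDescriptors(records, ref = ref)
  model <- pkaModel(config$pka_intercept, config$pka_slope)
  pka <- data.frame(id = desc$id, eta = desc$eta,
                    pka_qsar = if (nrow(desc)) pkaFromHardness(desc$eta, model)
                               else numeric(0),
                    stringsAsFactors = FALSE)
  display <- list(
    kid = .roundCols(kid, config$decimals_kid),
    descriptors = .roundCols(desc, config$decimals_descriptors),
    pka = .roundCols(pka, config$decimals_descriptors)
  )
  summary <- summarizeClasses(desc)
  bundle <- structure(list(
    kid = kid, descriptors = desc, pka = pka, display = display,
    class_summary = summary,
    metadata = list(
      package_version = as.character(utils::packageVersion("cdftools")),
      n_records = length(records),
      kid_tolerance = config$kid_tolerance,
      nucleophilicity_reference = ref@epsHomoRef,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  ), class = "ReportBundle")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    .writeTable(kid, display$kid, "kid_diagnostics", config$output_dir,
                config$formats)
    .writeTable(desc, display$descriptors, "global_descriptors",
                config$output_dir, config$formats)
    .writeTable(pka, display$pka, "pka_qsar", config$output_dir,
                config$formats)
    if ("structured" %in% config$formats)
      jsonlite::write_json(
        list(electrophile = as.list(summary$electrophile),
             nucleophile = as.list(summary$nucleophile)),
        file.path(config$output_dir, "class_summary.json"),
        auto_unbox = TRUE)
    jsonlite::write_json(bundle$metadata,
                         file.path(config$output_dir, "run_metadata.json"),
                         auto_unbox = TRUE)
  }
  bundle
}

#' @export
print.ReportBundle <- function(x, ...) {
  cat("ReportBundle:", x$metadata$n_records, "molecule(s)\n")
  cat("\nKID diagnostics (tolerance ", x$metadata$kid_tolerance, " eV):\n",
      sep = "")
  print(x$display$kid, row.names = FALSE)
  cat("\nGlobal reactivity descriptors (eV; softness eV^-1):\n")
  print(x$display$descriptors, row.names = FALSE)
  cat("\npKa (hardness QSAR):\n")
  print(x$display$pka, row.names = FALSE)
  cat("\nClass counts - electrophile:",
      paste(names(x$class_summary$electrophile),
            x$class_summary$electrophile, sep = ":", collapse = " "),
      "\n             nucleophile:",
      paste(names(x$class_summary$nucleophile),
            x$class_summary$nucleophile, sep = ":", collapse = " "), "\n")
  invisible(x)
}
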